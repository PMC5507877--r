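# Library-geometry model: adapter design constraints, the n-mer size law,
# and closed-form run-planning statistics for concatemer libraries.

#' The bundled default concatemer adapter
#'
#' A 30 bp adapter with a GC fraction of exactly 0.40 (12 of 30 bases G or
#' C), no homopolymer run of 5 or more, and a large edit distance (18) to
#' its own reverse complement so that forward and reverse-complement
#' occurrences are unambiguous at the scanning thresholds used by
#' [scan_adapters()].  Shipped as a FASTA file under `extdata/`.
#'
#' @return a single character string of length 30.
#' @examples
#' default_adapter()
#' gc_fraction(default_adapter())
#' @export
default_adapter <- function() {
  fa <- system.file("extdata", "adapter_default.fa", package = "concatseq")
  read_fastx(fa, format = "fasta")$seq[1]
}

#' n-mer size law for Gibson-assembled concatemers
#'
#' An n-mer built from adapter-flanked monomers of length `x` sharing one
#' adapter copy of length `y` at every junction has expected length
#' `n * x - (n - 1) * y`: each unit beyond the first adds `x - y` bases
#' because adjacent terminal adapters merge.
#'
#' @param n number of units (positive integer, vectorised).
#' @param x monomer length in bases (fragment plus two adapters).
#' @param y adapter length in bases; requires `x >= 2 * y`.
#' @return expected n-mer length in bases.
#' @examples
#' expected_nmer_length(2:7, x = 247, y = 30)
#' @export
expected_nmer_length <- function(n, x = 247, y = 30) {
  if (any(n < 1) || any(n != as.integer(n))) abort("n must be a positive integer")
  if (any(x < 2 * y)) abort("monomer length x must be at least 2 * adapter length y")
  n * x - (n - 1) * y
}

#' Length after appending one adapter to each end
#'
#' @param core_len length of the core product in bases (vectorised).
#' @param y adapter length in bases.
#' @return `core_len + 2 * y`.
#' @examples
#' with_adapters(187, 30)  # 247
#' with_adapters(220, 30) - 220  # ligation shift of 60
#' @export
with_adapters <- function(core_len, y = 30) {
  if (any(core_len < 0) || any(y < 0)) abort("lengths must be non-negative")
  core_len + 2 * y
}

#' GC fraction of a sequence
#'
#' @param seq non-empty character string over `A,C,G,T` (ambiguous `N`
#'   bases are an error).
#' @return fraction of `G` or `C` bases, in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) abort("empty sequence has no GC fraction")
  if (!grepl("^[ACGT]+$", seq)) {
    abort("sequence must contain only A, C, G, T (N is ambiguous)")
  }
  stringr::str_count(seq, "[GC]") / nchar(seq)
}

#' Library scale-up factor for a retained sub-population
#'
#' When size selection keeps only a fraction of the concatenated library
#' (for example, the reads carrying 10 or more fragments), the input mass
#' must be multiplied by `1 / fraction_retained` for the retained
#' sub-population alone to match the original library amount.
#'
#' @param fraction_retained fraction of the library kept, in `(0, 1]`.
#' @return the input-mass multiplier.
#' @examples
#' scaleup_factor(0.079)  # ~12.7x for the ~7.9% of reads with >= 10 fragments
#' @export
scaleup_factor <- function(fraction_retained) {
  if (any(fraction_retained <= 0) || any(fraction_retained > 1)) {
    abort("fraction_retained must be in (0, 1]")
  }
  1 / fraction_retained
}

#' Concatemer library architecture
#'
#' Describes the geometry of one library design: the amplified target,
#' the constant spacers introduced by the first PCR, and the shared
#' adapter.  Derived quantities: `fragment_len = target + spacers` (the
#' unit recovered after deconcatenation) and
#' `monomer_len = fragment_len + 2 * adapter`.
#'
#' The default reproduces the model design: a 120 bp target, 67 bp of
#' total spacer split 33/34, and a 30 bp adapter, giving a 187 bp
#' fragment and a 247 bp monomer.
#'
#' @param target_len target length in bases.
#' @param spacer5_len,spacer3_len 5' and 3' spacer lengths in bases.
#' @param adapter adapter sequence (character string).
#' @return an object of class `concatseq_architecture`.
#' @examples
#' architecture()
#' @export
architecture <- function(target_len = 120, spacer5_len = 33, spacer3_len = 34,
                         adapter = default_adapter()) {
  stopifnot(target_len >= 0, spacer5_len >= 0, spacer3_len >= 0,
            is.character(adapter), length(adapter) == 1, nchar(adapter) > 0)
  fragment_len <- target_len + spacer5_len + spacer3_len
  structure(
    list(
      target_len = as.integer(target_len),
      spacer5_len = as.integer(spacer5_len),
      spacer3_len = as.integer(spacer3_len),
      adapter = toupper(adapter),
      adapter_len = nchar(adapter),
      fragment_len = as.integer(fragment_len),
      monomer_len = as.integer(fragment_len + 2L * nchar(adapter))
    ),
    class = "concatseq_architecture"
  )
}

#' @export
print.concatseq_architecture <- function(x, ...) {
  cat("<concatseq architecture>\n")
  cat("  target: ", x$target_len, " bp, spacers: ", x$spacer5_len, "/",
      x$spacer3_len, " bp, adapter: ", x$adapter_len, " bp\n", sep = "")
  cat("  fragment: ", x$fragment_len, " bp, monomer: ", x$monomer_len,
      " bp\n", sep = "")
  invisible(x)
}

#' Read an architecture from a plain key-value config file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Recognised
#' keys: `target_len`, `spacer5_len`, `spacer3_len` and `adapter` (a
#' literal sequence or the path of a FASTA file).
#'
#' @param path config file path.
#' @return a `concatseq_architecture`.
#' @export
read_architecture_config <- function(path) {
  kv <- read_keyvalue(path)
  adapter <- kv[["adapter"]] %||% default_adapter()
  if (!grepl("^[ACGTNacgtn]+$", adapter) && file.exists(adapter)) {
    adapter <- read_fastx(adapter, format = "fasta")$seq[1]
  }
  architecture(
    target_len = as.integer(kv[["target_len"]] %||% 120),
    spacer5_len = as.integer(kv[["spacer5_len"]] %||% 33),
    spacer3_len = as.integer(kv[["spacer3_len"]] %||% 34),
    adapter = adapter
  )
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  setNames(as.list(vals), keys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
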