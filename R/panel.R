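# Amplicon reference panels.  A panel holds, per amplicon, the target
# reference sequence and its flanking spacers; the simulator emits
# fragments (spacer5 + target + spacer3) and the aligner soft-clips the
# spacers back off.  Known variants are carried as a per-panel tibble in
# target coordinates (1-based).

#' Build an amplicon panel
#'
#' @param refs named character vector of target reference sequences (the
#'   amplified targets, without spacers), or a tibble with columns
#'   `amplicon_id`, `ref_seq` and optionally `spacer5`, `spacer3`.
#' @param spacer5,spacer3 spacer sequences flanking every fragment
#'   (recycled across amplicons when given as scalars).
#' @param variants optional tibble of known variants with columns
#'   `amplicon_id`, `pos` (1-based position in the target), `ref`, `alt`
#'   and optionally `af` (simulated allele frequency in `[0, 1]`).
#' @return an object of class `concatseq_panel`: a tibble of amplicons
#'   with a `variants` attribute.
#' @examples
#' panel <- amplicon_panel(c(a1 = "ACGTACGTACGT"), spacer5 = "TT", spacer3 = "GG")
#' fragment_seqs(panel)
#' @export
amplicon_panel <- function(refs, spacer5 = "", spacer3 = "", variants = NULL) {
  if (is.character(refs)) {
    if (is.null(names(refs)) || any(names(refs) == "")) {
      abort("refs must be a named character vector")
    }
    entries <- tibble(
      amplicon_id = names(refs),
      ref_seq = toupper(unname(refs)),
      spacer5 = toupper(spacer5),
      spacer3 = toupper(spacer3)
    )
  } else {
    entries <- as_tibble(refs)
    stopifnot(all(c("amplicon_id", "ref_seq") %in% names(entries)))
    if (!"spacer5" %in% names(entries)) entries$spacer5 <- toupper(spacer5)
    if (!"spacer3" %in% names(entries)) entries$spacer3 <- toupper(spacer3)
    entries$ref_seq <- toupper(entries$ref_seq)
  }
  if (anyDuplicated(entries$amplicon_id)) abort("amplicon ids must be unique")
  if (any(nchar(entries$ref_seq) == 0)) abort("reference sequences must be non-empty")
  if (!is.null(variants)) {
    variants <- as_tibble(variants)
    stopifnot(all(c("amplicon_id", "pos", "ref", "alt") %in% names(variants)))
    if (!all(variants$amplicon_id %in% entries$amplicon_id)) {
      abort("variant refers to an amplicon not in the panel")
    }
    len <- nchar(entries$ref_seq)[match(variants$amplicon_id, entries$amplicon_id)]
    if (any(variants$pos < 1 | variants$pos > len)) {
      abort("variant position outside the amplicon reference")
    }
    obs <- substr(entries$ref_seq[match(variants$amplicon_id, entries$amplicon_id)],
                  variants$pos, variants$pos)
    if (any(obs != variants$ref)) {
      abort("variant ref base does not match the panel reference")
    }
  }
  structure(entries, variants = variants, class = c("concatseq_panel", class(entries)))
}

#' @export
print.concatseq_panel <- function(x, ...) {
  cat("<concatseq panel> ", nrow(x), " amplicon(s)\n", sep = "")
  NextMethod()
}

#' Variant table of a panel
#' @param panel a `concatseq_panel`.
#' @return the variants tibble, or `NULL`.
#' @export
panel_variants <- function(panel) attr(panel, "variants")

#' Fragment sequences of a panel
#'
#' The fragment carried through concatenation and recovered by
#' deconcatenation: `spacer5 + target + spacer3`.
#'
#' @param panel a `concatseq_panel`.
#' @return named character vector of fragment sequences.
#' @export
fragment_seqs <- function(panel) {
  setNames(paste0(panel$spacer5, panel$ref_seq, panel$spacer3), panel$amplicon_id)
}

#' Generate a synthetic amplicon panel
#'
#' Random uniform-composition targets with shared random spacers, for
#' simulation studies.  Uses the current RNG stream.
#'
#' @param n_amplicons number of amplicons.
#' @param target_len target length in bases.
#' @param spacer5_len,spacer3_len spacer lengths in bases.
#' @param variants optional tibble with columns `amplicon_id`, `pos`,
#'   `alt`, `af` (the `ref` column is filled in from the generated
#'   target); or `NULL`.
#' @return a `concatseq_panel`.
#' @export
synthetic_panel <- function(n_amplicons = 4, target_len = 120,
                            spacer5_len = 33, spacer3_len = 34,
                            variants = NULL) {
  stopifnot(n_amplicons >= 1, target_len >= 1)
  ids <- sprintf("amplicon%02d", seq_len(n_amplicons))
  refs <- setNames(vapply(ids, function(i) random_dna(target_len), ""), ids)
  sp5 <- if (spacer5_len > 0) random_dna(spacer5_len) else ""
  sp3 <- if (spacer3_len > 0) random_dna(spacer3_len) else ""
  if (!is.null(variants)) {
    variants <- as_tibble(variants)
    variants$ref <- substr(refs[variants$amplicon_id], variants$pos, variants$pos)
    # ensure alt differs from the generated ref base
    same <- which(variants$alt == variants$ref)
    for (i in same) {
      variants$alt[i] <- setdiff(c("A", "C", "G", "T"), variants$ref[i])[1]
    }
  }
  amplicon_panel(refs, spacer5 = sp5, spacer3 = sp3, variants = variants)
}

#' Read an amplicon panel from FASTA plus optional annotations
#'
#' @param fasta FASTA file of target reference sequences.
#' @param meta optional tab-separated annotation file with a header and
#'   columns `amplicon_id`, `spacer5`, `spacer3` (spacer sequences) and/or
#'   variant columns `pos`, `ref`, `alt`, `af` (one row per variant;
#'   spacer columns may repeat across rows).
#' @return a `concatseq_panel`.
#' @export
read_panel <- function(fasta, meta = NULL) {
  refs <- read_fastx(fasta, format = "fasta")
  sp5 <- ""
  sp3 <- ""
  variants <- NULL
  if (!is.null(meta)) {
    m <- as_tibble(utils::read.delim(meta, colClasses = "character"))
    if ("pos" %in% names(m)) {
      variants <- dplyr::filter(m, !is.na(.data$pos), .data$pos != "")
      variants <- tibble(
        amplicon_id = variants$amplicon_id,
        pos = as.integer(variants$pos),
        ref = variants$ref,
        alt = variants$alt,
        af = if ("af" %in% names(variants)) as.numeric(variants$af) else NA_real_
      )
      if (nrow(variants) == 0) variants <- NULL
    }
    if ("spacer5" %in% names(m)) sp5 <- m$spacer5[1]
    if ("spacer3" %in% names(m)) sp3 <- m$spacer3[1]
  }
  amplicon_panel(setNames(refs$seq, refs$id), spacer5 = sp5, spacer3 = sp3,
                 variants = variants)
}
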