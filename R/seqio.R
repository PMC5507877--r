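# Sequence I/O: FASTA/FASTQ readers and writers plus elementary sequence
# operations shared by the whole pipeline.  Records travel as tibbles with
# columns id / seq / qual; parsing is delegated to Biostrings.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a FASTA or FASTQ file into a tibble
#'
#' Sequences are upper-cased on input; `N` is preserved.  Qualities are
#' returned as Sanger-scaled (offset 33) strings for FASTQ and `NA` for
#' FASTA.  Records whose quality length does not match the sequence
#' length raise a parse error naming the record index.
#'
#' @param path path to the input file.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (guess from the file
#'   extension, defaulting to FASTA).
#' @return a tibble with columns `id` (character), `seq` (upper-case
#'   character over `A,C,G,T,N`) and `qual` (character or `NA`).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "acgtn", "+", "IIIII"), fq)
#' read_fastx(fq)
#' @export
read_fastx <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_fastx_format(path)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "fastq") {
    x <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    qual <- tryCatch(as.character(S4Vectors::mcols(x)$qualities),
                     error = function(e) NULL)
    if (is.null(qual)) fastq_abort_malformed(path)
    if (length(x) == 0) qual <- character(0)
  } else {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(x))
  }
  seq <- unname(toupper(as.character(x)))
  qual <- unname(qual)
  ids <- names(x)
  if (is.null(ids)) ids <- rep("", length(x))
  # strip FASTQ/FASTA description down to the first whitespace token
  ids <- sub("\\s.*$", "", ids)
  bad <- which(!grepl("^[ACGTN]*$", seq))
  if (length(bad) > 0) {
    abort(paste0("record ", bad[1], " ('", ids[bad[1]],
                 "') contains characters outside {A,C,G,T,N}"))
  }
  if (format == "fastq") {
    mism <- which(nchar(qual) != nchar(seq))
    if (length(mism) > 0) {
      abort(paste0("record ", mism[1], " ('", ids[mism[1]],
                   "'): quality length ", nchar(qual[mism[1]]),
                   " does not match sequence length ", nchar(seq[mism[1]])))
    }
  }
  tibble(id = ids, seq = seq, qual = qual)
}

#' Write sequence records to FASTA or FASTQ
#'
#' FASTA output is unwrapped (one line per sequence).  FASTQ output
#' requires a quality string of matching length on every record and
#' refuses empty sequences.
#'
#' @param records tibble with columns `id`, `seq` and (for FASTQ) `qual`.
#' @param path output file path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_fastx <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  if (nrow(records) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (format == "fastq") {
    if (!"qual" %in% names(records) || anyNA(records$qual)) {
      abort("FASTQ output requires a non-missing 'qual' for every record")
    }
    if (any(nchar(records$qual) != nchar(records$seq))) {
      abort("quality and sequence lengths differ")
    }
    if (any(nchar(records$seq) == 0)) {
      abort("empty sequences cannot be written to FASTQ")
    }
    x <- Biostrings::BStringSet(records$seq)
    names(x) <- records$id
    Biostrings::writeXStringSet(
      x, path, format = "fastq",
      qualities = Biostrings::BStringSet(records$qual)
    )
  } else {
    x <- Biostrings::BStringSet(records$seq)
    names(x) <- records$id
    # width is capped by Biostrings at 20000; effectively unwrapped at the
    # read lengths this library produces
    Biostrings::writeXStringSet(
      x, path, format = "fasta",
      width = max(min(max(nchar(records$seq)), 20000L), 1L)
    )
  }
  invisible(path)
}

# manual pass over a FASTQ file that Biostrings could not digest, to
# name the offending record in the error message
fastq_abort_malformed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- length(lines) %/% 4
  for (i in seq_len(n_rec)) {
    rec <- lines[(4 * i - 3):(4 * i)]
    id <- sub("\\s.*$", "", sub("^@", "", rec[1]))
    if (!startsWith(rec[1], "@") || !startsWith(rec[3], "+")) {
      abort(paste0("record ", i, " ('", id, "') is not a 4-line FASTQ record"))
    }
    if (nchar(rec[4]) != nchar(rec[2])) {
      abort(paste0("record ", i, " ('", id, "'): quality length ",
                   nchar(rec[4]), " does not match sequence length ",
                   nchar(rec[2])))
    }
  }
  abort(paste0("malformed FASTQ file: ", path))
}

guess_fastx_format <- function(path) {
  p <- sub("\\.gz$", "", tolower(path))
  if (grepl("\\.(fq|fastq)$", p)) "fastq" else "fasta"
}

#' Reverse complement of nucleotide sequences
#'
#' Vectorised Watson-Crick reverse complement over the alphabet
#' `A,C,G,T,N` (`N` maps to `N`).  Any other character is an error.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @examples
#' reverse_complement(c("AAGG", "ACGT"))
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  bad <- which(!grepl("^[ACGTN]*$", seq))
  if (length(bad) > 0) {
    abort(paste0("sequence ", bad[1], " contains characters outside {A,C,G,T,N}"))
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  unname(out)
}

# uniform random DNA; uses the current RNG stream
random_dna <- function(n_bases, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n_bases, replace = TRUE), collapse = "")
}
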