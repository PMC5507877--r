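# Deconcatenation: locate adapter occurrences in each read by greedy
# windowed approximate matching (unit-cost Levenshtein, both
# orientations) and split the read into adapter and fragment intervals
# that partition it exactly.

#' Adapter-scanning parameters
#'
#' @param adapter adapter sequence.
#' @param max_edits maximum edit distance (substitutions, insertions and
#'   deletions each cost 1) for a window to be called an adapter.
#' @param relaxed_max_edits threshold used by the relaxed rescan of
#'   suspect fragments ([relaxed_rescan()]).
#' @param window_len scanning window length; defaults to the adapter
#'   length.
#' @return an object of class `concatseq_scan_params`.
#' @examples
#' scan_params(max_edits = 4)
#' @export
scan_params <- function(adapter = default_adapter(), max_edits = 4,
                        relaxed_max_edits = 6, window_len = nchar(adapter)) {
  adapter <- toupper(adapter)
  stopifnot(grepl("^[ACGT]+$", adapter))
  if (!(0 <= max_edits && max_edits <= relaxed_max_edits &&
        relaxed_max_edits < window_len)) {
    abort("need 0 <= max_edits <= relaxed_max_edits < window_len")
  }
  structure(
    list(adapter = adapter, adapter_rc = reverse_complement(adapter),
         max_edits = as.integer(max_edits),
         relaxed_max_edits = as.integer(relaxed_max_edits),
         window_len = as.integer(window_len),
         min_terminal_window = 10L),
    class = "concatseq_scan_params"
  )
}

# The per-read greedy walk lives in C++ (cs_scan): full windows are
# tested at threshold k; once fewer than window_len bases remain,
# shortened terminal windows (>= min_terminal_window bases) are tested
# against adapter prefixes of matching length at the proportionally
# scaled threshold ceiling(k * len / window_len).  On entering a
# contiguous run of qualifying positions the hit is placed at the
# run's leftmost minimum-distance position: a window shifted s bases
# off a true adapter still matches within 2*s edits, so first-qualifying
# acceptance would sit a couple of bases upstream of the adapter.

#' Scan reads for approximate adapter occurrences
#'
#' A window of `window_len` bases slides left to right along each read
#' and is compared to the adapter and its reverse complement by
#' unit-cost Levenshtein distance.  If the smaller distance is at most
#' `max_edits` the position qualifies; the hit is placed at the
#' leftmost minimum-distance position of the contiguous qualifying run
#' (a window shifted s bases off a true adapter still matches within
#' 2s edits, so the first qualifying position can precede the adapter),
#' covers one window, and scanning resumes at its end.  When the two
#' orientations tie, forward is chosen and the `tie` column records it.
#' At the right read end, shortened windows of at least 10 bases are
#' compared against the adapter prefix of matching length at the
#' proportionally scaled threshold `ceiling(max_edits * len /
#' window_len)`; reads shorter than 10 bases are not scanned.
#'
#' @param reads tibble with columns `id` and `seq` (a bare character
#'   vector or a single string is also accepted).
#' @param params a [scan_params()].
#' @param max_edits optional override of `params$max_edits`.
#' @return a tibble of hits: `read_id`, `start`, `end` (0-based
#'   half-open), `orientation` (`"forward"`/`"revcomp"`), `distance`,
#'   `tie`.  Hits within a read are ordered and non-overlapping.
#' @examples
#' p <- scan_params()
#' scan_adapters(p$adapter, p)  # exact self-match at (0, 30)
#' @export
scan_adapters <- function(reads, params = scan_params(), max_edits = NULL) {
  reads <- as_read_tibble(reads)
  k <- if (is.null(max_edits)) params$max_edits else as.integer(max_edits)
  if (nrow(reads) == 0) {
    return(tibble(read_id = character(), start = integer(), end = integer(),
                  orientation = character(), distance = integer(),
                  tie = logical()))
  }
  mats <- lapply(reads$seq, cs_scan, adapter = params$adapter,
                 adapter_rc = params$adapter_rc, k = k,
                 w = params$window_len, min_term = params$min_terminal_window)
  n_hits <- vapply(mats, nrow, 1L)
  m <- do.call(rbind, mats)
  tibble(
    read_id = rep(reads$id, n_hits),
    start = as.integer(m[, "start"]),
    end = as.integer(m[, "end"]),
    orientation = c("revcomp", "forward")[as.integer(m[, "forward"]) + 1L],
    distance = as.integer(m[, "distance"]),
    tie = as.integer(m[, "tie"]) == 1L
  )
}

as_read_tibble <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- if (length(reads) == 1) "read" else
      paste0("read", seq_along(reads))
    return(tibble(id = ids, seq = toupper(unname(reads))))
  }
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  as_tibble(reads)
}

#' Split reads into fragments at adapter hits
#'
#' Fragments are the maximal non-empty intervals of each read not
#' covered by any adapter hit; together, fragment and adapter intervals
#' partition the read.  Hits must be sorted and non-overlapping within
#' each read (as produced by [scan_adapters()]).
#'
#' @param reads tibble with columns `id` and `seq`.
#' @param hits hits tibble from [scan_adapters()].
#' @return a tibble of fragments: `fragment_id`, `read_id`, `index`
#'   (ordinal within read), `start`, `end` (0-based half-open), `seq`,
#'   `at_read_start`, `at_read_end`.
#' @export
deconcatenate <- function(reads, hits) {
  reads <- as_read_tibble(reads)
  hit_split <- split(seq_len(nrow(hits)), factor(hits$read_id, levels = reads$id))
  rid <- character(0); fs <- integer(0); fe <- integer(0)
  ridx <- integer(0); fidx <- integer(0)
  for (i in seq_len(nrow(reads))) {
    id <- reads$id[i]
    L <- nchar(reads$seq[i])
    hi <- hit_split[[i]]
    hs <- hits$start[hi]; he <- hits$end[hi]
    if (length(hi) > 1) {
      if (is.unsorted(hs) || any(hs[-1] < he[-length(he)])) {
        abort(paste0("overlapping or unsorted adapter hits in read ", id))
      }
    }
    bs <- c(0L, he)
    be <- c(hs, L)
    keep <- be > bs
    ks <- bs[keep]
    rid <- c(rid, rep(id, length(ks)))
    ridx <- c(ridx, rep(i, length(ks)))
    fidx <- c(fidx, seq_along(ks))
    fs <- c(fs, ks); fe <- c(fe, be[keep])
  }
  L_all <- nchar(reads$seq)[ridx]
  res <- tibble(
    read_id = rid, index = fidx, start = fs, end = fe,
    seq = substring(reads$seq[ridx], fs + 1L, fe),
    at_read_start = fs == 0L,
    at_read_end = fe == L_all
  )
  dplyr::mutate(res,
                fragment_id = paste0(.data$read_id, "|frag=", .data$index,
                                     "|pos=", .data$start, "-", .data$end,
                                     "|ends=", as.integer(.data$at_read_start),
                                     as.integer(.data$at_read_end)),
                .before = 1)
}

#' Scan and split a set of reads in one step
#'
#' @inheritParams scan_adapters
#' @return list with `fragments` and `adapters` (hit tibble).
#' @export
deconcat_reads <- function(reads, params = scan_params()) {
  reads <- as_read_tibble(reads)
  hits <- scan_adapters(reads, params)
  list(fragments = deconcatenate(reads, hits), adapters = hits)
}

#' Deconcatenate a FASTQ file
#'
#' Applies [scan_adapters()] and [deconcatenate()] to every read.
#' Fragment FASTQ headers encode the source read, ordinal, coordinates
#' and terminal flags as
#' `<read_id>|frag=<i>|pos=<start>-<end>|ends=<s><e>` (parse with
#' [parse_fragment_id()]).  Adapter hits are written as BED-like
#' tab-separated text (0-based half-open).
#'
#' @param in_fastq input FASTQ path.
#' @param params a [scan_params()].
#' @param out_fragments_fastq,out_adapters_tsv output paths (optional).
#' @return named list of counts: `n_reads`, `n_fragments`, `n_adapters`,
#'   with the fragment and adapter tibbles attached as `fragments` /
#'   `adapters`.
#' @export
deconcat_file <- function(in_fastq, params = scan_params(),
                          out_fragments_fastq = NULL, out_adapters_tsv = NULL) {
  reads <- read_fastx(in_fastq, format = "fastq")
  r <- deconcat_reads(reads, params)
  if (!is.null(out_fragments_fastq)) {
    qual <- strrep("?", nchar(r$fragments$seq))
    write_fastx(tibble(id = r$fragments$fragment_id, seq = r$fragments$seq,
                       qual = qual),
                out_fragments_fastq, format = "fastq")
  }
  if (!is.null(out_adapters_tsv)) {
    utils::write.table(
      r$adapters[, c("read_id", "start", "end", "orientation", "distance")],
      out_adapters_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(n_reads = nrow(reads), n_fragments = nrow(r$fragments),
       n_adapters = nrow(r$adapters),
       fragments = r$fragments, adapters = r$adapters)
}

#' Parse a fragment FASTQ identifier
#'
#' Inverse of the header encoding used by [deconcat_file()].
#'
#' @param id character vector of fragment identifiers.
#' @return tibble with `read_id`, `index`, `start`, `end`,
#'   `at_read_start`, `at_read_end`.
#' @export
parse_fragment_id <- function(id) {
  m <- stringr::str_match(
    id, "^(.*)\\|frag=(\\d+)\\|pos=(\\d+)-(\\d+)\\|ends=([01])([01])$")
  if (anyNA(m[, 1])) abort("malformed fragment identifier")
  tibble(read_id = m[, 2], index = as.integer(m[, 3]),
         start = as.integer(m[, 4]), end = as.integer(m[, 5]),
         at_read_start = m[, 6] == "1", at_read_end = m[, 7] == "1")
}
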