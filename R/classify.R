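# Fragment classification: the single-base hairpin-ligation remnants,
# the expected-size population, oversized fragments carrying truncated
# terminal adapters, and the relaxed rescan used to pre-screen chimeric
# fragments.

#' Remove fragments below a minimum length
#'
#' Single-base fragments at read ends are ligation remnants of the
#' sequencing hairpin adapters and are removed before alignment.
#'
#' @param fragments fragment tibble from [deconcatenate()].
#' @param min_len minimum retained length in bases (default 2, i.e. the
#'   1 bp fragments are removed).
#' @return list with `kept` and `removed` tibbles, original order
#'   preserved.
#' @export
filter_short <- function(fragments, min_len = 2) {
  len <- fragments$end - fragments$start
  list(kept = fragments[len >= min_len, , drop = FALSE],
       removed = fragments[len < min_len, , drop = FALSE])
}

#' Classify fragments by length
#'
#' Labels: `remnant_1bp` (length 1), `expected_size` (length within
#' `band`), `oversized` (longer than the band), `undersized_other`
#' (everything else, retained through alignment).
#'
#' @param fragments fragment tibble (or a numeric vector of lengths).
#' @param expected_len expected fragment length in bases.
#' @param band inclusive `(low, high)` length band counted as expected
#'   size; must contain `expected_len`.
#' @return the fragment tibble with a `label` column added (or a
#'   character vector when `fragments` is numeric).
#' @examples
#' classify_length(c(1, 185, 187, 250, 40))
#' @export
classify_length <- function(fragments, expected_len = 187, band = c(181, 190)) {
  if (length(band) != 2 || band[1] > band[2] ||
      expected_len < band[1] || expected_len > band[2]) {
    abort("band must be (low, high) with low <= expected_len <= high")
  }
  len <- if (is.numeric(fragments)) fragments else fragments$end - fragments$start
  label <- dplyr::case_when(
    len == 1 ~ "remnant_1bp",
    len >= band[1] & len <= band[2] ~ "expected_size",
    len > band[2] ~ "oversized",
    TRUE ~ "undersized_other"
  )
  if (is.numeric(fragments)) return(label)
  dplyr::mutate(fragments, label = label)
}

#' Detect a truncated (partial) adapter at a terminal fragment end
#'
#' Terminal fragments that are slightly longer than expected usually
#' carry the remains of a truncated terminal adapter that the scanner
#' could not call.  The fragment's leading bases (when flagged
#' `at_read_start`) and trailing bases (when `at_read_end`) are
#' compared against adapter prefixes and suffixes of lengths
#' `min_prefix` up to the full adapter length, in both orientations, at
#' the length-scaled relaxed threshold
#' `ceiling(relaxed_max_edits * len / window_len)` (so a full-length
#' adapter eroded past the scanner's limit is still recognised).
#'
#' @param fragment one-row fragment tibble (needs `seq`,
#'   `at_read_start`, `at_read_end`).
#' @param params a [scan_params()].
#' @param min_prefix smallest partial-adapter length tested; evidence
#'   from shorter remnants is statistically meaningless.
#' @return a tibble with zero or one row — the best-supported match,
#'   ranked by the edit-penalized matched length `length - 2 * distance`
#'   (an edit voids itself and one matched base), ties broken toward
#'   the longer match: `side` (`"5prime"`/`"3prime"`), `length`,
#'   `distance`, `orientation`, `part` (`"prefix"`/`"suffix"`).
#' @export
detect_partial_adapter <- function(fragment, params = scan_params(),
                                   min_prefix = 8) {
  stopifnot(nrow(fragment) == 1)
  if (!isTRUE(fragment$at_read_start) && !isTRUE(fragment$at_read_end)) {
    abort("partial adapters are only sought at read-terminal fragments")
  }
  y <- nchar(params$adapter)
  kr <- params$relaxed_max_edits
  w <- params$window_len
  seq <- fragment$seq
  best <- NULL
  consider <- function(side, len, dist, orient, part) {
    score <- len - 2 * dist
    best_score <- if (is.null(best)) -Inf else best$length - 2 * best$distance
    if (score > best_score ||
        (score == best_score && !is.null(best) && len > best$length)) {
      best <<- list(side = side, length = len, distance = dist,
                    orientation = orient, part = part)
    }
  }
  sides <- c(if (isTRUE(fragment$at_read_start)) "5prime",
             if (isTRUE(fragment$at_read_end)) "3prime")
  lens <- seq(from = min_prefix, to = min(y, nchar(seq)))
  for (len in lens) {
    kl <- ceiling(kr * len / w)
    for (side in sides) {
      probe <- if (side == "5prime") substr(seq, 1, len) else
        substr(seq, nchar(seq) - len + 1, nchar(seq))
      for (orient in c("forward", "revcomp")) {
        ad <- if (orient == "forward") params$adapter else params$adapter_rc
        for (part in c("prefix", "suffix")) {
          piece <- if (part == "prefix") substr(ad, 1, len) else
            substr(ad, y - len + 1, y)
          d <- cs_edit_distance(probe, piece, kl)
          if (d <= kl) consider(side, len, d, orient, part)
        }
      }
    }
  }
  if (is.null(best)) {
    return(tibble(side = character(), length = integer(), distance = integer(),
                  orientation = character(), part = character()))
  }
  tibble(side = best$side, length = as.integer(best$length),
         distance = as.integer(best$distance), orientation = best$orientation,
         part = best$part)
}

#' Rescan fragments for adapters at the relaxed threshold
#'
#' [scan_adapters()] semantics with `max_edits = relaxed_max_edits`
#' (default 6); used to rescue multi-aligned fragments whose junction
#' adapter carries 5-6 edits.
#'
#' @param fragments fragment tibble (columns `fragment_id`/`id` and
#'   `seq`) or character vector.
#' @param params a [scan_params()].
#' @return hits tibble as from [scan_adapters()].
#' @export
relaxed_rescan <- function(fragments, params = scan_params()) {
  if (is.data.frame(fragments) && "fragment_id" %in% names(fragments)) {
    fragments <- tibble(id = fragments$fragment_id, seq = fragments$seq)
  }
  scan_adapters(fragments, params, max_edits = params$relaxed_max_edits)
}

#' Classify all fragments and collect partial-adapter evidence
#'
#' Applies [classify_length()] to every fragment and
#' [detect_partial_adapter()] to terminal fragments labelled
#' `oversized`.
#'
#' @inheritParams classify_length
#' @param params a [scan_params()].
#' @param min_prefix passed to [detect_partial_adapter()].
#' @return the fragment tibble with columns `label`, `partial_side`,
#'   `partial_len`, `partial_distance` added.
#' @export
classify_fragments <- function(fragments, params = scan_params(),
                               expected_len = 187, band = c(181, 190),
                               min_prefix = 8) {
  out <- classify_length(fragments, expected_len, band)
  out$partial_side <- NA_character_
  out$partial_len <- NA_integer_
  out$partial_distance <- NA_integer_
  idx <- which(out$label == "oversized" & (out$at_read_start | out$at_read_end))
  for (i in idx) {
    hit <- detect_partial_adapter(out[i, ], params, min_prefix)
    if (nrow(hit) == 1) {
      out$partial_side[i] <- hit$side
      out$partial_len[i] <- hit$length
      out$partial_distance[i] <- hit$distance
    }
  }
  out
}

#' Fragment-length histogram in fixed-width bins
#'
#' @param fragments fragment tibble.
#' @param binwidth bin width in bases (default 10).
#' @return tibble with `bin_start`, `bin_end`, `n`.
#' @export
fragment_size_histogram <- function(fragments, binwidth = 10) {
  len <- fragments$end - fragments$start
  bin <- (len %/% binwidth) * binwidth
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(tibble(bin_start = bin), .data$bin_start),
                     n = dplyr::n(), .groups = "drop"),
    .data$bin_start) |>
    dplyr::mutate(bin_end = .data$bin_start + binwidth, .after = "bin_start")
}

#' Plot the fragment-size distribution
#'
#' Mirrors the run-report fragment histogram (10 bp bins) with the
#' expected-size band highlighted.
#'
#' @param fragments fragment tibble.
#' @param binwidth bin width in bases.
#' @param band expected-size band to highlight, or `NULL`.
#' @return a ggplot.
#' @export
plot_fragment_sizes <- function(fragments, binwidth = 10, band = c(181, 190)) {
  len <- tibble(len = fragments$end - fragments$start)
  p <- ggplot2::ggplot(len, ggplot2::aes(x = .data$len)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, fill = "grey30") +
    ggplot2::labs(x = "fragment length (bp)", y = "fragments",
                  title = "Deconcatenated fragment sizes") +
    ggplot2::theme_minimal()
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "steelblue")
  }
  p
}
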