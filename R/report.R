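# Run-level statistics and the end-to-end pipeline wrapper: degree of
# concatenation, on-target rate, hybrid fraction, and the histograms a
# run report carries.

#' Degree of concatenation
#'
#' The ratio of fragments (after the 1 bp filter) to reads: the
#' throughput multiplier of a concatemer library.  Reported to 2
#' decimals in run summaries; full precision returned.
#'
#' @param n_fragments,n_reads counts (vectorised); `n_reads` must be
#'   at least 1.
#' @return `n_fragments / n_reads`.
#' @examples
#' degree_of_concatenation(83678, 14739)  # 5.68
#' @export
degree_of_concatenation <- function(n_fragments, n_reads) {
  if (any(n_reads < 1)) abort("n_reads must be at least 1")
  n_fragments / n_reads
}

#' On-target rate
#'
#' The fraction of fragments with a primary alignment to the panel.
#' Reported as a percentage to 1 decimal in run summaries; returned as
#' a fraction.
#'
#' @param n_aligned,n_fragments counts (vectorised); `n_fragments`
#'   must be at least 1.
#' @return `n_aligned / n_fragments`.
#' @examples
#' on_target_rate(82008, 83678)  # 0.980...
#' @export
on_target_rate <- function(n_aligned, n_fragments) {
  if (any(n_fragments < 1)) abort("n_fragments must be at least 1")
  n_aligned / n_fragments
}

#' Assemble run-level statistics
#'
#' Cross-checks the per-stage outputs of one run and assembles the
#' summary row (reads, fragments, degree of concatenation, aligned
#' fragments, on-target rate, hybrid fraction) plus fragment-length and
#' fragments-per-read histograms.
#'
#' @param n_reads number of input reads.
#' @param fragments fragment tibble after [filter_short()] (`kept`).
#' @param adapters adapter-hit tibble.
#' @param alignments alignment tibble from [map_to_panel()].
#' @param hybrid_calls optional `calls` tibble from [call_hybrids()].
#' @return an object of class `concatseq_run_stats`.
#' @export
build_run_stats <- function(n_reads, fragments, adapters, alignments = NULL,
                            hybrid_calls = NULL) {
  stopifnot(n_reads >= 1)
  if (length(unique(fragments$read_id)) > n_reads) {
    abort("fragments reference more reads than n_reads")
  }
  n_fragments <- nrow(fragments)
  n_aligned <- NA_integer_
  otr <- NA_real_
  if (!is.null(alignments)) {
    if (!all(alignments$fragment_id %in% fragments$fragment_id)) {
      abort("alignments reference unknown fragment ids")
    }
    n_aligned <- sum(alignments$role == "primary")
    otr <- if (n_fragments > 0) on_target_rate(n_aligned, n_fragments) else NA_real_
  }
  hybrid_fraction <- NA_real_
  if (!is.null(hybrid_calls) && n_fragments > 0) {
    hybrid_fraction <- sum(hybrid_calls$hybrid) / n_fragments
  }
  summary <- tibble(
    n_reads = as.integer(n_reads),
    n_fragments = n_fragments,
    n_adapters = nrow(adapters),
    degree_of_concatenation = if (n_fragments > 0)
      degree_of_concatenation(n_fragments, n_reads) else 0,
    n_aligned = n_aligned,
    on_target_rate = otr,
    hybrid_fraction = hybrid_fraction
  )
  per_read <- dplyr::count(fragments, .data$read_id, name = "n_fragments")
  structure(
    list(summary = summary,
         fragment_length_histogram = fragment_size_histogram(fragments),
         fragments_per_read = per_read),
    class = "concatseq_run_stats"
  )
}

#' @export
print.concatseq_run_stats <- function(x, ...) {
  s <- x$summary
  cat("<concatseq run statistics>\n")
  cat(format_run_stats(x), sep = "\n")
  invisible(x)
}

#' Format run statistics the way a run table prints them
#'
#' Degree of concatenation to 2 decimals, rates as percentages to 1
#' decimal.
#'
#' @param stats a `concatseq_run_stats`.
#' @return character vector of report lines.
#' @export
format_run_stats <- function(stats) {
  s <- stats$summary
  lines <- c(
    paste0("  reads:     ", s$n_reads),
    paste0("  fragments: ", s$n_fragments),
    paste0("  adapters:  ", s$n_adapters),
    paste0("  degree of concatenation: ",
           sprintf("%.2f", s$degree_of_concatenation))
  )
  if (!is.na(s$n_aligned)) {
    lines <- c(lines,
               paste0("  aligned fragments: ", s$n_aligned),
               paste0("  on-target rate: ",
                      sprintf("%.1f%%", 100 * s$on_target_rate)))
  }
  if (!is.na(s$hybrid_fraction)) {
    lines <- c(lines, paste0("  hybrid fraction: ",
                             sprintf("%.2f%%", 100 * s$hybrid_fraction)))
  }
  lines
}

#' Write a run report as tab-separated text
#'
#' A summary row plus the fragment-length and fragments-per-read
#' histograms, each as a tab-separated block.
#'
#' @param stats a `concatseq_run_stats`.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_run_report <- function(stats, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.table(stats$summary, file.path(dir, "run_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(stats$fragment_length_histogram,
                     file.path(dir, "fragment_length_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  fpr <- dplyr::count(stats$fragments_per_read, .data$n_fragments,
                      name = "n_reads")
  utils::write.table(fpr, file.path(dir, "fragments_per_read_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @method tidy concatseq_run_stats
#' @export
tidy.concatseq_run_stats <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
                      names_to = "metric", values_to = "value",
                      values_transform = as.numeric)
}

#' @method glance concatseq_run_stats
#' @export
glance.concatseq_run_stats <- function(x, ...) x$summary

#' Fragments-per-read histogram plot
#'
#' @param object a `concatseq_run_stats`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot concatseq_run_stats
#' @export
autoplot.concatseq_run_stats <- function(object, ...) {
  ggplot2::ggplot(object$fragments_per_read,
                  ggplot2::aes(x = .data$n_fragments)) +
    ggplot2::geom_bar(fill = "grey30") +
    ggplot2::labs(x = "fragments per read", y = "reads",
                  title = "Degree of concatenation") +
    ggplot2::theme_minimal()
}

#' Run the full deconcatenation pipeline on a set of reads
#'
#' Scan, split, filter 1 bp remnants, classify, align to the panel,
#' confirm hybrids, pile up, extract allele frequencies for any panel
#' variants, and assemble run statistics.
#'
#' @param reads read tibble (`id`, `seq`) or FASTQ path.
#' @param panel an [amplicon_panel()].
#' @param params a [scan_params()].
#' @param scoring an [align_scoring()].
#' @param expected_len,band fragment-length classification settings.
#' @return an object of class `concatseq_run`: list with `fragments`,
#'   `removed`, `adapters`, `classification`, `alignments`,
#'   `hybrids`, `pileup`, `variant_calls`, `coverage`, `stats`.
#' @export
run_pipeline <- function(reads, panel, params = scan_params(),
                         scoring = align_scoring(),
                         expected_len = NULL, band = NULL) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fastx(reads, format = "auto")
  }
  reads <- as_read_tibble(reads)
  if (is.null(expected_len)) {
    expected_len <- max(nchar(fragment_seqs(panel)))
  }
  if (is.null(band)) band <- c(expected_len - 6, expected_len + 3)
  dec <- deconcat_reads(reads, params)
  flt <- filter_short(dec$fragments)
  classification <- classify_fragments(flt$kept, params, expected_len, band)
  alignments <- map_to_panel(flt$kept, panel, scoring)
  hybrids <- call_hybrids(flt$kept, alignments, params, panel, scoring)
  pile <- pileup(alignments, panel)
  variant_calls <- NULL
  if (!is.null(panel_variants(panel))) {
    variant_calls <- extract_af(pile, panel_variants(panel))
  }
  coverage <- if (any(alignments$role == "primary")) {
    amplicon_coverage(alignments)
  } else NULL
  stats <- build_run_stats(nrow(reads), flt$kept, dec$adapters, alignments,
                           hybrids$calls)
  structure(
    list(fragments = flt$kept, removed = flt$removed, adapters = dec$adapters,
         classification = classification, alignments = alignments,
         hybrids = hybrids, pileup = pile, variant_calls = variant_calls,
         coverage = coverage, stats = stats),
    class = "concatseq_run"
  )
}

#' @export
print.concatseq_run <- function(x, ...) {
  cat("<concatseq run>\n")
  cat(format_run_stats(x$stats), sep = "\n")
  invisible(x)
}

#' @method tidy concatseq_run
#' @export
tidy.concatseq_run <- function(x, ...) {
  dplyr::select(x$classification, "fragment_id", "read_id", "index",
                "start", "end", "label")
}

#' @method glance concatseq_run
#' @export
glance.concatseq_run <- function(x, ...) x$stats$summary

#' @method autoplot concatseq_run
#' @export
autoplot.concatseq_run <- function(object, ...) {
  plot_fragment_sizes(object$fragments)
}

#' Fragments-per-read bar plot for a run
#'
#' @param run a `concatseq_run` or `concatseq_run_stats`.
#' @return a ggplot.
#' @export
plot_fragments_per_read <- function(run) {
  stats <- if (inherits(run, "concatseq_run")) run$stats else run
  autoplot(stats)
}
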