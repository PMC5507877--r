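# Synthetic concatemer library simulator.  Emits consensus-level reads
# (FASTQ) plus a ground-truth sidecar that tiles every error-free read
# into adapter / fragment / remnant intervals, so every downstream stage
# can be scored against known truth.
#
# RNG contract: one global R stream, seeded once per library from
# `config$seed`.  Draw order per read: (1) unit count; (2) per unit, in
# order: amplicon index, orientation, one Bernoulli per panel variant on
# that amplicon; (3) per internal junction, in order: hybrid Bernoulli,
# then overlap length when hybrid; (4) leading-adapter truncation
# Bernoulli then length, trailing likewise; (5) leading hairpin-remnant
# Bernoulli then base, trailing likewise; (6) sequencing errors.

#' Simulator configuration
#'
#' Defaults emulate the model concatemer library: units drawn uniformly
#' from the panel, random orientation, a truncated-geometric unit-count
#' distribution (mean 5, capped at 50), ~1% total consensus error
#' (substitution 0.006, insertion 0.002, deletion 0.002 per base),
#' single-base A/T hairpin-ligation remnants at the read ends
#' (probability 0.4 per end), terminal-adapter truncation (probability
#' 0.3 per end, uniform over 1..29 retained bases), and rare
#' adapter-free hybrid junctions (probability 0.005 per junction,
#' fused over a 5-20 bp homology overlap).
#'
#' @param panel a [amplicon_panel()]; fragments are
#'   `spacer5 + target + spacer3`.
#' @param adapter adapter sequence.
#' @param n_reads number of reads to simulate.
#' @param nmer unit-count law: `nmer_fixed(n)` or
#'   `nmer_geometric(mean, max)`.
#' @param weights optional per-amplicon sampling weights (default
#'   equimolar).
#' @param orientation_prob probability a unit is reverse-complemented.
#' @param error_rates named numeric `c(sub=, ins=, del=)` per-base rates.
#' @param hairpin_remnant_prob probability of a single leading (and,
#'   independently, trailing) A-or-T remnant base.
#' @param end_truncation_prob probability each terminal adapter is
#'   truncated, retaining a uniform 1..(adapter length - 1) bases.
#' @param hybrid_prob per-junction probability of an adapter-free hybrid
#'   fusion.
#' @param seed integer seed for the library stream.
#' @return an object of class `concatseq_sim_config`.
#' @export
sim_config <- function(panel,
                       adapter = default_adapter(),
                       n_reads = 100,
                       nmer = nmer_geometric(5, 50),
                       weights = NULL,
                       orientation_prob = 0.5,
                       error_rates = c(sub = 0.006, ins = 0.002, del = 0.002),
                       hairpin_remnant_prob = 0.4,
                       end_truncation_prob = 0.3,
                       hybrid_prob = 0.005,
                       seed = 1L) {
  stopifnot(inherits(panel, "concatseq_panel"), nrow(panel) >= 1,
            n_reads >= 0, nchar(adapter) >= 2)
  probs <- c(orientation_prob, error_rates, hairpin_remnant_prob,
             end_truncation_prob, hybrid_prob)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (!all(c("sub", "ins", "del") %in% names(error_rates))) {
    abort("error_rates must be named c(sub=, ins=, del=)")
  }
  if (is.null(weights)) weights <- rep(1, nrow(panel))
  stopifnot(length(weights) == nrow(panel), all(weights >= 0), sum(weights) > 0)
  structure(
    list(panel = panel, adapter = toupper(adapter), n_reads = as.integer(n_reads),
         nmer = nmer, weights = weights / sum(weights),
         orientation_prob = orientation_prob, error_rates = error_rates,
         hairpin_remnant_prob = hairpin_remnant_prob,
         end_truncation_prob = end_truncation_prob,
         hybrid_prob = hybrid_prob, seed = as.integer(seed)),
    class = "concatseq_sim_config"
  )
}

#' Unit-count laws for the simulator
#'
#' `nmer_fixed()` gives every read exactly `n` units; `nmer_geometric()`
#' draws `1 + Geometric(1/mean)` (mean `mean`), redrawing values above
#' `max`.
#'
#' @param n fixed unit count.
#' @param mean,max mean and cap of the truncated geometric law.
#' @return a unit-count specification list.
#' @export
nmer_fixed <- function(n) {
  stopifnot(n >= 1)
  list(type = "fixed", n = as.integer(n))
}

#' @rdname nmer_fixed
#' @export
nmer_geometric <- function(mean = 5, max = 50) {
  stopifnot(mean >= 1, max >= 1)
  list(type = "geometric", mean = mean, max = as.integer(max))
}

draw_n_units <- function(nmer) {
  if (nmer$type == "fixed") return(nmer$n)
  repeat {
    n <- rgeom(1, 1 / nmer$mean) + 1L
    if (n <= nmer$max) return(n)
  }
}

#' Apply per-base sequencing errors to a sequence
#'
#' Independent per-base events: substitution (uniform over the three
#' alternative bases), deletion, and insertion of a uniform base after
#' the position.  Substitution and deletion are mutually exclusive at a
#' base; insertion is independent.  Uses the current RNG stream.
#'
#' @param seq character string.
#' @param error_rates named numeric `c(sub=, ins=, del=)`.
#' @return the edited sequence, with attribute `n_events` (number of
#'   edit events applied).
#' @export
apply_errors <- function(seq, error_rates = c(sub = 0.006, ins = 0.002, del = 0.002)) {
  stopifnot(all(error_rates >= 0), all(error_rates <= 1),
            sum(error_rates[c("sub", "del")]) <= 1)
  L <- nchar(seq)
  if (L == 0) return(structure(seq, n_events = 0L))
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  ps <- error_rates[["sub"]]; pd <- error_rates[["del"]]; pi_ <- error_rates[["ins"]]
  u <- runif(L)
  is_sub <- u < ps
  is_del <- !is_sub & u < ps + pd
  out <- bases
  if (any(is_sub)) {
    alt <- c("A", "C", "G", "T")
    for (i in which(is_sub)) {
      choices <- setdiff(alt, bases[i])
      out[i] <- choices[sample.int(length(choices), 1)]
    }
  }
  out[is_del] <- ""
  is_ins <- runif(L) < pi_
  if (any(is_ins)) {
    for (i in which(is_ins)) {
      out[i] <- paste0(out[i], c("A", "C", "G", "T")[sample.int(4, 1)])
    }
  }
  structure(paste(out, collapse = ""),
            n_events = sum(is_sub) + sum(is_del) + sum(is_ins))
}

# fast scalar reverse complement (no Biostrings object overhead)
rc1 <- function(s) {
  x <- strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]
  paste(rev(x), collapse = "")
}

# per-library precomputed context: fragment sequences in both
# orientations, oriented adapters, variant lookup
sim_context <- function(config) {
  panel <- config$panel
  frags <- fragment_seqs(panel)
  list(
    panel = panel,
    frags = unname(frags),
    frags_rc = vapply(unname(frags), rc1, ""),
    vars = panel_variants(panel),
    ad_fwd = config$adapter,
    ad_rev = rc1(config$adapter),
    sp5_len = nchar(panel$spacer5)
  )
}

# one read; uses the current RNG stream; returns list(seq, truth, n_units)
simulate_read_impl <- function(config, n_units, read_id = "read1",
                               ctx = sim_context(config)) {
  panel <- ctx$panel
  vars <- ctx$vars
  y <- nchar(config$adapter)
  ad_fwd <- ctx$ad_fwd
  ad_rev <- ctx$ad_rev

  # (2) units
  unit_seq <- character(n_units)
  unit_amp <- character(n_units)
  unit_rev <- logical(n_units)
  unit_vars <- character(n_units)
  for (i in seq_len(n_units)) {
    ai <- sample.int(nrow(panel), 1, prob = config$weights)
    unit_amp[i] <- panel$amplicon_id[ai]
    unit_rev[i] <- runif(1) < config$orientation_prob
    s <- ctx$frags[ai]
    applied <- character(0)
    if (!is.null(vars)) {
      vi <- which(vars$amplicon_id == panel$amplicon_id[ai])
      for (v in vi) {
        af <- vars$af[v]
        if (is.na(af)) af <- 0
        if (runif(1) < af) {
          off <- ctx$sp5_len[ai] + vars$pos[v]
          substr(s, off, off) <- vars$alt[v]
          applied <- c(applied, paste0(vars$amplicon_id[ai], ":", vars$pos[v],
                                       ":", vars$alt[v]))
        }
      }
    }
    if (unit_rev[i]) {
      s <- if (length(applied) == 0) ctx$frags_rc[ai] else rc1(s)
    }
    unit_seq[i] <- s
    unit_vars[i] <- paste(applied, collapse = ";")
  }

  # adapters take the orientation of the unit to their right; the
  # trailing adapter that of the last unit
  ad_rev_flag <- c(unit_rev, unit_rev[n_units])
  ad_seq <- ifelse(ad_rev_flag, ad_rev, ad_fwd)

  # (3) hybrid junctions
  hybrid <- logical(max(n_units - 1, 0))
  overlap <- integer(max(n_units - 1, 0))
  for (j in seq_len(n_units - 1)) {
    hybrid[j] <- runif(1) < config$hybrid_prob
    if (hybrid[j]) overlap[j] <- sample(5:20, 1)
  }

  # (4) terminal truncation: leading adapter keeps its last t bases,
  # trailing adapter its first t bases
  lead_trunc <- runif(1) < config$end_truncation_prob
  t_lead <- if (lead_trunc) sample.int(y - 1, 1) else y
  trail_trunc <- runif(1) < config$end_truncation_prob
  t_trail <- if (trail_trunc) sample.int(y - 1, 1) else y

  # (5) hairpin-ligation remnants
  lead_rem <- runif(1) < config$hairpin_remnant_prob
  lead_base <- if (lead_rem) c("A", "T")[sample.int(2, 1)] else NULL
  trail_rem <- runif(1) < config$hairpin_remnant_prob
  trail_base <- if (trail_rem) c("A", "T")[sample.int(2, 1)] else NULL

  # assemble pieces
  piece_seq <- character(0)
  piece_type <- character(0)
  piece_unit <- integer(0)
  piece_amp <- character(0)
  piece_orient <- character(0)
  piece_trunc <- logical(0)
  piece_hybnext <- logical(0)
  piece_vars <- character(0)
  push <- function(seq, type, unit = NA_integer_, amp = NA_character_,
                   orient = NA_character_, trunc = FALSE, hybnext = FALSE,
                   vars = "") {
    piece_seq <<- c(piece_seq, seq)
    piece_type <<- c(piece_type, type)
    piece_unit <<- c(piece_unit, unit)
    piece_amp <<- c(piece_amp, amp)
    piece_orient <<- c(piece_orient, orient)
    piece_trunc <<- c(piece_trunc, trunc)
    piece_hybnext <<- c(piece_hybnext, hybnext)
    piece_vars <<- c(piece_vars, vars)
  }

  if (lead_rem) push(lead_base, "remnant")
  lead_ad <- substr(ad_seq[1], y - t_lead + 1, y)
  push(lead_ad, "adapter",
       orient = if (ad_rev_flag[1]) "revcomp" else "forward",
       trunc = lead_trunc)
  for (i in seq_len(n_units)) {
    s <- unit_seq[i]
    if (i > 1 && hybrid[i - 1]) s <- substr(s, overlap[i - 1] + 1, nchar(s))
    push(s, "fragment", unit = i, amp = unit_amp[i],
         orient = if (unit_rev[i]) "revcomp" else "forward",
         hybnext = if (i < n_units) hybrid[i] else FALSE,
         vars = unit_vars[i])
    if (i < n_units) {
      if (!hybrid[i]) {
        push(ad_seq[i + 1], "adapter",
             orient = if (ad_rev_flag[i + 1]) "revcomp" else "forward")
      }
    } else {
      trail_ad <- substr(ad_seq[n_units + 1], 1, t_trail)
      push(trail_ad, "adapter",
           orient = if (ad_rev_flag[n_units + 1]) "revcomp" else "forward",
           trunc = trail_trunc)
    }
  }
  if (trail_rem) push(trail_base, "remnant")

  len <- nchar(piece_seq)
  end <- cumsum(len)
  start <- end - len
  clean_seq <- paste(piece_seq, collapse = "")

  # plain vectors; the caller assembles one truth tibble per library
  truth <- list(
    read_id = rep(read_id, length(piece_seq)), type = piece_type,
    start = as.integer(start), end = as.integer(end),
    unit_index = piece_unit, amplicon_id = piece_amp,
    orientation = piece_orient, truncated = piece_trunc,
    hybrid_with_next = piece_hybnext, variants = piece_vars
  )

  # (6) errors
  final_seq <- if (sum(config$error_rates) == 0) clean_seq else
    apply_errors(clean_seq, config$error_rates)
  list(seq = as.character(final_seq), clean_seq = clean_seq, truth = truth,
       n_units = n_units)
}

#' Simulate a single concatemer read
#'
#' Builds an error-free backbone `adapter + unit + adapter + ... +
#' adapter` with units drawn from the panel (each unit and its flanking
#' adapter context independently reverse-complemented), applies the
#' configured artifact events, then sequencing errors.  Uses the current
#' RNG stream; see the package vignette for the documented draw order.
#'
#' @param config a [sim_config()].
#' @param n_units number of units (overrides the configured law); `NULL`
#'   draws from `config$nmer`.
#' @param read_id identifier for the emitted read.
#' @return a list with elements `record` (one-row tibble `id/seq/qual`)
#'   and `truth` (tibble of intervals tiling the error-free read,
#'   0-based half-open).
#' @export
simulate_read <- function(config, n_units = NULL, read_id = "read1") {
  stopifnot(inherits(config, "concatseq_sim_config"))
  if (is.null(n_units)) n_units <- draw_n_units(config$nmer)
  stopifnot(n_units >= 1)
  r <- simulate_read_impl(config, n_units, read_id)
  list(
    record = tibble(id = read_id, seq = r$seq,
                    qual = strrep("?", nchar(r$seq))),
    truth = as_tibble(r$truth)
  )
}

#' Simulate a concatemer library
#'
#' Deterministic given `config$seed`: seeds the R RNG once, then draws
#' reads in order.  Read lengths of error-free, artifact-free runs sit
#' exactly on the [expected_nmer_length()] lattice.
#'
#' @param config a [sim_config()].
#' @param out_fastq,out_truth,out_summary optional output paths (FASTQ;
#'   tab-separated truth sidecar; key-value summary).
#' @return an object of class `concatseq_sim`: list with `reads`
#'   (tibble `id/seq/qual`), `truth` (interval tibble, coordinates on
#'   the error-free read), and `summary` (named list of counts).
#' @examples
#' panel <- local({set.seed(1); synthetic_panel(2)})
#' sim <- simulate_library(sim_config(panel, n_reads = 3, seed = 7))
#' sim$summary$n_reads
#' @export
simulate_library <- function(config, out_fastq = NULL, out_truth = NULL,
                             out_summary = NULL) {
  stopifnot(inherits(config, "concatseq_sim_config"))
  set.seed(config$seed)
  n <- config$n_reads
  ids <- sprintf("read%06d", seq_len(n))
  ctx <- sim_context(config)
  recs <- vector("list", n)
  truths <- vector("list", n)
  n_units <- integer(n)
  for (i in seq_len(n)) {
    k <- draw_n_units(config$nmer)
    r <- simulate_read_impl(config, k, ids[i], ctx)
    recs[[i]] <- r$seq
    truths[[i]] <- r$truth
    n_units[i] <- k
  }
  seqs <- unlist(recs, use.names = FALSE) %||% character(0)
  reads <- tibble(id = ids, seq = seqs, qual = strrep("?", nchar(seqs)))
  fields <- c("read_id", "type", "start", "end", "unit_index", "amplicon_id",
              "orientation", "truncated", "hybrid_with_next", "variants")
  truth <- tibble(!!!setNames(lapply(fields, function(f) {
    unlist(lapply(truths, `[[`, f), use.names = FALSE)
  }), fields))
  if (n == 0) {
    truth <- tibble(read_id = character(), type = character(),
                    start = integer(), end = integer(),
                    unit_index = integer(), amplicon_id = character(),
                    orientation = character(), truncated = logical(),
                    hybrid_with_next = logical(), variants = character())
  }
  summary <- list(
    n_reads = n,
    n_units_total = sum(n_units),
    mean_units_per_read = if (n > 0) mean(n_units) else NA_real_,
    total_bases = sum(nchar(reads$seq)),
    n_hybrid_junctions = sum(truth$hybrid_with_next),
    seed = config$seed
  )
  if (!is.null(out_fastq)) write_fastx(reads, out_fastq, format = "fastq")
  if (!is.null(out_truth)) write_truth(truth, out_truth)
  if (!is.null(out_summary)) {
    writeLines(paste(names(summary), unlist(summary), sep = "\t"), out_summary)
  }
  structure(list(reads = reads, truth = truth, summary = summary,
                 config = config),
            class = "concatseq_sim")
}

#' @export
print.concatseq_sim <- function(x, ...) {
  cat("<concatseq simulated library> ", x$summary$n_reads, " reads, ",
      x$summary$n_units_total, " units, ", x$summary$total_bases,
      " bases\n", sep = "")
  invisible(x)
}

#' Write / read a ground-truth sidecar
#'
#' Tab-separated, one row per interval (adapter, fragment, or remnant),
#' 0-based half-open coordinates on the error-free read.
#'
#' @param truth truth tibble as produced by [simulate_library()].
#' @param path file path.
#' @return `path` (writer) or the truth tibble (reader).
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as_tibble(utils::read.delim(path, colClasses = c(
    read_id = "character", type = "character", start = "integer",
    end = "integer", unit_index = "integer", amplicon_id = "character",
    orientation = "character", truncated = "logical",
    hybrid_with_next = "logical", variants = "character"
  )))
}

#' Read-length histogram of a simulated library
#'
#' @param object a `concatseq_sim`.
#' @param binwidth histogram bin width in bases.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot concatseq_sim
#' @export
autoplot.concatseq_sim <- function(object, binwidth = 25, ...) {
  ggplot2::ggplot(object$reads, ggplot2::aes(x = nchar(.data$seq))) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey30") +
    ggplot2::labs(x = "read length (bp)", y = "reads",
                  title = "Simulated read-length distribution") +
    ggplot2::theme_minimal()
}
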