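# Independent oracles and fixture builders shared across the suite.
# The scan oracle re-implements the declared scanning semantics from
# scratch on top of utils::adist (exhaustive per-position generalized
# Levenshtein), independent of the package's C++ kernel and scan loop.

oracle_scan <- function(seq, params, k) {
  w <- params$window_len
  L <- nchar(seq)
  minw <- 10L
  empty <- tibble::tibble(start = integer(), end = integer(),
                          orientation = character(), distance = integer())
  if (L < minw) return(empty)
  n_full <- max(L - w + 1L, 0L)
  pos <- 0:(L - minw)                      # candidate 0-based starts
  full <- pos < n_full
  dist_f <- dist_r <- rep(NA_integer_, length(pos))
  thr <- integer(length(pos))
  if (any(full)) {
    wins <- substring(seq, pos[full] + 1L, pos[full] + w)
    dist_f[full] <- as.integer(utils::adist(wins, params$adapter))
    dist_r[full] <- as.integer(utils::adist(wins, params$adapter_rc))
    thr[full] <- k
  }
  if (any(!full)) {
    ps <- pos[!full]
    lens <- L - ps
    wins <- substring(seq, ps + 1L, L)
    dist_f[!full] <- mapply(function(wn, l) {
      as.integer(utils::adist(wn, substr(params$adapter, 1, l)))
    }, wins, lens)
    dist_r[!full] <- mapply(function(wn, l) {
      as.integer(utils::adist(wn, substr(params$adapter_rc, 1, l)))
    }, wins, lens)
    thr[!full] <- ceiling(k * lens / w)
  }
  dmin <- pmin(dist_f, dist_r)
  ok <- dmin <= thr
  hits <- list()
  p <- 0L
  last <- max(pos)
  while (p <= last) {
    if (!ok[p + 1L]) {
      p <- p + 1L
      next
    }
    best <- p
    q <- p + 1L
    while (q <= last && q < p + w && ok[q + 1L]) {
      if (dmin[q + 1L] < dmin[best + 1L]) best <- q
      q <- q + 1L
    }
    end <- if (best < n_full) best + w else L
    hits[[length(hits) + 1L]] <- tibble::tibble(
      start = best, end = end,
      orientation = if (dist_f[best + 1L] <= dist_r[best + 1L]) "forward"
                    else "revcomp",
      distance = dmin[best + 1L])
    p <- end
  }
  if (length(hits) == 0) empty else dplyr::bind_rows(hits)
}

# apply exactly n_ops random edit operations (sub/ins/del) to a sequence
mutate_edits <- function(seq, n_ops) {
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (i in seq_len(n_ops)) {
    op <- sample(c("sub", "ins", "del"), 1)
    p <- sample(length(b), 1)
    if (op == "sub") {
      b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
    } else if (op == "ins") {
      b <- append(b, sample(c("A", "C", "G", "T"), 1), after = p)
    } else if (length(b) > 1) {
      b <- b[-p]
    }
  }
  paste(b, collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# simulator config with all artifact and error channels off
clean_config <- function(panel, ...) {
  sim_config(panel, error_rates = c(sub = 0, ins = 0, del = 0),
             hairpin_remnant_prob = 0, end_truncation_prob = 0,
             hybrid_prob = 0, ...)
}

# true-interval key "read_id:start-end" sets for comparison with truth
interval_key <- function(df) paste0(df$read_id, ":", df$start, "-", df$end)

# mark deconcatenated fragments that span a true hybrid junction
truth_hybrid_flags <- function(fragments, truth) {
  tj <- truth[truth$type == "fragment" & truth$hybrid_with_next, , drop = FALSE]
  flag <- logical(nrow(fragments))
  for (i in seq_len(nrow(tj))) {
    flag <- flag | (fragments$read_id == tj$read_id[i] &
                      fragments$start <= tj$start[i] &
                      fragments$end > tj$end[i])
  }
  flag
}
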