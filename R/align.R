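# Fragment-to-panel alignment with spacer soft-clipping, primary /
# secondary role assignment (the SAM 0/16/256/272 convention), hybrid
# confirmation, pileups and allele-frequency extraction.

#' Alignment scoring parameters
#'
#' Defaults: match +2, mismatch -3, affine gaps costing
#' `gap_open + g * gap_extend` for a gap of `g` bases.  `N` scores 0
#' against everything.
#'
#' @param match,mismatch,gap_open,gap_extend scoring parameters
#'   (`gap_open`/`gap_extend` as non-negative costs).
#' @return a list of class `concatseq_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  mat <- matrix(as.numeric(mismatch), 5, 5,
                dimnames = list(VALID_BASES, VALID_BASES))
  diag(mat) <- match
  mat["N", ] <- 0
  mat[, "N"] <- 0
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = mat),
            class = "concatseq_scoring")
}

# batch local alignment of many queries against one reference; returns a
# tibble in pattern (query-as-given) coordinates, 1-based closed
align_batch <- function(queries, ref, scoring) {
  stopifnot(length(queries) >= 1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  aq <- as.character(Biostrings::pattern(aln))
  ar <- as.character(Biostrings::subject(aln))
  ncols <- nchar(aq)
  tibble(
    score = Biostrings::score(aln),
    p_start = Biostrings::start(Biostrings::pattern(aln)),
    p_end = Biostrings::end(Biostrings::pattern(aln)),
    r_start = Biostrings::start(Biostrings::subject(aln)),
    r_end = Biostrings::end(Biostrings::subject(aln)),
    identity = ifelse(ncols > 0, Biostrings::nmatch(aln) / ncols, 0),
    aligned_query = aq,
    aligned_ref = ar
  )
}

#' Semi-global alignment of one query against one reference
#'
#' Local-in-query alignment: the query ends (for example, the constant
#' spacers flanking a fragment) are clipped without penalty, mirroring
#' soft-clipping.  Coordinates are 0-based half-open; `aligned_query`
#' and `aligned_ref` are the gapped alignment strings.
#'
#' @param query,ref nucleotide strings.
#' @param scoring an [align_scoring()].
#' @return a one-row tibble: `score`, `query_start`, `query_end`,
#'   `ref_start`, `ref_end`, `clipped5`, `clipped3`, `identity`,
#'   `aligned_query`, `aligned_ref`.
#' @examples
#' semiglobal_align("TTTTACGTACGTTTT", "ACGTACGT")
#' @export
semiglobal_align <- function(query, ref, scoring = align_scoring()) {
  stopifnot(nchar(query) > 0, nchar(ref) > 0)
  b <- align_batch(query, ref, scoring)
  tibble(
    score = b$score,
    query_start = b$p_start - 1L, query_end = b$p_end,
    ref_start = b$r_start - 1L, ref_end = b$r_end,
    clipped5 = b$p_start - 1L, clipped3 = nchar(query) - b$p_end,
    identity = b$identity,
    aligned_query = b$aligned_query, aligned_ref = b$aligned_ref
  )
}

as_fragment_tibble <- function(fragments) {
  if (is.character(fragments)) {
    ids <- names(fragments)
    if (is.null(ids)) ids <- paste0("fragment", seq_along(fragments))
    return(tibble(fragment_id = ids, seq = toupper(unname(fragments))))
  }
  stopifnot(is.data.frame(fragments), "seq" %in% names(fragments))
  f <- as_tibble(fragments)
  if (!"fragment_id" %in% names(f)) {
    f$fragment_id <- paste0("fragment", seq_len(nrow(f)))
  }
  f
}

#' Map fragments to an amplicon panel
#'
#' Every fragment is aligned (both orientations) against every amplicon
#' by local-in-query alignment.  An alignment passes when its identity
#' is at least `min_identity` and it covers at least `min_ref_cover` of
#' the reference.  The best passing alignment is the fragment's primary
#' record; the query flanks left uncovered by it (at least
#' `min_new_query` bases) are then re-aligned against the panel, and
#' passing flank alignments become secondary records — the signature of
#' hybrid (adapter-free fused) fragments.  Fragments with no passing
#' alignment are off-target and absent from the result.
#'
#' @param fragments fragment tibble (columns `fragment_id`, `seq`) or a
#'   character vector.
#' @param panel an [amplicon_panel()].
#' @param scoring an [align_scoring()].
#' @param min_identity minimum identity over alignment columns.
#' @param min_ref_cover minimum aligned fraction of the reference.
#' @param min_new_query minimum uncovered-flank length re-examined for
#'   secondary alignments.
#' @param max_rounds cap on flank re-alignment rounds.
#' @return alignment tibble: `fragment_id`, `amplicon_id`, `orientation`,
#'   `role` (`"primary"`/`"secondary"`), `flag` (0/16/256/272), `score`,
#'   `identity`, `ref_start`, `ref_end`, `query_start`, `query_end`
#'   (0-based half-open, query coordinates on the original fragment),
#'   `clipped5`, `clipped3`, `aligned_query`, `aligned_ref`.
#' @export
map_to_panel <- function(fragments, panel, scoring = align_scoring(),
                         min_identity = 0.8, min_ref_cover = 0.5,
                         min_new_query = 25, max_rounds = 6) {
  fragments <- as_fragment_tibble(fragments)
  stopifnot(inherits(panel, "concatseq_panel"), nrow(panel) >= 1)
  if (anyDuplicated(fragments$fragment_id)) {
    abort("fragment ids must be unique")
  }
  results <- list()
  frag_len <- setNames(nchar(fragments$seq), fragments$fragment_id)
  # work items: sub-intervals of fragments still unexplained
  work <- tibble(fragment_id = fragments$fragment_id,
                 sub_start = 0L, seq = fragments$seq)
  round <- 0L
  while (nrow(work) > 0 && round < max_rounds) {
    round <- round + 1L
    role <- if (round == 1L) "primary" else "secondary"
    cand <- vector("list", 2L * nrow(panel))
    ci <- 0L
    for (a in seq_len(nrow(panel))) {
      ref <- panel$ref_seq[a]
      for (orient in c("forward", "revcomp")) {
        q <- if (orient == "forward") work$seq else reverse_complement(work$seq)
        b <- align_batch(q, ref, scoring)
        m <- nchar(work$seq)
        q0s_local <- ifelse(rep(orient == "forward", nrow(b)),
                            b$p_start - 1L, m - b$p_end)
        q0e_local <- ifelse(rep(orient == "forward", nrow(b)),
                            b$p_end, m - b$p_start + 1L)
        ci <- ci + 1L
        cand[[ci]] <- dplyr::mutate(
          b,
          fragment_id = work$fragment_id,
          work_index = seq_len(nrow(work)),
          amplicon_id = panel$amplicon_id[a],
          orientation = orient,
          ref_len = nchar(ref),
          query_start = work$sub_start + q0s_local,
          query_end = work$sub_start + q0e_local
        )
      }
    }
    cand <- dplyr::bind_rows(cand)
    cand <- dplyr::filter(
      cand,
      .data$identity >= min_identity,
      (.data$r_end - .data$r_start + 1) / .data$ref_len >= min_ref_cover)
    if (nrow(cand) == 0) break
    # deterministic best per work item: score, then panel order, then forward
    cand <- dplyr::arrange(cand, .data$work_index, dplyr::desc(.data$score),
                           match(.data$amplicon_id, panel$amplicon_id),
                           .data$orientation)
    best <- dplyr::slice_head(dplyr::group_by(cand, .data$work_index), n = 1)
    best <- dplyr::ungroup(best)
    fl <- frag_len[best$fragment_id]
    results[[round]] <- tibble(
      fragment_id = best$fragment_id,
      amplicon_id = best$amplicon_id,
      orientation = best$orientation,
      role = role,
      flag = flag_from_role(role, best$orientation),
      score = best$score,
      identity = best$identity,
      ref_start = best$r_start - 1L, ref_end = best$r_end,
      query_start = best$query_start, query_end = best$query_end,
      clipped5 = best$query_start,
      clipped3 = as.integer(fl - best$query_end),
      aligned_query = best$aligned_query,
      aligned_ref = best$aligned_ref
    )
    # uncovered flanks become the next round's work
    wseq <- work$seq[best$work_index]
    wstart <- work$sub_start[best$work_index]
    lstart <- wstart
    lend <- best$query_start
    rstart <- best$query_end
    rend <- wstart + nchar(wseq)
    nxt <- dplyr::bind_rows(
      tibble(fragment_id = best$fragment_id, sub_start = lstart,
             seq = substr(wseq, 1, lend - lstart))[lend - lstart >= min_new_query, ],
      tibble(fragment_id = best$fragment_id, sub_start = rstart,
             seq = substring(wseq, rstart - wstart + 1))[rend - rstart >= min_new_query, ]
    )
    work <- nxt
  }
  out <- dplyr::bind_rows(results)
  if (nrow(out) == 0) {
    return(tibble(fragment_id = character(), amplicon_id = character(),
                  orientation = character(), role = character(),
                  flag = integer(), score = numeric(), identity = numeric(),
                  ref_start = integer(), ref_end = integer(),
                  query_start = integer(), query_end = integer(),
                  clipped5 = integer(), clipped3 = integer(),
                  aligned_query = character(), aligned_ref = character()))
  }
  dplyr::arrange(out, match(.data$fragment_id, fragments$fragment_id),
                 .data$role, .data$query_start)
}

#' SAM flag from alignment role and orientation
#'
#' The bijection primary/forward = 0, primary/revcomp = 16,
#' secondary/forward = 256, secondary/revcomp = 272.
#'
#' @param role `"primary"` or `"secondary"`.
#' @param orientation `"forward"` or `"revcomp"`.
#' @return integer flag(s).
#' @export
flag_from_role <- function(role, orientation) {
  stopifnot(all(role %in% c("primary", "secondary")),
            all(orientation %in% c("forward", "revcomp")))
  as.integer(ifelse(role == "secondary", 256L, 0L) +
               ifelse(orientation == "revcomp", 16L, 0L))
}

#' @rdname flag_from_role
#' @param flag integer SAM flag in `{0, 16, 256, 272}`.
#' @export
role_from_flag <- function(flag) {
  stopifnot(all(flag %in% c(0L, 16L, 256L, 272L)))
  tibble(
    role = ifelse(bitwAnd(as.integer(flag), 256L) > 0L, "secondary", "primary"),
    orientation = ifelse(bitwAnd(as.integer(flag), 16L) > 0L, "revcomp", "forward")
  )
}

#' Confirm hybrid fragments and rescue missed junction adapters
#'
#' A fragment with secondary alignments is a candidate chimera.  The
#' query gap between each pair of neighbouring aligned intervals is
#' rescanned for the adapter at the relaxed threshold
#' (`params$relaxed_max_edits`): if an adapter is found the fragment is
#' *rescued* — the junction was a real, heavily-eroded adapter — and is
#' re-split at the hit(s) and re-mapped; otherwise the fragment is
#' called a *hybrid* (units fused outside the adapter region).
#'
#' @param fragments fragment tibble with `fragment_id` and `seq`.
#' @param alignments alignment tibble from [map_to_panel()].
#' @param params a [scan_params()].
#' @param panel panel used to re-map rescued sub-fragments (optional;
#'   re-mapping is skipped when `NULL`).
#' @param scoring scoring for the re-mapping.
#' @return list with `calls` (tibble `fragment_id`, `multi_aligned`,
#'   `junction_adapter`, `rescued`, `hybrid`), `rescued_fragments`
#'   (re-split pieces) and `rescued_alignments`.
#' @export
call_hybrids <- function(fragments, alignments, params = scan_params(),
                         panel = NULL, scoring = align_scoring()) {
  fragments <- as_fragment_tibble(fragments)
  w <- params$window_len
  multi <- unique(alignments$fragment_id[alignments$role == "secondary"])
  calls <- tibble(
    fragment_id = fragments$fragment_id,
    multi_aligned = fragments$fragment_id %in% multi,
    junction_adapter = FALSE, rescued = FALSE, hybrid = FALSE
  )
  resc_frags <- list()
  for (fid in multi) {
    seq <- fragments$seq[fragments$fragment_id == fid]
    L <- nchar(seq)
    ints <- alignments[alignments$fragment_id == fid, c("query_start", "query_end")]
    ints <- ints[order(ints$query_start), ]
    hits <- NULL
    for (j in seq_len(nrow(ints) - 1)) {
      js <- max(0L, ints$query_end[j] - w)
      je <- min(L, ints$query_start[j + 1] + w)
      if (je - js < params$min_terminal_window) next
      h <- scan_adapters(setNames(substr(seq, js + 1, je), fid), params,
                         max_edits = params$relaxed_max_edits)
      if (nrow(h) > 0) {
        h$start <- h$start + js
        h$end <- h$end + js
        hits <- dplyr::bind_rows(hits, h)
      }
    }
    i <- which(calls$fragment_id == fid)
    if (!is.null(hits) && nrow(hits) > 0) {
      calls$junction_adapter[i] <- TRUE
      calls$rescued[i] <- TRUE
      # re-split at the relaxed hits
      bs <- c(0L, hits$end)
      be <- c(hits$start, L)
      keep <- be > bs
      resc_frags[[fid]] <- tibble(
        fragment_id = paste0(fid, "|resplit=", seq_len(sum(keep))),
        parent_id = fid,
        start = bs[keep], end = be[keep],
        seq = substring(seq, bs[keep] + 1, be[keep])
      )
    } else {
      calls$hybrid[i] <- TRUE
    }
  }
  rescued_fragments <- dplyr::bind_rows(resc_frags)
  rescued_alignments <- NULL
  if (!is.null(panel) && length(resc_frags) > 0) {
    rescued_alignments <- map_to_panel(
      tibble(fragment_id = rescued_fragments$fragment_id,
             seq = rescued_fragments$seq),
      panel, scoring)
  }
  list(calls = calls, rescued_fragments = rescued_fragments,
       rescued_alignments = rescued_alignments)
}

#' Per-position base-count table from primary alignments
#'
#' Query bases are mapped to reference positions through the alignment
#' path; insertions relative to the reference are ignored and deletions
#' are counted in the `del` channel.  All positions of every panel
#' amplicon are reported (zero counts included), so depth-0 positions
#' are visible downstream.
#'
#' @param alignments alignment tibble from [map_to_panel()]; only
#'   `role == "primary"` records contribute.
#' @param panel the [amplicon_panel()] aligned against.
#' @return tibble: `amplicon_id`, `pos` (1-based), `ref`, `A`, `C`, `G`,
#'   `T`, `del`, `depth`.
#' @export
pileup <- function(alignments, panel) {
  stopifnot(inherits(panel, "concatseq_panel"))
  prim <- alignments[alignments$role == "primary", , drop = FALSE]
  qs <- strsplit(prim$aligned_query, "", fixed = TRUE)
  rs <- strsplit(prim$aligned_ref, "", fixed = TRUE)
  pos_l <- vector("list", nrow(prim))
  base_l <- vector("list", nrow(prim))
  n_obs <- integer(nrow(prim))
  for (i in seq_len(nrow(prim))) {
    qc <- qs[[i]]
    on_ref <- rs[[i]] != "-"
    pos <- cumsum(on_ref) + prim$ref_start[i]  # 1-based ref position
    pos_l[[i]] <- pos[on_ref]
    b <- qc[on_ref]
    b[b == "-"] <- "del"
    base_l[[i]] <- b
    n_obs[i] <- sum(on_ref)
  }
  obs <- tibble(
    amplicon_id = rep(prim$amplicon_id, n_obs),
    pos = unlist(pos_l, use.names = FALSE) %||% integer(0),
    base = unlist(base_l, use.names = FALSE) %||% character(0)
  )
  grid <- dplyr::bind_rows(purrr::map(seq_len(nrow(panel)), function(a) {
    tibble(amplicon_id = panel$amplicon_id[a],
           pos = seq_len(nchar(panel$ref_seq[a])),
           ref = strsplit(panel$ref_seq[a], "", fixed = TRUE)[[1]])
  }))
  counts <- if (nrow(obs) > 0) {
    tidyr::pivot_wider(
      dplyr::count(obs, .data$amplicon_id, .data$pos, .data$base),
      names_from = "base", values_from = "n", values_fill = 0L)
  } else {
    tibble(amplicon_id = character(), pos = integer())
  }
  for (b in c("A", "C", "G", "T", "del")) {
    if (!b %in% names(counts)) counts[[b]] <- 0L
  }
  out <- dplyr::left_join(grid, counts[, c("amplicon_id", "pos", "A", "C", "G", "T", "del")],
                          by = c("amplicon_id", "pos"))
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(c("A", "C", "G", "T", "del")),
                                          ~ tidyr::replace_na(.x, 0L)))
  dplyr::mutate(out, depth = .data$A + .data$C + .data$G + .data$T + .data$del)
}

#' Extract allele frequencies at known variant positions
#'
#' @param pileup_tbl pileup tibble from [pileup()].
#' @param variants tibble with `amplicon_id`, `pos`, `ref`, `alt`.
#' @return tibble: `amplicon_id`, `pos`, `ref`, `alt`, `alt_count`,
#'   `depth`, `af` (`NA` and `no_coverage = TRUE` at depth 0).
#' @export
extract_af <- function(pileup_tbl, variants) {
  variants <- as_tibble(variants)
  stopifnot(all(c("amplicon_id", "pos", "ref", "alt") %in% names(variants)))
  key <- dplyr::left_join(
    variants[, c("amplicon_id", "pos", "ref", "alt")],
    pileup_tbl, by = c("amplicon_id", "pos"), suffix = c("", ".pile"))
  if (anyNA(key$depth)) {
    abort("variant position outside the pileup (amplicon bounds)")
  }
  alt_count <- vapply(seq_len(nrow(key)), function(i) {
    b <- key$alt[i]
    if (!b %in% c("A", "C", "G", "T")) abort("alt base must be one of A,C,G,T")
    as.integer(key[[b]][i])
  }, integer(1))
  dplyr::mutate(
    tibble(amplicon_id = key$amplicon_id, pos = key$pos, ref = key$ref,
           alt = key$alt, alt_count = alt_count, depth = key$depth),
    af = ifelse(.data$depth > 0, .data$alt_count / .data$depth, NA_real_),
    no_coverage = .data$depth == 0
  )
}

#' Per-amplicon coverage fractions
#'
#' The number of primary-aligned fragments per amplicon divided by the
#' total number of aligned fragments; fractions sum to 1.
#'
#' @param alignments alignment tibble from [map_to_panel()].
#' @return tibble: `amplicon_id`, `n`, `fraction`.
#' @export
amplicon_coverage <- function(alignments) {
  prim <- alignments[alignments$role == "primary", , drop = FALSE]
  if (nrow(prim) == 0) abort("no aligned fragments")
  dplyr::mutate(dplyr::count(prim, .data$amplicon_id),
                fraction = .data$n / sum(.data$n))
}

#' Plot per-amplicon coverage fractions
#'
#' @param coverage tibble from [amplicon_coverage()] (or an alignment
#'   tibble, converted on the fly).
#' @return a ggplot.
#' @export
plot_amplicon_coverage <- function(coverage) {
  if (!"fraction" %in% names(coverage)) coverage <- amplicon_coverage(coverage)
  ggplot2::ggplot(coverage,
                  ggplot2::aes(x = .data$amplicon_id, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = NULL, y = "fraction of aligned fragments",
                  title = "Amplicon coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write alignments as minimal SAM
#'
#' Header plus one record per alignment; flags 0/16/256/272, CIGAR with
#' soft-clips, `SEQ` given in aligned orientation when fragment
#' sequences are supplied.
#'
#' @param alignments alignment tibble from [map_to_panel()].
#' @param panel the [amplicon_panel()] (for `@SQ` lines).
#' @param path output path.
#' @param fragments optional fragment tibble supplying sequences.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, panel, path, fragments = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", panel$amplicon_id, "\tLN:", nchar(panel$ref_seq)),
           "@PG\tID:concatseq\tPN:concatseq")
  seqs <- NULL
  if (!is.null(fragments)) {
    fragments <- as_fragment_tibble(fragments)
    seqs <- setNames(fragments$seq, fragments$fragment_id)
  }
  recs <- character(nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    al <- alignments[i, ]
    fl <- if (!is.null(seqs)) nchar(seqs[[al$fragment_id]]) else
      al$query_end + al$clipped3
    rev <- al$orientation == "revcomp"
    clip5 <- if (rev) fl - al$query_end else al$query_start
    clip3 <- if (rev) al$query_start else fl - al$query_end
    qc <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
    rc_ <- strsplit(al$aligned_ref, "", fixed = TRUE)[[1]]
    op <- ifelse(rc_ == "-", "I", ifelse(qc == "-", "D", "M"))
    r <- rle(op)
    cigar <- paste0(
      if (clip5 > 0) paste0(clip5, "S") else "",
      paste0(r$lengths, r$values, collapse = ""),
      if (clip3 > 0) paste0(clip3, "S") else "")
    seq_out <- "*"
    if (!is.null(seqs)) {
      s <- seqs[[al$fragment_id]]
      seq_out <- if (rev) reverse_complement(s) else s
    }
    recs[i] <- paste(al$fragment_id, al$flag, al$amplicon_id,
                     al$ref_start + 1L,
                     if (al$role == "primary") 60L else 0L,
                     cigar, "*", 0L, 0L, seq_out, "*", sep = "\t")
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
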