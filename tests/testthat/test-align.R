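test_that("semi-global alignment clips query ends without penalty", {
  set.seed(51)
  ref <- rand_dna(120)
  a <- semiglobal_align(ref, ref)
  expect_equal(a$score, 2 * 120)
  expect_equal(c(a$clipped5, a$clipped3), c(0L, 0L))
  expect_equal(c(a$ref_start, a$ref_end), c(0L, 120L))
  expect_equal(a$identity, 1)

  # spacers flanking the target are soft-clipped
  sp5 <- rand_dna(33); sp3 <- rand_dna(34)
  b <- semiglobal_align(paste0(sp5, ref, sp3), ref)
  expect_equal(c(b$clipped5, b$clipped3), c(33L, 34L))
  expect_equal(c(b$ref_start, b$ref_end), c(0L, 120L))
})

test_that("panel mapping recovers amplicon and orientation on clean data", {
  set.seed(52)
  panel <- synthetic_panel(4)
  sim <- simulate_library(clean_config(panel, n_reads = 150, seed = 61))
  dec <- deconcat_reads(sim$reads)
  aln <- map_to_panel(dec$fragments, panel)
  expect_equal(sort(unique(aln$role)), "primary")
  # exactly one record per fragment
  expect_equal(nrow(aln), nrow(dec$fragments))
  expect_equal(anyDuplicated(aln$fragment_id), 0)
  truth <- dplyr::inner_join(
    dec$fragments, sim$truth[sim$truth$type == "fragment", ],
    by = c("read_id", "start", "end"))
  m <- dplyr::inner_join(aln, truth, by = "fragment_id",
                         suffix = c(".aln", ".true"))
  expect_equal(nrow(m), nrow(dec$fragments))
  expect_true(all(m$amplicon_id.aln == m$amplicon_id.true))
  expect_true(all(m$orientation.aln == m$orientation.true))
  expect_true(all(m$identity == 1))
  # spacers are soft-clipped: the reference is covered end to end
  expect_true(all(m$ref_start == 0 & m$ref_end == 120))
})

test_that("random sequences are off-target under the declared thresholds", {
  set.seed(53)
  panel <- synthetic_panel(4)
  rand <- vapply(1:200, function(i) rand_dna(187), "")
  aln <- map_to_panel(rand, panel)
  expect_equal(nrow(aln), 0)
})

test_that("constructed hybrids earn a primary plus a disjoint secondary", {
  set.seed(54)
  panel <- synthetic_panel(3)
  fr <- fragment_seqs(panel)
  hyb <- paste0(fr[[1]], substr(fr[[2]], 11, nchar(fr[[2]])))  # 10 bp chew
  aln <- map_to_panel(c(h1 = hyb), panel)
  expect_equal(nrow(aln), 2)
  expect_setequal(aln$amplicon_id, c("amplicon01", "amplicon02"))
  expect_setequal(aln$role, c("primary", "secondary"))
  # query intervals are disjoint
  a <- aln[order(aln$query_start), ]
  expect_lte(a$query_end[1], a$query_start[2])
})

test_that("role/orientation encoding is bijective with SAM flags", {
  roles <- c("primary", "primary", "secondary", "secondary")
  orients <- c("forward", "revcomp", "forward", "revcomp")
  flags <- flag_from_role(roles, orients)
  expect_equal(flags, c(0L, 16L, 256L, 272L))
  back <- role_from_flag(flags)
  expect_equal(back$role, roles)
  expect_equal(back$orientation, orients)
  expect_error(role_from_flag(4L))
})

test_that("SAM output carries flags, positions and soft-clip CIGARs", {
  set.seed(55)
  panel <- synthetic_panel(2)
  fr <- fragment_seqs(panel)
  frags <- tibble::tibble(
    fragment_id = c("fwd", "rev"),
    seq = c(fr[[1]], reverse_complement(fr[[2]])))
  aln <- map_to_panel(frags, panel)
  d <- withr::local_tempfile(fileext = ".sam")
  write_sam(aln, panel, d, fragments = frags)
  lines <- readLines(d)
  expect_equal(sum(grepl("^@SQ", lines)), 2)
  recs <- strsplit(grep("^[^@]", lines, value = TRUE), "\t")
  expect_equal(length(recs), 2)
  flags <- vapply(recs, function(r) as.integer(r[2]), 1L)
  expect_setequal(flags, c(0L, 16L))
  cigars <- vapply(recs, function(r) r[6], "")
  expect_true(all(grepl("^33S120M34S$|^34S120M33S$", cigars)))
  expect_true(all(vapply(recs, function(r) as.integer(r[4]), 1L) == 1L))
})

test_that("pileup counts bases through the alignment path", {
  panel <- amplicon_panel(c(a = "ACGTACGTAC"))
  # one exact full-length alignment
  aln1 <- map_to_panel(c(f1 = "ACGTACGTAC"), panel)
  p1 <- pileup(aln1, panel)
  expect_equal(nrow(p1), 10)
  expect_true(all(p1$depth == 1))
  expect_true(all(mapply(function(ref, i) p1[[ref]][i], p1$ref, seq_len(10)) == 1))

  # second alignment carrying an alternate base at position 3 (G>T)
  aln2 <- map_to_panel(c(f1 = "ACGTACGTAC", f2 = "ACTTACGTAC"), panel)
  p2 <- pileup(aln2, panel)
  expect_equal(p2$depth[p2$pos == 3], 2)
  expect_equal(p2$G[p2$pos == 3], 1)
  expect_equal(p2$T[p2$pos == 3], 1)
})

test_that("pileup depth equals the interval cover of primary alignments", {
  set.seed(56)
  panel <- synthetic_panel(2)
  sim <- simulate_library(clean_config(panel, n_reads = 120, seed = 71))
  dec <- deconcat_reads(sim$reads)
  aln <- map_to_panel(dec$fragments, panel)
  pile <- pileup(aln, panel)
  prim <- aln[aln$role == "primary", ]
  for (amp in panel$amplicon_id) {
    cover <- integer(120)
    pa <- prim[prim$amplicon_id == amp, ]
    for (i in seq_len(nrow(pa))) {
      cover[(pa$ref_start[i] + 1):pa$ref_end[i]] <-
        cover[(pa$ref_start[i] + 1):pa$ref_end[i]] + 1L
    }
    expect_equal(pile$depth[pile$amplicon_id == amp], cover)
  }
  # depth equals the sum of the base channels everywhere
  expect_equal(pile$depth, pile$A + pile$C + pile$G + pile$T + pile$del)
})

test_that("allele frequencies are exact counts over depth", {
  set.seed(57)
  vars <- tibble::tibble(amplicon_id = "amplicon01", pos = 50, alt = "T",
                         af = 1.0)
  panel <- synthetic_panel(1, variants = vars)
  vt <- panel_variants(panel)
  sim <- simulate_library(clean_config(panel, n_reads = 200,
                                       nmer = nmer_fixed(1), seed = 81))
  dec <- deconcat_reads(sim$reads)
  aln <- map_to_panel(dec$fragments, panel)
  pile <- pileup(aln, panel)
  calls <- extract_af(pile, vt)
  expect_equal(calls$af, 1.0)           # af 1: every covering read carries alt
  expect_equal(calls$depth, 200L)

  # depth-0 position is reported, flagged, with undefined af
  empty <- pileup(aln[0, ], panel)
  c0 <- extract_af(empty, vt)
  expect_true(is.na(c0$af))
  expect_true(c0$no_coverage)

  # out-of-bounds variant position is an error
  bad <- tibble::tibble(amplicon_id = "amplicon01", pos = 500, ref = "A",
                        alt = "T")
  expect_error(extract_af(pile, bad), "outside")
})

test_that("coverage fractions are normalised and follow pool weights", {
  set.seed(58)
  panel <- synthetic_panel(4)
  w <- c(0.4, 0.3, 0.2, 0.1)
  sim <- simulate_library(clean_config(panel, n_reads = 400, weights = w,
                                       seed = 91))
  dec <- deconcat_reads(sim$reads)
  aln <- map_to_panel(dec$fragments, panel)
  cov <- amplicon_coverage(aln)
  expect_equal(sum(cov$fraction), 1)
  expect_gt(cor(cov$fraction[match(panel$amplicon_id, cov$amplicon_id)], w),
            0.99)
  # degenerate: all fragments from one amplicon
  one <- amplicon_coverage(aln[aln$amplicon_id == "amplicon01" &
                                 aln$role == "primary", ])
  expect_equal(one$fraction, 1)
  expect_error(amplicon_coverage(aln[0, ]), "no aligned")
})

test_that("panels round-trip through FASTA plus annotation files", {
  set.seed(59)
  d <- withr::local_tempdir()
  panel <- synthetic_panel(2)
  fa <- file.path(d, "panel.fa")
  write_fastx(tibble::tibble(id = panel$amplicon_id, seq = panel$ref_seq,
                             qual = NA), fa, format = "fasta")
  meta <- file.path(d, "meta.tsv")
  ref_base <- substr(panel$ref_seq[1], 25, 25)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  writeLines(c("amplicon_id\tspacer5\tspacer3\tpos\tref\talt\taf",
               paste("amplicon01", panel$spacer5[1], panel$spacer3[1],
                     25, ref_base, alt_base, 0.1, sep = "\t")), meta)
  back <- read_panel(fa, meta)
  expect_equal(back$ref_seq, panel$ref_seq)
  expect_equal(fragment_seqs(back)[["amplicon01"]],
               fragment_seqs(panel)[["amplicon01"]])
  vt <- panel_variants(back)
  expect_equal(vt$pos, 25L)
  expect_equal(vt$alt, alt_base)
  expect_equal(vt$af, 0.1)
  # a variant disagreeing with the reference base is refused
  writeLines(c("amplicon_id\tpos\tref\talt",
               paste("amplicon01", 25, alt_base, ref_base, sep = "\t")),
             meta)
  expect_error(read_panel(fa, meta), "does not match")
})
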