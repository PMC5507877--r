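params <- scan_params()

test_that("scanner finds exact, edited, and reverse-complement adapters", {
  ad <- params$adapter
  # exact self-match
  h <- scan_adapters(ad, params)
  expect_equal(h[, c("start", "end", "orientation", "distance")],
               tibble::tibble(start = 0L, end = 30L,
                              orientation = "forward", distance = 0L),
               ignore_attr = TRUE)

  # exactly 4 substitutions is a hit, 5 is not (distances checked
  # against the generalized-Levenshtein oracle before asserting)
  set.seed(31)
  bg1 <- rand_dna(100); bg2 <- rand_dna(100)
  b <- strsplit(ad, "")[[1]]
  pos <- c(3, 9, 17, 25, 29)
  for (p in pos) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  ad5 <- paste(b, collapse = "")
  ad4 <- ad; substr(ad4, 3, 3) <- substr(ad5, 3, 3)
  substr(ad4, 9, 9) <- substr(ad5, 9, 9)
  substr(ad4, 17, 17) <- substr(ad5, 17, 17)
  substr(ad4, 25, 25) <- substr(ad5, 25, 25)
  expect_equal(as.integer(utils::adist(ad4, ad)), 4)
  expect_equal(as.integer(utils::adist(ad5, ad)), 5)
  h4 <- scan_adapters(paste0(bg1, ad4, bg2), params)
  expect_equal(nrow(h4), 1)
  expect_equal(h4$distance, 4L)
  expect_equal(h4$start, 100L)
  h5 <- scan_adapters(paste0(bg1, ad5, bg2), params)
  expect_equal(nrow(h5), 0)

  # reverse-complement occurrence
  hr <- scan_adapters(paste0(bg1, reverse_complement(ad), bg2), params)
  expect_equal(nrow(hr), 1)
  expect_equal(hr$orientation, "revcomp")
  expect_equal(hr$start, 100L)
})

test_that("greedy scan matches the independent DP oracle on planted reads", {
  set.seed(32)
  for (rep in 1:60) {
    L <- sample(80:600, 1)
    seq <- rand_dna(L)
    n_plant <- sample(0:3, 1)
    if (n_plant > 0) {
      at <- sort(sample(0:(L - 31), n_plant))
      for (a in at) {
        load <- sample(0:6, 1)
        ad <- if (runif(1) < 0.5) params$adapter else params$adapter_rc
        planted <- mutate_edits(ad, load)
        substr(seq, a + 1, a + min(nchar(planted), L - a)) <-
          substr(planted, 1, min(nchar(planted), L - a))
      }
    }
    got <- scan_adapters(seq, params)
    exp <- oracle_scan(seq, params, params$max_edits)
    expect_equal(got[, c("start", "end", "orientation", "distance")], exp,
                 ignore_attr = TRUE)
  }
})

test_that("scanning the reverse complement mirrors the hit list", {
  set.seed(33)
  panel <- synthetic_panel(2)
  sim <- simulate_library(clean_config(panel, n_reads = 25, seed = 71))
  for (i in seq_len(nrow(sim$reads))) {
    s <- sim$reads$seq[i]
    L <- nchar(s)
    fwd <- scan_adapters(s, params)
    bwd <- scan_adapters(reverse_complement(s), params)
    expect_equal(nrow(bwd), nrow(fwd))
    mirrored <- tibble::tibble(start = L - rev(bwd$end), end = L - rev(bwd$start),
                               orientation = rev(ifelse(bwd$orientation == "forward",
                                                        "revcomp", "forward")))
    expect_equal(fwd[, c("start", "end", "orientation")], mirrored,
                 ignore_attr = TRUE)
  }
})

test_that("fragments and hits partition every read", {
  set.seed(34)
  panel <- synthetic_panel(3)
  # full default artifact and error model
  sim <- simulate_library(sim_config(panel, n_reads = 300, seed = 81))
  dec <- deconcat_reads(sim$reads)
  pieces <- dplyr::bind_rows(
    dec$fragments[, c("read_id", "start", "end")],
    dec$adapters[, c("read_id", "start", "end")])
  pieces <- dplyr::arrange(pieces, read_id, start)
  for (i in seq_len(nrow(sim$reads))) {
    id <- sim$reads$id[i]
    p <- pieces[pieces$read_id == id, ]
    expect_equal(p$start, c(0L, head(p$end, -1)))
    expect_equal(tail(p$end, 1), nchar(sim$reads$seq[i]))
    # re-concatenating the pieces reproduces the read byte for byte
    segs <- substring(sim$reads$seq[i], p$start + 1, p$end)
    expect_identical(paste(segs, collapse = ""), sim$reads$seq[i])
  }
})

test_that("reads without adapters give one spanning fragment", {
  set.seed(35)
  s <- rand_dna(300)
  stopifnot(nrow(scan_adapters(s, params)) == 0)
  fr <- deconcatenate(s, scan_adapters(s, params))
  expect_equal(nrow(fr), 1)
  expect_equal(c(fr$start, fr$end), c(0L, 300L))
  expect_true(fr$at_read_start && fr$at_read_end)
  # short reads are a single fragment without scanning
  fr2 <- deconcat_reads("ACGTACG")$fragments
  expect_equal(nrow(fr2), 1)
})

test_that("overlapping hits are rejected as a contract violation", {
  bad <- tibble::tibble(read_id = "read", start = c(0L, 10L), end = c(30L, 40L),
                        orientation = "forward", distance = 0L, tie = FALSE)
  expect_error(deconcatenate(rand_dna(100), bad), "overlapping")
})

test_that("clean libraries deconcatenate to exactly the true intervals", {
  set.seed(36)
  panel <- synthetic_panel(2)
  sim <- simulate_library(clean_config(panel, n_reads = 200, seed = 91))
  dec <- deconcat_reads(sim$reads)
  tf <- sim$truth[sim$truth$type == "fragment", ]
  ta <- sim$truth[sim$truth$type == "adapter", ]
  expect_setequal(interval_key(dec$fragments), interval_key(tf))
  expect_setequal(interval_key(dec$adapters), interval_key(ta))
  # every fragment sequence equals its true unit
  m <- dplyr::inner_join(dec$fragments, tf, by = c("read_id", "start", "end"))
  expect_equal(nrow(m), nrow(tf))
  truth_units <- fragment_seqs(panel)[m$amplicon_id]
  truth_units <- ifelse(m$orientation == "revcomp",
                        reverse_complement(unname(truth_units)),
                        unname(truth_units))
  expect_identical(m$seq, truth_units)
})

test_that("deconcat_file writes parseable fragments and counts", {
  set.seed(37)
  panel <- synthetic_panel(1)
  d <- withr::local_tempdir()
  fq <- file.path(d, "reads.fastq")
  simulate_library(clean_config(panel, n_reads = 100, nmer = nmer_fixed(5),
                                seed = 15), out_fastq = fq)
  out_fq <- file.path(d, "frags.fastq")
  out_tsv <- file.path(d, "adapters.tsv")
  counts <- deconcat_file(fq, params, out_fq, out_tsv)
  expect_equal(counts$n_reads, 100)
  expect_equal(counts$n_fragments, 500)
  expect_equal(counts$n_adapters, 600)
  frags <- read_fastx(out_fq, format = "fastq")
  meta <- parse_fragment_id(frags$id)
  expect_equal(nrow(meta), 500)
  expect_equal(meta$end - meta$start, nchar(frags$seq))
  tsv <- utils::read.delim(out_tsv)
  expect_equal(nrow(tsv), 600)
  expect_true(all(tsv$orientation %in% c("forward", "revcomp")))

  # empty input
  empty_fq <- file.path(d, "empty.fastq")
  file.create(empty_fq)
  out2 <- deconcat_file(empty_fq, params, file.path(d, "e1.fastq"),
                        file.path(d, "e2.tsv"))
  expect_equal(out2$n_reads, 0)
  expect_equal(out2$n_fragments, 0)
})
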