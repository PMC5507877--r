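params <- scan_params()

make_frag <- function(seq, at_start = FALSE, at_end = FALSE, start = 0) {
  tibble::tibble(fragment_id = "f1", read_id = "r1", index = 1L,
                 start = as.integer(start),
                 end = as.integer(start + nchar(seq)), seq = seq,
                 at_read_start = at_start, at_read_end = at_end)
}

test_that("the 1 bp filter removes remnants and keeps 2 bp fragments", {
  f1 <- make_frag("A", at_start = TRUE)
  f2 <- make_frag("AC")
  both <- dplyr::bind_rows(f1, f2)
  out <- filter_short(both)
  expect_equal(out$removed$seq, "A")
  expect_equal(out$kept$seq, "AC")
  empty <- filter_short(both[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("length classification is total, single-valued, and banded", {
  expect_equal(classify_length(c(187, 250, 1, 5, 181, 190, 191, 180)),
               c("expected_size", "oversized", "remnant_1bp",
                 "undersized_other", "expected_size", "expected_size",
                 "oversized", "undersized_other"))
  expect_error(classify_length(10, expected_len = 187, band = c(190, 200)),
               "band")
  set.seed(41)
  lens <- sample(1:400, 200, replace = TRUE)
  labels <- classify_length(lens)
  expect_false(anyNA(labels))
  expect_true(all(labels %in% c("remnant_1bp", "expected_size", "oversized",
                                "undersized_other")))
})

test_that("partial adapters are detected at fragment termini", {
  set.seed(42)
  ad <- params$adapter
  unit <- rand_dna(187)
  # keep the unit from accidentally extending the planted adapter match
  substr(unit, 1, 2) <- chartr("ACGT", "TGCA", substr(ad, 16, 17))

  # 15 bp of adapter ahead of a unit at the read start
  f <- make_frag(paste0(substr(ad, 1, 15), unit), at_start = TRUE)
  hit <- detect_partial_adapter(f, params)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$side, "5prime")
  expect_equal(hit$length, 15L)
  expect_equal(hit$distance, 0L)

  # truncated-suffix geometry at the read start is found too
  f2 <- make_frag(paste0(substr(ad, 16, 30), unit), at_start = TRUE)
  hit2 <- detect_partial_adapter(f2, params)
  expect_equal(hit2$distance, 0L)
  expect_equal(hit2$part, "suffix")

  # clean fragment: nothing
  expect_equal(nrow(detect_partial_adapter(make_frag(unit, at_end = TRUE),
                                           params)), 0)

  # full adapter at 5 edits at the read end, missed by the k=4 scan but
  # within the scaled relaxed bound (distance verified by oracle first)
  b <- strsplit(ad, "")[[1]]
  for (p in c(2, 8, 15, 22, 28)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  ad5 <- paste(b, collapse = "")
  stopifnot(utils::adist(ad5, ad) == 5)
  f3 <- make_frag(paste0(unit, ad5), at_end = TRUE)
  stopifnot(nrow(scan_adapters(f3$seq, params)) == 0)
  hit3 <- detect_partial_adapter(f3, params)
  expect_equal(hit3$side, "3prime")
  expect_equal(hit3$length, 30L)
  expect_equal(hit3$distance, 5L)

  expect_error(detect_partial_adapter(make_frag(unit)), "terminal")
})

test_that("relaxed rescan accepts 6 edits but not 7", {
  set.seed(43)
  ad <- params$adapter
  b <- strsplit(ad, "")[[1]]
  for (p in c(2, 6, 11, 16, 21, 26)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  ad6 <- paste(b, collapse = "")
  b7 <- b
  b7[29] <- setdiff(c("A", "C", "G", "T"), b7[29])[1]
  ad7 <- paste(b7, collapse = "")
  stopifnot(utils::adist(ad6, ad) == 6, utils::adist(ad7, ad) == 7)
  bg1 <- rand_dna(150); bg2 <- rand_dna(150)
  f6 <- make_frag(paste0(bg1, ad6, bg2))
  f7 <- make_frag(paste0(bg1, ad7, bg2))
  expect_equal(nrow(relaxed_rescan(f6, params)), 1)
  expect_equal(relaxed_rescan(f6, params)$distance, 6L)
  expect_equal(nrow(relaxed_rescan(f7, params)), 0)
  # clean fragment: empty
  expect_equal(nrow(relaxed_rescan(make_frag(rand_dna(200)), params)), 0)
})

test_that("relaxed rescan recovers at least the strict hits", {
  set.seed(44)
  for (i in 1:25) {
    load <- sample(0:4, 1)
    frag <- paste0(rand_dna(120), mutate_edits(params$adapter, load),
                   rand_dna(120))
    strict <- scan_adapters(frag, params)
    relaxed <- relaxed_rescan(make_frag(frag), params)
    expect_true(all(strict$start %in% relaxed$start))
  }
})

test_that("forced terminal truncation leaves detectable partial adapters", {
  set.seed(45)
  panel <- synthetic_panel(1)
  cfg <- sim_config(panel, n_reads = 150, nmer = nmer_fixed(3),
                    error_rates = c(sub = 0, ins = 0, del = 0),
                    hairpin_remnant_prob = 0, end_truncation_prob = 1,
                    hybrid_prob = 0, seed = 55)
  sim <- simulate_library(cfg)
  dec <- deconcat_reads(sim$reads)
  cls <- classify_fragments(filter_short(dec$fragments)$kept, params)
  over <- cls[cls$label == "oversized" &
                (cls$at_read_start | cls$at_read_end), ]
  expect_gt(nrow(over), 0)
  # remnant length implied by the excess over the clean fragment size;
  # remnants below the 8 bp detection floor carry no usable signal
  excess <- (over$end - over$start) - 187L
  detectable <- excess >= 8
  expect_gt(sum(detectable), 0)
  expect_true(all(!is.na(over$partial_side[detectable])))
  side_ok <- ifelse(over$at_read_start[detectable],
                    over$partial_side[detectable] == "5prime",
                    over$partial_side[detectable] == "3prime")
  expect_true(all(side_ok))
})

test_that("fragment size histogram uses fixed 10 bp bins", {
  fr <- dplyr::bind_rows(make_frag(rand_dna(187)), make_frag(rand_dna(189)),
                         make_frag(rand_dna(5)))
  h <- fragment_size_histogram(fr)
  expect_equal(h$n[h$bin_start == 180], 2)
  expect_equal(h$n[h$bin_start == 0], 1)
  expect_equal(sum(h$n), 3)
})
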