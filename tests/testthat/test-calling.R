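make_fit <- function(lambda, counts, width = 200L, mode = "hm") {
  tr <- make_track(counts, width = width, mode = mode)
  structure(
    list(
      track = dplyr::mutate(tibble::as_tibble(tr),
        lambda_hat = lambda, cp_prob = NA_real_
      ),
      params = bcp_params(1, 1, 0.01), bcmix = bcmix_config(),
      log_lik = NA_real_, mode = mode, window = width
    ),
    class = "bcp_fit"
  )
}

test_that("poisson_quantile is the smallest k with CDF >= q", {
  expect_equal(poisson_quantile(1, 0.90), 2) # cumsum of dpois: 0.92 at k = 2
  expect_equal(poisson_quantile(1, 0.50), 1)
  expect_equal(poisson_quantile(5, 1e-12), 0)
  # agreement with the direct pmf cumulative sum
  for (m in c(0.5, 2, 7)) {
    for (q in c(0.5, 0.9, 0.99)) {
      k <- 0
      while (sum(stats::dpois(0:k, m)) < q) k <- k + 1
      expect_equal(poisson_quantile(m, q), k)
    }
  }
})

test_that("segment_hm finds maximal runs above the background quantile", {
  fit <- make_fit(c(1, 1, 6, 6, 6, 1), rep(1L, 6)) # ybar = 1 -> C = 2
  isl <- segment_hm(fit, q = 0.90)
  expect_equal(attr(isl, "threshold"), 2)
  expect_equal(nrow(isl), 1)
  expect_equal(isl$start, 400L) # blocks 3-5 of width 200 starting at 0
  expect_equal(isl$end, 1000L)
  expect_equal(isl$mean_level, 6)

  expect_equal(nrow(segment_hm(make_fit(rep(1, 6), rep(1L, 6)))), 0)

  all_up <- segment_hm(make_fit(rep(9, 6), rep(1L, 6)))
  expect_equal(nrow(all_up), 1)
  expect_equal(all_up$start, 0L)
  expect_equal(all_up$end, 1200L)
})

test_that("call_tf_peaks extends the summit while steps stay below one", {
  lam <- c(3, 9, 10, 9.5, 4)
  fit <- make_fit(lam, c(0L, 0L, 1L, 0L, 0L), width = 50L, mode = "tf")
  # ybar = 0.2 -> C = qpois(0.99, 0.2) = 2; all blocks above
  pk <- call_tf_peaks(fit, q = 0.99)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$start, 0L)
  expect_equal(pk$end, 250L)
  # summit block 3 ([100,150)); |10-9| = 1 stops left, |10-9.5| < 1 extends right
  expect_equal(pk$sub_start, 100L)
  expect_equal(pk$sub_end, 200L)
  expect_equal(pk$summit, 125L)

  # single above-threshold block: sub-area is that block
  lam <- c(0.5, 8, 0.5)
  one <- call_tf_peaks(make_fit(lam, c(0L, 1L, 0L), width = 50L, mode = "tf"))
  expect_equal(one$sub_start, 50L)
  expect_equal(one$sub_end, 100L)
  expect_equal(one$summit, 75L)

  # two equal maxima: leftmost chosen
  lam <- c(0.5, 8, 3, 8, 0.5)
  two <- call_tf_peaks(make_fit(lam, c(0L, 1L, 0L, 1L, 0L),
    width = 50L, mode = "tf"
  ))
  expect_equal(two$summit, 75L)
})

test_that("input_filter applies the upper-tail Poisson test", {
  cand <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L,
    mean_level = 5, n_blocks = 5L
  )
  mk_reads <- function(n_in, n_out) {
    tibble::tibble(
      chrom = "chr1",
      start = c(
        as.integer(seq(10, 980, length.out = n_in)),
        as.integer(seq(5000, 8000, length.out = n_out))
      ),
      strand = "+"
    ) |> dplyr::mutate(end = start + 10L)
  }
  chip <- mk_reads(50, 50)
  ctrl <- mk_reads(10, 90) # same total: scale = 1
  out <- input_filter(cand, chip, ctrl, mode = "hm")
  expect_equal(out$chip_count, 50L)
  expect_equal(out$lambda0, 10)
  expect_equal(out$pvalue, stats::ppois(49, 10, lower.tail = FALSE))
  expect_equal(out$score, -log10(out$pvalue))

  # observed equal to expectation: p about 0.5, rejected at 1e-3
  even <- input_filter(cand, mk_reads(10, 90), ctrl, mode = "hm")
  expect_equal(nrow(even), 0)
  kept <- input_filter(cand, mk_reads(10, 90), ctrl,
    mode = "hm",
    pvalue_cutoff = 1
  )
  expect_gt(kept$pvalue, 0.4)

  # identical chip and control: nothing survives a 1e-3 cutoff
  self <- input_filter(cand, chip, chip, mode = "hm")
  expect_equal(nrow(self), 0)
})

test_that("lambda0 floor engages when the control is locally empty", {
  cand <- tibble::tibble(
    chrom = "chr1", start = 0L, end = 1000L,
    mean_level = 5, n_blocks = 5L
  )
  chip <- tibble::tibble(
    chrom = "chr1", start = as.integer(seq(10, 980, length.out = 30)),
    end = as.integer(seq(10, 980, length.out = 30)) + 10L, strand = "+"
  )
  ctrl <- tibble::tibble(
    chrom = "chr1", start = c(5000L, 9000L), end = c(5010L, 9010L),
    strand = "+"
  )
  out <- input_filter(cand, chip, ctrl, mode = "hm", pvalue_cutoff = 1)
  expect_gt(out$lambda0, 0)
  expect_lt(out$pvalue, 1)
})

test_that("stricter thresholds never increase the number of calls", {
  sim <- simulate_track(800, bcp_params(2, 1, 0.01), seed = 41)
  fit <- posterior_means(sim$track, bcp_params(2, 1, 0.01))
  n_calls <- vapply(
    c(0.5, 0.9, 0.99),
    function(q) nrow(segment_hm(fit, q = q)), numeric(1)
  )
  expect_true(all(diff(n_calls) <= 0))
})

test_that("fdr_curve reproduces the definition", {
  test_scores <- c(100:51, seq(50, 2, length.out = 50)) # 100 peaks
  neg_scores <- rep(2, 5) # all weaker than the rank-50 score
  cv <- fdr_curve(test_scores, neg_scores)
  expect_equal(cv$fdr[50], 0)
  expect_equal(cv$fdr[100], 5 / 100) # overall: negatives / test peaks
  expect_equal(fdr_curve(test_scores, numeric())$fdr, rep(0, 100))
})

test_that("empirical FDR is 1 for identical samples and low for signal", {
  paths <- run_simulate(withr::local_tempdir(), seed = 7, chrom_span = 5e5,
    n_segments = 4)
  chip <- read_bed(paths$chip)
  self <- empirical_fdr(chip, chip, mode = "hm")
  expect_true(self$n_test == 0 || self$fdr == 1)
})
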