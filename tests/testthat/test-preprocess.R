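test_that("deduplicate keeps one read per coordinate tuple", {
  r <- tibble::tibble(
    chrom = "chr1",
    start = c(100L, 100L, 100L, 100L),
    end = c(136L, 136L, 136L, 136L),
    strand = c("+", "+", "+", "-")
  )
  d <- deduplicate(r)
  expect_equal(nrow(d), 2) # same start, different strand: both retained
  expect_equal(d$strand, c("+", "-"))
  expect_equal(nrow(deduplicate(r[0, ])), 0)
})

test_that("estimate_shift recovers half the strand offset at one site", {
  rr <- tibble::tibble(
    chrom = "chr1",
    start = c(rep(1000L, 500), rep(1164L, 500)),
    end = c(rep(1036L, 500), rep(1200L, 500)),
    strand = rep(c("+", "-"), each = 500)
  )
  expect_equal(estimate_shift(rr, min_pairs = 1), 100L)
})

test_that("estimate_shift recovers fragment_length/2 from simulated sites", {
  starts <- as.integer(seq(5e4, 1.9e6, length.out = 40))
  prof <- sim_profile(
    segments = tibble::tibble(
      start = starts, end = starts + 10L, density = 0.5
    ),
    background_density = 1e-4, seed = 5
  )
  reads <- deduplicate(simulate_reads(prof, 30000, seed = 5))
  expect_lte(abs(estimate_shift(reads) - 100L), 5)
})

test_that("estimate_shift falls back with a warning on degenerate input", {
  plus_only <- tibble::tibble(
    chrom = "chr1", start = 1:20 * 10L, end = 1:20 * 10L + 36L, strand = "+"
  )
  expect_warning(s <- estimate_shift(plus_only), "falling back")
  expect_equal(s, 100L)
})

test_that("build_tf_track blocks runs of equal coverage and tiles the span", {
  # two shifted reads covering [100,136) and [120,156)
  reads <- tibble::tibble(
    chrom = "chr1", start = c(100L, 120L), end = c(136L, 156L),
    strand = c("+", "+")
  )
  tr <- build_tf_track(reads, shift = 0)
  expect_equal(tr$start, c(0L, 100L, 120L, 136L))
  expect_equal(tr$end, c(100L, 120L, 136L, 156L))
  expect_equal(tr$count, c(0L, 1L, 2L, 1L))

  one <- build_tf_track(reads[1, ], shift = 0, span = c(chr1 = 400))
  expect_equal(one$count, c(0L, 1L, 0L))

  none <- build_tf_track(reads[0, ], shift = 0, span = c(chr1 = 500))
  expect_equal(none$count, 0L)
  expect_equal(none$end, 500L)

  expect_error(build_tf_track(reads, shift = -1), "non-negative")
})

test_that("TF track is run-maximal and conserves read-base mass", {
  set.seed(8)
  reads <- tibble::tibble(
    chrom = "chr1",
    start = sort(sample.int(5000, 300, replace = TRUE)),
    strand = sample(c("+", "-"), 300, TRUE)
  )
  reads$end <- reads$start + 36L
  tr <- build_tf_track(reads, shift = 10)
  expect_true(all(diff(tr$count) != 0)) # no two adjacent blocks equal
  expect_equal(tr$start[-1], tr$end[-nrow(tr)]) # contiguous
  expect_equal(
    sum(as.numeric(tr$count) * (tr$end - tr$start)),
    nrow(reads) * 36
  )
})

test_that("build_hm_track extends reads and averages per window", {
  one <- tibble::tibble(chrom = "chr1", start = 0L, end = 36L, strand = "+")
  tr <- build_hm_track(one,
    fragment_length = 200, window = 200,
    span = c(chr1 = 400)
  )
  expect_equal(tr$count, c(1L, 0L))

  # minus-strand read extends upstream from its 5' (right) end
  minus <- tibble::tibble(chrom = "chr1", start = 364L, end = 400L, strand = "-")
  tr <- build_hm_track(minus,
    fragment_length = 200, window = 200,
    span = c(chr1 = 400)
  )
  expect_equal(tr$count, c(0L, 1L))

  # average 1.5 rounds half away from zero -> 2
  tr <- build_hm_track(
    tibble::tibble(
      chrom = "chr1", start = c(0L, 100L), end = c(36L, 136L), strand = "+"
    ),
    fragment_length = 200, window = 200, span = c(chr1 = 400)
  )
  expect_equal(tr$count[1], 2L) # coverage 1 on [0,100), 2 on [100,200): avg 1.5
})

test_that("HM windows tile the chromosome; mass is conserved to rounding", {
  set.seed(9)
  reads <- tibble::tibble(
    chrom = "chr1",
    start = sort(sample.int(10000, 400, replace = TRUE)),
    strand = sample(c("+", "-"), 400, TRUE)
  )
  reads$end <- reads$start + 36L
  span <- c(chr1 = 10500)
  tr <- build_hm_track(reads, fragment_length = 200, window = 200, span = span)
  expect_equal(nrow(tr), ceiling(10500 / 200))
  expect_equal(tr$end[nrow(tr)], 10500L) # last window shorter
  # window rounding moves at most 0.5 * window of mass per window; a few
  # minus-strand reads near the origin lose mass to clipping
  est <- sum(as.numeric(tr$count) * 200)
  true_mass <- 400 * 200
  expect_lte(abs(est - true_mass), 0.5 * nrow(tr) * 200 + 2000)

  # 10 reads tiled inside one window: average coverage 640/200 = 3.2 -> 3
  tiled <- tibble::tibble(
    chrom = "chr1", start = as.integer(seq(0, 135, by = 15)), strand = "+"
  )
  tiled$end <- tiled$start + 36L
  tr2 <- build_hm_track(tiled,
    fragment_length = 64, window = 200,
    span = c(chr1 = 400)
  )
  expect_equal(tr2$count, c(3L, 0L))
})

test_that("shift_reads moves strands in opposite directions and clips", {
  r <- tibble::tibble(
    chrom = "chr1", start = c(100L, 10L), end = c(136L, 46L),
    strand = c("+", "-")
  )
  s <- shift_reads(r, 50)
  expect_equal(s$start, c(150L, 0L))
  expect_equal(s$end, c(186L, 1L))
})
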