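test_that("segment_evidence matches closed forms and numerical integration", {
  pp <- bcp_params(1, 1, 0.5)
  # single zero count under Gamma(1,1): geometric marginal 1/2
  ev <- segment_evidence(pp, 0L, 1, 1)
  expect_equal(ev$shape, 1)
  expect_equal(ev$rate, 2)
  expect_equal(ev$log_marginal, log(0.5), tolerance = 1e-12)

  # y = [2, 2] as one segment: integrate Poisson likelihood x Gamma prior
  ev <- segment_evidence(pp, c(2L, 2L), 1, 2)
  expect_equal(ev$shape, 5)
  expect_equal(ev$rate, 3)
  num <- stats::integrate(
    function(l) l^4 * exp(-2 * l) / 4 * exp(-l),
    0, Inf, rel.tol = 1e-12
  )$value
  expect_equal(ev$log_marginal, log(num), tolerance = 1e-9)

  # length-one segment: rate = beta + 1
  ev <- segment_evidence(bcp_params(2.5, 3, 0.1), c(7L, 1L), 2, 2)
  expect_equal(ev$rate, 4)
  expect_error(segment_evidence(pp, c(1L, 2L), 2, 3), "out of range")
})

test_that("filters match the enumeration oracle on small tracks", {
  set.seed(11)
  exact <- bcmix_config(enabled = FALSE)
  for (rep in 1:25) {
    n <- sample(2:8, 1)
    y <- sample(0:10, n, replace = TRUE)
    pp <- bcp_params(runif(1, 0.2, 5), runif(1, 0.2, 5), runif(1, 0.05, 0.9))
    tr <- make_track(y)
    fw <- forward_filter(tr, pp, exact)
    for (t in seq_len(n)) {
      w <- fw[fw$t == t, ]
      expect_equal(sum(w$weight), 1, tolerance = 1e-12)
      orc <- oracle_forward_weights(y, pp$alpha, pp$beta, pp$p, t)
      expect_equal(w$weight[order(w$i)], orc[w$i[order(w$i)]],
        tolerance = 1e-10
      )
    }
    # backward weights on the reversed track mirror forward weights
    bw <- backward_filter(tr, pp, exact)
    fw_rev <- forward_filter(make_track(rev(y)), pp, exact)
    for (t in seq_len(n)) {
      b <- bw[bw$t == t, ]
      f <- fw_rev[fw_rev$t == n + 1 - t, ]
      expect_equal(sort(b$weight), sort(f$weight), tolerance = 1e-12)
      expect_equal(sort(n + 1 - b$j), sort(f$i))
    }
  }
})

test_that("posterior means and log-likelihood match enumeration", {
  set.seed(12)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    y <- sample(0:10, n, replace = TRUE)
    pp <- bcp_params(runif(1, 0.2, 5), runif(1, 0.2, 5), runif(1, 0.05, 0.9))
    orc <- oracle_smoother(y, pp$alpha, pp$beta, pp$p)
    for (cfg in list(
      bcmix_config(enabled = FALSE),
      bcmix_config(k_total = 20, m_recent = 10)
    )) {
      fit <- posterior_means(make_track(y), pp, cfg)
      expect_equal(fit$track$lambda_hat, orc$lambda, tolerance = 1e-8)
      expect_equal(fit$log_lik, orc$loglik, tolerance = 1e-8)
    }
  }
})

test_that("degenerate change probabilities give closed-form limits", {
  y <- c(0L, 4L)
  f1 <- posterior_means(
    make_track(y), bcp_params(1, 1, 1 - 1e-12),
    bcmix_config(enabled = FALSE)
  )
  expect_equal(f1$track$lambda_hat, c(0.5, 2.5), tolerance = 1e-9)

  y <- c(2L, 2L, 2L)
  f0 <- posterior_means(
    make_track(y), bcp_params(1, 1, 1e-12),
    bcmix_config(enabled = FALSE)
  )
  expect_equal(f0$track$lambda_hat, rep(7 / 4, 3), tolerance = 1e-9)

  # n = 1: single hypothesis, posterior mean (alpha + y) / (beta + 1)
  f <- posterior_means(make_track(5L), bcp_params(2, 1, 0.3))
  expect_equal(f$track$lambda_hat, 7 / 2, tolerance = 1e-12)
  fw <- forward_filter(make_track(5L), bcp_params(2, 1, 0.3))
  expect_equal(fw$weight, 1)
  expect_equal(fw$i, 1L)
})

test_that("log-likelihood is direction invariant and loglik of n=1 is exact", {
  expect_equal(
    log_likelihood(make_track(0L), bcp_params(1, 1, 0.5)),
    log(0.5),
    tolerance = 1e-12
  )
  set.seed(13)
  y <- sample(0:6, 30, replace = TRUE)
  pp <- bcp_params(1.5, 0.8, 0.1)
  expect_equal(
    log_likelihood(make_track(y), pp, bcmix_config(enabled = FALSE)),
    log_likelihood(make_track(rev(y)), pp, bcmix_config(enabled = FALSE)),
    tolerance = 1e-10
  )
})

test_that("posterior means lie in the convex hull and grow with the data", {
  set.seed(14)
  y <- sample(0:8, 40, replace = TRUE)
  pp <- bcp_params(2, 1, 0.05)
  fit <- posterior_means(make_track(y), pp, bcmix_config(enabled = FALSE))
  # convex hull of supported segment posterior means
  n <- length(y)
  mus <- outer(seq_len(n), seq_len(n), function(i, j) {
    ifelse(i <= j,
      (pp$alpha + (cumsum(y)[j] - c(0, cumsum(y))[i])) / (pp$beta + j - i + 1),
      NA
    )
  })
  expect_true(all(fit$track$lambda_hat >= min(mus, na.rm = TRUE) - 1e-12))
  expect_true(all(fit$track$lambda_hat <= max(mus, na.rm = TRUE) + 1e-12))
  expect_true(all(fit$track$lambda_hat > 0))

  # monotonicity: adding a constant to every count raises every estimate
  fit2 <- posterior_means(make_track(y + 3L), pp, bcmix_config(enabled = FALSE))
  expect_true(all(fit2$track$lambda_hat > fit$track$lambda_hat))
})

test_that("multi-chromosome tracks are smoothed independently", {
  y1 <- c(1L, 1L, 8L, 8L)
  y2 <- c(3L, 3L)
  both <- make_track(c(y1, y2))
  both$chrom <- rep(c("chr1", "chr2"), c(4, 2))
  pp <- bcp_params(2, 1, 0.1)
  fit <- posterior_means(both, pp)
  f1 <- posterior_means(make_track(y1), pp)
  f2 <- posterior_means(make_track(y2), pp)
  expect_equal(
    fit$track$lambda_hat,
    c(f1$track$lambda_hat, f2$track$lambda_hat)
  )
  expect_equal(fit$log_lik, f1$log_lik + f2$log_lik)
})

test_that("tidy and glance expose the fit", {
  y <- c(0L, 2L, 9L)
  fit <- posterior_means(make_track(y), bcp_params(1, 1, 0.2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("chrom", "start", "end", "count", "lambda_hat", "cp_prob"))
  expect_equal(td$cp_prob[1], 1) # the first block always starts a segment
  g <- glance(fit)
  expect_equal(g$n_blocks, 3L)
  expect_equal(g$p, 0.2)
  expect_s3_class(autoplot(fit), "ggplot")
})
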