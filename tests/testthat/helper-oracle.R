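# Brute-force enumeration oracle for the Poisson-Gamma change-point model.
# Independent of the package's compiled path: plain R, enumerating all
# 2^(n-1) change-point configurations with Bernoulli(p) priors and
# closed-form Gamma-Poisson segment evidences.

oracle_evidence <- function(y, alpha, beta) {
  s <- alpha + sum(y)
  r <- beta + length(y)
  exp(alpha * log(beta) - lgamma(alpha) + lgamma(s) - s * log(r) -
    sum(lgamma(y + 1)))
}

oracle_configs <- function(n) {
  if (n == 1) {
    return(list(logical(0)))
  }
  lapply(0:(2^(n - 1) - 1), function(b) {
    as.logical(bitwAnd(b, 2^(0:(n - 2))) > 0)
  })
}

# posterior over segmentations: per-config prior * evidence, plus the
# per-block segment posterior mean under each config
oracle_smoother <- function(y, alpha, beta, p) {
  n <- length(y)
  configs <- oracle_configs(n)
  wts <- numeric(length(configs))
  mu <- matrix(0, length(configs), n)
  for (ci in seq_along(configs)) {
    ch <- c(TRUE, configs[[ci]])
    starts <- which(ch)
    ends <- c(starts[-1] - 1L, n)
    prior <- p^(sum(ch) - 1) * (1 - p)^(n - sum(ch))
    ev <- 1
    for (k in seq_along(starts)) {
      seg <- y[starts[k]:ends[k]]
      ev <- ev * oracle_evidence(seg, alpha, beta)
      mu[ci, starts[k]:ends[k]] <-
        (alpha + sum(seg)) / (beta + length(seg))
    }
    wts[ci] <- prior * ev
  }
  list(
    lambda = colSums(mu * wts) / sum(wts),
    loglik = log(sum(wts))
  )
}

# P(most recent change-point = i | y[1..t]) by enumeration on the prefix
oracle_forward_weights <- function(y, alpha, beta, p, t) {
  yt <- y[seq_len(t)]
  configs <- oracle_configs(t)
  w <- numeric(t)
  for (cf in configs) {
    ch <- c(TRUE, cf)
    starts <- which(ch)
    ends <- c(starts[-1] - 1L, t)
    prior <- p^(sum(ch) - 1) * (1 - p)^(t - sum(ch))
    ev <- prod(vapply(
      seq_along(starts),
      function(k) oracle_evidence(yt[starts[k]:ends[k]], alpha, beta),
      numeric(1)
    ))
    w[max(starts)] <- w[max(starts)] + prior * ev
  }
  w / sum(w)
}

make_track <- function(y, chrom = "chr1", width = 1L, mode = "hm") {
  structure(
    tibble::tibble(
      chrom = chrom,
      start = (seq_along(y) - 1L) * width,
      end = seq_along(y) * width,
      count = y
    ),
    class = c("bcp_track", class(tibble::tibble())),
    mode = mode, window = width
  )
}

# fixed small TF benchmark profile: strong point sources over 1 Mb
tf_benchmark_profile <- function(n_sites = 150, seed = 2) {
  set.seed(seed)
  starts <- as.integer(sort(sample(seq(2e4, 9.9e5, by = 1000), n_sites)))
  sim_profile(
    chrom_span = 1e6,
    segments = tibble::tibble(
      start = starts, end = starts + 12L, density = 0.42
    ),
    background_density = 0.005, seed = seed
  )
}
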