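#' Method-of-moments estimate of the Gamma prior
#'
#' Marginally, each block count is Gamma-Poisson (negative binomial) with
#' mean `m = alpha/beta` and variance `v = alpha/beta + alpha/beta^2`, and
#' the counts are exchangeable, so the prior shape and rate follow from
#' the pooled sample mean and (unbiased) sample variance:
#' `beta = m / (v - m)`, `alpha = m^2 / (v - m)`. Requires over-dispersion
#' (`v > m`); Poisson-like or under-dispersed counts trigger a fallback
#' prior with `alpha = m^2`, `beta = m` (prior mean `m`, prior variance 1)
#' and a warning.
#'
#' @param track A `bcp_track`; counts are pooled across chromosomes.
#' @return Named list with `alpha` and `beta`.
#' @export
estimate_alpha_beta <- function(track) {
  y <- track$count
  if (length(y) < 2) stop("need at least 2 blocks", call. = FALSE)
  m <- mean(y)
  v <- stats::var(y)
  if (v <= m || m <= 0) {
    warning("counts are not over-dispersed (variance <= mean); ",
      "using fallback prior alpha = mean^2, beta = mean",
      call. = FALSE
    )
    m <- max(m, 1e-8)
    return(list(alpha = m^2, beta = m))
  }
  list(alpha = m^2 / (v - m), beta = m / (v - m))
}

#' Default grid for the change probability search
#'
#' Probabilities of the form `j * 10^-i` for digits `j = 1..9` and decades
#' `i = 1..7`, restricted to `(0, 0.5]`, in increasing order.
#'
#' @return Numeric vector of candidate change probabilities.
#' @export
default_p_grid <- function() {
  g <- signif(as.vector(outer(1:9, 10^-(1:7))), 1)
  sort(g[g <= 0.5])
}

#' Grid-search maximum-likelihood estimate of the change probability
#'
#' Evaluates the marginal log-likelihood ([log_likelihood()]) at each
#' candidate `p` with `alpha` and `beta` held at their moment estimates,
#' and returns the maximizer. Deterministic; ties go to the smaller `p`.
#'
#' @param track A `bcp_track`.
#' @param alpha,beta Gamma prior shape and rate.
#' @param grid Candidate probabilities in (0, 1); see [default_p_grid()].
#' @param bcmix A [bcmix_config()] used for the likelihood evaluations.
#' @return The selected change probability.
#' @export
estimate_p <- function(track, alpha, beta, grid = default_p_grid(),
                       bcmix = bcmix_config()) {
  stopifnot(length(grid) >= 1, all(grid > 0), all(grid < 1))
  grid <- sort(grid)
  ll <- vapply(
    grid,
    function(p) log_likelihood(track, bcp_params(alpha, beta, p), bcmix),
    numeric(1)
  )
  grid[which.max(ll)]
}

#' Estimate all hyperparameters from a count track
#'
#' Convenience wrapper: method-of-moments `alpha`, `beta`
#' ([estimate_alpha_beta()]) followed by grid-search `p` ([estimate_p()]).
#' Any component supplied explicitly is taken as given and not estimated.
#'
#' @inheritParams estimate_p
#' @param alpha,beta,p Optional fixed values overriding estimation.
#' @return A [bcp_params()] object.
#' @export
estimate_params <- function(track, alpha = NULL, beta = NULL, p = NULL,
                            grid = default_p_grid(),
                            bcmix = bcmix_config()) {
  if (is.null(alpha) || is.null(beta)) {
    ab <- estimate_alpha_beta(track)
    if (is.null(alpha)) alpha <- ab$alpha
    if (is.null(beta)) beta <- ab$beta
  }
  if (is.null(p)) p <- estimate_p(track, alpha, beta, grid, bcmix)
  bcp_params(alpha, beta, p)
}
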