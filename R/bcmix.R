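#' Bounded-complexity mixture (BCMIX) configuration
#'
#' The exact change-point filters carry one hypothesis per possible
#' change-point index, so the mixture grows with every block. BCMIX caps
#' it: after each step at most `k_total` hypotheses are retained — always
#' the `m_recent` most recent indices, plus the largest-weight survivors
#' among the rest — keeping genome-wide smoothing near-linear in the
#' number of blocks at negligible accuracy cost.
#'
#' @param k_total Maximum hypotheses retained per step (>= 2).
#' @param m_recent Most recent hypotheses always retained
#'   (`1 <= m_recent < k_total`).
#' @param enabled If `FALSE`, the exact (unpruned) algorithms are used.
#' @return A `bcmix_config` object.
#' @export
bcmix_config <- function(k_total = 20L, m_recent = 10L, enabled = TRUE) {
  k_total <- as.integer(k_total)
  m_recent <- as.integer(m_recent)
  stopifnot(k_total >= 2, m_recent >= 1, m_recent < k_total)
  structure(
    list(k_total = k_total, m_recent = m_recent, enabled = isTRUE(enabled)),
    class = "bcmix_config"
  )
}

#' Prune a filter weight map to bounded size
#'
#' Reference implementation of the BCMIX truncation rule on one step's
#' weight map: if the support exceeds `k_total`, retain the `m_recent`
#' most recent (largest) indices plus the `k_total - m_recent`
#' largest-weight remaining indices (ties keep the more recent index), and
#' renormalize. The compiled filters apply the identical rule internally.
#'
#' @param weights Tibble with columns `i` (hypothesis index) and `weight`
#'   (normalized).
#' @param config A [bcmix_config()].
#' @return Pruned tibble, weights summing to 1, sorted by `i`.
#' @export
prune <- function(weights, config = bcmix_config()) {
  s <- nrow(weights)
  if (!config$enabled || s <= config$k_total) {
    return(weights)
  }
  weights <- dplyr::arrange(weights, .data$i)
  recent <- weights$i[(s - config$m_recent + 1L):s]
  older <- weights[seq_len(s - config$m_recent), ]
  older <- dplyr::arrange(older, dplyr::desc(.data$weight), dplyr::desc(.data$i))
  keep_old <- older$i[seq_len(config$k_total - config$m_recent)]
  out <- dplyr::filter(weights, .data$i %in% c(recent, keep_old))
  dplyr::mutate(out, weight = .data$weight / sum(.data$weight))
}
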