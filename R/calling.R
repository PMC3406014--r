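#' Poisson quantile threshold
#'
#' Smallest integer `k` such that the Poisson CDF at `k` reaches `q`; used
#' as the cut line across posterior means, with the Poisson mean set to
#' the genome-wide average read count (the background level).
#'
#' @param mean Poisson mean, > 0.
#' @param q Quantile in (0, 1).
#' @return Integer threshold.
#' @export
poisson_quantile <- function(mean, q) {
  stopifnot(mean > 0, q > 0, q < 1)
  stats::qpois(q, mean)
}

# background mean count: per-block mean in HM mode (equal-width windows),
# width-weighted (per-base) mean in TF mode where block widths vary
background_mean <- function(track) {
  if (identical(track_mode(track), "tf")) {
    w <- track$end - track$start
    sum(track$count * w) / sum(w)
  } else {
    mean(track$count)
  }
}

# maximal runs of TRUE within each chromosome -> tibble of run index ranges
runs_above <- function(df, above) {
  r <- rle(above)
  last <- cumsum(r$lengths)
  first <- c(1L, utils::head(last, -1) + 1L)
  keep <- r$values
  tibble::tibble(first = first[keep], last = last[keep])
}

#' Segment a posterior mean track into enrichment islands
#'
#' Histone-modification mode: thresholds the smoothed posterior mean
#' density at the Poisson quantile of the background (`C`), and reports
#' each maximal run of consecutive blocks with `lambda_hat > C` as a
#' candidate island. Because the posterior mean is smoothed by upstream
#' and downstream information, local gaps inside broad domains do not
#' fragment the islands.
#'
#' @param fit A `bcp_fit` from [posterior_means()].
#' @param q Background quantile for the cut line (lenient by design for
#'   diffuse marks).
#' @return Tibble of candidate islands: `chrom`, `start`, `end`,
#'   `mean_level` (average posterior mean over the island), `n_blocks`.
#'   The threshold used is stored in attribute `"threshold"`.
#' @export
segment_hm <- function(fit, q = 0.90) {
  tr <- fit$track
  ybar <- mean(tr$count)
  C <- poisson_quantile(max(ybar, 1e-8), q)
  out <- lapply(split(tr, factor(tr$chrom, unique(tr$chrom))), function(d) {
    rr <- runs_above(d, d$lambda_hat > C)
    if (nrow(rr) == 0) {
      return(NULL)
    }
    tibble::tibble(
      chrom = d$chrom[1],
      start = d$start[rr$first],
      end = d$end[rr$last],
      mean_level = vapply(
        seq_len(nrow(rr)),
        function(k) mean(d$lambda_hat[rr$first[k]:rr$last[k]]), numeric(1)
      ),
      n_blocks = rr$last - rr$first + 1L
    )
  })
  structure(dplyr::bind_rows(out), threshold = C)
}

#' Call transcription-factor peaks with summits
#'
#' TF mode: thresholds the posterior mean density at a strict background
#' Poisson quantile; each maximal above-threshold area becomes a candidate
#' peak. Within each area the block with the largest posterior mean is
#' located (leftmost on ties), the summit is that block's midpoint, and
#' the block is extended in both directions while the difference of
#' adjacent posterior means stays below one — the extended span is the
#' sub-area, an approximation of the true enrichment area used for the
#' input-control test.
#'
#' @param fit A `bcp_fit` on a TF-mode track.
#' @param q Background quantile (stricter than the HM default).
#' @return Tibble of candidate peaks with `chrom`, `start`, `end`,
#'   `summit`, `sub_start`, `sub_end`, `mean_level`, `n_blocks`; threshold
#'   in attribute `"threshold"`.
#' @export
call_tf_peaks <- function(fit, q = 0.99) {
  tr <- fit$track
  ybar <- background_mean(structure(tr, mode = fit$mode %||% "tf"))
  C <- poisson_quantile(max(ybar, 1e-8), q)
  out <- lapply(split(tr, factor(tr$chrom, unique(tr$chrom))), function(d) {
    rr <- runs_above(d, d$lambda_hat > C)
    if (nrow(rr) == 0) {
      return(NULL)
    }
    lam <- d$lambda_hat
    peaks <- lapply(seq_len(nrow(rr)), function(k) {
      a <- rr$first[k]
      b <- rr$last[k]
      m <- a + which.max(lam[a:b]) - 1L # leftmost maximum
      l <- m
      while (l > a && abs(lam[l - 1L] - lam[l]) < 1) l <- l - 1L
      r <- m
      while (r < b && abs(lam[r + 1L] - lam[r]) < 1) r <- r + 1L
      tibble::tibble(
        chrom = d$chrom[1],
        start = d$start[a], end = d$end[b],
        summit = (d$start[m] + d$end[m]) %/% 2L,
        sub_start = d$start[l], sub_end = d$end[r],
        mean_level = mean(lam[a:b]),
        n_blocks = b - a + 1L
      )
    })
    dplyr::bind_rows(peaks)
  })
  structure(dplyr::bind_rows(out), threshold = C)
}

# number of reads whose midpoint falls in each of a set of disjoint,
# sorted regions (per chromosome)
count_reads_in <- function(regions, reads) {
  if (is.null(regions) || nrow(regions) == 0) {
    return(integer())
  }
  counts <- integer(nrow(regions))
  mids <- (reads$start + reads$end) %/% 2L
  for (ch in unique(regions$chrom)) {
    rk <- which(regions$chrom == ch)
    o <- rk[order(regions$start[rk])]
    m <- mids[reads$chrom == ch]
    idx <- findInterval(m, regions$start[o])
    inside <- idx >= 1L & m < regions$end[o][pmax(idx, 1L)]
    counts[o] <- counts[o] + tabulate(idx[inside], nbins = length(o))
  }
  counts
}

#' Validate candidate regions against an input control
#'
#' For each candidate, forms the expected ChIP read count under the null
#' from the input-control reads in the matched region — for islands the
#' candidate region itself; for TF peaks the larger of the control density
#' in the sub-area and the average density over summit-centered windows
#' one to five candidate-peak widths wide — scaled by the library-size
#' ratio, and tests the observed ChIP count with a one-sided upper-tail
#' Poisson test. Candidates with `pvalue < pvalue_cutoff` are retained and
#' scored as `-log10(pvalue)`.
#'
#' @param candidates Tibble from [segment_hm()] or [call_tf_peaks()].
#' @param chip_reads,control_reads Deduplicated read tibbles.
#' @param mode `"hm"` or `"tf"`.
#' @param pvalue_cutoff Retention cutoff on the Poisson p-value.
#' @param scale Library-size ratio (total ChIP / total control); computed
#'   from the read sets when `NULL`. Set to 1 to disable depth scaling.
#' @param score_cap Score assigned when the p-value underflows to 0.
#' @return Validated regions with `chip_count`, `lambda0`, `pvalue`,
#'   `score` columns, sorted by `(chrom, start)`.
#' @export
input_filter <- function(candidates, chip_reads, control_reads,
                         mode = c("hm", "tf"), pvalue_cutoff = 1e-3,
                         scale = NULL, score_cap = 1000) {
  mode <- match.arg(mode)
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      chip_count = integer(), lambda0 = numeric(), pvalue = numeric(),
      score = numeric()
    ))
  }
  if (is.null(scale)) scale <- nrow(chip_reads) / max(nrow(control_reads), 1)
  span <- sum(vapply(
    split(control_reads$end, control_reads$chrom), max, numeric(1)
  ))
  genome_density <- nrow(control_reads) / max(span, 1)
  if (nrow(control_reads) == 0 || genome_density <= 0) {
    warning("no control reads genome-wide; applying a one-read density floor",
      call. = FALSE
    )
    genome_density <- 1 / max(span, 1)
  }

  obs <- count_reads_in(candidates, chip_reads)
  len <- candidates$end - candidates$start
  if (mode == "hm") {
    ctrl <- count_reads_in(candidates, control_reads)
    lambda0 <- ctrl * scale
  } else {
    sub <- tibble::tibble(
      chrom = candidates$chrom,
      start = candidates$sub_start, end = candidates$sub_end
    )
    d_sub <- count_reads_in(sub, control_reads) / (sub$end - sub$start)
    d_ext <- rowMeans(vapply(1:5, function(k) {
      ext <- tibble::tibble(
        chrom = candidates$chrom,
        start = pmax(candidates$summit - k * len, 0L),
        end = candidates$summit + k * len
      )
      count_reads_in(ext, control_reads) / (ext$end - ext$start)
    }, numeric(nrow(candidates))))
    lambda0 <- pmax(d_sub, d_ext) * len * scale
  }
  floor0 <- lambda0 <= 0
  lambda0[floor0] <- genome_density * len[floor0] * scale
  pval <- stats::ppois(obs - 1, lambda0, lower.tail = FALSE)
  out <- dplyr::mutate(candidates,
    chip_count = obs, lambda0 = lambda0, pvalue = pval,
    score = ifelse(pval <= 0, score_cap, pmin(-log10(pval), score_cap))
  )
  out <- dplyr::filter(out, .data$pvalue < pvalue_cutoff)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Empirical false discovery rate by sample inversion
#'
#' Runs the full pipeline twice: once with the ChIP sample as test and the
#' input as control (test peaks), and once with the samples swapped
#' (negative peaks). The overall empirical FDR is the number of negative
#' peaks divided by the number of test peaks; the rank curve reports, for
#' test peaks sorted by p-value, the fraction of negative peaks scoring at
#' least as high.
#'
#' @param chip_reads,control_reads Read tibbles (not yet deduplicated).
#' @param mode `"hm"` or `"tf"`.
#' @param ... Passed to [bcp_call()] (thresholds, hyperparameters, BCMIX
#'   settings, ...).
#' @return List with `fdr` (overall; `NA` if no test peaks), `n_test`,
#'   `n_neg`, and `curve`, a tibble `(rank, score, fdr)`.
#' @export
empirical_fdr <- function(chip_reads, control_reads, mode = c("hm", "tf"),
                          ...) {
  mode <- match.arg(mode)
  test <- bcp_call(chip_reads, control_reads, mode = mode, ...)$regions
  neg <- bcp_call(control_reads, chip_reads, mode = mode, ...)$regions
  n_test <- nrow(test)
  n_neg <- nrow(neg)
  if (n_test == 0) {
    return(list(
      fdr = NA_real_, n_test = 0L, n_neg = n_neg,
      curve = tibble::tibble(
        rank = integer(), score = numeric(), fdr = numeric()
      )
    ))
  }
  list(
    fdr = n_neg / n_test, n_test = n_test, n_neg = n_neg,
    curve = fdr_curve(test$score, neg$score)
  )
}

#' Empirical FDR rank curve
#'
#' Given the scores (`-log10` p-values) of test peaks and of negative
#' peaks from the inverted run, computes, for each rank `r` of the test
#' peaks sorted by decreasing score, the number of negative peaks scoring
#' at least as high divided by `r`.
#'
#' @param test_scores,neg_scores Numeric score vectors.
#' @return Tibble `(rank, score, fdr)`.
#' @export
fdr_curve <- function(test_scores, neg_scores) {
  s <- sort(test_scores, decreasing = TRUE)
  tibble::tibble(
    rank = seq_along(s),
    score = s,
    fdr = vapply(
      seq_along(s),
      function(r) sum(neg_scores >= s[r]) / r, numeric(1)
    )
  )
}
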