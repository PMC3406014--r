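#' Run the full calling pipeline on read sets
#'
#' End-to-end per-chromosome analysis: deduplication, read shifting (TF)
#' or fragment extension into windows (HM), empirical-Bayes hyperparameter
#' estimation pooled genome-wide, posterior mean smoothing, candidate
#' generation, and input-control validation.
#'
#' @param chip_reads Read tibble for the ChIP sample (see [read_bed()]).
#' @param control_reads Read tibble for the input control, or `NULL` to
#'   skip validation (candidates are returned unfiltered with `NA`
#'   p-values).
#' @param mode `"hm"` for diffuse histone-modification islands, `"tf"`
#'   for punctate transcription-factor peaks with summits.
#' @param fragment_length Fragment length (bp) for HM extension and the
#'   TF shift fallback.
#' @param window HM window width (bp).
#' @param shift TF read shift in bp; estimated from strand asymmetry when
#'   `NULL`.
#' @param quantile Background Poisson quantile for the cut line; defaults
#'   to 0.90 (HM) or 0.99 (TF).
#' @param pvalue_cutoff Input-control retention cutoff.
#' @param alpha,beta,p Optional fixed hyperparameters; estimated when
#'   `NULL`.
#' @param bcmix A [bcmix_config()].
#' @param scale_control Scale the control by the library-size ratio.
#' @param span Optional named vector of chromosome spans (bp).
#' @return A `bcp_call` object: list with `regions` (validated calls),
#'   `candidates`, `fit` (the `bcp_fit`), `params`, `shift`, `threshold`,
#'   `scale`, `mode`.
#' @export
bcp_call <- function(chip_reads, control_reads = NULL, mode = c("hm", "tf"),
                     fragment_length = 200L, window = 200L, shift = NULL,
                     quantile = NULL, pvalue_cutoff = 1e-3,
                     alpha = NULL, beta = NULL, p = NULL,
                     bcmix = bcmix_config(), scale_control = TRUE,
                     span = NULL) {
  mode <- match.arg(mode)
  if (is.null(quantile)) quantile <- if (mode == "tf") 0.99 else 0.90
  chip <- deduplicate(chip_reads)
  ctrl <- if (!is.null(control_reads)) deduplicate(control_reads)

  if (mode == "tf") {
    if (is.null(shift)) {
      shift <- estimate_shift(chip, fragment_length = fragment_length)
    }
    track <- build_tf_track(chip, shift = shift, span = span)
  } else {
    shift <- NA_integer_
    track <- build_hm_track(chip,
      fragment_length = fragment_length,
      window = window, span = span
    )
  }

  params <- estimate_params(track,
    alpha = alpha, beta = beta, p = p,
    bcmix = bcmix
  )
  fit <- posterior_means(track, params, bcmix)
  candidates <- if (mode == "tf") {
    call_tf_peaks(fit, q = quantile)
  } else {
    segment_hm(fit, q = quantile)
  }

  # observed counts must live in the coordinates of the track the
  # candidates came from: shifted reads in TF mode
  chip_obs <- if (mode == "tf") shift_reads(chip, shift) else chip
  regions <- if (is.null(ctrl)) {
    if (!is.null(candidates) && nrow(candidates) > 0) {
      dplyr::mutate(candidates,
        chip_count = count_reads_in(candidates, chip_obs),
        lambda0 = NA_real_, pvalue = NA_real_, score = NA_real_
      )
    } else {
      candidates
    }
  } else {
    input_filter(candidates, chip_obs, ctrl,
      mode = mode,
      pvalue_cutoff = pvalue_cutoff,
      scale = if (scale_control) NULL else 1
    )
  }

  structure(
    list(
      regions = regions, candidates = candidates, fit = fit,
      params = params, shift = shift,
      threshold = attr(candidates, "threshold", exact = TRUE),
      scale = if (!is.null(ctrl)) nrow(chip) / max(nrow(ctrl), 1),
      mode = mode, quantile = quantile, pvalue_cutoff = pvalue_cutoff,
      window = if (mode == "hm") as.integer(window) else NA_integer_
    ),
    class = "bcp_call"
  )
}

#' @export
print.bcp_call <- function(x, ...) {
  cat(sprintf(
    "<bcp_call> mode %s: %d validated region(s) of %d candidate(s)\n",
    x$mode, nrow(x$regions), if (is.null(x$candidates)) 0 else nrow(x$candidates)
  ))
  cat(sprintf(
    "  alpha = %.4g, beta = %.4g, p = %.4g, threshold C = %s\n",
    x$params$alpha, x$params$beta, x$params$p,
    if (is.null(x$threshold)) "NA" else format(x$threshold)
  ))
  invisible(x)
}

#' @describeIn bcp_call Tidy the validated regions of a pipeline run.
#' @param x,object A `bcp_call` object.
#' @param ... Unused.
#' @export
tidy.bcp_call <- function(x, ...) tibble::as_tibble(x$regions)

#' @describeIn bcp_call One-row run summary (parameters, threshold,
#'   counts).
#' @export
glance.bcp_call <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    n_candidates = if (is.null(x$candidates)) 0L else nrow(x$candidates),
    n_regions = nrow(x$regions),
    alpha = x$params$alpha, beta = x$params$beta, p = x$params$p,
    threshold = if (is.null(x$threshold)) NA_real_ else x$threshold,
    quantile = x$quantile, pvalue_cutoff = x$pvalue_cutoff,
    shift = x$shift,
    scale = if (is.null(x$scale)) NA_real_ else x$scale,
    log_lik = x$fit$log_lik
  )
}

#' @describeIn bcp_call Posterior mean track with called regions shaded.
#' @export
autoplot.bcp_call <- function(object, ...) {
  pl <- autoplot(object$fit)
  if (nrow(object$regions) > 0) {
    pl <- pl + ggplot2::geom_rect(
      data = object$regions,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "#B2182B", alpha = 0.15
    )
  }
  if (!is.null(object$threshold)) {
    pl <- pl + ggplot2::geom_hline(
      yintercept = object$threshold,
      linetype = "dashed", colour = "#B2182B"
    )
  }
  pl
}
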