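# sort and merge overlapping/touching intervals within each chromosome
merge_intervals <- function(df) {
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    run_end <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1] > run_end[-nrow(d)])
    grp <- cumsum(new_run)
    tibble::tibble(
      chrom = d$chrom[1],
      start = d$start[new_run],
      end = as.vector(tapply(d$end, grp, max))
    )
  })
  dplyr::bind_rows(out)
}

# base pairs of [start, end) covered by merged features, per query interval
feature_overlap_bp <- function(query, features) {
  features <- merge_intervals(features)
  bp <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qk <- which(query$chrom == ch)
    f <- features[features$chrom == ch, ]
    if (nrow(f) == 0) next
    cumlen <- c(0, cumsum(f$end - f$start))
    # feature base pairs strictly below x
    below <- function(x) {
      k <- pmax(findInterval(x, f$start), 1L)
      v <- cumlen[k] + pmax(pmin(x, f$end[k]) - f$start[k], 0)
      v[findInterval(x, f$start) == 0L] <- 0
      v
    }
    bp[qk] <- below(query$end[qk]) - below(query$start[qk])
  }
  bp
}

#' Fraction of reads inside called islands
#'
#' The number of reads falling within island boundaries divided by the
#' total number of reads; a read counts as inside if its midpoint lies in
#' an island. Used to match operating points between callers.
#'
#' @param islands Tibble of regions (`chrom`, `start`, `end`).
#' @param reads Read tibble.
#' @return Fraction in `[0, 1]`.
#' @export
island_read_coverage <- function(islands, reads) {
  if (nrow(reads) == 0) stop("no reads supplied", call. = FALSE)
  if (is.null(islands) || nrow(islands) == 0) {
    return(0)
  }
  sum(count_reads_in(islands, reads)) / nrow(reads)
}

#' Average base-pair overlap fraction of islands with a feature set
#'
#' Islands not intersecting any feature over at least one base pair are
#' first filtered out; each remaining island contributes the number of its
#' base pairs intersecting the features divided by its own length, and the
#' ratios are averaged (islands weighted equally).
#'
#' @param islands Tibble of called regions.
#' @param features Tibble of feature intervals (genes, intergenic space, a
#'   replicate's islands, ...); overlapping features are merged first.
#' @return Mean overlap ratio in `[0, 1]`; 0 with a warning if no island
#'   overlaps any feature.
#' @export
overlap_fraction <- function(islands, features) {
  if (is.null(islands) || nrow(islands) == 0 ||
    is.null(features) || nrow(features) == 0) {
    warning("no overlapping islands", call. = FALSE)
    return(0)
  }
  ov <- feature_overlap_bp(islands, features)
  keep <- ov > 0
  if (!any(keep)) {
    warning("no overlapping islands", call. = FALSE)
    return(0)
  }
  mean(ov[keep] / (islands$end - islands$start)[keep])
}

#' Cumulative motif occurrence over ranked peaks
#'
#' Peaks are evaluated in rank order (strongest first); a peak matches if
#' the window of `flank` bp either side of its summit intersects at least
#' one motif hit. The curve value at rank `r` is the number of matching
#' peaks among the top `r` divided by `r`.
#'
#' @param ranked_peaks Tibble of TF peaks sorted by decreasing score, with
#'   a `summit` column.
#' @param motif_hits Tibble of motif match intervals.
#' @param flank Half-width of the summit window in bp.
#' @return Tibble `(rank, matched, rate)`.
#' @export
cumulative_motif_rate <- function(ranked_peaks, motif_hits, flank = 150L) {
  if (!"summit" %in% names(ranked_peaks) || anyNA(ranked_peaks$summit)) {
    stop("peaks must carry summits (TF mode)", call. = FALSE)
  }
  win <- tibble::tibble(
    chrom = ranked_peaks$chrom,
    start = pmax(ranked_peaks$summit - flank, 0L),
    end = ranked_peaks$summit + flank + 1L
  )
  matched <- if (is.null(motif_hits) || nrow(motif_hits) == 0) {
    rep(FALSE, nrow(ranked_peaks))
  } else {
    feature_overlap_bp(win, motif_hits) > 0
  }
  tibble::tibble(
    rank = seq_len(nrow(ranked_peaks)),
    matched = matched,
    rate = cumsum(matched) / seq_len(nrow(ranked_peaks))
  )
}
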