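# evaluate code with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a count track from the generative model
#'
#' Draws the model exactly as specified: the first block starts a segment
#' with level `lambda ~ Gamma(alpha, beta)`; at each subsequent block a
#' change occurs with probability `p`, in which case a new level is drawn;
#' counts are Poisson around the current level.
#'
#' @param n Number of blocks.
#' @param params A [bcp_params()] object.
#' @param seed Integer seed; the caller's RNG state is untouched.
#' @return List with `lambda` (true level per block) and `track`, a
#'   unit-width `bcp_track`.
#' @export
simulate_track <- function(n, params, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    change <- c(TRUE, stats::runif(n - 1) < params$p)
    levels <- stats::rgamma(sum(change), shape = params$alpha, rate = params$beta)
    lambda <- levels[cumsum(change)]
    y <- stats::rpois(n, lambda)
    list(
      lambda = lambda,
      track = new_bcp_track(
        tibble::tibble(
          chrom = "sim",
          start = 0:(n - 1), end = 1:n, count = y
        ),
        mode = "hm", window = 1L
      )
    )
  })
}

#' Describe a simulated chromosome
#'
#' A piecewise-constant fragment-density profile over one chromosome:
#' background density everywhere except inside enriched segments, where
#' the stated density applies. Densities are expected fragments per base
#' pair.
#'
#' @param chrom Chromosome name.
#' @param chrom_span Chromosome length in bp.
#' @param segments Tibble with `start`, `end`, `density` (disjoint, inside
#'   the span) or `NULL` for background only.
#' @param background_density Fragments per bp outside segments. The
#'   default, with 200 bp fragments, gives a mean window count of about 1.
#' @param fragment_length,read_length Fragment and read sizes in bp.
#' @param seed Default seed for [simulate_reads()].
#' @return A `sim_profile` object.
#' @export
sim_profile <- function(chrom = "chr1", chrom_span = 2e6, segments = NULL,
                        background_density = 0.005, fragment_length = 200L,
                        read_length = 36L, seed = 1L) {
  if (!is.null(segments)) {
    segments <- segments[order(segments$start), ]
    stopifnot(
      all(segments$density > 0),
      all(segments$start >= 0), all(segments$end <= chrom_span),
      all(segments$start < segments$end),
      all(diff(as.vector(rbind(segments$start, segments$end))) >= 0)
    )
  }
  structure(
    list(
      chrom = chrom, chrom_span = chrom_span, segments = segments,
      background_density = background_density,
      fragment_length = as.integer(fragment_length),
      read_length = as.integer(read_length), seed = seed
    ),
    class = "sim_profile"
  )
}

#' Draw random enriched segments for a profile
#'
#' Places `n` disjoint enriched segments of uniform random length between
#' `min_len` and `max_len` on a chromosome, each at `fold` times the
#' background density — mimicking broad histone-modification domains.
#'
#' @param n Number of segments.
#' @param chrom_span Chromosome length (bp).
#' @param min_len,max_len Segment length range (bp).
#' @param fold Enrichment over background.
#' @param background_density Background fragments per bp.
#' @param seed Integer seed.
#' @return Tibble `(start, end, density)` sorted by `start`.
#' @export
sim_segments <- function(n = 10, chrom_span = 2e6, min_len = 5000,
                         max_len = 50000, fold = 5,
                         background_density = 0.005, seed = 1L) {
  with_seed(seed, {
    for (attempt in 1:100) {
      len <- as.integer(stats::runif(n, min_len, max_len))
      start <- as.integer(sort(stats::runif(n, 0, chrom_span - max(len))))
      end <- start + len
      if (all(start[-1] > utils::head(end, -1) + 1000)) break
    }
    if (any(start[-1] <= utils::head(end, -1) + 1000)) {
      stop("could not place disjoint segments; reduce n or lengths",
        call. = FALSE
      )
    }
    tibble::tibble(start = start, end = end, density = fold * background_density)
  })
}

#' Simulate stranded reads from a density profile
#'
#' Fragment start positions are drawn proportional to the profile density
#' (uniform background only when `is_control = TRUE`); each fragment is
#' sequenced from a uniformly random end, so plus-strand reads are the
#' first `read_length` bp and minus-strand reads the last `read_length`
#' bp. This reproduces the bimodal strand offset around point sources that
#' [estimate_shift()] recovers.
#'
#' @param profile A [sim_profile()].
#' @param n_reads Number of reads, >= 1.
#' @param is_control If `TRUE`, ignore segments and draw uniformly.
#' @param seed Integer seed (defaults to the profile's).
#' @return Read tibble sorted by `(chrom, start)`.
#' @export
simulate_reads <- function(profile, n_reads, is_control = FALSE,
                           seed = profile$seed) {
  if (n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  fl <- profile$fragment_length
  rl <- profile$read_length
  hi <- profile$chrom_span - fl
  pieces <- tibble::tibble(
    start = 0, end = hi,
    density = profile$background_density
  )
  if (!is_control && !is.null(profile$segments)) {
    seg <- profile$segments
    bounds <- sort(unique(c(0, pmin(c(seg$start, seg$end), hi), hi)))
    dens <- rep(profile$background_density, length(bounds) - 1)
    for (k in seq_len(nrow(seg))) {
      inside <- bounds[-length(bounds)] >= seg$start[k] &
        bounds[-1] <= min(seg$end[k], hi)
      dens[inside] <- seg$density[k]
    }
    pieces <- tibble::tibble(
      start = bounds[-length(bounds)], end = bounds[-1], density = dens
    )
  }
  with_seed(seed, {
    w <- pieces$density * (pieces$end - pieces$start)
    piece <- sample.int(nrow(pieces), n_reads, replace = TRUE, prob = w)
    fs <- floor(pieces$start[piece] +
      stats::runif(n_reads) * (pieces$end - pieces$start)[piece])
    plus <- stats::runif(n_reads) < 0.5
    tibble::tibble(
      chrom = profile$chrom,
      start = as.integer(ifelse(plus, fs, fs + fl - rl)),
      end = as.integer(ifelse(plus, fs + rl, fs + fl)),
      strand = ifelse(plus, "+", "-")
    ) |>
      dplyr::arrange(.data$start, .data$end, .data$strand)
  })
}
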