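new_bcp_track <- function(df, mode, window = NA_integer_) {
  structure(df,
    class = c("bcp_track", class(tibble::tibble())),
    mode = mode, window = window
  )
}

track_mode <- function(track) attr(track, "mode", exact = TRUE)

# per-base coverage of [start, end) intervals as a step function over
# [0, span): tibble(start, end, count) tiling the span, runs NOT merged
coverage_steps <- function(starts, ends, span) {
  keep <- ends > 0 & starts < span
  starts <- pmax(starts[keep], 0)
  ends <- pmin(ends[keep], span)
  brk <- sort(unique(c(0, starts, ends, span)))
  m <- length(brk)
  ns <- findInterval(brk[-m], sort(starts))
  ne <- findInterval(brk[-m], sort(ends))
  tibble::tibble(
    start = as.integer(brk[-m]), end = as.integer(brk[-1]),
    count = ns - ne
  )
}

#' Remove duplicate reads
#'
#' Retains at most one read per identical `(chrom, start, end, strand)`
#' tuple, reducing spurious PCR amplification and repeat bias. Reads that
#' share a start but differ in strand or end are all retained. Input order
#' is preserved.
#'
#' @param reads Tibble of reads sorted by `(chrom, start)`.
#' @return Tibble with duplicates removed.
#' @export
deduplicate <- function(reads) {
  dplyr::distinct(reads, .data$chrom, .data$start, .data$end, .data$strand,
    .keep_all = TRUE
  )
}

# local maxima of the 5'-end density on one strand. After coordinate
# deduplication at most one read remains per position, so the density is
# the number of 5' ends within +/- flank bp of each occupied position; a
# local maximum is a position whose density is >= every density within
# +/- flank. Returned sorted by density desc, position asc.
strand_local_maxima <- function(pos5, flank = 25L, n_cand = 5000L) {
  tab <- table(pos5)
  p_all <- sort(as.integer(names(tab)))
  c_all <- as.integer(tab[as.character(p_all)])
  cum <- c(0L, cumsum(c_all))
  wcount <- function(x) {
    cum[findInterval(x + flank, p_all) + 1L] -
      cum[findInterval(x - flank - 1L, p_all) + 1L]
  }
  w_all <- wcount(p_all)
  cand <- utils::head(order(-w_all, p_all), n_cand)
  lo <- findInterval(p_all[cand] - flank - 1L, p_all) + 1L
  hi <- findInterval(p_all[cand] + flank, p_all)
  is_max <- vapply(
    seq_along(cand),
    function(k) w_all[cand[k]] >= max(w_all[lo[k]:hi[k]]), logical(1)
  )
  tibble::tibble(pos = p_all[cand[is_max]], count = w_all[cand[is_max]])
}

#' Estimate the fragment shift from strand asymmetry
#'
#' ChIP fragments are sequenced from their 5' ends, so reads around a
#' binding site form a bimodal profile: plus-strand reads pile up upstream
#' of the site, minus-strand reads downstream, separated by roughly the
#' fragment length. This pairs highly enriched local maxima of the
#' 5'-end density on the two strands and returns half the median pair
#' distance: the number of base pairs each read should be shifted toward
#' the fragment center (transcription-factor mode).
#'
#' @param reads Tibble of deduplicated reads (`chrom`, `start`, `end`,
#'   `strand`); both strands must be represented.
#' @param max_pair_distance Maximum plus-to-minus distance (bp) for a
#'   valid pair.
#' @param n_top Number of top plus-strand maxima to pair.
#' @param min_pairs Minimum number of pairs required; below this the
#'   estimate falls back to `fragment_length / 2` with a warning.
#' @param fragment_length Fallback fragment length (bp).
#' @return Non-negative integer shift in bp.
#' @export
estimate_shift <- function(reads, max_pair_distance = 500L, n_top = 1000L,
                           min_pairs = 10L, fragment_length = 200L) {
  fallback <- function(msg) {
    warning(msg, "; falling back to fragment_length/2 = ",
      as.integer(fragment_length / 2),
      call. = FALSE
    )
    as.integer(fragment_length / 2)
  }
  if (!all(c("+", "-") %in% reads$strand)) {
    return(fallback("reads do not contain both strands"))
  }
  dists <- unlist(lapply(
    split(reads, reads$chrom),
    function(r) {
      plus <- r$start[r$strand == "+"] # plus-strand 5' end
      minus <- r$end[r$strand == "-"] # minus-strand 5' end (half-open end)
      if (length(plus) == 0 || length(minus) == 0) {
        return(numeric())
      }
      pk_p <- strand_local_maxima(plus)
      pk_m <- strand_local_maxima(minus)
      # "highly enriched" maxima only: drop singleton piles and anything
      # far below the strongest maximum (background positions)
      thr <- max(2, ceiling(0.1 * max(pk_p$count, pk_m$count)))
      pk_p <- dplyr::filter(pk_p, .data$count >= thr)
      pk_m <- dplyr::filter(pk_m, .data$count >= thr)
      if (nrow(pk_p) == 0 || nrow(pk_m) == 0) {
        return(numeric())
      }
      pk_p <- utils::head(pk_p, n_top)
      mpos <- sort(pk_m$pos)
      # nearest minus-strand maximum strictly downstream of each plus max
      idx <- findInterval(pk_p$pos, mpos) + 1L
      ok <- idx <= length(mpos)
      d <- mpos[idx[ok]] - pk_p$pos[ok]
      d[d > 0 & d <= max_pair_distance]
    }
  ), use.names = FALSE)
  if (length(dists) < min_pairs) {
    return(fallback(sprintf(
      "only %d pairable strand maxima (min %d)", length(dists), min_pairs
    )))
  }
  as.integer(floor(stats::median(dists) / 2 + 0.5))
}

#' Shift reads toward the fragment center
#'
#' Moves plus-strand reads `shift` bp downstream and minus-strand reads
#' `shift` bp upstream, clipping at position 0.
#'
#' @param reads Read tibble.
#' @param shift Non-negative shift in bp.
#' @return Read tibble with shifted coordinates.
#' @export
shift_reads <- function(reads, shift) {
  if (shift < 0) stop("shift must be non-negative", call. = FALSE)
  d <- ifelse(reads$strand == "+", as.integer(shift), -as.integer(shift))
  dplyr::mutate(reads,
    start = pmax(.data$start + d, 0L),
    end = pmax(.data$end + d, 1L)
  )
}

#' Build a transcription-factor count track
#'
#' Shifts each read `shift` bp toward the fragment center (plus strand
#' downstream, minus strand upstream), computes per-base read coverage,
#' and blocks together maximal runs of adjacent positions with identical
#' coverage. Block widths are data driven; zero-coverage blocks are kept
#' so blocks tile `[0, span)` per chromosome.
#'
#' @param reads Deduplicated reads tibble.
#' @param shift Non-negative shift in bp (see [estimate_shift()]).
#' @param span Optional named vector of chromosome spans (bp); defaults to
#'   the maximum shifted read end per chromosome.
#' @return A `bcp_track` tibble with columns `chrom`, `start`, `end`,
#'   `count` (mode `"tf"`).
#' @export
build_tf_track <- function(reads, shift, span = NULL) {
  if (shift < 0) stop("shift must be non-negative", call. = FALSE)
  shift <- as.integer(shift)
  if (nrow(reads) == 0) {
    blocks <- if (is.null(span)) {
      tibble::tibble(
        chrom = character(), start = integer(),
        end = integer(), count = integer()
      )
    } else {
      tibble::tibble(
        chrom = names(span), start = 0L,
        end = as.integer(span), count = 0L
      )
    }
    return(new_bcp_track(blocks, mode = "tf"))
  }
  shifted <- shift_reads(reads, shift)
  out <- lapply(split(shifted, shifted$chrom), function(r) {
    sp <- if (!is.null(span)) span[[r$chrom[1]]] else max(r$end)
    steps <- coverage_steps(r$start, r$end, sp)
    runs <- rle(steps$count)
    last <- cumsum(runs$lengths)
    first <- c(1L, utils::head(last, -1) + 1L)
    tibble::tibble(
      chrom = r$chrom[1],
      start = steps$start[first], end = steps$end[last],
      count = runs$values
    )
  })
  new_bcp_track(dplyr::bind_rows(out), mode = "tf")
}

#' Build a histone-modification count track
#'
#' Extends each read from its 5' end in the strand direction to the
#' specified fragment length, computes per-base coverage, and averages it
#' over fixed, consecutive windows tiling the chromosome from position 0
#' (the last window may be shorter). Window averages are rounded to the
#' nearest integer (halves away from zero) to give the observation
#' sequence.
#'
#' @param reads Deduplicated reads tibble.
#' @param fragment_length Fragment length in bp to extend each read to.
#' @param window Window width in bp; 200 approximates one nucleosome unit
#'   (wound plus linker DNA) and the typical size-selected fragment.
#' @param span Optional named vector of chromosome spans.
#' @return A `bcp_track` tibble (mode `"hm"`, fixed-width blocks).
#' @export
build_hm_track <- function(reads, fragment_length = 200L, window = 200L,
                           span = NULL) {
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  out <- lapply(split(reads, reads$chrom), function(r) {
    plus <- r$strand == "+"
    s <- ifelse(plus, r$start, pmax(r$end - fragment_length, 0L))
    e <- ifelse(plus, r$start + fragment_length, r$end)
    sp <- if (!is.null(span)) span[[r$chrom[1]]] else max(e)
    steps <- coverage_steps(s, e, sp)
    # cumulative coverage mass up to each breakpoint
    cum <- c(0, cumsum(as.numeric(steps$count) * (steps$end - steps$start)))
    brk <- c(steps$start, sp)
    w <- unique(c(seq(0L, sp, by = as.integer(window)), sp))
    mass_at <- function(x) {
      k <- findInterval(x, brk, rightmost.closed = TRUE)
      k <- pmax(pmin(k, length(steps$count)), 1L)
      cum[k] + steps$count[k] * (x - brk[k])
    }
    mass <- mass_at(w)
    avg <- diff(mass) / diff(w)
    tibble::tibble(
      chrom = r$chrom[1],
      start = as.integer(utils::head(w, -1)), end = as.integer(w[-1]),
      count = as.integer(floor(avg + 0.5))
    )
  })
  new_bcp_track(dplyr::bind_rows(out), mode = "hm", window = as.integer(window))
}
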