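#' Read aligned reads from a BED file
#'
#' Parses a BED file of aligned reads into a tibble of stranded genomic
#' intervals. Coordinates follow the UCSC BED convention: 0-based,
#' half-open `[start, end)`. Lines with six or more fields use field 6 as
#' the strand; files with only three fields are accepted, with the strand
#' defaulting to `"+"` and a warning (strand matters for fragment-shift
#' estimation in transcription-factor mode, where it must be present).
#'
#' Duplicate reads are *not* removed here; see [deduplicate()].
#'
#' @param path Path to a BED file (plain text, tab or whitespace
#'   separated). Comment lines starting with `#`, `track` or `browser`
#'   are ignored.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   grouped by chromosome and sorted by `start` within each.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t136\tr1\t0\t+", "chr1\t90\t126\tr2\t0\t-"), bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    stop("BED file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|track\\b|browser\\b|$)", lines)
  if (!any(keep)) {
    return(tibble::tibble(
      chrom = character(), start = integer(),
      end = integer(), strand = character()
    ))
  }
  lineno <- which(keep)
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- lineno[which(nf < 3)[1]]
    stop("malformed BED line ", bad, ": fewer than 3 fields", call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- lineno[which(is.na(start) | is.na(end))[1]]
    stop("malformed BED line ", bad, ": non-numeric coordinates",
      call. = FALSE
    )
  }
  if (any(nf >= 6L)) {
    strand <- rep("+", length(fields))
    has6 <- nf >= 6L
    strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
    strand[strand == "."] <- "+"
    if (!all(has6)) {
      warning("some BED lines lack a strand field; defaulting to '+'",
        call. = FALSE
      )
    }
    ok <- strand %in% c("+", "-")
    if (!all(ok)) {
      bad <- lineno[which(!ok)[1]]
      stop("malformed BED line ", bad, ": strand must be '+' or '-'",
        call. = FALSE
      )
    }
  } else {
    warning("BED file has no strand column; defaulting all reads to '+'",
      call. = FALSE
    )
    strand <- rep("+", length(fields))
  }
  if (any(start < 0L)) {
    bad <- lineno[which(start < 0L)[1]]
    stop("invalid interval at BED line ", bad, ": start < 0", call. = FALSE)
  }
  if (any(end <= start)) {
    bad <- lineno[which(end <= start)[1]]
    stop("invalid interval at BED line ", bad, ": end <= start",
      call. = FALSE
    )
  }
  tibble::tibble(chrom = chrom, start = start, end = end, strand = strand) |>
    dplyr::arrange(.data$chrom, .data$start, .data$end, .data$strand)
}

#' Write reads to a BED6 file
#'
#' Inverse of [read_bed()] for synthetic or processed read sets: writes
#' `chrom start end name 0 strand` lines.
#'
#' @param reads Tibble with `chrom`, `start`, `end`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reads_bed <- function(reads, path) {
  lines <- sprintf(
    "%s\t%d\t%d\tread_%d\t0\t%s",
    reads$chrom, reads$start, reads$end, seq_len(nrow(reads)), reads$strand
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write called regions to a BED file
#'
#' Writes peaks or islands as BED6: `chrom start end name score strand`,
#' with names `peak_N` (TF mode) or `island_N` (HM mode), score
#' `-log10(p-value)` and strand `"."`. In TF mode the summit offset
#' relative to `start` is appended as a seventh column. When the p-value
#' underflows to zero the score is written as `score_cap`.
#'
#' @param regions Tibble of region calls sorted by `(chrom, start)`, with
#'   columns `chrom`, `start`, `end`, `pvalue` and, in TF mode, `summit`.
#' @param path Output path.
#' @param mode `"hm"` (islands) or `"tf"` (peaks with summit column).
#' @param score_cap Score written when the p-value is exactly 0.
#' @return Invisibly, `path`.
#' @export
write_regions_bed <- function(regions, path, mode = c("hm", "tf"),
                              score_cap = 1000) {
  mode <- match.arg(mode)
  header <- "# chrom\tstart\tend\tname\tscore\tstrand"
  if (is.null(regions) || nrow(regions) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  label <- if (mode == "tf") "peak" else "island"
  score <- ifelse(regions$pvalue <= 0, score_cap,
    pmin(-log10(regions$pvalue), score_cap)
  )
  lines <- sprintf(
    "%s\t%d\t%d\t%s_%d\t%s\t.",
    regions$chrom, regions$start, regions$end, label,
    seq_len(nrow(regions)), format(score, trim = TRUE, digits = 8)
  )
  if (mode == "tf") {
    lines <- sprintf("%s\t%d", lines, regions$summit - regions$start)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a posterior mean track as bedGraph
#'
#' Serializes the per-block posterior mean density to bedGraph, merging
#' maximal runs of adjacent blocks with equal values. Zero values are kept
#' (the output exactly tiles each chromosome's span).
#'
#' @param track Tibble with `chrom`, `start`, `end`, `lambda_hat` (e.g.
#'   `tidy()` of a [posterior_means()] fit), blocks sorted and
#'   non-overlapping.
#' @param path Output path.
#' @param digits Decimal places for the value column.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path, digits = 4) {
  if (nrow(track) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  val <- round(track$lambda_hat, digits)
  new_run <- c(TRUE, val[-1] != val[-length(val)] |
    track$chrom[-1] != track$chrom[-nrow(track)] |
    track$start[-1] != track$end[-nrow(track)])
  run <- cumsum(new_run)
  merged <- tibble::tibble(
    chrom = track$chrom[new_run],
    start = track$start[new_run],
    end = tapply(track$end, run, function(e) e[length(e)]),
    value = val[new_run]
  )
  lines <- sprintf(
    "%s\t%d\t%d\t%s",
    merged$chrom, merged$start, as.integer(merged$end),
    formatC(merged$value, format = "f", digits = digits)
  )
  writeLines(lines, path)
  invisible(path)
}
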