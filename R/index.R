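#' Compute per-bulk SNP/InDel-index and the delta-index track
#'
#' For each marker and bulk, the index is the fraction of reads carrying the
#' non-P1 allele: 0 when the bulk fully matches the reference (papilla)
#' parent, 1 when fully mismatched. The delta-index is the non-papilla bulk's
#' index minus the papilla bulk's index, so a dominant P1 papilla allele pulls
#' the delta toward +2/3 at linked markers. Markers with zero depth in either
#' bulk are excluded and counted.
#'
#' @param markers A screened marker table ([screen_homozygous_differential()]
#'   or [marker_table_from_sim()]).
#' @return An index-track tibble: `marker_class`, `chrom`, `pos`,
#'   `index_papilla`, `index_nonpapilla`, `delta_index`, sorted by chromosome
#'   and position. The number of zero-depth markers excluded is attached as
#'   attribute `"zero_depth_excluded"`.
#' @examples
#' tbl <- tibble::tibble(
#'   marker_class = "SNP", chrom = "chr1", pos = c(100L, 200L),
#'   ref = "A", alt = "G", parent1_gt = "0/0", parent2_gt = "1/1",
#'   pap_p1 = c(10L, 20L), pap_nonp1 = c(10L, 10L),
#'   nonpap_p1 = c(0L, 2L), nonpap_nonp1 = c(12L, 18L)
#' )
#' compute_index(tbl)
#' @export
compute_index <- function(markers) {
  pap_depth <- markers$pap_p1 + markers$pap_nonp1
  nonpap_depth <- markers$nonpap_p1 + markers$nonpap_nonp1
  keep <- pap_depth > 0 & nonpap_depth > 0
  out <- tibble::tibble(
    marker_class = markers$marker_class,
    chrom = markers$chrom,
    pos = markers$pos,
    index_papilla = markers$pap_nonp1 / pap_depth,
    index_nonpapilla = markers$nonpap_nonp1 / nonpap_depth
  )[keep, ]
  out$delta_index <- out$index_nonpapilla - out$index_papilla
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  attr(out, "zero_depth_excluded") <- sum(!keep)
  out
}

#' Aggregate a delta-index track into sliding windows
#'
#' Windows of width `window_size` start at position 1 and advance by `step`
#' along each chromosome, up to the chromosome length (taken from
#' `chrom_lengths` or, failing that, the last marker position). Each window
#' carries the arithmetic mean delta-index over the markers it contains;
#' windows holding no markers are flagged `empty` and never thresholded.
#'
#' @param track An index track from [compute_index()].
#' @param window_size Window width in bp (default 1 Mb).
#' @param step Stride in bp (default 100 kb); must satisfy
#'   `window_size >= step > 0`.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp.
#' @return A window-track tibble: `chrom`, `start`, `end`, `n_markers`,
#'   `mean_delta`, `empty`.
#' @export
window_track <- function(track, window_size = 1e6, step = 1e5,
                         chrom_lengths = NULL) {
  if (step <= 0 || window_size < step) {
    stop("need window_size >= step > 0", call. = FALSE)
  }
  by_chrom <- split(track, track$chrom)
  purrr::map_dfr(names(by_chrom), function(ch) {
    t <- dplyr::arrange(by_chrom[[ch]], .data$pos)
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(t$pos)
    }
    starts <- seq(1, len, by = step)
    ends <- pmin(starts + window_size - 1, len)
    cs <- cumsum(t$delta_index)
    lo <- findInterval(starts - 1, t$pos) # markers at pos < start
    hi <- findInterval(ends, t$pos) # markers at pos <= end
    n <- hi - lo
    total <- c(0, cs)[hi + 1] - c(0, cs)[lo + 1]
    tibble::tibble(
      chrom = ch,
      start = as.numeric(starts),
      end = as.numeric(ends),
      n_markers = as.integer(n),
      mean_delta = ifelse(n > 0, total / n, NA_real_),
      empty = n == 0
    )
  })
}

#' Call candidate intervals from a window track
#'
#' Selects windows whose absolute mean delta-index meets the screening
#' threshold (boundary included) and merges overlapping or book-ended
#' selected windows on the same chromosome into candidate intervals. Windows
#' that are empty or hold fewer than `min_markers` markers never qualify,
#' which suppresses spurious single-marker calls.
#'
#' @param windows A window track from [window_track()].
#' @param track The marker-level index track; used to count supporting
#'   markers and locate the peak |delta| marker inside each interval.
#'   `NULL` leaves those columns `NA`.
#' @param threshold Screening threshold on |mean delta-index|, in (0, 1]
#'   (default 0.5).
#' @param min_markers Minimum markers per window for it to qualify.
#' @return Tibble of candidate intervals: `chrom`, `start`, `end`,
#'   `n_windows`, `n_markers`, `peak_pos`, `peak_delta`.
#' @export
call_intervals <- function(windows, track = NULL, threshold = 0.5,
                           min_markers = 5) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  hit <- windows[!windows$empty &
    windows$n_markers >= min_markers &
    abs(windows$mean_delta) >= threshold, ]
  out <- tibble::tibble(
    chrom = character(), start = numeric(), end = numeric(),
    n_windows = integer(), n_markers = integer(),
    peak_pos = numeric(), peak_delta = numeric()
  )
  if (nrow(hit) == 0) {
    return(out)
  }
  hit <- dplyr::arrange(hit, .data$chrom, .data$start)
  merged <- list()
  cur <- NULL
  for (i in seq_len(nrow(hit))) {
    w <- hit[i, ]
    if (!is.null(cur) && w$chrom == cur$chrom && w$start <= cur$end + 1) {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      if (!is.null(cur)) merged[[length(merged) + 1]] <- cur
      cur <- list(
        chrom = w$chrom, start = w$start, end = w$end, n_windows = 1L
      )
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- purrr::map_dfr(merged, function(iv) {
    n_mk <- NA_integer_
    peak_pos <- NA_real_
    peak_delta <- NA_real_
    if (!is.null(track)) {
      inside <- track[track$chrom == iv$chrom &
        track$pos >= iv$start & track$pos <= iv$end, ]
      n_mk <- nrow(inside)
      if (n_mk > 0) {
        k <- which.max(abs(inside$delta_index))
        peak_pos <- inside$pos[k]
        peak_delta <- inside$delta_index[k]
      }
    }
    tibble::tibble(
      chrom = iv$chrom, start = iv$start, end = iv$end,
      n_windows = iv$n_windows, n_markers = n_mk,
      peak_pos = peak_pos, peak_delta = peak_delta
    )
  })
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Per-chromosome summary of above-threshold markers
#'
#' Counts, per chromosome, markers whose |delta-index| meets the threshold,
#' and reports the genome-wide argmax |delta| marker. The argmax is reported
#' only when the maximum |delta| is positive; an empty or all-zero track has
#' no argmax.
#'
#' @param track An index track from [compute_index()].
#' @param threshold Threshold on |delta-index| (default 0.5).
#' @return Tibble with one row per chromosome: `chrom`, `n_markers`,
#'   `n_above_threshold`, `is_argmax_chrom`. Attributes `argmax_chrom`,
#'   `argmax_pos`, `argmax_delta` carry the peak marker (all `NA` when
#'   undefined); [glance_chromosome_summary()] exposes them tidily.
#' @export
summarize_chromosomes <- function(track, threshold = 0.5) {
  out <- track |>
    dplyr::group_by(chrom = .data$chrom) |>
    dplyr::summarise(
      n_markers = dplyr::n(),
      n_above_threshold = sum(abs(.data$delta_index) >= threshold),
      .groups = "drop"
    )
  argmax_chrom <- NA_character_
  argmax_pos <- NA_real_
  argmax_delta <- NA_real_
  if (nrow(track) > 0 && max(abs(track$delta_index)) > 0) {
    k <- which.max(abs(track$delta_index))
    argmax_chrom <- track$chrom[k]
    argmax_pos <- track$pos[k]
    argmax_delta <- track$delta_index[k]
  }
  out$is_argmax_chrom <- !is.na(argmax_chrom) & out$chrom == argmax_chrom
  attr(out, "argmax_chrom") <- argmax_chrom
  attr(out, "argmax_pos") <- argmax_pos
  attr(out, "argmax_delta") <- argmax_delta
  out
}

#' @rdname summarize_chromosomes
#' @param summary Output of [summarize_chromosomes()].
#' @export
glance_chromosome_summary <- function(summary) {
  tibble::tibble(
    argmax_chrom = attr(summary, "argmax_chrom"),
    argmax_pos = attr(summary, "argmax_pos"),
    argmax_delta = attr(summary, "argmax_delta"),
    top_count_chrom = if (nrow(summary) > 0 && any(summary$n_above_threshold > 0)) {
      summary$chrom[which.max(summary$n_above_threshold)]
    } else {
      NA_character_
    }
  )
}

#' Export candidate intervals as BED
#'
#' BED uses 0-based half-open coordinates; internal intervals are 1-based
#' inclusive, so starts shift down by one.
#'
#' @param intervals Output of [call_intervals()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  lines <- sprintf(
    "%s\t%d\t%d\tinterval_%d\t%s\t.",
    intervals$chrom,
    as.integer(intervals$start - 1),
    as.integer(intervals$end),
    seq_len(nrow(intervals)),
    format(intervals$peak_delta, digits = 4)
  )
  writeLines(lines, path)
  invisible(path)
}
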