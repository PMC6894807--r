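# Movement segmentation: short-time energy of the accelerometer norm, an
# adaptive threshold found as the slope change-point of the sorted energy
# array, and merging of stable frames into intervals.

#' Short-time accelerometer frame energy
#'
#' Sum of squared samples over 5 s frames (100 samples at 20 Hz) with 50%
#' overlap. The trailing partial frame is dropped.
#'
#' @param accel_norm accelerometer norm series at `rate` Hz.
#' @param rate sampling rate, Hz.
#' @param frame_len frame length in samples (default 100 = 5 s).
#' @param hop hop in samples (default `frame_len / 2`).
#' @return object of class `frame_energy`: list with `energies`,
#'   `frame_times` (frame centres, s), `frame_len_samples`, `hop_samples`,
#'   `rate`.
#' @export
frame_energy <- function(accel_norm, rate = 20, frame_len = 100L,
                         hop = frame_len %/% 2L) {
  n <- length(accel_norm)
  if (n < frame_len) {
    warning("frame_energy: series shorter than one frame")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n - frame_len + 1L, by = hop)
  }
  cs <- c(0, cumsum(accel_norm^2))
  energies <- cs[starts + frame_len] - cs[starts]
  structure(list(
    energies = energies,
    frame_times = (starts - 1 + frame_len / 2) / rate,
    frame_len_samples = frame_len,
    hop_samples = hop,
    rate = rate
  ), class = "frame_energy")
}

#' Adaptive energy threshold separating rest from movement
#'
#' Finds a frame-energy threshold by change-point detection on the sorted
#' energy distribution: (1) energies sorted ascending; (2) resampled to
#' exactly `n_resampled` (1080) points by uniform index selection (linear
#' interpolation upward when fewer frames are available); (3) the slope of
#' a linear regression over every 6 consecutive points with 50% overlap,
#' giving 359 slopes; (4) scanning from slope index 90 (25% of 359 --- at
#' least a quarter of the night is assumed at rest), the first slope
#' exceeding `slope_ratio` (5.8) times the running mean of all previous
#' slopes marks the change point; (5) the threshold is the median of that
#' window's 6 energy values. If no slope qualifies the whole night is
#' considered stable and the maximum energy is returned with a warning.
#'
#' @param fe a [frame_energy()] object, or a bare numeric vector of frame
#'   energies.
#' @param slope_ratio slope-jump ratio (default 5.8).
#' @param rest_fraction assumed minimum fraction of the night at rest
#'   (default 0.25); sets the scan start index.
#' @param n_resampled length of the resampled sorted array (default 1080).
#' @param slope_window,slope_hop regression window and hop (defaults 6, 3).
#' @return threshold (numeric scalar) with attribute `details`: list with
#'   `sorted_resampled`, `slopes`, `scan_start` (0-based), `change_index`
#'   (0-based, NA if none).
#' @export
adaptive_energy_threshold <- function(fe, slope_ratio = 5.8,
                                      rest_fraction = 0.25,
                                      n_resampled = 1080L,
                                      slope_window = 6L, slope_hop = 3L) {
  e <- if (inherits(fe, "frame_energy")) fe$energies else as.numeric(fe)
  if (length(e) < slope_window)
    stop("adaptive_energy_threshold: need at least ", slope_window, " frames")
  s <- sort(e)
  n <- length(s)
  if (n >= n_resampled) {
    idx <- round(seq(1, n, length.out = n_resampled))
    sr <- s[idx]
  } else {
    sr <- approx(seq_len(n), s, xout = seq(1, n, length.out = n_resampled))$y
  }

  starts <- seq(1L, n_resampled - slope_window + 1L, by = slope_hop)
  xs <- seq_len(slope_window)
  xc <- xs - mean(xs)
  denom <- sum(xc^2)
  slopes <- vapply(starts, function(st) {
    y <- sr[st:(st + slope_window - 1L)]
    sum(xc * y) / denom
  }, numeric(1))

  n_slopes <- length(slopes)
  scan_start <- round(n_slopes * rest_fraction)      # 0-based index
  change <- NA_integer_
  run_sum <- cumsum(slopes)
  for (i in (scan_start + 1L):n_slopes) {            # 1-based loop
    prev_mean <- run_sum[i - 1L] / (i - 1L)
    if (is.finite(prev_mean) && prev_mean > 0 &&
        slopes[i] > slope_ratio * prev_mean) { change <- i; break }
  }

  if (is.na(change)) {
    warning("adaptive_energy_threshold: no slope change found; whole night stable")
    thr <- max(e)
  } else {
    st <- starts[change]
    thr <- median(sr[st:(st + slope_window - 1L)])
  }
  attr(thr, "details") <- list(
    sorted_resampled = sr,
    slopes = slopes,
    scan_start = scan_start,
    change_index = if (is.na(change)) NA_integer_ else change - 1L
  )
  thr
}

#' Segment the night into stable (movement-free) periods
#'
#' Frames below the threshold are stable; overlapping stable frames merge
#' into intervals; movement gaps shorter than `max_gap_s` (2 min) between
#' stable intervals are absorbed to preserve signal congruity.
#'
#' @param fe a [frame_energy()] object.
#' @param threshold energy threshold from [adaptive_energy_threshold()].
#' @param max_gap_s movement gaps shorter than this are absorbed (s).
#' @return object of class `stable_periods`: list with `intervals`
#'   (data.frame `start_s`, `end_s`, `has_gap`) and `energy_threshold`.
#' @export
segment_stable_periods <- function(fe, threshold, max_gap_s = 120) {
  stopifnot(inherits(fe, "frame_energy"))
  half <- fe$frame_len_samples / 2 / fe$rate
  stable <- fe$energies < threshold
  iv <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (any(stable)) {
    r <- rle(stable)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    iv <- data.frame(start_s = fe$frame_times[starts[keep]] - half,
                     end_s = fe$frame_times[ends[keep]] + half)
    iv$start_s <- pmax(iv$start_s, 0)
  }
  # absorb short movement gaps, one left-to-right pass
  has_gap <- logical(nrow(iv))
  if (nrow(iv) > 1) {
    out <- iv[1, , drop = FALSE]
    gaps <- logical(1)
    for (i in 2:nrow(iv)) {
      gap <- iv$start_s[i] - out$end_s[nrow(out)]
      if (gap < max_gap_s) {
        out$end_s[nrow(out)] <- iv$end_s[i]
        gaps[length(gaps)] <- TRUE
      } else {
        out <- rbind(out, iv[i, , drop = FALSE])
        gaps <- c(gaps, FALSE)
      }
    }
    iv <- out
    has_gap <- gaps
  }
  iv$has_gap <- has_gap
  rownames(iv) <- NULL
  structure(list(intervals = iv, energy_threshold = as.numeric(threshold)),
            class = "stable_periods")
}

#' @export
print.stable_periods <- function(x, ...) {
  cat("<stable_periods>", nrow(x$intervals), "interval(s), threshold",
      format(x$energy_threshold), "\n")
  if (nrow(x$intervals)) print(x$intervals)
  invisible(x)
}

#' Export stable periods
#'
#' Writes intervals as a BED-like 3-column text file (`start_s`, `end_s`,
#' label) or JSON.
#'
#' @param sp a `stable_periods` object.
#' @param path output path.
#' @param format `"bed"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_stable_periods <- function(sp, path, format = c("bed", "json")) {
  format <- match.arg(format)
  iv <- sp$intervals
  if (format == "bed") {
    lab <- ifelse(iv$has_gap, "stable_with_gap", "stable")
    utils::write.table(data.frame(iv$start_s, iv$end_s, lab), path,
                       sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    jsonlite::write_json(list(energy_threshold = sp$energy_threshold,
                              intervals = iv), path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
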