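# Automatic multiscale-based peak detection (AMPD): a local-maxima
# scalogram over window scales k = 1..L; the scale with the most local
# maxima (the row of minima of the scalogram) selects lambda, and peaks are
# the samples that are local maxima at every scale up to lambda. The
# deterministic form of the scalogram is used (membership counts instead of
# randomized entries); the selected scale and surviving columns are
# identical.

#' AMPD peak detection on one window
#'
#' The window is linearly detrended first, as the scalogram construction
#' assumes. Complexity is O(n * L); cap `max_scale` (samples) to the
#' longest plausible half-period.
#'
#' @param x numeric window.
#' @param max_scale largest scale (samples) considered; default
#'   `ceiling(length(x)/2) - 1`.
#' @param pad odd-reflection padding length (samples) applied after
#'   detrending so extrema within `max_scale` of the window edges are not
#'   lost; default equal to the scale cap.
#' @return integer vector of peak indices into `x` (possibly empty).
#' @export
ampd <- function(x, max_scale = NULL, pad = max_scale) {
  n0 <- length(x)
  if (n0 < 5) return(integer(0))
  t_idx <- seq_len(n0)
  fit <- stats::lm.fit(cbind(1, t_idx), x)
  xd <- fit$residuals
  np <- 0L
  if (!is.null(pad) && pad > 0) {
    np <- min(n0 - 1L, as.integer(pad))
    xd <- c(2 * xd[1] - xd[(np + 1):2], xd,
            2 * xd[n0] - xd[(n0 - 1):(n0 - np)])
  }
  n <- length(xd)
  L <- ceiling(n / 2) - 1L
  if (!is.null(max_scale)) L <- min(L, as.integer(max_scale))
  if (L < 1) return(integer(0))

  counts <- integer(L)
  is_max <- vector("list", L)
  for (k in seq_len(L)) {
    ok <- rep(FALSE, n)
    i <- (k + 1L):(n - k)
    ok[i] <- xd[i] > xd[i - k] & xd[i] > xd[i + k]
    is_max[[k]] <- ok
    counts[k] <- sum(ok)
  }
  lambda <- which.max(counts)
  keep <- is_max[[1L]]
  if (lambda > 1) for (k in 2:lambda) keep <- keep & is_max[[k]]
  idx <- which(keep) - np
  idx[idx >= 1L & idx <= n0]
}
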