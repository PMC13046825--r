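# Differential scanning fluorimetry: melting temperature as the maximum of
# the first derivative of the melt curve, plus condition comparison.

#' Melting temperature from a melt curve
#'
#' The curve is optionally smoothed with a centered moving average
#' (`smooth_window` points, odd; 1 = raw data), the first derivative is
#' taken by central differences, and Tm is the temperature of the maximal
#' derivative. Tm is invariant under positive affine transformation of the
#' fluorescence axis. Ties (e.g. a strictly linear ramp) report the first
#' maximum with `tie = TRUE`; a maximum at either end of the usable range
#' sets `boundary = TRUE` since the transition may be truncated.
#'
#' @param temperature degrees C, strictly increasing.
#' @param fluorescence melt-curve readings.
#' @param smooth_window odd moving-average window (points); must be shorter
#'   than the series.
#' @return list with `tm`, `dmax` (max derivative), `boundary`, `tie`.
#' @export
melt_tm <- function(temperature, fluorescence, smooth_window = 5) {
  n <- length(temperature)
  if (n != length(fluorescence))
    stop("temperature and fluorescence lengths differ", call. = FALSE)
  if (any(diff(temperature) <= 0))
    stop("temperature must be strictly increasing", call. = FALSE)
  if (smooth_window %% 2 != 1 || smooth_window < 1)
    stop("smooth_window must be odd and >= 1", call. = FALSE)
  if (smooth_window >= n)
    stop("smooth_window must be shorter than the series", call. = FALSE)
  y <- fluorescence
  if (smooth_window > 1) {
    y <- as.numeric(stats::filter(y, rep(1 / smooth_window, smooth_window),
                                  sides = 2))
    keep <- !is.na(y)
    y <- y[keep]; temperature <- temperature[keep]; n <- length(y)
  }
  if (n < 3) stop("too few points after smoothing", call. = FALSE)
  idx <- 2:(n - 1)
  d <- (y[idx + 1] - y[idx - 1]) / (temperature[idx + 1] -
                                      temperature[idx - 1])
  dmax <- max(d)
  if (dmax <= 0)
    stop("no melting transition: derivative never positive", call. = FALSE)
  hits <- which(d >= dmax * (1 - 1e-12))
  i <- hits[1]
  list(tm = temperature[idx[i]], dmax = dmax,
       boundary = i == 1 || i == length(d), tie = length(hits) > 1)
}

#' Melting-temperature shift between conditions
#'
#' \eqn{\Delta T_m = \bar{T}_m(condition) - \bar{T}_m(reference)}, with the
#' per-replicate values retained for downstream statistics.
#'
#' @param condition_tms,reference_tms numeric vectors of per-replicate Tm
#'   values (degrees C), each non-empty.
#' @return list with `delta_tm`, `condition`, `reference`.
#' @export
delta_tm <- function(condition_tms, reference_tms) {
  if (length(condition_tms) == 0 || length(reference_tms) == 0)
    stop("need >= 1 replicate Tm per group", call. = FALSE)
  list(delta_tm = mean(condition_tms) - mean(reference_tms),
       condition = condition_tms, reference = reference_tms)
}
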