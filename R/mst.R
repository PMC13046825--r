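# Microscale thermophoresis: one-phase decay fits to IR-on timetraces,
# temperature-jump responses, and concentration-response summaries (EC50 via
# a four-parameter log-logistic fit, plus a linear response slope).

#' One-phase exponential decay
#'
#' \deqn{y = (Y_0 - Y_{plateau}) e^{-K x} + Y_{plateau}}
#'
#' @param x time since IR-on (s).
#' @param y0 value at `x = 0`.
#' @param plateau asymptote.
#' @param k decay constant (1/s).
#' @export
eval_decay <- function(x, y0, plateau, k) {
  (y0 - plateau) * exp(-k * x) + plateau
}

#' Fit a one-phase decay to an MST timetrace
#'
#' Least-squares fit of [eval_decay()] restricted to the stated time window
#' (default 5-35 s after IR-on, the standard thermophoresis window that
#' skips the temperature-jump transient).
#'
#' @param time seconds (IR-on at 0).
#' @param fluorescence normalized fluorescence counts.
#' @param window inclusive fit window in seconds.
#' @return object of class `decay_fit`: `y0`, `plateau`, `k`, `window`,
#'   `rss`, `converged`, `non_decaying`, `n`.
#' @export
fit_mst_decay <- function(time, fluorescence, window = c(5, 35)) {
  keep <- time >= window[1] & time <= window[2]
  x <- time[keep]; y <- fluorescence[keep]
  if (length(x) < 6)
    stop("need >= 6 points inside the fit window", call. = FALSE)
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(1, abs(y[1]))) {
    return(structure(list(y0 = y[1], plateau = y[1], k = NA_real_,
                          window = window, rss = 0, converged = FALSE,
                          non_decaying = TRUE, n = length(x)),
                     class = "decay_fit"))
  }
  start <- c(y0 = y[1], plateau = y[length(y)],
             k = 3 / diff(range(x)))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ (y0 - plateau) * exp(-k * (x - 0)) + plateau,
                      start = start,
                      lower = c(y0 = -Inf, plateau = -Inf, k = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(structure(list(y0 = start["y0"], plateau = start["plateau"],
                          k = NA_real_, window = window, rss = NA_real_,
                          converged = FALSE, non_decaying = FALSE,
                          n = length(x)),
                     class = "decay_fit"))
  }
  co <- coef(fit)
  structure(list(y0 = unname(co["y0"]), plateau = unname(co["plateau"]),
                 k = unname(co["k"]), window = window,
                 rss = sum(residuals(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 non_decaying = unname(co["k"]) <= 0, n = length(x)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y0 = %.6g, plateau = %.6g, k = %.6g /s%s\n",
              x$y0, x$plateau, x$k,
              if (x$non_decaying) " [non-decaying]" else ""))
  invisible(x)
}

#' Decay constant from a single model point
#'
#' Algebraic inverse of [eval_decay()]:
#' \deqn{K = -\ln\!\left(\frac{y - Y_{plateau}}{Y_0 - Y_{plateau}}\right)/x}
#' Exact on model-generated points; the normalized residual
#' `(y - plateau)/(y0 - plateau)` must lie in (0, 1].
#'
#' @param x time since IR-on (s), > 0.
#' @param y observed value at `x`.
#' @param fit a `decay_fit`, or anything with `y0`/`plateau` fields.
#' @export
decay_constant <- function(x, y, fit) {
  if (x <= 0) stop("x must be > 0", call. = FALSE)
  ratio <- (y - fit$plateau) / (fit$y0 - fit$plateau)
  if (!is.finite(ratio) || ratio <= 0 || ratio > 1)
    stop("(y - plateau)/(y0 - plateau) must lie in (0, 1]", call. = FALSE)
  -log(ratio) / x
}

#' Temperature-jump response of an MST trace
#'
#' Difference between the mean fluorescence just after and just before
#' IR-on. Window defaults are relative to IR-on at t = 0 and are
#' configurable because instrument timing varies.
#'
#' @param time seconds.
#' @param fluorescence trace values.
#' @param pre_window,post_window inclusive windows (s); must be disjoint and
#'   each contain >= 3 points.
#' @return `mean(post) - mean(pre)`.
#' @export
temperature_jump <- function(time, fluorescence,
                             pre_window = c(-1, 0),
                             post_window = c(0.5, 1.5)) {
  if (!(pre_window[2] < post_window[1] || post_window[2] < pre_window[1]))
    stop("pre and post windows must be disjoint", call. = FALSE)
  pre <- fluorescence[time >= pre_window[1] & time <= pre_window[2]]
  post <- fluorescence[time >= post_window[1] & time <= post_window[2]]
  if (length(pre) < 3 || length(post) < 3)
    stop("each window must contain >= 3 points inside the trace",
         call. = FALSE)
  mean(post) - mean(pre)
}

#' Four-parameter log-logistic concentration-response fit (EC50)
#'
#' Fits \eqn{y = bottom + (top - bottom)/(1 + (EC_{50}/c)^{hill})} to
#' (concentration, response) pairs by constrained least squares. `top` is
#' the high-concentration asymptote; responses may run in either direction.
#' The EC50 is flagged `extrapolated` when it falls outside the tested
#' concentration range, and a flat response set is returned `degenerate`
#' rather than fitted.
#'
#' @param conc concentrations (uM), > 0.
#' @param response responses at each concentration.
#' @return object of class `ec50_fit`: `bottom`, `top`, `ec50`, `hill`,
#'   `rss`, `converged`, `degenerate`, `extrapolated`, `n`.
#' @export
fit_ec50 <- function(conc, response) {
  if (length(conc) != length(response))
    stop("conc and response lengths differ", call. = FALSE)
  keep <- conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(conc) < 5)
    stop("need >= 5 positive concentrations spanning the transition",
         call. = FALSE)
  o <- order(conc); conc <- conc[o]; response <- response[o]
  rng <- diff(range(response))
  if (rng <= .Machine$double.eps * max(1, abs(response[1]))) {
    return(structure(list(bottom = response[1], top = response[1],
                          ec50 = NA_real_, hill = NA_real_, rss = 0,
                          converged = FALSE, degenerate = TRUE,
                          extrapolated = NA, n = length(conc)),
                     class = "ec50_fit"))
  }
  bottom0 <- response[1]; top0 <- response[length(response)]
  half <- (bottom0 + top0) / 2
  ec0 <- suppressWarnings(approx(response, conc, xout = half,
                                 ties = "ordered")$y)
  if (is.na(ec0)) ec0 <- exp(mean(log(range(conc))))
  start <- c(bottom = bottom0, top = top0, ec50 = ec0, hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(response ~ bottom + (top - bottom) /
                        (1 + (ec50 / conc)^hill),
                      start = start,
                      lower = c(bottom = -Inf, top = -Inf,
                                ec50 = .Machine$double.xmin, hill = 1e-3),
                      upper = c(bottom = Inf, top = Inf, ec50 = Inf,
                                hill = 10),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(structure(list(bottom = bottom0, top = top0, ec50 = NA_real_,
                          hill = NA_real_, rss = NA_real_, converged = FALSE,
                          degenerate = FALSE, extrapolated = NA,
                          n = length(conc)),
                     class = "ec50_fit"))
  }
  co <- coef(fit)
  structure(list(bottom = unname(co["bottom"]), top = unname(co["top"]),
                 ec50 = unname(co["ec50"]), hill = unname(co["hill"]),
                 rss = sum(residuals(fit)^2),
                 converged = isTRUE(fit$convInfo$isConv),
                 degenerate = FALSE,
                 extrapolated = co["ec50"] < min(conc) ||
                   co["ec50"] > max(conc),
                 n = length(conc)),
            class = "ec50_fit")
}

#' @export
print.ec50_fit <- function(x, ...) {
  cat(sprintf("<ec50_fit> EC50 = %.6g uM (hill = %.4g)%s%s\n",
              x$ec50, x$hill,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else "",
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Linear slope of a concentration-response series
#'
#' Ordinary least-squares slope of response versus concentration, the
#' summary used to compare thermophoresis responses across ligand series.
#' A log10 concentration axis is available via `log_conc = TRUE`.
#'
#' @param conc concentrations (uM).
#' @param response responses.
#' @param log_conc regress on `log10(conc)` instead of `conc`.
#' @export
response_slope <- function(conc, response, log_conc = FALSE) {
  if (length(conc) < 3) stop("need >= 3 concentrations", call. = FALSE)
  x <- if (log_conc) log10(conc) else conc
  unname(coef(lm(response ~ x))[2])
}
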