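# Kinetic liposome (LUV) dye-release analysis: control-based normalization,
# constrained asymmetric five-parameter sigmoid fitting, and the analytic
# slope at the inflection point as a maximal-rate statistic.

#' Modified five-parameter sigmoid
#'
#' \deqn{y = B + \frac{T - B}{\left(1 + (E/x)^H\right)^S}}
#'
#' `B` and `T` are the bottom and top asymptotes (percent permeabilization),
#' `E` the half-transition scale (s), `H` the steepness exponent and `S` the
#' asymmetry exponent. At `x = E` the curve passes through
#' `B + (T-B)/2^S` regardless of `H`. The model is defined for `x > 0`;
#' `x = 0` is evaluated as the limit `B` (valid for `h > 0`).
#'
#' @param x time (seconds), >= 0.
#' @param b,t,e,h,s model parameters.
#' @export
eval_5pl <- function(x, b, t, e, h, s) {
  y <- b + (t - b) / (1 + (e / x)^h)^s
  y[x == 0] <- b
  y
}

#' Normalization references from plate controls
#'
#' The 0% reference is the minimum reading of the buffer control wells over
#' the entire assay; the 100% reference is the mean reading of the
#' detergent-solubilized (`detergent_max`) wells over the entire assay.
#'
#' @param plate an [assay_plate()] whose map marks at least one `buffer` and
#'   one `detergent_max` well.
#' @return object of class `normalization_refs` with fields `f0`, `f100`.
#' @export
luv_refs <- function(plate) {
  stopifnot(inherits(plate, "assay_plate"))
  buf <- plate$map$well[plate$map$role == "buffer"]
  det <- plate$map$well[plate$map$role == "detergent_max"]
  if (!length(buf)) stop("plate map has no buffer wells", call. = FALSE)
  if (!length(det)) stop("plate map has no detergent_max wells",
                         call. = FALSE)
  normalization_refs(min(plate$signal[, buf]), mean(plate$signal[, det]))
}

#' @rdname luv_refs
#' @param f0,f100 raw-signal values mapping to 0% and 100%.
#' @export
normalization_refs <- function(f0, f100) {
  if (!is.finite(f0) || !is.finite(f100) || f100 <= f0)
    stop("degenerate controls: need f100 > f0", call. = FALSE)
  structure(list(f0 = f0, f100 = f100), class = "normalization_refs")
}

#' Normalize raw signal to percent permeabilization
#'
#' Affine map \eqn{\% = 100 (F - F_0) / (F_{100} - F_0)}. Values outside
#' \[0, 100\] are preserved, not clipped (the detergent reference is a mean,
#' so readings can legitimately exceed it); clipping happens only at the
#' synergy stage via [to_fraction()].
#'
#' @param x numeric vector/matrix of raw signal, or an [assay_plate()].
#' @param refs a `normalization_refs` object.
#' @return same shape as `x`, in percent.
#' @export
normalize_percent <- function(x, refs) {
  stopifnot(inherits(refs, "normalization_refs"))
  if (inherits(x, "assay_plate")) {
    x$signal <- (x$signal - refs$f0) / (refs$f100 - refs$f0) * 100
    return(x)
  }
  (x - refs$f0) / (refs$f100 - refs$f0) * 100
}

#' Fit the constrained five-parameter sigmoid to a normalized trace
#'
#' Box-constrained Levenberg-Marquardt least squares of [eval_5pl()] with
#' the model constraints `T >= B` (enforced by fitting the non-negative span
#' `T - B`), `0 < S <= 10`, `0 < H <= 20`, `E > 0`. Starting values are
#' `B0 = min(y)`, `T0 = max(y)`, `E0` = time of half-rise by linear
#' interpolation, `H0 = S0 = 1`.
#'
#' A reading at exactly `t = 0` is assigned the midpoint of the first
#' interval (the model is singular at `x = 0`); set `zero_time = "drop"` to
#' discard it instead. A flat trace (no transition) is returned with
#' `degenerate = TRUE` and `T ~ B` rather than fitted.
#'
#' @param time seconds; strictly increasing.
#' @param signal normalized percent permeabilization.
#' @param init optional named vector `c(b, t, e, h, s)` overriding the
#'   default starting values.
#' @param zero_time how to treat a `t = 0` read: `"midpoint"` (default) or
#'   `"drop"`.
#' @return object of class `fit_5pl`: fields `par` (named b/t/e/h/s), `rss`,
#'   `converged`, `degenerate`, `x_ip`, `max_rate` (both `NA` unless
#'   `h * s > 1`), `n`.
#' @export
fit_5pl <- function(time, signal, init = NULL,
                    zero_time = c("midpoint", "drop")) {
  zero_time <- match.arg(zero_time)
  if (length(time) != length(signal))
    stop("time and signal lengths differ", call. = FALSE)
  if (any(time == 0)) {
    if (zero_time == "midpoint") {
      time[time == 0] <- min(time[time > 0]) / 2
      o <- order(time); time <- time[o]; signal <- signal[o]
    } else {
      keep <- time > 0; time <- time[keep]; signal <- signal[keep]
    }
  }
  if (length(time) < 6)
    stop("need at least 6 positive-time points to fit 5 parameters",
         call. = FALSE)
  b0 <- min(signal); t0 <- max(signal); rng <- t0 - b0
  if (rng <= .Machine$double.eps * max(1, abs(t0))) {
    return(new_fit_5pl(c(b = b0, t = t0, e = NA_real_, h = NA_real_,
                         s = NA_real_),
                       rss = sum((signal - mean(signal))^2),
                       converged = FALSE, degenerate = TRUE,
                       n = length(time)))
  }
  e0 <- suppressWarnings(approx(signal, time, xout = (b0 + t0) / 2,
                                ties = "ordered")$y)
  if (is.na(e0)) e0 <- median(time)
  start <- c(b = b0, d = rng, e = e0, h = 1, s = 1)
  if (!is.null(init)) {
    init <- init[c("b", "t", "e", "h", "s")]
    start <- c(b = unname(init["b"]), d = unname(init["t"] - init["b"]),
               e = unname(init["e"]), h = unname(init["h"]),
               s = unname(init["s"]))
  }
  lower <- c(b = b0 - rng, d = 0, e = .Machine$double.eps,
             h = 1e-6, s = 1e-6)
  upper <- c(b = t0, d = 2 * rng + abs(t0), e = 10 * max(time),
             h = 20, s = 10)
  start <- pmin(pmax(start, lower), upper)
  x <- time; y <- signal
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ b + d / (1 + (e / x)^h)^s,
                      start = start, lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
    error = function(err) NULL)
  if (is.null(fit)) {
    return(new_fit_5pl(c(b = b0, t = t0, e = e0, h = NA_real_,
                         s = NA_real_),
                       rss = NA_real_, converged = FALSE, degenerate = FALSE,
                       n = length(x)))
  }
  co <- coef(fit)
  par <- c(b = unname(co["b"]), t = unname(co["b"] + co["d"]),
           e = unname(co["e"]), h = unname(co["h"]), s = unname(co["s"]))
  new_fit_5pl(par, rss = sum(residuals(fit)^2),
              converged = isTRUE(fit$convInfo$isConv), degenerate = FALSE,
              n = length(x))
}

new_fit_5pl <- function(par, rss, converged, degenerate, n) {
  hs <- unname(par["h"] * par["s"])
  ip <- if (!degenerate && is.finite(hs) && hs > 1)
    maximal_rate(par) else list(rate = NA_real_, x_ip = NA_real_)
  structure(list(par = par, rss = rss, converged = converged,
                 degenerate = degenerate, x_ip = ip$x_ip,
                 max_rate = ip$rate, n = n),
            class = "fit_5pl")
}

#' @export
print.fit_5pl <- function(x, ...) {
  cat("<fit_5pl>", if (x$degenerate) "(degenerate: no transition)"
      else if (!x$converged) "(NOT converged)" else "", "\n")
  print(round(x$par, 6))
  cat(sprintf("rss = %.6g; x_ip = %.6g s; max_rate = %.6g %%/s\n",
              x$rss, x$x_ip, x$max_rate))
  invisible(x)
}

#' Analytic maximal rate (slope at the inflection point)
#'
#' Closed form for the first derivative of [eval_5pl()] evaluated at its
#' inflection point, derived from the second derivative of the model:
#' \deqn{x_{IP} = E \left(\frac{HS - 1}{H + 1}\right)^{1/H}, \qquad
#'  \left.\frac{dy}{dx}\right|_{x_{IP}} =
#'  \frac{H S (T-B) \left(\frac{H+1}{HS-1}\right)^{\frac{H+1}{H}}}
#'       {E \left(1 + \frac{H+1}{HS-1}\right)^{S+1}}.}
#' An inflection point at positive time exists only when `h * s > 1`.
#'
#' @param fit a `fit_5pl` object or a named vector `c(b, t, e, h, s)`.
#' @return list with `rate` (percent per second) and `x_ip` (seconds).
#' @export
maximal_rate <- function(fit) {
  par <- if (inherits(fit, "fit_5pl")) fit$par else fit
  b <- unname(par["b"]); t <- unname(par["t"]); e <- unname(par["e"])
  h <- unname(par["h"]); s <- unname(par["s"])
  if (any(!is.finite(c(b, t, e, h, s))))
    stop("non-finite 5PL parameters", call. = FALSE)
  if (h * s <= 1)
    stop("no inflection point at positive time: need H * S > 1",
         call. = FALSE)
  r <- (h + 1) / (h * s - 1)
  rate <- h * s * (t - b) * r^((h + 1) / h) / (e * (1 + r)^(s + 1))
  list(rate = rate, x_ip = e * ((h * s - 1) / (h + 1))^(1 / h))
}

#' Endpoint percent permeabilization
#'
#' Mean of the final `k_last` normalized readings (default: the single final
#' reading, matching endpoint reporting of kinetic assays).
#'
#' @param signal normalized trace (percent).
#' @param k_last number of trailing readings to average.
#' @export
endpoint_percent <- function(signal, k_last = 1) {
  n <- length(signal)
  if (n == 0) stop("empty trace", call. = FALSE)
  if (k_last < 1 || k_last > n)
    stop("k_last must be between 1 and the series length", call. = FALSE)
  mean(signal[(n - k_last + 1):n])
}

#' Normalize, average and fit every sample condition on a LUV plate
#'
#' Pipeline convenience: computes control references, normalizes all wells,
#' averages replicate wells per condition (the module default; set
#' `average_replicates = FALSE` to fit each well separately), fits the 5PL,
#' and reports endpoint permeabilization and the maximal-rate statistic.
#'
#' @param plate an [assay_plate()] of raw LUV traces.
#' @param refs optional precomputed [normalization_refs()]; defaults to
#'   [luv_refs()] of the plate.
#' @param average_replicates fit the replicate mean (default) or each well.
#' @param k_last trailing readings averaged for the endpoint.
#' @return tidy data frame, one row per condition (or well), with the fitted
#'   parameters, `x_ip`, `max_rate`, `endpoint_pct` and fit flags.
#' @export
fit_luv_plate <- function(plate, refs = luv_refs(plate),
                          average_replicates = TRUE, k_last = 1) {
  norm <- normalize_percent(plate, refs)
  map <- norm$map[norm$map$role %in% c("sample", "vehicle_protein"), ]
  groups <- if (average_replicates) split(map$well, map$condition)
            else setNames(as.list(map$well), map$well)
  rows <- lapply(names(groups), function(g) {
    wells <- groups[[g]]
    y <- rowMeans(norm$signal[, wells, drop = FALSE])
    fit <- fit_5pl(norm$axis, y)
    info <- norm$map[norm$map$well == wells[1], ]
    data.frame(condition = info$condition, dose_a = info$dose_a,
               dose_b = info$dose_b, n_wells = length(wells),
               b = fit$par["b"], t = fit$par["t"], e = fit$par["e"],
               h = fit$par["h"], s = fit$par["s"], rss = fit$rss,
               x_ip = fit$x_ip, max_rate = fit$max_rate,
               endpoint_pct = endpoint_percent(y, k_last),
               converged = fit$converged, degenerate = fit$degenerate,
               row.names = NULL)
  })
  do.call(rbind, rows)
}
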