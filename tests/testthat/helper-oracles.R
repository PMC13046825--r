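# Independent numerical oracles and small simulation helpers shared across
# the test files. The maximal-rate oracle never touches the closed form it
# is used to check: it locates and evaluates the maximum of a finite-
# difference derivative of the sigmoid's transition term.

# 5-point central-difference derivative of (T-B)/(1+(E/x)^H)^S; the constant
# offset B is omitted purely to avoid catastrophic cancellation at small x.
numeric_max_rate <- function(b, t, e, h, s) {
  g <- function(x) (t - b) / (1 + (e / x)^h)^s
  d5 <- function(x) {
    hh <- x * 1e-3
    (g(x - 2 * hh) - 8 * g(x - hh) + 8 * g(x + hh) - g(x + 2 * hh)) /
      (12 * hh)
  }
  ug <- seq(log(e) - 30, log(e) + 5, length.out = 1500)
  i <- which.max(vapply(exp(ug), d5, 0))
  u0 <- optimize(function(u) d5(exp(u)),
                 interval = c(ug[max(1, i - 2)], ug[min(length(ug), i + 2)]),
                 maximum = TRUE, tol = 1e-12)$maximum
  x0 <- exp(u0)
  optimize(d5, interval = c(x0 * 0.9, x0 * 1.1), maximum = TRUE,
           tol = x0 * 1e-11)$objective
}

# random valid 5PL parameter set with an inflection at positive time
random_5pl_params <- function() {
  b <- runif(1, 0, 50); t <- b + runif(1, 10, 100)
  e <- runif(1, 10, 3000)
  repeat {
    h <- runif(1, 0.2, 6); s <- runif(1, 0.1, 10)
    if (h * s > 1) break
  }
  c(b = b, t = t, e = e, h = h, s = s)
}

# default generating kinetics for the recovery studies: lag/burst/creep
# dye-release shape on a 90-read, 55 s-interval schedule (see the methods
# vignette for the identifiability rationale)
luv_truth <- c(b = 10, t = 90, e = 3000, h = 10, s = 0.3)
luv_time <- function() seq(55, by = 55, length.out = 90)

make_noisy_luv_trace <- function(seed, noise_sd, n_rep = 3) {
  spec <- sim_plate_spec(55, 55, 90, list(
    plate_condition("bax", "sample",
                    as.list(luv_truth), n_rep = n_rep),
    plate_condition("buffer", "buffer", list(level = 0)),
    plate_condition("chaps", "detergent_max", list(level = 100))),
    noise_sd = noise_sd, seed = seed)
  plate <- sim_luv_plate(spec)
  wells <- plate$map$well[plate$map$role == "sample"]
  list(time = plate$axis,
       signal = rowMeans(plate$signal[, wells, drop = FALSE]))
}
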