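test_that("normalization references follow the control rules", {
  map <- data.frame(well = c("b1", "b2", "c1", "c2"),
                    condition = c("buf", "buf", "chaps", "chaps"),
                    role = c("buffer", "buffer", "detergent_max",
                             "detergent_max"),
                    replicate = c(1, 2, 1, 2))
  sig <- cbind(b1 = c(10, 12), b2 = c(9, 11),
               c1 = c(200, 200), c2 = c(220, 220))
  refs <- luv_refs(assay_plate(c(1, 2), sig, map))
  expect_equal(refs$f0, 9)     # global minimum over all buffer readings
  expect_equal(refs$f100, 210) # mean over all detergent readings
  expect_error(normalization_refs(100, 50), "degenerate")
  no_buf <- assay_plate(c(1, 2), sig[, 3:4, drop = FALSE], map[3:4, ])
  expect_error(luv_refs(no_buf), "buffer")
})

test_that("percent normalization is the stated affine map, unclipped", {
  refs <- normalization_refs(9, 210)
  expect_equal(normalize_percent(9, refs), 0)
  expect_equal(normalize_percent(210, refs), 100)
  expect_equal(normalize_percent((9 + 210) / 2, refs), 50)
  expect_equal(normalize_percent(250, refs), (250 - 9) / 201 * 100)
  expect_gt(normalize_percent(250, refs), 100)  # preserved, not clipped
})

test_that("normalization is invariant to positive affine rescaling of the plate", {
  spec <- sim_plate_spec(55, 55, 30, list(
    plate_condition("bax", "sample",
                    list(b = 60, t = 480, e = 900, h = 3, s = 1)),
    plate_condition("buf", "buffer", list(level = 50)),
    plate_condition("chaps", "detergent_max", list(level = 500))),
    noise_sd = 3, seed = 5)
  plate <- sim_luv_plate(spec)
  norm1 <- normalize_percent(plate, luv_refs(plate))
  rescaled <- plate
  rescaled$signal <- 3.7 * plate$signal + 1234   # gain/offset change
  norm2 <- normalize_percent(rescaled, luv_refs(rescaled))
  expect_equal(norm2$signal, norm1$signal, tolerance = 1e-12)
})

test_that("5PL fit recovers a noiseless generated trace", {
  x <- seq(1, 90, length.out = 90)
  fit <- fit_5pl(x, eval_5pl(x, 0, 100, 30, 2, 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$par["b"]), 1e-6)   # true bottom is 0
  true <- c(t = 100, e = 30, h = 2, s = 1)
  expect_lt(max(abs(fit$par[names(true)] - true) / true), 1e-6)
})

test_that("the fitted curve at x = E equals B + (T-B)/2^S by construction", {
  x <- seq(55, by = 55, length.out = 90)
  set.seed(21)
  y <- eval_5pl(x, 10, 90, 2000, 4, 2) + rnorm(90, 0, 2)
  fit <- fit_5pl(x, y)
  p <- fit$par
  expect_equal(eval_5pl(p["e"], p["b"], p["t"], p["e"], p["h"], p["s"]),
               unname(p["b"] + (p["t"] - p["b"]) / 2^p["s"]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a constant trace is flagged degenerate with T ~ B", {
  fit <- fit_5pl(seq_len(20) * 10, rep(42, 20))
  expect_true(fit$degenerate)
  expect_false(fit$converged)
  expect_equal(unname(fit$par["t"]), unname(fit$par["b"]))
})

test_that("a t = 0 read is shifted to the first-interval midpoint", {
  x <- seq(0, by = 55, length.out = 91)
  y <- eval_5pl(x, 10, 90, 3000, 10, 0.3)
  fit <- fit_5pl(x, y)     # must not error on the singular origin
  expect_true(fit$converged)
  expect_lt(max(abs(fit$par - c(10, 90, 3000, 10, 0.3)) /
                  c(10, 90, 3000, 10, 0.3)), 1e-5)
  expect_error(fit_5pl(c(0, 1, 2, 3, 4), c(1, 2, 3, 4, 5)), "6")
})

test_that("maximal rate matches its worked example and edge cases", {
  mr <- maximal_rate(c(b = 0, t = 100, e = 30, h = 2, s = 1))
  # frozen from the independent finite-difference oracle (helper-oracles.R)
  expect_equal(mr$rate, 2.1650635, tolerance = 1e-7)
  expect_equal(mr$x_ip, 30 / sqrt(3), tolerance = 1e-12)
  expect_equal(maximal_rate(c(b = 50, t = 50, e = 30, h = 2, s = 1))$rate, 0)
  expect_error(maximal_rate(c(b = 0, t = 100, e = 30, h = 0.5, s = 1)),
               "H \\* S > 1")
})

test_that("maximal rate increases with span and decreases with E", {
  base <- c(b = 0, t = 100, e = 30, h = 2, s = 1)
  spans <- seq(50, 150, by = 10)
  rates_span <- vapply(spans, function(tt)
    maximal_rate(replace(base, "t", tt))$rate, 0)
  expect_true(all(diff(rates_span) > 0))
  es <- seq(10, 200, by = 10)
  rates_e <- vapply(es, function(ee)
    maximal_rate(replace(base, "e", ee))$rate, 0)
  expect_true(all(diff(rates_e) < 0))
})

test_that("endpoint percent averages the trailing readings", {
  expect_equal(endpoint_percent(c(10, 50, 85)), 85)
  expect_equal(endpoint_percent(c(10, 80, 82, 84), k_last = 3), 82)
  expect_error(endpoint_percent(c(1, 2), k_last = 3), "k_last")
  expect_error(endpoint_percent(numeric(0)), "empty")
})

test_that("plate-level fitting reports per-condition kinetics", {
  spec <- sim_plate_spec(55, 55, 90, list(
    plate_condition("bax_bim", "sample",
                    list(b = 95, t = 455, e = 2000, h = 4, s = 1),
                    n_rep = 3, dose_a = 2.5),
    plate_condition("buf", "buffer", list(level = 50), n_rep = 2),
    plate_condition("chaps", "detergent_max", list(level = 500),
                    n_rep = 2)),
    noise_sd = 0, seed = 2)
  res <- fit_luv_plate(sim_luv_plate(spec))
  expect_equal(nrow(res), 1)
  expect_equal(res$dose_a, 2.5)
  # raw (95, 455) on (f0 = 50, f100 = 500) controls -> 10% and 90%
  expect_equal(res$b, 10, tolerance = 1e-6)
  expect_equal(res$t, 90, tolerance = 1e-6)
  expect_equal(res$e, 2000, tolerance = 1e-4)
  expect_equal(res$endpoint_pct,
               normalize_percent(eval_5pl(4950, 95, 455, 2000, 4, 1),
                                 normalization_refs(50, 500)))
})
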