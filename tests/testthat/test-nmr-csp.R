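test_that("the weighted CSP matches its arithmetic and symmetries", {
  expect_equal(csp(0, 0), 0)
  expect_equal(csp(0.1, 0.5), sqrt(0.03))
  expect_equal(csp(-0.1, 0.5), csp(0.1, 0.5))    # even in each argument
  expect_equal(csp(0.1, -0.5), csp(0.1, 0.5))
  # strictly increasing in each |argument|
  dh <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(csp(dh, 0.2)) > 0))
  expect_true(all(diff(csp(0.1, dh)) > 0))
})

test_that("CSP tables pair residues and carry proline/missing status", {
  pk <- sim_hsqc_peaklists(30, proline_positions = c(4, 11),
                           missing_positions = 17, seed = 9)
  tab <- csp_table(pk$reference, pk$treated)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$status[c(4, 11)], c("proline", "proline"))
  expect_equal(tab$status[17], "missing")
  expect_true(all(is.na(tab$delta_delta[tab$status != "measured"])))
  # identical lists give all-zero perturbations
  same <- csp_table(pk$reference, pk$reference)
  expect_true(all(same$delta_delta[same$status == "measured"] == 0))
  # numbering mismatch
  shifted <- pk$treated; shifted$residue_number <- shifted$residue_number + 1
  expect_error(csp_table(pk$reference, shifted), "numbering mismatch")
})

test_that("injected perturbations land on exactly the designated residues", {
  pert <- data.frame(residue_number = c(5, 9), d_h = c(0.1, 0.05),
                     d_n = c(0.5, 0.2))
  pk <- sim_hsqc_peaklists(40, proline_positions = 7, perturbed = pert,
                           seed = 2)
  tab <- csp_table(pk$reference, pk$treated)
  expect_equal(tab$delta_delta[5], csp(0.1, 0.5))
  expect_equal(tab$delta_delta[9], csp(0.05, 0.2))
  others <- tab$status == "measured" & !tab$residue_number %in% c(5, 9)
  expect_true(all(tab$delta_delta[others] == 0))
})

test_that("significance thresholds are mean + 1/2 SD with strict exceedance", {
  tab <- data.frame(residue_number = 1:5, residue_name = "ALA",
                    d_h = 0, d_n = 0,
                    delta_delta = c(0, 0, 0, 0, 1), status = "measured")
  sig <- csp_significance(tab)
  expect_equal(sig$theta1, 0.2 + sd(c(0, 0, 0, 0, 1)))
  expect_equal(sig$theta2, 0.2 + 2 * sd(c(0, 0, 0, 0, 1)))
  # 1.0 exceeds mean + 1 SD (~0.647) but not mean + 2 SD (~1.094)
  expect_equal(sig$table$class[5], "above_1sd")
  expect_equal(sig$table$class[1:4], rep("ns", 4))
  # all-equal perturbations: SD 0, nothing strictly exceeds the mean
  flat <- tab; flat$delta_delta <- rep(0.3, 5)
  expect_true(all(csp_significance(flat)$table$class == "ns"))
  expect_error(csp_significance(tab[1, ]), ">= 2 measured")
})

test_that("prolines and missing residues never enter threshold statistics", {
  tab <- data.frame(residue_number = 1:7, residue_name = "ALA",
                    d_h = 0, d_n = 0,
                    delta_delta = c(0, 0, 0, 0, 1, NA, NA),
                    status = c(rep("measured", 5), "proline", "missing"))
  tab$residue_name[6] <- "PRO"
  sig <- csp_significance(tab)
  expect_equal(sig$n_measured, 5)
  expect_equal(sig$theta1, 0.2 + sd(c(0, 0, 0, 0, 1)))  # unchanged by 6-7
  expect_true(all(is.na(sig$table$class[6:7])))
})

test_that("classification is reorder-invariant and scales with the data", {
  pk <- sim_hsqc_peaklists(60, perturbed = data.frame(
    residue_number = c(10, 20), d_h = 0.12, d_n = 0.4),
    jitter_sd = 0.003, seed = 33)
  tab <- csp_table(pk$reference, pk$treated)
  sig <- csp_significance(tab)
  perm <- sample(nrow(tab))
  sig_perm <- csp_significance(tab[perm, ])
  expect_equal(sig_perm$theta1, sig$theta1)
  expect_equal(sig_perm$table$class[order(sig_perm$table$residue_number)],
               sig$table$class[order(sig$table$residue_number)])
  scaled <- tab; scaled$delta_delta <- 3 * scaled$delta_delta
  sig3 <- csp_significance(scaled)
  expect_equal(sig3$theta1, 3 * sig$theta1)
  expect_equal(sig3$theta2, 3 * sig$theta2)
  expect_equal(sig3$table$class, sig$table$class)
})

test_that("concentration averaging keeps residues measured anywhere", {
  t1 <- data.frame(residue_number = 1:3, residue_name = "ALA",
                   d_h = c(0.1, 0, NA), d_n = c(0.1, 0, NA),
                   delta_delta = c(0.1, 0, NA),
                   status = c("measured", "measured", "missing"))
  t2 <- data.frame(residue_number = 1:3, residue_name = "ALA",
                   d_h = c(0.3, 0, NA), d_n = c(0.3, 0, NA),
                   delta_delta = c(0.3, 0, NA),
                   status = c("measured", "measured", "missing"))
  avg <- average_csp(list(t1, t2))
  expect_equal(avg$delta_delta[avg$residue_number == 1], 0.2)
  expect_false(3 %in% avg$residue_number)   # unmeasured everywhere: dropped
  # residue measured in a subset of tables averages over that subset
  t2$status[1] <- "missing"; t2$delta_delta[1] <- NA
  avg2 <- average_csp(list(t1, t2))
  expect_equal(avg2$delta_delta[avg2$residue_number == 1], 0.1)
  # single table: identity on its measurable content
  one <- average_csp(list(t1))
  expect_equal(one, t1[t1$status == "measured", ], ignore_attr = TRUE)
  expect_error(average_csp(list()), "empty")
})
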