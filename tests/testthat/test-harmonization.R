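test_that("panel-vs-WES regression recovers identity and noise artifacts", {
  co <- generate_synthetic_cohort("lusc_like", 300, seed = 51)
  exact <- co
  exact$tmb_panel <- exact$tmb_wes  # ground-truth map is the identity
  fit <- regress_panel_vs_wes(exact)
  expect_equal(fit$slope, 1, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$n_pairs, 300)

  # the Poisson driver term shifts the regression offset upward by ~lambda/L
  big <- generate_synthetic_cohort("lusc_like", 3000, seed = 52)
  lam0 <- add_panel_measurements(big, panel_model(1, lambda_driver = 0), seed = 53)
  lam2 <- add_panel_measurements(big, panel_model(1, lambda_driver = 2), seed = 53)
  int0 <- regress_panel_vs_wes(lam0)$intercept
  int2 <- regress_panel_vs_wes(lam2)$intercept
  expect_gt(int2, int0 + 1)  # expected shift is lambda/L = 2 mutations/Mb

  two <- exact[1:1, ]
  expect_error(regress_panel_vs_wes(two), "insufficient")
  flat <- exact[1:5, ]
  flat$tmb_wes <- 4
  expect_error(regress_panel_vs_wes(flat), "degenerate")
})

test_that("regression slopes are more variable for low-TMB histologies", {
  dists <- list(BRCA = preset_dist("low_tmb_like"),
                LUSC = preset_dist("lusc_like"))
  pm <- panel_model(1.33)
  scan <- regression_variability_scan(dists, pm, n_per_cohort = 200,
                                      n_boot = 100, seed = 55)
  expect_equal(scan$histology, c("BRCA", "LUSC"))  # sorted by median TMB
  expect_gt(scan$slope_iqr[scan$histology == "BRCA"],
            scan$slope_iqr[scan$histology == "LUSC"])

  scan2 <- regression_variability_scan(dists, pm, n_per_cohort = 200,
                                       n_boot = 100, seed = 55)
  expect_identical(scan, scan2)

  expect_error(regression_variability_scan(dists, pm, n_boot = 10), "n_boot")
  expect_error(regression_variability_scan(dists[1], pm), "histolog")
})

test_that("threshold solvers round-trip their targets", {
  du <- uniform_dist()
  wes <- noiseless_wes()

  tau <- threshold_for_fraction(du, wes, 0.2)
  expect_equal(as.numeric(tau), 16, tolerance = 1e-3)
  expect_lt(abs(attr(tau, "achieved") - 0.2), 1e-3)

  # large panel: counts are fine enough for a tight round-trip
  d <- preset_dist("luad_like")
  big <- panel_model(35.6)
  tf <- threshold_for_fraction(d, big, 0.2)
  expect_lt(abs(attr(tf, "achieved") - 0.2), 1e-3)
  expect_equal(treated_fraction(d, big, as.numeric(tf)), attr(tf, "achieved"))

  # small panel: nearest attainable step, self-consistent
  small <- panel_model(1)
  ts <- threshold_for_fraction(d, small, 0.2)
  expect_equal(treated_fraction(d, small, as.numeric(ts)),
               attr(ts, "achieved"))
  expect_lt(abs(attr(ts, "gap")), 0.05)
  # noise widens the measured tail: thresholds differ across panel sizes
  expect_true(as.numeric(ts) != as.numeric(tf))

  # ORR solver: noiseless + matched step response has a plateau at 1;
  # the smallest satisfying threshold is the response threshold
  to <- threshold_for_orr(du, wes, response_step(12), 1.0)
  expect_equal(as.numeric(to), 12, tolerance = 0.02)

  # two-level response reaches 0.8 exactly once all selected are true-high
  two <- response_two_level(6, 0.8, 0.2)
  t8 <- threshold_for_orr(d, wes, two, 0.8)
  expect_lt(abs(attr(t8, "achieved") - 0.8), 1e-3)
  expect_equal(as.numeric(t8), 6, tolerance = 0.05)

  # unattainable target names the attainable range
  expect_error(threshold_for_orr(d, wes, two, 0.99), "attainable range")
  expect_error(threshold_for_orr(d, panel_model(1), two, 0.99),
               "attainable range")

  # noisy-panel ORR solver round-trips through expected_orr
  psi <- response_gamma(1, 0.08)
  tn <- threshold_for_orr(d, small, psi, 0.5)
  expect_equal(expected_orr(d, psi, small, as.numeric(tn)),
               attr(tn, "achieved"))
  expect_lt(abs(attr(tn, "gap")), 0.05)
})

test_that("fraction and ORR harmonization are mutually exclusive across noise levels", {
  d <- preset_dist("luad_like")
  rate <- calibrate_gamma_rate(d, 1, 0.2, 0.5)
  psi <- response_gamma(1, rate)
  wes <- noiseless_wes()
  small <- panel_model(1)

  rep <- harmonization_tradeoff(d, wes, small, psi,
                                target_fraction = 0.2, target_orr = 0.5)
  # fraction-matched thresholds: the noisier panel dilutes the treated group
  expect_lt(rep$orr_gap_at_matched_fraction, 0)
  # ORR-matched thresholds shrink the noisy panel's treated population
  expect_lt(rep$fraction_gap_at_matched_orr, 0)
  # within the noisy panel, the two criteria demand different thresholds
  expect_gt(abs(rep$panel_b$tau_fraction - rep$panel_b$tau_orr), 0.5)
  expect_true(rep$impossible)

  # identical devices: no gap, harmonization trivially possible
  same <- harmonization_tradeoff(d, small, small, psi, 0.2, 0.5)
  expect_equal(same$orr_gap_at_matched_fraction, 0)
  expect_equal(same$fraction_gap_at_matched_orr, 0)
  expect_false(same$impossible)
})

test_that("quantile-based selection is invariant under increasing affine maps", {
  d <- preset_dist("luad_like")
  readout <- simulate_panel_tmb(panel_model(1.33), sample_tmb(d, 2000, 81),
                                n_reps = 1, seed = 82)
  sel <- readout > quantile(readout, 0.8)
  trans <- 3.7 * readout + 2.2
  sel_t <- trans > quantile(trans, 0.8)
  expect_identical(sel, sel_t)
})

test_that("energy statistic and its permutation test behave correctly", {
  x <- c(1.2, 3.4, 0.7, 5.1, 2.2)
  y <- c(2.0, 4.1, 1.1, 0.3, 6.0)
  # brute-force double sums on a tiny instance
  cross <- mean(outer(x, y, function(a, b) abs(a - b)))
  wx <- mean(outer(x, x, function(a, b) abs(a - b)))
  wy <- mean(outer(y, y, function(a, b) abs(a - b)))
  brute <- (length(x) * length(y) / (length(x) + length(y))) *
    (cross - wx / 2 - wy / 2)
  expect_equal(energy_statistic(x, y), brute, tolerance = 1e-12)

  same <- cramer_concordance(x, x, n_perm = 199, seed = 1)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  a <- withr::with_seed(2, runif(100, 0, 1))
  b <- withr::with_seed(3, runif(100, 5, 6))
  apart <- cramer_concordance(a, b, n_perm = 999, seed = 4)
  expect_lt(apart$p_value, 0.01)

  expect_error(cramer_concordance(numeric(0), y), "insufficient")
  expect_error(cramer_concordance(x, y, n_perm = 10), "n_perm")
})
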