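test_that("treated fraction reduces to the survival function for a noiseless device", {
  du <- uniform_dist()
  wes <- noiseless_wes()
  expect_equal(treated_fraction(du, wes, 0), 1, tolerance = 1e-9)
  expect_equal(treated_fraction(du, wes, 16), 0.2, tolerance = 1e-3)

  # strictly decreasing in tau wherever the distribution has mass
  d <- preset_dist("luad_like")
  z <- vapply(c(2, 5, 8, 12, 20), function(tau)
    treated_fraction(d, wes, tau), numeric(1))
  expect_true(all(diff(z) < 0))

  # smaller panels select more patients at a fixed threshold
  tau <- quantile_threshold(d, 0.2)
  expect_gt(treated_fraction(d, panel_model(1), tau),
            treated_fraction(d, panel_model(35.6), tau))
})

test_that("expected ORR obeys the normalization identities", {
  d <- preset_dist("luad_like")
  du <- uniform_dist()
  wes <- noiseless_wes()
  flat <- response_two_level(5, p_high = 0.37, p_low = 0.37)  # constant psi

  # a constant response factors out of the ratio, for any device
  for (panel in list(wes, panel_model(1), panel_model(1.33))) {
    expect_equal(expected_orr(d, flat, panel, 8), 0.37, tolerance = 1e-9)
  }

  # noiseless device + matched step response: everyone selected responds
  expect_equal(expected_orr(du, response_step(16), wes, 16), 1)
  expect_equal(expected_orr(d, response_step(10), wes, 10), 1)

  # no stratification + perfect top-20% step response: ORR is 20%
  tau20 <- quantile_threshold(du, 0.2)
  expect_equal(expected_orr(du, response_step(tau20), wes, 0), 0.2,
               tolerance = 1e-3)

  # nobody selected
  expect_error(expected_orr(du, response_step(5), wes, 1000), "undefined")
})

test_that("quadrature agrees with Monte Carlo for Z and ORR", {
  d <- preset_dist("luad_like")
  pm <- panel_model(1.33)
  psi <- response_gamma(1, 0.044)
  tau <- 10
  n <- 1e5
  t_true <- sample_tmb(d, n, seed = 61)
  readout <- simulate_panel_tmb(pm, t_true, n_reps = 1, seed = 62)
  sel <- readout > tau

  z_mc <- mean(sel)
  z_q <- treated_fraction(d, pm, tau)
  expect_lt(abs(z_q - z_mc), 3 * sqrt(z_mc * (1 - z_mc) / n))

  resp <- withr::with_seed(63, rbinom(n, 1, evaluate_response(psi, t_true)))
  orr_mc <- mean(resp[sel])
  orr_q <- expected_orr(d, psi, pm, tau)
  expect_lt(abs(orr_q - orr_mc), 3 * sqrt(orr_mc * (1 - orr_mc) / sum(sel)))
})

test_that("classification metrics agree with a hand-built confusion table", {
  # perfect agreement when the device is noiseless and thresholds match
  d <- preset_dist("luad_like")
  m <- classification_metrics(d, noiseless_wes(), tau_panel = 8,
                              n_mc = 2000, seed = 3)
  expect_equal(unlist(m[c("ppa", "npa", "opa", "ppv", "npv")]),
               c(ppa = 1, npa = 1, opa = 1, ppv = 1, npv = 1))

  # two-point distribution, panel threshold below the support: every call is
  # positive, so PPA = 1, NPA = 0, NPV undefined, PPV = prevalence
  x <- seq(0, 12, length.out = 4096)
  fx <- dnorm(x, 2, 0.01) + dnorm(x, 10, 0.01)
  d2 <- grid_distribution(x, fx, "two-point")
  m2 <- classification_metrics(d2, noiseless_wes(), tau_panel = 1,
                               tau_truth = 6, n_mc = 4000, seed = 5)
  t_true <- sample_tmb(d2, 4000, seed = 5)  # same draws as inside
  prev <- mean(t_true >= 6)
  expect_equal(m2$ppa, 1)
  expect_equal(m2$npa, 0)
  expect_true(is.na(m2$npv))
  expect_equal(m2$ppv, prev)
  expect_equal(m2$opa, prev)

  # a device whose output is independent of T has PPV equal to prevalence
  noise_only <- panel_model(1e-6, C0 = 20, lambda_driver = 0)
  m3 <- classification_metrics(d, noise_only, tau_panel = 10, tau_truth = 10,
                               n_mc = 40000, seed = 7)
  prev3 <- mean(sample_tmb(d, 40000, seed = 7) >= 10)
  expect_lt(abs(m3$ppv - prev3), 0.02)
})

test_that("outcome grids are deterministic and obey the panel-size laws", {
  dists <- list(LUAD = preset_dist("luad_like"),
                BRCA = preset_dist("low_tmb_like"))
  psi <- response_gamma(1, 0.044)

  g1 <- outcome_grid(dists, psi, panel_sizes = c(0.5, 1, 2, 35.6),
                     thresholds = 10, n_mc = 20000, seed = 9)
  g2 <- outcome_grid(dists, psi, panel_sizes = c(0.5, 1, 2, 35.6),
                     thresholds = 10, n_mc = 20000, seed = 9)
  expect_identical(g1, g2)

  luad <- g1[g1$histology == "LUAD", ]
  luad <- luad[order(luad$panel_size_L), ]
  # larger panels are less noisy: OPA nondecreasing in L (MC slack)
  expect_true(all(diff(luad$opa) > -0.01))
  # accuracy gains diminish with panel size: going from 0.5 to 1 Mbp buys
  # more OPA than going from 1 to 2 Mbp
  expect_gt(luad$opa[2] - luad$opa[1], luad$opa[3] - luad$opa[2])

  # low-TMB histology: lower PPV, higher OPA than the long-tailed one
  g133 <- outcome_grid(dists, psi, panel_sizes = 1.33, thresholds = 10,
                       n_mc = 20000, seed = 9)
  brca <- g133[g133$histology == "BRCA", ]
  luad133 <- g133[g133$histology == "LUAD", ]
  expect_lt(brca$ppv, luad133$ppv)
  expect_gt(brca$opa, luad133$opa)

  # per-histology top-fraction thresholds are resolved per distribution
  gt <- outcome_grid(dists, psi, panel_sizes = 1.33,
                     thresholds = list(top_fraction = 0.2),
                     n_mc = 1000, seed = 2)
  expect_equal(gt$threshold_tau[gt$histology == "LUAD"],
               quantile_threshold(dists$LUAD, 0.2))
  expect_true(gt$threshold_tau[gt$histology == "LUAD"] !=
                gt$threshold_tau[gt$histology == "BRCA"])

  # a failing cell is recorded, not fatal
  gerr <- outcome_grid(dists, psi, panel_sizes = 1.33, thresholds = -5,
                       n_mc = 1000, seed = 2)
  expect_true(all(!is.na(gerr$error)))
  expect_true(all(is.na(gerr$orr)))
})
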