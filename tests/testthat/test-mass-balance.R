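test_that("total DIC flux sums components with quadrature uncertainty", {
  t1 <- total_dic_flux(flux_budget())
  expect_equal(round(t1$mean, 1), 2.5)
  expect_equal(t1$sigma, sqrt(0.17^2 + 0.2^2))
  # adding carbonate precipitation shifts the total linearly
  t2 <- total_dic_flux(flux_budget(carbonate_precipitation = 0.1))
  expect_equal(t2$mean - t1$mean, 0.1)
  # zero budget
  t0 <- total_dic_flux(flux_budget(0, 0, 0, 0, 0, 0, 0))
  expect_equal(t0$mean, 0)
})

test_that("budget invariants are enforced", {
  expect_error(flux_budget(lateral_dic_export = -1), ">= 0")
  expect_error(flux_budget(petrogenic_low = 0.3, petrogenic_high = 0.2),
               "petrogenic_low")
  expect_error(flux_budget(petrogenic_high = 3), "smaller than the total")
})

test_that("residual F14C reproduces the published mass-balance bracket", {
  expect_equal(round(residual_f14c(0.919, 2.5, 0.150), 3), 0.978)
  expect_equal(round(residual_f14c(0.919, 2.5, 0.218), 3), 1.007)
  # no petrogenic flux leaves the signal unchanged
  expect_equal(residual_f14c(0.87, 2.5, 0), 0.87)
  expect_error(residual_f14c(0.9, 2.5, 2.5), "mass-balance violation")
  expect_error(residual_f14c(0.9, 2.5, 3.0), "mass-balance violation")
})

test_that("two-endmember inversion is exact at the endpoints and beyond", {
  p <- two_endmember_proportions(0.841, 1.226, 0.841)
  expect_equal(p$a_raw, 0)
  expect_equal(p$b_raw, 1)
  p <- two_endmember_proportions(1.226, 1.226, 0.841)
  expect_equal(p$a_raw, 1)
  # derived worked example: (0.978 - 0.841) / (1.226 - 0.841)
  p <- two_endmember_proportions(0.978, 1.226, 0.841)
  expect_equal(round(p$a_raw, 4), 0.3558)
  # out-of-bracket residuals flow through flagged, not clamped
  p <- two_endmember_proportions(1.5, 1.226, 0.841)
  expect_gt(p$a_raw, 1)
  expect_true(p$out_of_range)
  expect_error(two_endmember_proportions(1, 0.9, 0.9), "degenerate")
})

test_that("endmember set rejects overlapping or inverted ranges", {
  expect_error(endmember_set(millennial_range = c(0.8, 1.1)), "overlap")
  expect_error(endmember_set(decadal_range = c(1.4, 1.0)))
  expect_equal(endmember_set()$petrogenic, 0)
})

test_that("Monte Carlo runs match an independent brute-force oracle", {
  mc <- monte_carlo_partition(n_runs = 500, seed = 99)
  d <- mc$draws
  # straight-line recomputation of the chain from this run's draws
  total <- 0.52 + 2.0
  res_o <- 0.919 * total / (total - d$petro_flux)
  a_raw_o <- (res_o - d$f_mil) / (d$f_dec - d$f_mil)
  c_o <- d$petro_flux / total
  a_o <- a_raw_o * (1 - c_o)
  b_o <- (1 - a_raw_o) * (1 - c_o)
  expect_equal(d$residual, res_o, tolerance = 1e-12)
  expect_equal(d$a, a_o, tolerance = 1e-12)
  expect_equal(d$b, b_o, tolerance = 1e-12)
  expect_equal(d$c, c_o, tolerance = 1e-12)
  # per-run conservation
  expect_true(all(abs(d$a + d$b + d$c - 1) < 1e-12))
  # draws stay inside the stated windows
  expect_true(all(d$petro_flux >= 0.150 & d$petro_flux <= 0.218))
  expect_true(all(d$f_dec >= 1.011 & d$f_dec <= 1.442))
  expect_true(all(d$f_mil >= 0.808 & d$f_mil <= 0.874))
})

test_that("same seed gives bit-identical results; seeds differ otherwise", {
  m1 <- monte_carlo_partition(n_runs = 200, seed = 7)
  m2 <- monte_carlo_partition(n_runs = 200, seed = 7)
  expect_identical(m1$draws, m2$draws)
  m3 <- monte_carlo_partition(n_runs = 200, seed = 8)
  expect_false(identical(m1$draws, m3$draws))
})

test_that("degenerate Monte Carlo equals the deterministic chain", {
  eps <- 1e-9
  em <- endmember_set(decadal_range = 1.226 + c(-eps, eps),
                      millennial_range = 0.841 + c(-eps, eps))
  bd <- flux_budget(petrogenic_low = 0.18, petrogenic_high = 0.18 + eps)
  mc <- monte_carlo_partition(bd, em, f14c_river = 0.919, n_runs = 100,
                              seed = 1)
  total <- total_dic_flux(bd)$mean
  res <- residual_f14c(0.919, total, 0.18)
  pr <- two_endmember_proportions(res, 1.226, 0.841)
  cc <- 0.18 / total
  expect_equal(mc$summary$mean, c(pr$a_raw * (1 - cc), pr$b_raw * (1 - cc),
                                  cc), tolerance = 1e-6)
  expect_equal(mc$summary$sd, rep(0, 3), tolerance = 1e-6)
})

test_that("mean decadal share increases strictly with bulk F14C", {
  means <- vapply(c(0.85, 0.90, 0.95, 1.0), function(f) {
    monte_carlo_partition(f14c_river = f, n_runs = 2000, seed = 5)$
      summary$mean[1]
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("truncated-normal sampling stays in range and centres correctly", {
  mc <- monte_carlo_partition(n_runs = 4000, seed = 21,
                              distribution = "truncnorm")
  d <- mc$draws
  expect_true(all(d$f_dec >= 1.011 & d$f_dec <= 1.442))
  expect_true(all(d$f_mil >= 0.808 & d$f_mil <= 0.874))
  # symmetric truncation keeps the mean at the endmember mean
  expect_equal(mean(d$f_dec), 1.226, tolerance = 0.01)
  expect_equal(mean(d$f_mil), 0.841, tolerance = 0.005)
})

test_that("flux partitioning multiplies proportions by the emission flux", {
  # near-degenerate run pinned to the decadal endmember: proportions
  # (≈1, ≈0, ≈0), fixed emission of 2.0 gives a decadal flux of 2.0
  eps <- 1e-9
  em <- endmember_set(decadal_range = 1.2 + c(-eps, eps),
                      millennial_range = 0.8 + c(-eps, eps))
  bd <- flux_budget(petrogenic_low = 0, petrogenic_high = eps)
  mc <- monte_carlo_partition(bd, em, f14c_river = 1.2 * (2.52 / 2.52),
                              n_runs = 50, seed = 2)
  fl <- partition_to_fluxes(mc, vertical_mean = 2.0, vertical_sigma = 0)
  expect_equal(fl$mean[fl$source == "decadal"], 2.0, tolerance = 1e-5)
  expect_equal(fl$mean[fl$source == "old"], 0, tolerance = 1e-5)
  # old = millennial + petrogenic by construction
  mc2 <- monte_carlo_partition(n_runs = 1000, seed = 3)
  fl2 <- partition_to_fluxes(mc2, vertical_sigma = 0)
  expect_equal(fl2$mean[fl2$source == "old"],
               fl2$mean[fl2$source == "millennial"] +
                 fl2$mean[fl2$source == "petrogenic"], tolerance = 1e-12)
})

test_that("residence-time range combines the sigma bounds pessimistically", {
  rt <- residence_time_range(840, 280, 1.1, 0.3)
  expect_equal(rt$low, 560 / 1.4)
  expect_equal(rt$high, 1120 / 0.8)
  expect_equal(rt$low_display, 400)
  expect_equal(rt$high_display, 1400)
  # zero sigmas collapse to the single turnover time
  rt0 <- residence_time_range(840, 0, 1.1, 0)
  expect_equal(rt0$low, rt0$high)
  expect_equal(rt0$low, 840 / 1.1)
  expect_error(residence_time_range(840, 280, 0.3, 0.3), "unbounded")
})
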