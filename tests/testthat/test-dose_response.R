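test_that("percent inhibition obeys its control identities", {
  expect_equal(percent_inhibition(100, 100, 0), 0)
  expect_equal(percent_inhibition(0, 100, 0), 100)
  expect_equal(percent_inhibition(25, 100, 0), 75)
  expect_error(percent_inhibition(5, 10, 10), "differ")
  # affine invariance: y -> a*y + b applied to sample and both controls
  s <- c(12, 55, 80); hi <- 90; lo <- 8
  for (ab in list(c(2, 5), c(-0.3, 100), c(10, -40))) {
    expect_equal(percent_inhibition(ab[1] * s + ab[2], ab[1] * hi + ab[2],
                                    ab[1] * lo + ab[2]),
                 percent_inhibition(s, hi, lo), tolerance = 1e-12)
  }
})

test_that("4PL fits are exact on noise-free data and self-consistent", {
  doses <- 10^seq(-3, 1, length.out = 8)
  d <- simulate_dose_response(0.1, 1.0, ec50 = 0.09, hill = 1, doses = doses)
  fit <- fit_4pl(d$dose, d$response)
  expect_equal(fit$bottom, 0.1, tolerance = 1e-6)
  expect_equal(fit$top, 1.0, tolerance = 1e-6)
  expect_equal(fit$ec50, 0.09, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-6)
  expect_equal(fit$dmax, 0.9, tolerance = 1e-5)
  # inflection identity on the fitted curve
  expect_equal(predict(fit, fit$ec50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-10)
  # absolute midpoint crossing lies on the curve at 0.5
  expect_equal(predict(fit, fit$abs_dc50), 0.5, tolerance = 1e-8)
  expect_true(fit$bottom < 0.5 && fit$top > 0.5)
})

test_that("4PL handles ascending curves and refuses degenerate designs", {
  doses <- 10^seq(-2, 2, length.out = 10)
  up <- simulate_dose_response(0, 100, ec50 = 1, hill = -1.2, doses = doses)
  fit <- fit_4pl(up$dose, up$response)
  expect_equal(fit$ec50, 1, tolerance = 1e-5)
  expect_lt(fit$bottom, fit$top)
  expect_error(fit_4pl(c(1, 2, 3), c(1, 0.5, 0.2)), "4 distinct")
  expect_error(fit_4pl(c(-1, 1, 2, 3, 4), rep(1, 5)), "positive")
})

test_that("4PL recovers the midpoint from noisy triplicates", {
  # unit-slope curve, 8 doses, triplicate, 5% CV: the midpoint's sampling
  # error is ~6% here, so assert a typical-error bound plus a loose tail
  doses <- 10^seq(-3, 1, length.out = 8)
  err <- vapply(1:40, function(s) {
    d <- simulate_dose_response(0.1, 1, 0.09, 1, doses, cv = 0.05,
                                n_rep = 3, seed = 7000 + s)
    f <- fit_4pl(d$dose, d$response)
    abs(f$ec50 - 0.09) / 0.09
  }, numeric(1))
  expect_lt(median(err), 0.1)
  expect_gte(mean(err < 0.25), 0.95)
})

test_that("ratiometric degradation follows the background-subtracted ratio", {
  expect_equal(ratiometric_degradation(1100, 620, 100, 120, dmso_ratio = 2), 0)
  expect_equal(ratiometric_degradation(100, 620, 100, 120, dmso_ratio = 2), 1)
  expect_warning(
    out <- ratiometric_degradation(100, 100, 100, 120, dmso_ratio = 2),
    "background")
  expect_true(is.na(out))
  # generator consistency: at dose = dc50 degradation is half of Dmax
  fl <- simulate_flow_ratiometric(dc50 = 0.5, gi50 = 5, doses = c(0.2, 0.5, 1),
                                  dmax = 0.9, dmso_ratio = 2)
  deg <- ratiometric_degradation(fl$median_gfp, fl$median_mch,
                                 100, 120, dmso_ratio = 2)
  expect_equal(deg[2], 0.45, tolerance = 1e-9)
})

test_that("the viability gate floors at 25% of the DMSO fraction", {
  v <- viability_from_gate(c(900, 500, 230, 100), rep(1000, 4),
                           dmso_fraction = 0.9)
  expect_equal(v$rel_viability[1], 1.0)
  expect_equal(v$excluded, c(FALSE, FALSE, FALSE, TRUE))  # 0.111 < 0.25
  expect_error(viability_from_gate(1, 0, 0.9), "positive")
  # monotone toxicity makes the excluded set a suffix of the dose ladder
  doses <- 10^seq(-2, 1.5, length.out = 12)
  fl <- simulate_flow_ratiometric(dc50 = 0.05, gi50 = 1, doses = doses,
                                  viable_bottom = 0.01)
  v2 <- viability_from_gate(round(1e4 * fl$viable_fraction), rep(1e4, 12),
                            dmso_fraction = 1)
  exc <- which(v2$excluded)
  expect_true(length(exc) > 0)
  expect_equal(exc, seq(min(exc), 12))
})

test_that("the V/D window score applies top-dose fallbacks", {
  w <- vd_score(gi50 = 1.20, dc50 = 0.09, top_dose = 25)
  expect_equal(w$vd_score, 1.20 / 0.09, tolerance = 1e-12)
  expect_equal(round(w$vd_score, 1), 13.3)
  expect_false(w$gi50_fallback_used || w$dc50_fallback_used)

  w2 <- vd_score(gi50 = NA, dc50 = 0.01, top_dose = 25)
  expect_equal(w2$vd_score, 2500)
  expect_true(w2$gi50_fallback_used)

  w3 <- vd_score(gi50 = 0.3 * 10, dc50 = NA, top_dose = 10)
  expect_equal(w3$vd_score, 0.3)
  expect_lt(w3$vd_score, 1)

  w4 <- vd_score(gi50 = NA, dc50 = NA, top_dose = 10)
  expect_equal(w4$vd_score, 1.0)
  expect_true(w4$gi50_fallback_used && w4$dc50_fallback_used)

  # scale invariance: concentrations in nM instead of uM
  w5 <- vd_score(gi50 = 1200, dc50 = 90, top_dose = 25000)
  expect_equal(w5$vd_score, w$vd_score, tolerance = 1e-12)
})

test_that("V/D is recovered from simulated flow data end to end", {
  doses <- 10^seq(-2.5, 1.4, length.out = 10)
  fl <- simulate_flow_ratiometric(dc50 = 0.09, gi50 = 1.20, doses = doses,
                                  dmax = 0.95, cv = 0.05, seed = 404)
  deg <- ratiometric_degradation(fl$median_gfp, fl$median_mch,
                                 100, 120, dmso_ratio = 2)
  keep <- !viability_from_gate(round(1e4 * fl$viable_fraction),
                               rep(1e4, 10), 1)$excluded
  deg_fit <- fit_4pl(doses[keep], 1 - deg[keep])  # fraction of DMSO signal
  via_fit <- fit_4pl(doses, fl$viable_fraction)
  w <- vd_score(gi50 = via_fit$abs_dc50, dc50 = deg_fit$rel_dc50,
                top_dose = max(doses))
  expect_equal(w$vd_score, 1.20 / 0.09, tolerance = 0.15)
})

test_that("dual-reporter ratios are DMSO-normalized", {
  expect_equal(dual_reporter_ratio(500, 1000, 500, 1000), 1)
  expect_equal(dual_reporter_ratio(250, 1000, 500, 1000), 0.5)
  expect_error(dual_reporter_ratio(0, 1, 1, 1), "positive")
  # full-rescue wells in a simulated screen sit near 1, non-hits near 1 - d
  sim <- simulate_screen(screen_sim_config(
    n_genes = 40, hit_genes = c(G0021 = 1), measurement_cv = 0.02,
    infection_failure_rate = 0, seed = 77))
  w <- sim$wells
  pos <- w$well_class == "plate_pos_ctrl"
  lib <- w$well_class == "library" & w$gene_id != "G0021"
  hit <- w$gene_id == "G0021"
  # use the plate positive controls (full rescue) as the DMSO-like reference
  ref_h <- median(w$hibit_rlu[pos]); ref_f <- median(w$firefly_rlu[pos])
  rr_hit <- dual_reporter_ratio(w$hibit_rlu[hit], w$firefly_rlu[hit],
                                ref_h, ref_f)
  rr_lib <- dual_reporter_ratio(w$hibit_rlu[lib], w$firefly_rlu[lib],
                                ref_h, ref_f)
  expect_equal(median(rr_hit), 1, tolerance = 0.15)
  expect_equal(median(rr_lib), 0.1, tolerance = 0.2)
})
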