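qc_fixture <- function(firefly) {
  n <- length(firefly)
  data.frame(
    plate_id = "LP1", replicate_id = "R1",
    well_id = sprintf("%s%02d", rep(LETTERS[1:16], each = 24), 1:24)[seq_len(n + 2)],
    gene_id = c(sprintf("G%02d", seq_len(n)), "", ""),
    guide_ids = c(sprintf("G%02d_sg1", seq_len(n)), "", ""),
    well_class = c(rep("library", n), "media_ctrl", "uninfected_ctrl"),
    hibit_rlu = 100,
    firefly_rlu = c(firefly, 1000, 1000),
    stringsAsFactors = FALSE)
}

test_that("the Firefly gate is a ratio test against plate control wells", {
  w <- firefly_qc(qc_fixture(c(1200, 1300, 1000, 5000)))
  # reference is 1000 RLU; threshold log10(1.25) = 0.0969
  expect_equal(w$firefly_log10_ratio[1], log10(1.2), tolerance = 1e-12)
  expect_false(w$qc_pass[1])               # 0.0792 < 0.0969
  expect_equal(w$firefly_log10_ratio[2], log10(1.3), tolerance = 1e-12)
  expect_true(w$qc_pass[2])                # 0.1139 > 0.0969
  expect_false(w$qc_pass[3])               # log10(1) = 0
  expect_true(w$qc_pass[4])
  expect_false(any(w$qc_pass[w$well_class != "library"]))
})

test_that("QC is monotone in the threshold and needs control wells", {
  w <- qc_fixture(seq(800, 6000, length.out = 30))
  passes <- vapply(c(0.05, 0.0969, 0.3, 0.6),
                   function(th) sum(firefly_qc(w, th)$qc_pass), numeric(1))
  expect_true(all(diff(passes) <= 0))
  no_ctrl <- w[w$well_class == "library", ]
  expect_error(firefly_qc(no_ctrl), "without media/uninfected control")
})

test_that("an exact cubic is recovered to high precision", {
  x <- seq(2000, 30000, length.out = 40)
  w <- qc_fixture(x)
  w$hibit_rlu[seq_along(x)] <- 2 * (x / 1e4)^3 + (x / 1e4)
  # express as raw polynomial in x: y = 1e-4 x + 2e-12 x^3
  w <- firefly_qc(w)
  poly <- fit_plate_polynomial(w)
  cf <- poly$coefficients
  # non-zero coefficients to >= 10 significant digits; zero ones near zero
  expect_lt(abs(cf[2] - 1e-4) / 1e-4, 1e-10)
  expect_lt(abs(cf[4] - 2e-12) / 2e-12, 1e-10)
  expect_lt(abs(cf[1]), 1e-8)
  expect_lt(abs(cf[3]), 1e-12)
  norm <- normalize_wells(w, list("LP1/R1" = poly))
  lib <- norm$well_class == "library" & norm$qc_pass
  expect_equal(norm$rel_change[lib], rep(1, sum(lib)), tolerance = 1e-9)
})

test_that("the robust re-fit pass resists displaced wells", {
  set.seed(21)
  x <- runif(96, 3000, 30000)
  y <- 50 + 0.8 * x + 1e-6 * x^2
  y_contaminated <- y
  bump <- sample(96, 5)
  y_contaminated[bump] <- y_contaminated[bump] * 10
  w <- qc_fixture(x)
  w$hibit_rlu[1:96] <- y_contaminated
  w <- firefly_qc(w)
  robust <- fit_plate_polynomial(w, robustify = TRUE)
  plain <- fit_plate_polynomial(w, robustify = FALSE)
  resid_of <- function(poly) {
    pred <- predict_poly <- poly$coefficients[1] +
      poly$coefficients[2] * x + poly$coefficients[3] * x^2 +
      poly$coefficients[4] * x^3
    median(abs(y_contaminated[-bump] - pred[-bump]))
  }
  expect_lt(resid_of(robust), resid_of(plain))
  expect_lte(robust$n_points_used, 91L)  # all 5 displaced wells removed
  expect_gte(robust$n_points_used, 80L)
})

test_that("degenerate polynomial fits are refused", {
  w <- firefly_qc(qc_fixture(rep(5000, 30)))
  expect_error(fit_plate_polynomial(w), "singular")
  w2 <- firefly_qc(qc_fixture(c(4000, 5000, 6000, 7000)))
  expect_error(fit_plate_polynomial(w2), "too few")
})

test_that("rel_change is the observed/predicted ratio with clamping", {
  x <- seq(2000, 30000, length.out = 40)
  w <- qc_fixture(x)
  w$hibit_rlu[seq_along(x)] <- 0.05 * x  # linear relation, exact fit
  w <- firefly_qc(w)
  polys <- fit_plate_polynomials(w)
  w$hibit_rlu[1] <- 0.05 * x[1] / 2      # halve one observation
  norm <- normalize_wells(w, polys)
  expect_equal(norm$rel_change[1], 0.5, tolerance = 1e-8)
  expect_equal(norm$rel_change[2], 1.0, tolerance = 1e-8)
  expect_false(any(norm$domain_clamped[norm$qc_pass], na.rm = TRUE))
})

test_that("noise-free null screens normalize to constant rel_change", {
  sim <- simulate_screen(screen_sim_config(
    n_genes = 80, measurement_cv = 0, infection_failure_rate = 0,
    rho_jitter_kappa = Inf, seed = 9))
  norm <- normalize_screen(sim$wells)$wells
  lib <- norm$qc_pass & norm$well_class == "library"
  rel <- norm$rel_change[lib]
  expect_gt(sum(lib), 200)
  expect_lt(max(abs(rel - 1)), 1e-6)  # constant to >= 6 significant digits
})

test_that("normalized activity tracks the generator's ground truth", {
  # plant rescuers across the whole effect range so the true relative change
  # varies from well to well (per-well guide-potency jitter adds spread);
  # the correlation is assessed on the rescuer wells, where the ground truth
  # is continuous rather than a single tied value
  set.seed(2)
  ids <- sprintf("G%04d", sample(943, 30))
  sim <- simulate_screen(screen_sim_config(
    n_genes = 943, hit_genes = setNames(runif(30, 0.2, 1), ids), seed = 31))
  norm <- normalize_screen(sim$wells)$wells
  key <- paste(norm$plate_id, norm$replicate_id, norm$well_id)
  tkey <- paste(sim$truth_wells$plate_id, sim$truth_wells$replicate_id,
                sim$truth_wells$well_id)
  truth <- sim$truth_wells$true_rel_change[match(key, tkey)]
  use <- norm$qc_pass & norm$well_class == "library" & !is.na(truth) &
    norm$gene_id %in% ids
  expect_gt(sum(use), 50)
  expect_gt(cor(norm$rel_change[use], truth[use], method = "spearman"), 0.9)
})

test_that("robust z-scores follow the median/MAD definition", {
  z <- robust_zscore(c(0, 1, 2, 3, 4))
  expect_equal(z[5], 2 / (1.4826 * 1), tolerance = 1e-10)
  expect_equal(z[3], 0)
  expect_equal(robust_zscore(rep(7, 6)), rep(0, 6))
  expect_error(robust_zscore(c(1, 2, 3, NA, NaN, Inf)), "at least 5")

  # affine invariance up to sign
  set.seed(4)
  x <- rnorm(50)
  expect_equal(robust_zscore(3 * x - 2), robust_zscore(x), tolerance = 1e-12)
  expect_equal(robust_zscore(-2 * x + 1), -robust_zscore(x), tolerance = 1e-12)

  # large-sample: median ~ 0, scaled MAD ~ 1
  set.seed(5)
  z2 <- robust_zscore(rnorm(1e5))
  expect_lt(abs(median(z2)), 0.02)
  expect_equal(mad(z2), 1, tolerance = 0.02)
})
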