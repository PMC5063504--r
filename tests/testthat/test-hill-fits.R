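noiseless_series <- function(params, pX, model = NULL, replicates = 1,
                             ion = "Ca", response_kind = "fret_ratio") {
  if (!is.null(model)) params$model <- model
  cfg <- simulation_config(seed = 1, noise_sd = 0, mode = "hill",
                           model_params = params)
  simulate_titration(cfg, pX, replicates = replicates, ion = ion,
                     response_kind = response_kind)
}

test_that("force-pCa fit recovers published fiber parameters exactly", {
  s <- noiseless_series(list(p50 = 5.74, n = 1.37), seq(8, 4, by = -0.25),
                        model = "force", response_kind = "normalized_force")
  f <- fit_hill_force(s)
  expect_equal(coef(f)[["p50"]], 5.74, tolerance = 1e-6)
  expect_equal(coef(f)[["n"]], 1.37, tolerance = 1e-6)
  # midpoint identity
  expect_equal(predict(f, 5.74), 50, tolerance = 1e-6)
  # limits under the fitted parameters
  expect_equal(predict(f, -20), 100, tolerance = 1e-6)
  expect_equal(predict(f, 30), 0, tolerance = 1e-6)
})

test_that("force fit rejects malformed inputs", {
  s <- noiseless_series(list(p50 = 5.74, n = 1.37), seq(8, 4, by = -0.5),
                        model = "force", response_kind = "normalized_force")
  bad <- s; bad$response <- rev(bad$response)
  expect_error(fit_hill_force(bad), "orientation|increases")
  s2 <- s; s2$response[1] <- 300
  expect_error(fit_hill_force(s2), "normalization")
  tiny <- titration_series(data.frame(pX = c(8, 7, 6), response = c(90, 50, 10)),
                           ion = "Ca", response_kind = "normalized_force")
  expect_error(fit_hill_force(tiny), "distinct pX")
})

test_that("single Hill fit recovers the published Mg titration exactly", {
  s <- noiseless_series(mg_hill_truth, seq(5.5, 1.5, length.out = 15),
                        ion = "Mg")
  f <- fit_single_hill(s)
  expect_equal(coef(f)[["p50"]], 3.28, tolerance = 1e-6)
  expect_equal(coef(f)[["n"]], 1.09, tolerance = 1e-6)
  expect_equal(coef(f)[["f_min"]], 0.043, tolerance = 1e-6)
  expect_equal(coef(f)[["f_max"]], 0.215, tolerance = 1e-6)

  # adding a constant shifts only f_min
  s_shift <- s; s_shift$response <- s$response + 0.5
  f2 <- fit_single_hill(s_shift)
  expect_equal(coef(f2)[["f_min"]], coef(f)[["f_min"]] + 0.5,
               tolerance = 1e-6)
  expect_equal(coef(f2)[c("f_max", "n", "p50")],
               coef(f)[c("f_max", "n", "p50")], tolerance = 1e-6)
})

test_that("flat data are rejected as having no transition", {
  set.seed(5)
  flat <- titration_series(
    data.frame(pX = rep(seq(5.5, 1.5, length.out = 10), each = 4),
               response = 0.1 + rnorm(40, sd = 0.01),
               replicate = rep(1:4, 10)),
    ion = "Mg")
  expect_error(fit_single_hill(flat), "no transition")
})

test_that("double Hill fit recovers all seven published parameters", {
  s <- noiseless_series(double_hill_truth, seq(9.5, 4.0, length.out = 25))
  f <- fit_double_hill(s)
  truth <- unlist(double_hill_truth)
  expect_equal(coef(f)[names(truth)], truth, tolerance = 1e-4)
  expect_true(coef(f)[["p50_1"]] > coef(f)[["p50_2"]])
  expect_false(isTRUE(f$weakly_identified))
  expect_true(all(is.finite(sqrt(diag(vcov(f))))))
})

test_that("double Hill reduces to single Hill when one amplitude is zero", {
  params <- list(f_min = 0.04, f_max1 = 0.2, n1 = 1.5, p50_1 = 6,
                 f_max2 = 0, n2 = 1, p50_2 = 4.5)
  s <- noiseless_series(params, seq(9, 3, length.out = 20))
  f2 <- suppressWarnings(fit_double_hill(s))
  s1 <- titration_series(as.data.frame(s), ion = "Ca")
  f1 <- fit_single_hill(s1)
  # predictions agree and the second amplitude vanishes
  grid_pX <- seq(9, 3, length.out = 50)
  keep <- abs(coef(f2)[["f_max1"]]) >= abs(coef(f2)[["f_max2"]])
  amp2 <- if (keep) coef(f2)[["f_max2"]] else coef(f2)[["f_max1"]]
  expect_lt(abs(amp2), 1e-3 * abs(params$f_max1))
  expect_equal(predict(f2, grid_pX), predict(f1, grid_pX),
               tolerance = 1e-5)
})

test_that("stochastic recovery of midpoints is unbiased at the study scale", {
  # double Hill: published no-Mg parameter set, sd 0.005, 25 points, 4 reps
  p1 <- vapply(1:20, function(seed) {
    cfg <- simulation_config(seed = seed, noise_sd = 0.005, mode = "hill",
                             model_params = double_hill_truth)
    s <- simulate_titration(cfg, seq(9.5, 4.0, length.out = 25),
                            replicates = 4)
    coef(fit_double_hill(s))[["p50_1"]]
  }, numeric(1))
  expect_equal(mean(p1), 7.17, tolerance = 0.05 / 7.17)

  # single Hill: published Mg parameter set
  pmg <- vapply(1:20, function(seed) {
    cfg <- simulation_config(seed = 100 + seed, noise_sd = 0.005,
                             mode = "hill", model_params = mg_hill_truth)
    s <- simulate_titration(cfg, seq(5.5, 1.5, length.out = 15),
                            replicates = 4, ion = "Mg")
    coef(fit_single_hill(s))[["p50"]]
  }, numeric(1))
  expect_equal(mean(pmg), 3.28, tolerance = 0.05 / 3.28)
})

test_that("parameter SEs shrink roughly as 1/sqrt(replicates)", {
  ses <- vapply(c(2, 8), function(reps) {
    cfg <- simulation_config(seed = 17, noise_sd = 0.005, mode = "hill",
                             model_params = mg_hill_truth)
    s <- simulate_titration(cfg, seq(5.5, 1.5, length.out = 15),
                            replicates = reps, ion = "Mg")
    fit_single_hill(s)$se[["p50"]]
  }, numeric(1))
  expect_lt(ses[2], ses[1])
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.5)
})

test_that("association constants follow Ka = 10^p50 and print at 2 s.f.", {
  expect_equal(ka_from_p50(0), 1)
  expect_equal(ka_from_p50(7.17, signif_digits = 2), 1.5e7)
  expect_equal(ka_from_p50(3.28, signif_digits = 2), 1.9e3)
  p <- seq(-2, 9, by = 0.37)
  expect_true(all(diff(ka_from_p50(p)) > 0))
})

test_that("Gaussian peak fitting recovers sedimentation coefficients", {
  g <- seq(3, 5.5, by = 0.01)
  d <- simulate_auc_distribution(data.frame(a0 = 1, mean = 4.18,
                                            delta = 0.12), g)
  f <- fit_gaussian_peak(d$s, d$frequency)
  expect_equal(coef(f)[["mean"]], 4.18, tolerance = 1e-6)
  expect_equal(coef(f)[["delta"]], 0.12, tolerance = 1e-6)
  expect_equal(coef(f)[["a0"]], 1, tolerance = 1e-6)
  # symmetric data: fitted mean within one grid step of the argmax
  expect_lt(abs(coef(f)[["mean"]] - d$s[which.max(d$frequency)]), 0.01 + 1e-9)

  # two-peak mixture with a window isolating the Ca-saturated peak
  d2 <- simulate_auc_distribution(
    data.frame(a0 = c(0.9, 1), mean = c(4.18, 4.45), delta = c(0.1, 0.1)),
    g, noise_sd = 0.002, seed = 3)
  f2 <- fit_gaussian_peak(d2$s, d2$frequency, window = c(4.33, 5.0))
  expect_equal(coef(f2)[["mean"]], 4.45, tolerance = 0.02 / 4.45)

  flat <- data.frame(s = g, frequency = seq_along(g))
  expect_error(fit_gaussian_peak(flat$s, flat$frequency), "local maximum")
})

test_that("fiber QC percentages and flags follow the stated thresholds", {
  r <- force_recovery(100, 20, 70)
  expect_equal(r$extraction_residual_pct, 20)
  expect_false(r$extraction_ok)   # strict < 20
  expect_true(r$recovery_ok)
  r2 <- force_recovery(100, 15, 70)
  expect_true(r2$extraction_ok && r2$recovery_ok)
  r3 <- force_recovery(100, 0, 100)
  expect_equal(r3$extraction_residual_pct, 0)
  expect_equal(r3$recovery_pct, 100)
  expect_error(force_recovery(0, 1, 1), "positive")
})
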