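test_that("the Ca panel round-trips the published contributions exactly", {
  sig <- panel_signals(ca_contrib_truth, ca_baseline_truth, "Ca")
  dec <- decompose_sites(sig, "Ca")
  expect_equal(dec$contributions, ca_contrib_truth, tolerance = 1e-12)
  expect_equal(dec$baseline, ca_baseline_truth, tolerance = 1e-12)
  expect_lt(dec$residual_norm, 1e-12)
})

test_that("the Mg panel round-trips the published contributions exactly", {
  sig <- panel_signals(mg_contrib_truth, mg_baseline_truth, "Mg")
  dec <- decompose_sites(sig, "Mg")
  expect_equal(dec$contributions, mg_contrib_truth, tolerance = 1e-12)
  expect_equal(dec$baseline, mg_baseline_truth, tolerance = 1e-12)
})

test_that("all-zero signals give all-zero contributions", {
  sig <- panel_signals(c(II = 0, III = 0, IV = 0), 0, "Ca")
  dec <- decompose_sites(sig, "Ca")
  expect_equal(unname(dec$contributions), c(0, 0, 0))
  expect_equal(dec$baseline, 0)
})

test_that("decompose-predict identity holds on random full-rank panels", {
  set.seed(13)
  for (i in 1:25) {
    contrib <- round(runif(3, -0.3, 0.3), 4)
    names(contrib) <- c("II", "III", "IV")
    base <- round(runif(1, -0.05, 0.1), 4)
    sig <- panel_signals(contrib, base, "Ca")
    dec <- decompose_sites(sig, "Ca")
    expect_equal(dec$contributions, contrib, tolerance = 1e-10)
    expect_equal(dec$baseline, base, tolerance = 1e-10)
    # predict() reproduces every construct's raw signal
    for (j in seq_len(nrow(sig)))
      expect_equal(predict(dec, sig$active_sites[[j]],
                           baseline_subtracted = FALSE),
                   sig$delta_fr[j], tolerance = 1e-10)
  }
})

test_that("the weighted solve equals the normal-equations oracle", {
  sig <- panel_signals(ca_contrib_truth, ca_baseline_truth, "Ca")
  set.seed(3)
  sig$delta_fr <- sig$delta_fr + rnorm(nrow(sig), sd = 0.01)
  sig$se <- runif(nrow(sig), 0.005, 0.02)
  dec <- decompose_sites(sig, "Ca")
  X <- cbind(1, t(sapply(sig$active_sites, function(a)
    as.numeric(c("II", "III", "IV") %in% a))))
  W <- diag(1 / sig$se^2)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% sig$delta_fr)
  expect_equal(unname(c(dec$baseline, dec$contributions)), c(beta),
               tolerance = 1e-10)
})

test_that("contribution SEs scale linearly with input SEs", {
  sig <- panel_signals(ca_contrib_truth, ca_baseline_truth, "Ca")
  sig$se <- rep(0.01, nrow(sig))
  se1 <- decompose_sites(sig, "Ca")$se
  sig$se <- rep(0.03, nrow(sig))
  se3 <- decompose_sites(sig, "Ca")$se
  expect_equal(unname(se3 / se1), rep(3, length(se1)), tolerance = 1e-8)
})

test_that("rank-deficient panels are rejected with the offending columns", {
  sig <- panel_signals(ca_contrib_truth, ca_baseline_truth, "Ca")
  sig <- sig[sig$construct_id %in% c("CTV-TnC WT", "D104A", "D140A",
                                     "D104-140A"), ]
  # II is active in every retained construct: II and baseline collinear
  expect_error(decompose_sites(sig, "Ca"), "rank-deficient")
  expect_error(decompose_sites(sig[1:2, ], "Ca"), "at least as many")
  dup <- rbind(sig, sig[1, ])
  expect_error(decompose_sites(dup, "Ca"), "distinct")
})

test_that("forward predictions reproduce the published sums", {
  ca <- ctv_site_contributions("Ca")
  mg <- ctv_site_contributions("Mg")
  expect_equal(predict(ca, c("II", "III", "IV")), 0.204)
  expect_equal(predict(mg, c("II", "III", "IV")), 0.193)
  expect_equal(predict(ca, character(0)), 0)
  expect_equal(predict(ca, c("II", "III", "IV"),
                       baseline_subtracted = FALSE), 0.214)
  # Mg prediction ignores site II
  expect_equal(predict(mg, c("II", "III")), 0.079)
})

test_that("additivity comparison matches the published discrepancies", {
  ca_check <- compare_to_wt(0.204, 0.217)
  expect_equal(ca_check$discrepancy, 0.013)
  mg_check <- compare_to_wt(0.193, 0.169)
  expect_equal(mg_check$discrepancy, 0.024)
  expect_equal(compare_to_wt(0.2, 0.2)$discrepancy, 0)
  flagged <- compare_to_wt(0.204, 0.217, se_predicted = 0.002,
                           se_observed = 0.002)
  expect_true(flagged$additivity_violated)
  ok <- compare_to_wt(0.204, 0.217, se_predicted = 0.01,
                      se_observed = 0.01)
  expect_false(ok$additivity_violated)
})
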