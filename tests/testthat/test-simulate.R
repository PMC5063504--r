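test_that("noiseless spectra are exact linear mixes", {
  refs <- default_refs()
  # f_r = 0, no direct: pure donor
  sp <- simulate_spectrum(0, 2.0, 433, refs)
  expect_equal(sp$intensity, 2.0 * refs$donor)
  # published WT FRET ratio as target: acceptor amplitude forced to 21.7
  sp2 <- simulate_spectrum(0.217, 100, 433, refs)
  expect_equal(sp2$truth$f_acc_fret, 21.7)
  expect_equal(sp2$intensity, 100 * refs$donor + 21.7 * refs$acceptor)
})

test_that("seeded simulation is bit-identical and restores the caller RNG", {
  refs <- default_refs()
  set.seed(99); before <- runif(1)
  set.seed(99)
  a <- simulate_spectrum(0.3, 100, 433, refs, noise_sd = 0.5, seed = 42)
  b <- simulate_spectrum(0.3, 100, 433, refs, noise_sd = 0.5, seed = 42)
  expect_identical(a$intensity, b$intensity)
  expect_identical(runif(1), before)

  cfg <- simulation_config(seed = 7, noise_sd = 0.01, mode = "hill",
                           model_params = mg_hill_truth)
  s1 <- simulate_titration(cfg, seq(5.5, 1.5, length.out = 15),
                           replicates = 4, ion = "Mg")
  s2 <- simulate_titration(cfg, seq(5.5, 1.5, length.out = 15),
                           replicates = 4, ion = "Mg")
  expect_identical(s1$response, s2$response)
})

test_that("acceptor-only scans scale with the direct-excitation profile", {
  refs <- default_refs()
  sp <- simulate_acceptor_only(515, 50, refs)
  expect_equal(max(sp$intensity), 50)
  sp400 <- simulate_acceptor_only(400, 50, refs)
  expect_lt(sp400$truth$f_acc, 50)
  expect_equal(sp400$truth$f_acc,
               50 * refs$acceptor_direct_profile(400))
  # unmixing an acceptor-only control returns a vanishing donor amplitude
  u <- unmix(sp400, refs)
  expect_lt(abs(u$f_don), 1e-9)
})

test_that("end-point truths follow the additive site model", {
  ca <- ctv_site_contributions("Ca")
  cfg <- simulation_config(seed = 3, noise_sd = 0)
  panel <- ctv_constructs()

  # no active sites: all three conditions at baseline
  ds0 <- simulate_endpoint_experiment(panel[panel$construct_id == "3XEF", ],
                                      ca, "Ca-in-EDTA", cfg)
  expect_equal(unname(ds0$truth$f_r), rep(cfg$f_r_apo + ca$baseline, 3))
  expect_equal(ds0$truth$delta_fr, 0)

  # WT: delta is the sum of all three contributions
  dsw <- simulate_endpoint_experiment(panel[1, ], ca, "Ca-in-EDTA", cfg)
  expect_equal(dsw$truth$delta_fr, 0.204)
  # site II alone: delta is c_II
  dsd <- simulate_endpoint_experiment(
    panel[panel$construct_id == "D104-140A", ], ca, "Ca-in-EDTA", cfg)
  expect_equal(dsd$truth$delta_fr, -0.120)

  # reversibility is built in and additivity holds for every construct
  for (i in seq_len(nrow(panel))) {
    ds <- simulate_endpoint_experiment(panel[i, ], ca, "Ca-in-EDTA", cfg)
    expect_identical(ds$truth$f_r[["chelated"]],
                     ds$truth$f_r[["rechelated"]])
    expect_equal(ds$truth$delta_fr,
                 sum(ca$contributions[intersect(panel$active_sites[[i]],
                                                names(ca$contributions))]))
  }
})

test_that("protocol and contribution ion must match", {
  mg <- ctv_site_contributions("Mg")
  expect_error(simulate_endpoint_experiment(ctv_constructs()[1, ], mg,
                                            "Ca-in-EDTA",
                                            simulation_config()),
               "Ca contributions")
  expect_error(simulate_titration(
    simulation_config(mode = "hill",
                      model_params = list(f_min = 0, f_max = 1, n = 1)),
    seq(8, 4), replicates = 1), "missing model parameter")
})

test_that("titration generator reproduces model identities", {
  # single Hill midpoint identity: response at p50 is f_min + f_max/2
  cfg <- simulation_config(seed = 1, noise_sd = 0, mode = "hill",
                           model_params = mg_hill_truth)
  s <- simulate_titration(cfg, mg_hill_truth$p50, replicates = 1,
                          ion = "Mg")
  expect_equal(s$response, mg_hill_truth$f_min + mg_hill_truth$f_max / 2)

  # biphasic curve rises then falls over the published parameter set
  cfg2 <- simulation_config(seed = 1, noise_sd = 0, mode = "hill",
                            model_params = double_hill_truth)
  pCa <- seq(9.5, 4.0, length.out = 100)
  s2 <- simulate_titration(cfg2, pCa, replicates = 1)
  i_max <- which.max(s2$response)
  expect_gt(i_max, 1)
  expect_lt(i_max, length(pCa))
  expect_gt(s2$response[i_max], s2$response[1] + 0.05)
  expect_gt(s2$response[i_max], s2$response[length(pCa)] + 0.05)
})

test_that("site-additive generative mode matches per-site occupancy", {
  ca <- ctv_site_contributions("Ca")
  cfg <- simulation_config(
    seed = 1, noise_sd = 0, mode = "site-additive",
    site_params = list(contributions = ca,
                       p50 = c(II = 5.47, III = 7.17, IV = 7.17)))
  pCa <- c(12, 6.3, 2)
  s <- simulate_titration(cfg, pCa, replicates = 1)
  # saturating Ca: baseline + all contributions; none: baseline
  expect_equal(s$response[3], ca$baseline + sum(ca$contributions),
               tolerance = 1e-3)
  expect_equal(s$response[1], ca$baseline, tolerance = 1e-3)
})

test_that("intensity noise converges to the configured SD", {
  refs <- default_refs()
  draws <- vapply(seq_len(10000), function(i)
    simulate_spectrum(0.2, 100, 433, refs, noise_sd = 0.5,
                      seed = i)$intensity[1], numeric(1))
  expect_equal(sd(draws), 0.5, tolerance = 0.1)
})

test_that("sedimentation distributions follow the Gaussian sum", {
  g <- seq(3, 5.5, by = 0.01)
  d <- simulate_auc_distribution(data.frame(a0 = 1, mean = 4.18,
                                            delta = 0.12), g)
  expect_equal(d$s[which.max(d$frequency)], 4.18)
  expect_equal(max(d$frequency), 1)

  expect_equal(simulate_auc_distribution(list(), g)$frequency,
               numeric(length(g)))
  d2 <- simulate_auc_distribution(
    data.frame(a0 = c(1, 0.8), mean = c(3.5, 4.8),
               delta = c(0.1, 0.1)), g)
  local_max <- which(diff(sign(diff(d2$frequency))) == -2) + 1
  expect_equal(length(local_max), 2)
  expect_error(simulate_auc_distribution(
    data.frame(a0 = 1, mean = 4, delta = 0), g), "delta")
  expect_error(simulate_auc_distribution(
    data.frame(a0 = 1, mean = 9, delta = 0.1), g), "inside")
})
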