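test_that("unmixing recovers exact amplitudes on noiseless mixes", {
  refs <- default_refs()
  sp <- new_spectrum(refs$wavelength_nm, 2.0 * refs$donor, 433)
  u <- unmix(sp, refs)
  expect_equal(u$f_don, 2.0, tolerance = 1e-12)
  expect_equal(u$f_acc, 0.0, tolerance = 1e-12)
  expect_lt(u$residual_ss, 1e-20)
})

test_that("unmixing equals the normal-equations and grid-search oracles", {
  refs <- default_refs()
  set.seed(11)
  noise <- rnorm(length(refs$wavelength_nm), sd = 0.01)
  y <- 1.5 * refs$donor + 0.8 * refs$acceptor + noise
  sp <- new_spectrum(refs$wavelength_nm, y, 433)
  u <- unmix(sp, refs)

  ne <- normal_equations_oracle(y, refs$donor, refs$acceptor)
  expect_equal(u$f_don, ne[["f_don"]], tolerance = 1e-10)
  expect_equal(u$f_acc, ne[["f_acc"]], tolerance = 1e-10)

  gs <- grid_search_oracle(y, refs$donor, refs$acceptor)
  expect_equal(u$f_don, gs[["f_don"]], tolerance = 2e-4)
  expect_equal(u$f_acc, gs[["f_acc"]], tolerance = 2e-4)

  # recovery within 3 SE of the generating amplitudes (SE from the fit's
  # residual variance and the design)
  sigma2 <- u$residual_ss / (length(y) - 2)
  X <- cbind(refs$donor, refs$acceptor)
  se <- sqrt(diag(solve(crossprod(X))) * sigma2)
  expect_lt(abs(u$f_don - 1.5), 3 * se[1])
  expect_lt(abs(u$f_acc - 0.8), 3 * se[2])
})

test_that("references are interpolated onto the scan grid, never extrapolated", {
  refs <- default_refs()
  wl <- seq(450, 600, by = 1.5)
  d <- approx(refs$wavelength_nm, refs$donor, wl)$y
  sp <- new_spectrum(wl, 3 * d, 433)
  u <- unmix(sp, refs)
  expect_equal(u$f_don, 3, tolerance = 1e-10)
  refs_narrow <- make_reference_spectra(wavelength_nm = seq(460, 600, by = 1))
  sp_wide <- new_spectrum(refs$wavelength_nm, refs$donor, 433)
  expect_error(unmix(sp_wide, refs_narrow), "extrapolation")
})

test_that("direct-excitation fraction matches the generator profile", {
  refs <- default_refs()
  c433 <- simulate_acceptor_only(433, 50, refs)
  c515 <- simulate_acceptor_only(515, 50, refs)
  r <- direct_excitation_fraction(c433, c515, refs)
  expect_equal(r, refs$acceptor_direct_profile(433), tolerance = 1e-10)
  expect_equal(direct_excitation_fraction(c515, c515, refs), 1)
  # non-increasing across the working excitation series
  rs <- vapply(c(433, 424, 420, 418, 414, 410, 408, 404, 400), function(ex)
    direct_excitation_fraction(simulate_acceptor_only(ex, 50, refs),
                               c515, refs), numeric(1))
  expect_true(all(diff(rs) <= 1e-12))
  # unusable control
  dead <- new_spectrum(refs$wavelength_nm, numeric(length(refs$acceptor)),
                       515)
  expect_error(direct_excitation_fraction(c433, dead, refs), "unusable")
})

test_that("direct-excitation correction is the stated subtraction", {
  expect_equal(correct_direct(5, 10, 0), 5)
  expect_equal(correct_direct(2, 20, 0.1), 0)
  flagged <- correct_direct(1, 20, 0.5, noise_se = 1)
  expect_equal(as.numeric(flagged), -9)
  expect_match(attr(flagged, "quality_flag"), "negative")
})

test_that("FRET ratio round-trips generator truth through the full pipeline", {
  refs <- default_refs()
  direct <- 20 * refs$acceptor_direct_profile(433)
  sp <- simulate_spectrum(0.217, 100, 433, refs,
                          acceptor_direct_amount = direct)
  res <- unmix_scan(sp,
                    simulate_acceptor_only(433, 20, refs),
                    simulate_acceptor_only(515, 20, refs),
                    simulate_acceptor_only(515, 20, refs), refs)
  expect_equal(res$f_r, 0.217, tolerance = 1e-9)
  expect_lt(abs(res$f_acc_fret - 21.7), 1e-9)
  # acceptor-channel conservation holds exactly by construction
  expect_identical(res$f_acc, res$f_acc_fret + res$f_acc_direct)
  expect_error(fret_ratio(1, 0), "positive")
  expect_equal(fret_ratio(0, 10), 0)
})

test_that("peak reads behave as the documented simple alternative", {
  refs <- default_refs()
  flat <- new_spectrum(refs$wavelength_nm, rep(1, length(refs$donor)), 433)
  expect_equal(unname(peak_read(flat)), c(1, 1))
  pure_don <- new_spectrum(refs$wavelength_nm, refs$donor, 433)
  pr <- peak_read(pure_don)
  # donor bleed-through into the 515 nm acceptor read
  expect_equal(pr[["f_acc"]], refs$donor[refs$wavelength_nm == 515])
  expect_gt(pr[["f_acc"]], 0)
  expect_error(peak_read(flat, acceptor_peak_nm = 700), "outside")
})
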