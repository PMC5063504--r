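# Parametric stand-ins for the Cerulean (donor) and Venus (acceptor) emission
# shapes, plus the acceptor direct-excitation profile. Real fluorescent-
# protein emission spectra are right-skewed, so each shape is a Gaussian core
# with a long-wavelength exponential tail. The analysis only assumes linear
# mixing of known shapes, so the exact parametric form is not load-bearing.

# Right-skewed unit-peak emission shape: Gaussian below the peak, a mixture of
# Gaussian and exponential tail above it. Continuous, equal to 1 at the peak.
skewed_emission_shape <- function(wavelength_nm, peak_nm, width_nm,
                                  tail_nm, tail_weight) {
  z <- (wavelength_nm - peak_nm) / width_nm
  core <- exp(-0.5 * z^2)
  up <- wavelength_nm >= peak_nm
  out <- core
  out[up] <- (1 - tail_weight) * core[up] +
    tail_weight * exp(-(wavelength_nm[up] - peak_nm) / tail_nm)
  out
}

#' Reference emission shapes for the donor/acceptor pair
#'
#' Builds unit-peak donor (Cerulean-like, emission maximum 475 nm) and
#' acceptor (Venus-like, emission maximum ~525 nm) emission shapes on a common
#' wavelength grid, together with the acceptor direct-excitation profile: the
#' relative efficiency with which the excitation beam itself excites the
#' acceptor, normalised to 1 at the acceptor's direct-excitation maximum
#' (515 nm). The profile is log-normal in excitation wavelength, so it decays
#' monotonically as the excitation moves from 515 nm down toward 400 nm; with
#' the default log-width the ratio profile(433)/profile(515) is 0.10 --
#' direct excitation is a minor correction at donor excitation wavelengths
#' and smaller still at shorter ones.
#'
#' A donor excitation-efficiency curve (bump around 433 nm, exactly zero at
#' and beyond 490 nm) is also attached; it scales total brightness per
#' excitation wavelength. Because the FRET ratio is a ratio, that scalar
#' cancels, which is precisely the property that makes \eqn{F_R} independent
#' of excitation wavelength.
#'
#' @param wavelength_nm emission wavelength grid (nm), strictly increasing.
#' @param donor_peak_nm,acceptor_em_peak_nm emission maxima (nm).
#' @param donor_width_nm,acceptor_width_nm Gaussian core widths (nm), > 0 and
#'   at least one grid step.
#' @param donor_tail_nm,acceptor_tail_nm long-wavelength tail constants (nm).
#' @param tail_weight mixing weight of the exponential tail in `[0, 1)`.
#' @param direct_peak_nm excitation wavelength of maximal direct acceptor
#'   excitation (nm; 515 for Venus).
#' @param direct_log_sd log-width of the direct-excitation profile.
#' @param acceptor_read_nm wavelength used for acceptor peak reads (nm). The
#'   acceptor emits maximally near 525 nm but peak reads follow the 515 nm
#'   convention; both are exposed as configuration.
#' @return An object of class `reference_spectra`: wavelength grid, `donor`
#'   and `acceptor` unit-peak shapes, `acceptor_direct_profile(ex_nm)` and
#'   `donor_excitation_efficiency(ex_nm)` functions, and the peak-read
#'   wavelengths.
#' @examples
#' refs <- make_reference_spectra()
#' max(refs$donor)                       # exactly 1
#' refs$acceptor_direct_profile(515)     # exactly 1
#' @export
make_reference_spectra <- function(wavelength_nm = seq(445, 610, by = 1),
                                   donor_peak_nm = 475,
                                   acceptor_em_peak_nm = 525,
                                   donor_width_nm = 14,
                                   acceptor_width_nm = 12,
                                   donor_tail_nm = 38,
                                   acceptor_tail_nm = 45,
                                   tail_weight = 0.35,
                                   direct_peak_nm = 515,
                                   direct_log_sd = 0.0808,
                                   acceptor_read_nm = 515) {
  stopifnot(length(wavelength_nm) >= 50, all(diff(wavelength_nm) > 0))
  step <- min(diff(wavelength_nm))
  if (donor_width_nm < step || acceptor_width_nm < step)
    stop("emission width below the wavelength grid step: shape would be degenerate")
  if (donor_peak_nm <= min(wavelength_nm) || donor_peak_nm >= max(wavelength_nm) ||
      acceptor_em_peak_nm <= min(wavelength_nm) ||
      acceptor_em_peak_nm >= max(wavelength_nm))
    stop("emission peaks must lie inside the wavelength grid")
  if (donor_tail_nm <= 0 || acceptor_tail_nm <= 0 || direct_log_sd <= 0)
    stop("tail constants and direct_log_sd must be positive")
  if (tail_weight < 0 || tail_weight >= 1)
    stop("tail_weight must be in [0, 1)")

  donor <- skewed_emission_shape(wavelength_nm, donor_peak_nm,
                                 donor_width_nm, donor_tail_nm, tail_weight)
  acceptor <- skewed_emission_shape(wavelength_nm, acceptor_em_peak_nm,
                                    acceptor_width_nm, acceptor_tail_nm,
                                    tail_weight)
  donor <- donor / max(donor)
  acceptor <- acceptor / max(acceptor)

  gram <- crossprod(cbind(donor, acceptor))
  cn <- kappa(gram, exact = TRUE)
  if (!is.finite(cn) || cn >= 1e6)
    stop("donor and acceptor shapes are (near-)collinear: unmixing would be singular ",
         "(Gram condition number ", format(cn), ")")

  direct_profile <- local({
    pk <- direct_peak_nm; s <- direct_log_sd
    function(excitation_nm) {
      if (any(excitation_nm < 350 | excitation_nm > 650))
        stop("excitation wavelength outside the direct-excitation profile domain (350-650 nm)")
      exp(-log(excitation_nm / pk)^2 / (2 * s^2))
    }
  })
  # Donor absorption bump centred at 433 nm, clamped to exactly zero at and
  # beyond 490 nm so scans excited at 515 nm carry no donor or FRET emission.
  donor_eff <- function(excitation_nm) {
    f <- exp(-0.5 * ((excitation_nm - 433) / 35)^2)
    f0 <- exp(-0.5 * ((490 - 433) / 35)^2)
    pmax(0, (f - f0) / (1 - f0))
  }

  structure(list(
    wavelength_nm = wavelength_nm,
    donor = donor,
    acceptor = acceptor,
    donor_peak_nm = donor_peak_nm,
    acceptor_em_peak_nm = acceptor_em_peak_nm,
    acceptor_peak_nm = acceptor_read_nm,
    direct_peak_nm = direct_peak_nm,
    acceptor_direct_profile = direct_profile,
    donor_excitation_efficiency = donor_eff
  ), class = "reference_spectra")
}

#' @export
print.reference_spectra <- function(x, ...) {
  cat("Reference emission spectra\n")
  cat(sprintf("  grid: %g-%g nm (%d points)\n", min(x$wavelength_nm),
              max(x$wavelength_nm), length(x$wavelength_nm)))
  cat(sprintf("  donor peak %g nm, acceptor emission peak %g nm (read at %g nm)\n",
              x$donor_peak_nm, x$acceptor_em_peak_nm, x$acceptor_peak_nm))
  cat(sprintf("  direct excitation max %g nm; profile(433) = %.3f\n",
              x$direct_peak_nm, x$acceptor_direct_profile(433)))
  invisible(x)
}

#' A single emission scan
#'
#' Container for one fluorescence emission scan: a strictly increasing
#' wavelength grid, intensities, the excitation wavelength, and labels.
#'
#' @param wavelength_nm,intensity equal-length numeric vectors; the grid must
#'   be strictly increasing and intensities finite.
#' @param excitation_nm excitation wavelength (nm).
#' @param condition,construct_id labels.
#' @param truth optional list of generator ground truth (kept as attribute-
#'   style list entry, used only by tests).
#' @return An object of class `spectrum`.
#' @export
new_spectrum <- function(wavelength_nm, intensity, excitation_nm,
                         condition = NA_character_,
                         construct_id = NA_character_, truth = NULL) {
  stopifnot(length(wavelength_nm) == length(intensity))
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (!all(is.finite(intensity)))
    stop("all intensities must be finite")
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 excitation_nm = excitation_nm, condition = condition,
                 construct_id = construct_id, truth = truth),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "Emission scan: %g-%g nm (%d pts), ex %g nm, condition '%s', construct '%s'\n",
    min(x$wavelength_nm), max(x$wavelength_nm), length(x$wavelength_nm),
    x$excitation_nm, x$condition, x$construct_id))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ...) {
  graphics::plot(x$wavelength_nm, x$intensity, type = "l",
                 xlab = "wavelength (nm)", ylab = "intensity (a.u.)",
                 main = sprintf("ex %g nm, %s", x$excitation_nm, x$condition),
                 ...)
  invisible(x)
}
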