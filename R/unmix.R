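# Two-component linear spectral decomposition and the FRET-ratio statistic.
#
# Each scan is modelled as intensity ~ F_Don * donor_shape +
# F_Acc * acceptor_shape; (F_Don, F_Acc) is the global least-squares
# solution. F_Acc splits into a FRET-driven part and a direct-excitation
# part, F_Acc = F_AccFRET + F_AccDirect; the direct part is estimated from an
# acceptor-only control and subtracted, and F_R = F_AccFRET / F_Don.

interp_refs <- function(refs, wavelength_nm) {
  if (identical(refs$wavelength_nm, wavelength_nm))
    return(cbind(donor = refs$donor, acceptor = refs$acceptor))
  if (min(wavelength_nm) < min(refs$wavelength_nm) ||
      max(wavelength_nm) > max(refs$wavelength_nm))
    stop("spectrum grid extends beyond the reference grid; ",
         "extrapolation of reference shapes is not allowed")
  cbind(
    donor = stats::approx(refs$wavelength_nm, refs$donor, wavelength_nm)$y,
    acceptor = stats::approx(refs$wavelength_nm, refs$acceptor,
                             wavelength_nm)$y)
}

#' Unmix a scan into donor and acceptor amplitudes
#'
#' Ordinary least squares of the scan onto the two reference shapes
#' (references are linearly interpolated onto the scan's grid when the grids
#' differ; extrapolation is refused). Amplitudes are deliberately
#' unconstrained -- under noise an amplitude near zero may come out slightly
#' negative, and truncating it would bias it upward -- and a `negative_flag`
#' is set instead.
#'
#' @param spectrum a [new_spectrum()] object.
#' @param refs a [make_reference_spectra()] object.
#' @param window emission window (nm) used for the fit.
#' @return An object of class `unmix_fit`: `f_don`, `f_acc`, `residual_ss`,
#'   `negative_flag`, and the fitted values.
#' @examples
#' refs <- make_reference_spectra()
#' sp <- simulate_spectrum(0.2, 100, 433, refs)
#' unmix(sp, refs)
#' @export
unmix <- function(spectrum, refs, window = c(445, 610)) {
  stopifnot(inherits(spectrum, "spectrum"),
            inherits(refs, "reference_spectra"))
  keep <- spectrum$wavelength_nm >= window[1] &
    spectrum$wavelength_nm <= window[2]
  if (sum(keep) < 50)
    stop("fewer than 50 points inside the analysis window; cannot unmix")
  X <- interp_refs(refs, spectrum$wavelength_nm[keep])
  cn <- kappa(crossprod(X), exact = TRUE)
  if (!is.finite(cn) || cn > 1e8)
    stop("reference shapes are collinear on this grid ",
         "(Gram condition number ", format(cn), "); unmixing is singular")
  y <- spectrum$intensity[keep]
  fit <- stats::lm.fit(X, y)
  co <- fit$coefficients
  structure(list(f_don = unname(co["donor"]),
                 f_acc = unname(co["acceptor"]),
                 residual_ss = sum(fit$residuals^2),
                 negative_flag = any(co < 0),
                 fitted = fit$fitted.values,
                 window = window, n = sum(keep)),
            class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf("Spectral unmixing: F_Don = %.6g, F_Acc = %.6g (RSS %.3g, n = %d)\n",
              x$f_don, x$f_acc, x$residual_ss, x$n))
  if (x$negative_flag) cat("  warning flag: negative amplitude\n")
  invisible(x)
}

#' Direct-excitation fraction from acceptor-only controls
#'
#' Ratio of the unmixed acceptor amplitude of an acceptor-only control excited
#' at the working wavelength to that of the same control excited at the
#' direct-excitation maximum (515 nm): the fraction of maximal direct
#' excitation reaching the acceptor at that excitation wavelength.
#'
#' @param control_at_lambda,control_at_direct_max acceptor-only control scans
#'   of the same sample, excited at the working wavelength and at the direct
#'   maximum respectively.
#' @param refs a [make_reference_spectra()] object.
#' @return `r`, dimensionless (expected in `[0, 1]`).
#' @export
direct_excitation_fraction <- function(control_at_lambda,
                                       control_at_direct_max, refs) {
  num <- unmix(control_at_lambda, refs)$f_acc
  den <- unmix(control_at_direct_max, refs)$f_acc
  if (!is.finite(den) || den <= 0)
    stop("control at the direct-excitation maximum has nonpositive acceptor ",
         "amplitude; unusable control")
  num / den
}

#' Correct the acceptor amplitude for direct excitation
#'
#' `f_acc_fret = f_acc - r * sample_acc_at_direct_max`: the sample's
#' directly-excited acceptor amplitude at the working excitation is its
#' amplitude under 515 nm excitation scaled by the control-derived fraction
#' `r`.
#'
#' @param f_acc unmixed acceptor amplitude of the sample scan (a.u.).
#' @param sample_acc_at_direct_max the sample's unmixed acceptor amplitude
#'   under excitation at the direct maximum (a.u.).
#' @param r direct-excitation fraction from
#'   [direct_excitation_fraction()], >= 0.
#' @param noise_se optional amplitude SE; a result below `-3 * noise_se` sets
#'   attribute `quality_flag`.
#' @return `f_acc_fret` (a.u.), with attribute `quality_flag` when strongly
#'   negative.
#' @export
correct_direct <- function(f_acc, sample_acc_at_direct_max, r,
                           noise_se = 0) {
  stopifnot(is.finite(f_acc), is.finite(sample_acc_at_direct_max),
            is.finite(r), r >= 0)
  out <- f_acc - r * sample_acc_at_direct_max
  if (out < -3 * noise_se && noise_se > 0)
    attr(out, "quality_flag") <- "f_acc_fret strongly negative"
  out
}

#' The FRET ratio
#'
#' \eqn{F_R = F_{AccFRET} / F_{Don}}. Enhanced FRET raises the FRET-driven
#' acceptor emission while lowering donor emission, so \eqn{F_R} is a
#' sensitive, excitation-intensity-independent FRET indicator.
#'
#' @param f_acc_fret FRET-driven acceptor amplitude (a.u.).
#' @param f_don donor amplitude (a.u.), must be > 0.
#' @return \eqn{F_R}, dimensionless.
#' @export
fret_ratio <- function(f_acc_fret, f_don) {
  if (!is.finite(f_don) || f_don <= 0)
    stop("donor amplitude must be positive; scan is uninterpretable")
  f_acc_fret / f_don
}

#' Full per-scan unmixing result
#'
#' Convenience wrapper running [unmix()], [direct_excitation_fraction()],
#' [correct_direct()] and [fret_ratio()] on one sample scan with its
#' controls. The identity `f_acc == f_acc_fret + f_acc_direct` holds exactly
#' by construction.
#'
#' @param sample sample scan.
#' @param control,control_at_direct_max acceptor-only control scans at the
#'   sample's excitation and at the direct maximum.
#' @param sample_at_direct_max sample scan excited at the direct maximum.
#' @param refs reference shapes.
#' @return An object of class `unmix_result` with fields `f_don`, `f_acc`,
#'   `f_acc_direct`, `f_acc_fret`, `f_r`, `residual_ss`, `negative_flag`.
#' @export
unmix_scan <- function(sample, control, control_at_direct_max,
                       sample_at_direct_max, refs) {
  u <- unmix(sample, refs)
  r <- direct_excitation_fraction(control, control_at_direct_max, refs)
  acc_max <- unmix(sample_at_direct_max, refs)$f_acc
  f_acc_fret <- correct_direct(u$f_acc, acc_max, r)
  structure(list(f_don = u$f_don, f_acc = u$f_acc,
                 f_acc_direct = u$f_acc - f_acc_fret,
                 f_acc_fret = as.numeric(f_acc_fret),
                 f_r = fret_ratio(as.numeric(f_acc_fret), u$f_don),
                 residual_ss = u$residual_ss,
                 negative_flag = u$negative_flag,
                 r = r, excitation_nm = sample$excitation_nm,
                 condition = sample$condition,
                 construct_id = sample$construct_id),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf(
    "Scan (ex %g nm, %s): F_Don %.5g, F_Acc %.5g = FRET %.5g + direct %.5g; F_R = %.5g\n",
    x$excitation_nm, x$condition, x$f_don, x$f_acc, x$f_acc_fret,
    x$f_acc_direct, x$f_r))
  invisible(x)
}

#' Peak intensity reads at the donor and acceptor wavelengths
#'
#' The simpler alternative to full unmixing used for full-range titration
#' series: raw intensities at the grid points nearest 475 nm (donor) and
#' 515 nm (acceptor). Note the acceptor read contains donor bleed-through
#' (the donor shape is nonzero at 515 nm), which is why unmixing is the
#' default for end-point analysis; on a fixed instrument the two differ by a
#' constant construct-specific factor. Nearest-grid-point ties resolve to the
#' lower wavelength.
#'
#' @param spectrum a [new_spectrum()] object.
#' @param donor_peak_nm,acceptor_peak_nm read wavelengths (nm); must lie
#'   inside the scan window.
#' @return Named numeric vector `c(f_don, f_acc)`.
#' @export
peak_read <- function(spectrum, donor_peak_nm = 475, acceptor_peak_nm = 515) {
  wl <- spectrum$wavelength_nm
  for (p in c(donor_peak_nm, acceptor_peak_nm))
    if (p < min(wl) || p > max(wl))
      stop("read wavelength ", p, " nm outside the scan window")
  nearest <- function(p) {
    d <- abs(wl - p)
    which(d == min(d))[1]  # tie -> lower wavelength
  }
  c(f_don = spectrum$intensity[nearest(donor_peak_nm)],
    f_acc = spectrum$intensity[nearest(acceptor_peak_nm)])
}
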