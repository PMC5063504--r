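# Hill-type response models in pX = -log10(free ion) and their nonlinear
# least-squares fitters (Levenberg-Marquardt via minpack.lm, multi-start over
# a midpoint grid, box bounds 0.2 <= n <= 6 on Hill slopes). All fitters
# return classed S3 objects sharing print/summary/coef/predict/plot/
# residuals/fitted methods.

#' Hill-type response curves
#'
#' `hill_force_curve()` is the normalized force--pCa relation
#' \eqn{F = 100 / (1 + 10^{n_H (pCa - pCa_{50})})} (force approaches 100% at
#' saturating Ca2+, 0 at low Ca2+). `hill_curve()` is the 4-parameter single
#' Hill response \eqn{f = F_{min} + F_{max} / (1 + 10^{n (pX - pX_{50})})},
#' and `double_hill_curve()` the 7-parameter sum of two such components,
#' which describes the sensor's biphasic Ca2+ response (a rising
#' high-affinity C-domain component and a falling -- negative amplitude --
#' low-affinity N-domain component).
#'
#' @param pX,pCa \eqn{-\log_{10}} free-ion concentration.
#' @param p50,p50_1,p50_2 transition midpoints (pX units).
#' @param n,n1,n2 Hill coefficients (> 0).
#' @param f_min response offset at low free ion (high pX).
#' @param f_max,f_max1,f_max2 response amplitudes; amplitudes may be
#'   negative.
#' @return Numeric response vector.
#' @export
hill_force_curve <- function(pCa, p50, n) {
  100 / (1 + 10^(n * (pCa - p50)))
}

#' @rdname hill_force_curve
#' @export
hill_curve <- function(pX, f_min, f_max, n, p50) {
  f_min + f_max / (1 + 10^(n * (pX - p50)))
}

#' @rdname hill_force_curve
#' @export
double_hill_curve <- function(pCa, f_min, f_max1, n1, p50_1,
                              f_max2, n2, p50_2) {
  f_min + f_max1 / (1 + 10^(n1 * (pCa - p50_1))) +
    f_max2 / (1 + 10^(n2 * (pCa - p50_2)))
}

new_hill_fit <- function(fit, data, model, extra = list()) {
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, length(co)))
  structure(c(list(coefficients = co, se = se,
                   residual_ss = sum(stats::residuals(fit)^2),
                   converged = fit$convInfo$isConv %||% TRUE,
                   vcov = tryCatch(stats::vcov(fit),
                                   error = function(e) NULL),
                   data = data, model = model, nls = fit),
              extra),
            class = c(paste0(model, "_fit"), "hill_family_fit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_series <- function(series, min_distinct, response_kind = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (!is.null(response_kind) &&
      attr(series, "response_kind") != response_kind)
    stop("series response_kind must be '", response_kind, "'")
  if (length(unique(series$pX)) < min_distinct)
    stop("need at least ", min_distinct,
         " distinct pX values for this fit")
  invisible(series)
}

p50_start_grid <- function(pX) stats::quantile(pX, c(0.25, 0.5, 0.75),
                                               names = FALSE)

run_multistart <- function(starts, fit_one) {
  best <- NULL
  for (st in starts) {
    f <- tryCatch(fit_one(st), error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from every start point")
  best$fit
}

#' Fit the force--pCa Hill relation
#'
#' Fits \eqn{F = 100 / (1 + 10^{n_H (pCa - pCa_{50})})} to normalized (%)
#' steady-state force, with the numerator fixed at 100 (force is normalized
#' to the same fiber's maximum at saturating Ca2+, so the plateau is 100 by
#' construction). Two free parameters: `p50` (pCa50) and `n` (Hill
#' coefficient, bounded to `[0.2, 6]`).
#'
#' @param series a [titration_series] with
#'   `response_kind = "normalized_force"`, responses in percent.
#' @return An object of class `hill_force_fit`.
#' @examples
#' cfg <- simulation_config(seed = 7, noise_sd = 2, mode = "hill",
#'   model_params = list(model = "force", p50 = 5.74, n = 1.37))
#' s <- simulate_titration(cfg, seq(8, 4, length.out = 12), replicates = 6,
#'                         response_kind = "normalized_force")
#' coef(fit_hill_force(s))
#' @export
fit_hill_force <- function(series) {
  check_series(series, 6, "normalized_force")
  # responses should sit in [-5, 110]% up to noise; a gross excursion means
  # the data were never normalized to the post-reconstitution maximum
  if (any(series$response < -15 | series$response > 125))
    stop("normalized force outside [-15, 125]%: check normalization")
  if (stats::cor(series$pX, series$response) > 0.5)
    stop("force increases with pCa: data orientation is inconsistent with ",
         "a force-pCa relation")
  df <- data.frame(pX = series$pX, y = series$response)
  starts <- lapply(p50_start_grid(df$pX), function(p) list(p50 = p, n = 1))
  fit <- run_multistart(starts, function(st)
    minpack.lm::nlsLM(y ~ 100 / (1 + 10^(n * (pX - p50))), data = df,
                      start = st,
                      lower = c(p50 = min(df$pX) - 2, n = 0.2),
                      upper = c(p50 = max(df$pX) + 2, n = 6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)))
  new_hill_fit(fit, series, "hill_force")
}

#' Fit a single Hill response
#'
#' Fits the 4-parameter model \eqn{f = F_{min} + F_{max} / (1 + 10^{n (pX -
#' pX_{50})})}, used for Mg2+ titrations of the sensor (non-normalized
#' \eqn{F_R} fit directly). Initialization: `f_min`/`f_max` from the response
#' extrema, midpoint starts at the 25/50/75% quantiles of the observed pX
#' range, `n` starts at 1 with bounds `[0.2, 6]`.
#'
#' @param series a [titration_series] with >= 6 distinct pX values.
#' @return An object of class `single_hill_fit`.
#' @export
fit_single_hill <- function(series) {
  check_series(series, 6)
  df <- data.frame(pX = series$pX, y = series$response)
  agg <- tapply(df$y, df$pX, mean)
  noise <- stats::median(tapply(df$y, df$pX, stats::sd), na.rm = TRUE)
  if (!is.na(noise) && noise > 0 && diff(range(agg)) < 5 * noise)
    stop("no transition: response range below 5x the replicate noise")
  lo_pX <- agg[[length(agg)]]; hi_pX <- agg[[1]]  # agg ordered by pX
  f_min0 <- min(df$y)
  f_max0 <- lo_pX - hi_pX  # response at low pX minus at high pX
  if (abs(f_max0) < 1e-12) f_max0 <- diff(range(df$y))
  starts <- lapply(p50_start_grid(df$pX), function(p)
    list(f_min = f_min0, f_max = f_max0, n = 1, p50 = p))
  fit <- run_multistart(starts, function(st)
    minpack.lm::nlsLM(y ~ f_min + f_max / (1 + 10^(n * (pX - p50))),
                      data = df, start = st,
                      lower = c(f_min = -Inf, f_max = -Inf, n = 0.2,
                                p50 = min(df$pX) - 2),
                      upper = c(f_min = Inf, f_max = Inf, n = 6,
                                p50 = max(df$pX) + 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)))
  new_hill_fit(fit, series, "single_hill")
}

#' Fit the biphasic double Hill response
#'
#' Fits \eqn{f = F_{min} + F_{max1}/(1 + 10^{n_1 (pCa - pCa_{501})}) +
#' F_{max2}/(1 + 10^{n_2 (pCa - pCa_{502})})}, evaluating the high- and
#' low-affinity EF-hand classes simultaneously. After convergence the
#' components are relabelled so component 1 has the higher midpoint
#' (`p50_1 > p50_2`, ties broken by amplitude magnitude); when the two
#' midpoints collapse (|difference| < 0.3) the fit is flagged weakly
#' identified rather than rejected.
#'
#' Multi-start: all ordered pairs of midpoint starts from the 25/50/75%
#' quantiles of the observed pX range, both slopes starting at 1.
#'
#' @param series a [titration_series] with >= 10 distinct pX values spanning
#'   both transitions.
#' @return An object of class `double_hill_fit`, with `weakly_identified`
#'   flag and the fit covariance in `$vcov`.
#' @export
fit_double_hill <- function(series) {
  check_series(series, 10)
  df <- data.frame(pX = series$pX, y = series$response)
  agg <- tapply(df$y, df$pX, mean)     # ordered by increasing pX
  f_min0 <- min(df$y)
  # biphasic shape: rises from the high-pX end to a maximum, then falls
  f_max10 <- max(agg) - agg[[length(agg)]]
  f_max20 <- agg[[1]] - max(agg)
  if (abs(f_max10) < 1e-12) f_max10 <- diff(range(df$y))
  if (abs(f_max20) < 1e-12) f_max20 <- -diff(range(df$y)) / 2
  q <- p50_start_grid(df$pX)
  starts <- list()
  for (p1 in q) for (p2 in q) if (p1 >= p2)
    starts[[length(starts) + 1]] <-
      list(f_min = f_min0, f_max1 = f_max10, n1 = 1, p50_1 = p1,
           f_max2 = f_max20, n2 = 1, p50_2 = p2)
  fit <- run_multistart(starts, function(st)
    minpack.lm::nlsLM(
      y ~ f_min + f_max1 / (1 + 10^(n1 * (pX - p50_1))) +
        f_max2 / (1 + 10^(n2 * (pX - p50_2))),
      data = df, start = st,
      lower = c(f_min = -Inf, f_max1 = -Inf, n1 = 0.2,
                p50_1 = min(df$pX) - 2, f_max2 = -Inf, n2 = 0.2,
                p50_2 = min(df$pX) - 2),
      upper = c(f_min = Inf, f_max1 = Inf, n1 = 6, p50_1 = max(df$pX) + 2,
                f_max2 = Inf, n2 = 6, p50_2 = max(df$pX) + 2),
      control = minpack.lm::nls.lm.control(maxiter = 400)))
  out <- new_hill_fit(fit, series, "double_hill")

  co <- out$coefficients
  swap <- co["p50_1"] < co["p50_2"] ||
    (co["p50_1"] == co["p50_2"] &&
       abs(co["f_max1"]) < abs(co["f_max2"]))
  if (swap) {
    perm <- c("f_min", "f_max2", "n2", "p50_2", "f_max1", "n1", "p50_1")
    names(perm) <- c("f_min", "f_max1", "n1", "p50_1", "f_max2", "n2",
                     "p50_2")
    out$coefficients <- stats::setNames(co[perm], names(perm))
    out$se <- stats::setNames(out$se[match(perm, names(co))], names(perm))
    if (!is.null(out$vcov))
      out$vcov <- out$vcov[perm, perm]
  }
  out$weakly_identified <-
    abs(out$coefficients["p50_1"] - out$coefficients["p50_2"]) < 0.3
  if (out$weakly_identified)
    warning("double-Hill midpoints closer than 0.3 pX units: components ",
            "weakly identified")
  out
}

#' Association constant from a Hill midpoint
#'
#' \eqn{K_a = 1 / 10^{-pX_{50}} = 10^{pX_{50}}} (L/mol). Reported values in
#' the field are conventionally rounded to 2 significant figures; pass
#' `signif_digits = 2` to match.
#'
#' @param p50 Hill midpoint (pX units), finite; vectorized.
#' @param signif_digits optional rounding (significant figures).
#' @return \eqn{K_a} in L/mol.
#' @examples
#' ka_from_p50(7.17, signif_digits = 2)  # 1.5e7
#' @export
ka_from_p50 <- function(p50, signif_digits = NULL) {
  stopifnot(all(is.finite(p50)))
  ka <- 10^p50
  if (!is.null(signif_digits)) ka <- signif(ka, signif_digits)
  ka
}

#' Fit a Gaussian sedimentation peak
#'
#' Nonlinear least squares of
#' \eqn{f = A_0 \exp(-0.5 ((x - s)/\delta)^2)} to a sedimentation-coefficient
#' distribution inside a window that must contain one dominant interior
#' maximum; `s` is the mean sedimentation coefficient (Svedberg), `delta` its
#' standard deviation.
#'
#' @param s_grid,frequency the distribution (s in Svedberg, relative
#'   frequency).
#' @param window s range to fit over (default: whole grid).
#' @param start_mean optional start for the mean (default: windowed argmax).
#' @return An object of class `gaussian_peak_fit` with coefficients `a0`,
#'   `mean`, `delta`.
#' @examples
#' d <- simulate_auc_distribution(data.frame(a0 = 1, mean = 4.18,
#'                                           delta = 0.12),
#'                                seq(3, 5.5, by = 0.01))
#' coef(fit_gaussian_peak(d$s, d$frequency))
#' @export
fit_gaussian_peak <- function(s_grid, frequency, window = range(s_grid),
                              start_mean = NULL) {
  keep <- s_grid >= window[1] & s_grid <= window[2]
  s <- s_grid[keep]; y <- frequency[keep]
  if (length(s) < 5) stop("window contains too few points")
  imax <- which.max(y)
  if (imax == 1L || imax == length(s))
    stop("no interior local maximum in the window; cannot fit a peak")
  a00 <- y[imax]
  mean0 <- start_mean %||% s[imax]
  # width start from the half-maximum span
  above <- s[y >= a00 / 2]
  delta0 <- max((max(above) - min(above)) / 2.355, diff(range(s)) / 50)
  df <- data.frame(s = s, y = y)
  fit <- minpack.lm::nlsLM(y ~ a0 * exp(-0.5 * ((s - m) / delta)^2),
                           data = df,
                           start = list(a0 = a00, m = mean0, delta = delta0),
                           lower = c(a0 = 0, m = window[1],
                                     delta = .Machine$double.eps),
                           upper = c(a0 = Inf, m = window[2], delta = Inf),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  structure(list(coefficients = c(a0 = unname(co["a0"]),
                                  mean = unname(co["m"]),
                                  delta = unname(co["delta"])),
                 se = tryCatch(sqrt(diag(stats::vcov(fit)))[c("a0", "m",
                                                              "delta")],
                               error = function(e) rep(NA_real_, 3)),
                 residual_ss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 window = window, data = df, nls = fit),
            class = c("gaussian_peak_fit", "hill_family_fit"))
}

#' Fiber quality control: extraction and reconstitution percentages
#'
#' Expresses post-extraction residual force and post-reconstitution maximal
#' force as percentages of the pre-extraction force P0, with the standard
#' acceptance flags: extraction satisfactory when the residual is strictly
#' below 20% of P0, reconstitution satisfactory when recovery exceeds 60%.
#'
#' @param force_pre pre-extraction maximal Ca2+-activated force P0 (> 0).
#' @param force_post_extraction residual force after TnC extraction.
#' @param force_post_reconstitution maximal force after reconstitution.
#' @return A list: `extraction_residual_pct`, `recovery_pct`,
#'   `extraction_ok`, `recovery_ok`.
#' @examples
#' force_recovery(100, 15, 70)
#' @export
force_recovery <- function(force_pre, force_post_extraction,
                           force_post_reconstitution) {
  if (!is.finite(force_pre) || force_pre <= 0)
    stop("pre-extraction force P0 must be positive")
  residual <- 100 * force_post_extraction / force_pre
  recovery <- 100 * force_post_reconstitution / force_pre
  list(extraction_residual_pct = residual, recovery_pct = recovery,
       extraction_ok = residual < 20, recovery_ok = recovery > 60)
}
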