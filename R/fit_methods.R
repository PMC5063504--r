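# Shared methods for the fitted-model classes.

fit_curve_fun <- function(object) {
  co <- as.list(object$coefficients)
  switch(class(object)[1],
    hill_force_fit = function(pX)
      hill_force_curve(pX, co$p50, co$n),
    single_hill_fit = function(pX)
      hill_curve(pX, co$f_min, co$f_max, co$n, co$p50),
    double_hill_fit = function(pX)
      double_hill_curve(pX, co$f_min, co$f_max1, co$n1, co$p50_1,
                        co$f_max2, co$n2, co$p50_2),
    gaussian_peak_fit = function(pX)
      co$a0 * exp(-0.5 * ((pX - co$mean) / co$delta)^2),
    stop("unknown fit class"))
}

#' @export
coef.hill_family_fit <- function(object, ...) object$coefficients

#' @export
residuals.hill_family_fit <- function(object, ...)
  stats::residuals(object$nls)

#' @export
fitted.hill_family_fit <- function(object, ...)
  stats::fitted(object$nls)

#' @export
vcov.hill_family_fit <- function(object, ...)
  object$vcov %||% stats::vcov(object$nls)

#' Predict from a fitted titration or peak model
#'
#' @param object a fitted model from [fit_hill_force()],
#'   [fit_single_hill()], [fit_double_hill()] or [fit_gaussian_peak()].
#' @param newdata optional numeric vector of pX (or s) values, or a data
#'   frame with a `pX` (or `s`) column; defaults to the fitted abscissae.
#' @param ... unused.
#' @return Predicted responses.
#' @export
predict.hill_family_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) {
    if (!is.null(object$data$pX)) object$data$pX else object$data$s
  } else if (is.data.frame(newdata)) {
    newdata$pX %||% newdata$s
  } else as.numeric(newdata)
  fit_curve_fun(object)(x)
}

#' @export
print.hill_family_fit <- function(x, ...) {
  label <- switch(class(x)[1],
                  hill_force_fit = "Force-pCa Hill fit (plateau fixed at 100%)",
                  single_hill_fit = "Single Hill fit",
                  double_hill_fit = "Double (biphasic) Hill fit",
                  gaussian_peak_fit = "Gaussian sedimentation-peak fit")
  cat(label, "\n")
  tab <- data.frame(estimate = x$coefficients, se = x$se)
  print(round(tab, 6))
  cat(sprintf("  residual SS %.4g; %s\n", x$residual_ss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (isTRUE(x$weakly_identified))
    cat("  flag: midpoints collapse, components weakly identified\n")
  invisible(x)
}

#' @export
summary.hill_family_fit <- function(object, ...) {
  out <- list(fit = object, nls_summary = summary(object$nls))
  if (class(object)[1] %in% c("hill_force_fit", "single_hill_fit"))
    out$ka <- ka_from_p50(object$coefficients[["p50"]], signif_digits = 2)
  if (class(object)[1] == "double_hill_fit")
    out$ka <- c(component1 = ka_from_p50(object$coefficients[["p50_1"]],
                                         signif_digits = 2),
                component2 = ka_from_p50(object$coefficients[["p50_2"]],
                                         signif_digits = 2))
  class(out) <- "summary.hill_family_fit"
  out
}

#' @export
print.summary.hill_family_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$ka)) {
    cat("  association constant(s) K_a = 10^p50 (2 s.f.):\n")
    print(x$ka)
  }
  invisible(x)
}

#' @export
plot.hill_family_fit <- function(x, ...) {
  d <- x$data
  xs <- d$pX %||% d$s
  ys <- d$y %||% d$response
  graphics::plot(xs, ys,
                 xlab = if (!is.null(d$pX)) "pX" else "s (Svedberg)",
                 ylab = "response", ...)
  grid_x <- seq(min(xs), max(xs), length.out = 300)
  graphics::lines(grid_x, fit_curve_fun(x)(grid_x), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate replicate responses from a fitted Hill-type model
#'
#' Draws `nsim` sets of responses at the fitted abscissae: fitted curve plus
#' i.i.d. Gaussian noise with SD equal to the fit's residual standard error.
#'
#' @param object a fitted `hill_family_fit`.
#' @param nsim number of simulated response sets.
#' @param seed optional seed (local to the call).
#' @param ... unused.
#' @return A data frame with one column per simulation.
#' @export
simulate.hill_family_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sigma <- sqrt(object$residual_ss / max(1, length(mu) -
                                           length(object$coefficients)))
  with_seed(seed, as.data.frame(
    matrix(rep(mu, nsim) + stats::rnorm(length(mu) * nsim, sd = sigma),
           ncol = nsim, dimnames = list(NULL, paste0("sim_", seq_len(nsim))))))
}
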