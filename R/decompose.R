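# Per-EF-hand contribution decomposition. Under the independence assumption
# a construct's end-point signal is the sum of its active sites'
# contributions plus a construct-independent baseline (the signal of the
# triple mutant with no functional EF hand). Stacking the mutant panel gives
# a linear system: rows are constructs, columns are active-site indicators
# plus a baseline column of ones; it is solved by (weighted) least squares
# and is an exact solve when the panel is square.

build_design <- function(active_sites_list, ion) {
  sites <- site_names_for_ion(ion)
  ind <- t(vapply(active_sites_list,
                  function(a) as.numeric(sites %in% a),
                  numeric(length(sites))))
  X <- cbind(1, ind)
  colnames(X) <- c("baseline", sites)
  X
}

#' Decompose construct signals into per-EF-hand contributions
#'
#' Weighted least-squares solve of the additive site model over a mutant
#' panel. Weights are `1/se^2` when standard errors are provided, otherwise
#' the solve is unweighted. The baseline is a fitted column and is reported
#' separately; site contributions are therefore baseline-subtracted, matching
#' the convention of subtracting the triple-mutant signal.
#'
#' @param signals a data frame with columns `construct_id`, `active_sites`
#'   (list column of character vectors, or `"+"`-separated strings),
#'   `delta_fr`, and optionally `se`; all rows must share one ion.
#' @param ion `"Ca"` or `"Mg"`. Mg panels carry no site-II column (site II
#'   binds Mg2+ at most very weakly, so a Mg panel cannot inform it).
#' @return A [site_contributions] object with standard errors (from the
#'   weighted normal equations) and the residual norm of the solve.
#' @examples
#' panel <- ctv_constructs()
#' truth <- ctv_site_contributions("Ca")
#' sig <- data.frame(construct_id = panel$construct_id,
#'                   active_sites = I(panel$active_sites))
#' sig$delta_fr <- sapply(panel$active_sites, function(a)
#'   truth$baseline + sum(truth$contributions[intersect(a, names(truth$contributions))]))
#' decompose_sites(sig, "Ca")
#' @export
decompose_sites <- function(signals, ion = c("Ca", "Mg")) {
  ion <- match.arg(ion)
  stopifnot(is.data.frame(signals),
            all(c("construct_id", "active_sites", "delta_fr") %in%
                  names(signals)))
  if (anyDuplicated(signals$construct_id))
    stop("constructs must be distinct")
  active <- lapply(signals$active_sites, function(a)
    if (is.character(a) && length(a) == 1 && grepl("\\+", a))
      strsplit(a, "\\+")[[1]] else as.character(a))
  X <- build_design(active, ion)
  if (nrow(X) < ncol(X))
    stop("need at least as many constructs (", nrow(X),
         ") as unknowns (", ncol(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop("design is rank-deficient; unidentifiable columns: ",
         paste(bad, collapse = ", "))
  }
  w <- if (!is.null(signals$se)) {
    if (any(signals$se <= 0)) stop("standard errors must be positive")
    1 / signals$se^2
  } else rep(1, nrow(X))
  fit <- stats::lm.wfit(X, signals$delta_fr, w)
  beta <- fit$coefficients
  # SEs by linear error propagation from the input SEs (when given):
  # cov(beta) = (X'WX)^{-1} with W = diag(1/se^2); unweighted panels get NA.
  se <- if (!is.null(signals$se)) {
    XtWX <- crossprod(X * sqrt(w))
    sqrt(diag(solve(XtWX)))
  } else rep(NA_real_, length(beta))
  names(se) <- names(beta)
  site_contributions(
    ion,
    contributions = beta[setdiff(names(beta), "baseline")],
    baseline = unname(beta["baseline"]),
    se = se,
    residual_norm = sqrt(sum(fit$residuals^2)))
}

#' Predict a construct's signal from per-site contributions
#'
#' Forward model: the sum of the contributions of the construct's active
#' sites (restricted to the sites the ion binds), plus the baseline when a
#' raw -- non-baseline-subtracted -- signal is requested.
#'
#' @param object a [site_contributions] object.
#' @param construct a row of [ctv_constructs()], a list with
#'   `active_sites`, or a character vector of active sites.
#' @param baseline_subtracted if `TRUE` (default) return the pure sum of
#'   site contributions; if `FALSE` add the baseline.
#' @param ... unused.
#' @return Predicted \eqn{\Delta F_R} (dimensionless).
#' @examples
#' predict(ctv_site_contributions("Ca"), c("II", "III", "IV"))  # 0.204
#' predict(ctv_site_contributions("Mg"), c("II", "III", "IV"))  # 0.193
#' @export
predict.site_contributions <- function(object, construct,
                                       baseline_subtracted = TRUE, ...) {
  active <- if (is.character(construct)) construct
            else if (is.data.frame(construct)) construct$active_sites[[1]]
            else construct$active_sites
  sites <- intersect(active, names(object$contributions))
  out <- sum(object$contributions[sites])
  if (!baseline_subtracted) out <- out + object$baseline
  out
}

#' Compare a predicted signal with the wild-type observation
#'
#' Additivity check: absolute and relative discrepancy between the summed
#' per-site prediction and the directly measured wild-type signal, flagged
#' as an additivity violation when the discrepancy exceeds 3 combined
#' standard errors.
#'
#' @param predicted,observed_wt \eqn{\Delta F_R} values for the same ion.
#' @param se_predicted,se_observed optional standard errors.
#' @return A list: `discrepancy`, `relative`, `combined_se`,
#'   `additivity_violated` (NA when no SEs are available).
#' @examples
#' compare_to_wt(0.204, 0.217)  # discrepancy 0.013
#' @export
compare_to_wt <- function(predicted, observed_wt,
                          se_predicted = NA, se_observed = NA) {
  d <- observed_wt - predicted
  comb <- sqrt(se_predicted^2 + se_observed^2)
  list(discrepancy = abs(d), signed_discrepancy = d,
       relative = abs(d) / abs(observed_wt),
       combined_se = comb,
       additivity_violated = if (is.na(comb)) NA else abs(d) > 3 * comb)
}
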