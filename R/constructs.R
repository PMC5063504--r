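# EF-hand construct panel and shipped per-site contribution defaults.
# cTnC has three functional divalent-cation sites: regulatory site II in the
# N-domain (Ca2+-specific, low affinity) and structural sites III/IV in the
# C-domain (Ca2+ or Mg2+, high affinity). Mutants inactivate sites by an
# Asp -> Ala substitution of the first coordinating residue.

#' Construct designs of the CTV-TnC sensor panel
#'
#' The wild-type sensor and its EF-hand inactivation mutants, each defined by
#' the set of still-active binding sites. D104A inactivates site III, D140A
#' site IV, D104-140A both C-domain sites, 3XEF all three.
#'
#' @return A data frame with columns `construct_id` and `active_sites` (a
#'   list column of character vectors drawn from `c("II", "III", "IV")`).
#' @examples
#' ctv_constructs()
#' @export
ctv_constructs <- function() {
  data.frame(
    construct_id = c("CTV-TnC WT", "D104A", "D140A", "D104-140A", "3XEF"),
    active_sites = I(list(c("II", "III", "IV"), c("II", "IV"),
                          c("II", "III"), "II", character(0)))
  )
}

site_names_for_ion <- function(ion) {
  switch(ion,
         Ca = c("II", "III", "IV"),
         Mg = c("III", "IV"),   # site II binds Mg2+ at most very weakly
         stop("ion must be 'Ca' or 'Mg'"))
}

#' Per-EF-hand FRET-ratio contributions
#'
#' Constructor for a set of per-site contributions to the sensor's FRET
#' ratio, plus the baseline (the signal of the triple mutant with no active
#' EF hands). Contributions are baseline-subtracted: the predicted raw signal
#' of a construct is `baseline + sum(contributions[active sites])`.
#'
#' @param ion `"Ca"` or `"Mg"`. Mg contributions are defined for sites III
#'   and IV only.
#' @param contributions named numeric vector of per-site \eqn{F_R}
#'   contributions (dimensionless), names among the sites valid for `ion`.
#' @param baseline dimensionless baseline \eqn{F_R} signal.
#' @param se optional named standard errors (same names), plus optionally
#'   `baseline`.
#' @param residual_norm residual norm of the solve that produced the values
#'   (0 for exactly determined systems).
#' @return An object of class `site_contributions`.
#' @seealso [decompose_sites()], [predict.site_contributions()],
#'   [ctv_site_contributions()]
#' @export
site_contributions <- function(ion, contributions, baseline = 0,
                               se = NULL, residual_norm = NA_real_) {
  valid <- site_names_for_ion(ion)
  if (is.null(names(contributions)) || !all(names(contributions) %in% valid))
    stop("contributions must be named with sites among: ",
         paste(valid, collapse = ", "))
  structure(list(ion = ion,
                 contributions = contributions[order(match(names(contributions), valid))],
                 baseline = baseline, se = se,
                 residual_norm = residual_norm),
            class = "site_contributions")
}

#' Shipped default per-site contributions for the CTV-TnC sensor
#'
#' Reference values from the published characterisation of the CTV-TnC
#' sensor's EF-hand mutant panel: per-site, baseline-subtracted \eqn{F_R}
#' contributions together with the triple-mutant baseline. They are defaults
#' for simulation and worked examples, and are user-overridable everywhere
#' they are consumed.
#'
#' @param ion `"Ca"` or `"Mg"`.
#' @return A [site_contributions] object.
#' @examples
#' ctv_site_contributions("Ca")
#' @export
ctv_site_contributions <- function(ion = c("Ca", "Mg")) {
  ion <- match.arg(ion)
  if (ion == "Ca")
    site_contributions("Ca", c(II = -0.120, III = 0.224, IV = 0.100),
                       baseline = 0.010, residual_norm = 0)
  else
    site_contributions("Mg", c(III = 0.079, IV = 0.114),
                       baseline = 0.094, residual_norm = 0)
}

#' @export
print.site_contributions <- function(x, ...) {
  cat(sprintf("Per-EF-hand F_R contributions (%s2+), baseline-subtracted\n",
              x$ion))
  tab <- data.frame(site = names(x$contributions),
                    contribution = unname(x$contributions))
  if (!is.null(x$se))
    tab$se <- unname(x$se[names(x$contributions)])
  print(tab, row.names = FALSE)
  cat(sprintf("  baseline ('None'): %.4g\n", x$baseline))
  cat(sprintf("  sum of sites:      %.4g\n", sum(x$contributions)))
  if (is.finite(x$residual_norm))
    cat(sprintf("  solve residual norm: %.3g\n", x$residual_norm))
  invisible(x)
}
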