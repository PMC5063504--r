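# End-point analysis: per-condition mean FRET ratio across excitation
# wavelengths and the Ca2+-induced change
#   delta F_R = mean over excitations of
#               [F_R(saturated) - (F_R(chelated) + F_R(rechelated)) / 2],
# with a reversibility diagnostic comparing the first and last (both
# cation-free) conditions.

#' Analyze a 3-condition end-point dataset
#'
#' For every condition and excitation wavelength the sample scan is unmixed,
#' corrected for direct excitation using the acceptor-only controls and the
#' condition's 515 nm sample scan, and converted to \eqn{F_R}. Per-condition
#' means and standard errors are taken across excitation wavelengths
#' (SE = sample SD / sqrt(number of excitations)). Excitations lacking a
#' control are dropped with a warning; a missing condition is an error.
#'
#' @param dataset an `endpoint_dataset` from
#'   [simulate_endpoint_experiment()], or any list with the same fields
#'   (`spectra` named `<condition>_<excitation>`, `sample_at_direct_max`,
#'   `controls` incl. one at the direct maximum, `excitation_list`).
#' @param refs reference shapes; defaults to the dataset's own.
#' @return An object of class `endpoint_result`: `per_condition` (mean, se,
#'   n per condition), `per_scan` (one row per scan), `delta_fr`,
#'   `delta_fr_se`, and the reversibility diagnostic (`reversibility_gap`,
#'   `reversible` flag: gap within 3 combined SE).
#' @export
analyze_endpoint <- function(dataset, refs = dataset$refs) {
  conds <- c("chelated", "saturated", "rechelated")
  direct_nm <- as.character(refs$direct_peak_nm)
  if (!direct_nm %in% names(dataset$controls))
    stop("no acceptor-only control at the direct-excitation maximum (",
         direct_nm, " nm)")
  ctrl_max <- dataset$controls[[direct_nm]]

  ex_list <- dataset$excitation_list
  have_ctrl <- as.character(ex_list) %in% names(dataset$controls)
  if (!all(have_ctrl)) {
    warning("no acceptor-only control for excitation ",
            paste(ex_list[!have_ctrl], collapse = ", "),
            " nm; excluding from the analysis")
    ex_list <- ex_list[have_ctrl]
  }
  if (length(ex_list) < 1) stop("no usable excitation wavelengths")

  rows <- list()
  for (cond in conds) {
    if (is.null(dataset$sample_at_direct_max[[cond]]))
      stop("condition '", cond, "' missing from the dataset")
    for (ex in ex_list) {
      key <- paste(cond, ex, sep = "_")
      if (is.null(dataset$spectra[[key]]))
        stop("condition '", cond, "' missing scan at ", ex, " nm")
      res <- unmix_scan(dataset$spectra[[key]],
                        dataset$controls[[as.character(ex)]], ctrl_max,
                        dataset$sample_at_direct_max[[cond]], refs)
      rows[[key]] <- data.frame(condition = cond, excitation_nm = ex,
                                f_don = res$f_don, f_acc = res$f_acc,
                                f_acc_direct = res$f_acc_direct,
                                f_acc_fret = res$f_acc_fret, f_r = res$f_r,
                                negative_flag = res$negative_flag)
    }
  }
  per_scan <- do.call(rbind, rows)
  rownames(per_scan) <- NULL

  agg <- do.call(rbind, lapply(conds, function(cond) {
    v <- per_scan$f_r[per_scan$condition == cond]
    data.frame(condition = cond, mean_f_r = mean(v),
               se_f_r = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))

  fr <- function(cond) per_scan$f_r[per_scan$condition == cond]
  d_per_ex <- fr("saturated") - 0.5 * (fr("chelated") + fr("rechelated"))
  delta_fr <- mean(d_per_ex)
  delta_fr_se <- stats::sd(d_per_ex) / sqrt(length(d_per_ex))

  gap <- abs(agg$mean_f_r[agg$condition == "chelated"] -
               agg$mean_f_r[agg$condition == "rechelated"])
  gap_se <- sqrt(agg$se_f_r[agg$condition == "chelated"]^2 +
                   agg$se_f_r[agg$condition == "rechelated"]^2)

  structure(list(per_condition = agg, per_scan = per_scan,
                 delta_fr = delta_fr, delta_fr_se = delta_fr_se,
                 reversibility_gap = gap, reversibility_gap_se = gap_se,
                 reversible = is.na(gap_se) || gap_se == 0 ||
                   gap <= 3 * gap_se,
                 construct_id = dataset$construct_id,
                 ion_protocol = dataset$ion_protocol),
            class = "endpoint_result")
}

#' @export
print.endpoint_result <- function(x, ...) {
  cat(sprintf("End-point analysis: %s, protocol %s\n",
              x$construct_id, x$ion_protocol))
  print(x$per_condition, row.names = FALSE)
  cat(sprintf("  delta F_R = %.4g (SE %.2g)\n", x$delta_fr, x$delta_fr_se))
  cat(sprintf("  reversibility gap |F_R(1) - F_R(3)| = %.3g (%s)\n",
              x$reversibility_gap,
              if (isTRUE(x$reversible)) "reversible"
              else "NOT reversible: flagged"))
  invisible(x)
}

#' @export
plot.endpoint_result <- function(x, ...) {
  d <- x$per_scan
  cond <- factor(d$condition, levels = c("chelated", "saturated",
                                         "rechelated"))
  graphics::plot(d$excitation_nm, d$f_r, col = as.integer(cond), pch = 19,
                 xlab = "excitation (nm)", ylab = expression(F[R]),
                 main = x$construct_id, ...)
  graphics::legend("topleft", levels(cond), col = 1:3, pch = 19, bty = "n")
  invisible(x)
}
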