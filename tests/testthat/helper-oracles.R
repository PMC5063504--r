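# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, naive iteration, and brute-force
# search.

default_refs <- function() make_reference_spectra()

# Closed-form two-variable least squares by Cramer's rule on the normal
# equations (independent of lm.fit/qr).
normal_equations_oracle <- function(y, d, a) {
  s_dd <- sum(d * d); s_aa <- sum(a * a); s_da <- sum(d * a)
  s_dy <- sum(d * y); s_ay <- sum(a * y)
  det <- s_dd * s_aa - s_da^2
  c(f_don = (s_dy * s_aa - s_ay * s_da) / det,
    f_acc = (s_dd * s_ay - s_da * s_dy) / det)
}

# Two-stage brute-force grid search over (f_don, f_acc), final resolution
# 1e-4, centred on a coarse scan of the plausible amplitude range.
grid_search_oracle <- function(y, d, a, lo = 0, hi = 3) {
  ss <- function(fd, fa) sum((y - fd * d - fa * a)^2)
  best <- c(NA, NA); best_ss <- Inf
  g <- seq(lo, hi, length.out = 61)
  for (fd in g) for (fa in g)
    if (ss(fd, fa) < best_ss) { best_ss <- ss(fd, fa); best <- c(fd, fa) }
  step <- g[2] - g[1]
  g1 <- seq(best[1] - step, best[1] + step, by = 1e-4)
  g2 <- seq(best[2] - step, best[2] + step, by = 1e-4)
  for (fd in g1) for (fa in g2)
    if (ss(fd, fa) < best_ss) { best_ss <- ss(fd, fa); best <- c(fd, fa) }
  stats::setNames(best, c("f_don", "f_acc"))
}

# Free metal in a single-metal/single-ligand 1:1 system: positive root of
# K x^2 + (1 + K (L - M)) x - M = 0, in the cancellation-free form for
# either sign of the linear coefficient.
quadratic_free_metal <- function(M, L, K) {
  b <- 1 + K * (L - M)
  disc <- sqrt(b^2 + 4 * K * M)
  if (b >= 0) 2 * M / (b + disc) else (-b + disc) / (2 * K)
}

# Naive dense fixed-point iteration on free ligands with arithmetic damping;
# no Newton step, many iterations.
naive_speciation_oracle <- function(metals, ligands, K, iters = 5000) {
  x <- ligands
  for (i in seq_len(iters)) {
    m <- metals / (1 + as.numeric(K %*% x))
    x_new <- ligands / (1 + as.numeric(crossprod(K, m)))
    x <- 0.5 * x + 0.5 * x_new
  }
  m <- metals / (1 + as.numeric(K %*% x))
  list(free = m, free_ligand = x)
}

# Table of published reference values used as generator ground truth.
ca_contrib_truth <- c(II = -0.120, III = 0.224, IV = 0.100)
ca_baseline_truth <- 0.010
mg_contrib_truth <- c(III = 0.079, IV = 0.114)
mg_baseline_truth <- 0.094
double_hill_truth <- list(f_min = 0.040, f_max1 = 0.133, n1 = 2.70,
                          p50_1 = 7.17, f_max2 = -0.082, n2 = 0.94,
                          p50_2 = 5.47)
mg_hill_truth <- list(f_min = 0.043, f_max = 0.215, n = 1.09, p50 = 3.28)

raw_signal <- function(active, contrib, baseline)
  baseline + sum(contrib[intersect(active, names(contrib))])

panel_signals <- function(contrib, baseline, ion,
                          constructs = ctv_constructs()) {
  if (ion == "Mg")
    constructs <- constructs[constructs$construct_id != "D104-140A", ]
  data.frame(construct_id = constructs$construct_id,
             active_sites = I(constructs$active_sites),
             delta_fr = vapply(constructs$active_sites, raw_signal,
                               numeric(1), contrib, baseline))
}
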