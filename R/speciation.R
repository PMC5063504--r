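# Metal--chelator speciation under simultaneous 1:1 equilibria with apparent
# (pH-conditional) association constants:
#   complex(M, L) = K'(M, L) * free(M) * free_ligand(L)
#   total(M) = free(M) + sum_L complex(M, L)
#   total(L) = free_ligand(L) + sum_M complex(M, L)
# Solved by a damped fixed point on the free-ligand concentrations followed
# by a Newton polish in log space. No proton or ionic-strength chemistry is
# computed: constants are taken as valid at the recorded pH.

#' Representative apparent binding constants at pH 7.0
#'
#' Apparent 1:1 association constants K' (L/mol) for Ca2+ and Mg2+ with
#' EGTA, EDTA, NTA and ATP at pH 7.0, 22 degC. These are representative
#' textbook-scale values intended as overridable defaults -- apparent
#' constants depend on pH, ionic strength and temperature, and any serious
#' use should supply constants matched to the actual recipe.
#'
#' @return A metals x ligands matrix with attribute
#'   `provenance = "shipped-default"`.
#' @export
default_binding_constants <- function() {
  k <- rbind(
    Ca = c(EGTA = 2.0e6, EDTA = 2.0e7, NTA = 5.0e3, ATP = 4.0e3),
    Mg = c(EGTA = 4.0e1, EDTA = 1.6e5, NTA = 5.0e2, ATP = 1.0e4))
  attr(k, "provenance") <- "shipped-default"
  k
}

#' Define a multi-chelator buffer system
#'
#' @param metals named numeric vector of total metal concentrations (mol/L),
#'   names among `"Ca"`, `"Mg"`.
#' @param ligands named numeric vector of total ligand concentrations
#'   (mol/L).
#' @param constants metals x ligands matrix of apparent 1:1 association
#'   constants K' (L/mol) valid at `pH`; missing pairs are treated as
#'   K' = 0 (no binding). Must carry a `provenance` attribute; matrices
#'   supplied without one are labelled `"user-supplied"`.
#' @param pH,temperature recorded scalars (no proton chemistry is computed).
#' @return An object of class `buffer_system`.
#' @examples
#' sys <- buffer_system(c(Mg = 4.4e-3), c(EGTA = 2e-3, NTA = 5e-3))
#' solve_free(sys)
#' @export
buffer_system <- function(metals, ligands,
                          constants = default_binding_constants(),
                          pH = 7.0, temperature = 22) {
  stopifnot(is.numeric(metals), is.numeric(ligands),
            !is.null(names(metals)) || length(metals) == 0,
            !is.null(names(ligands)) || length(ligands) == 0,
            all(metals >= 0), all(ligands >= 0))
  if (!all(names(metals) %in% c("Ca", "Mg")))
    stop("metals must be named 'Ca' and/or 'Mg'")
  K <- matrix(0, length(metals), length(ligands),
              dimnames = list(names(metals), names(ligands)))
  for (m in names(metals)) for (l in names(ligands))
    if (m %in% rownames(constants) && l %in% colnames(constants))
      K[m, l] <- constants[m, l]
  if (any(K < 0)) stop("association constants must be >= 0")
  prov <- attr(constants, "provenance")
  if (is.null(prov)) prov <- "user-supplied"
  structure(list(metals = metals, ligands = ligands, K = K,
                 pH = pH, temperature = temperature, provenance = prov),
            class = "buffer_system")
}

speciation_residual <- function(x, system) {
  # x: free-ligand concentrations; returns ligand mass-balance residuals
  # and implied free metals.
  K <- system$K
  m_free <- system$metals / (1 + as.numeric(K %*% x))
  g <- x * (1 + as.numeric(crossprod(K, m_free))) - system$ligands
  list(g = g, m_free = m_free)
}

#' Solve a buffer system for free and bound concentrations
#'
#' @param system a [buffer_system()].
#' @param tol relative mass-balance tolerance the Newton polish aims for
#'   (default 1e-14; every converged result satisfies the 1e-10 contract
#'   with margin).
#' @param max_iter iteration cap for each phase of the solver.
#' @return An object of class `speciation_result`: `free` (per metal),
#'   `free_ligand`, `complexes` (metals x ligands matrix),
#'   `max_mass_balance_residual` (relative), `converged`, `pX` (per-metal
#'   \eqn{-\log_{10}} free).
#' @export
solve_free <- function(system, tol = 1e-14, max_iter = 200) {
  stopifnot(inherits(system, "buffer_system"))
  M <- system$metals; L <- system$ligands; K <- system$K
  if (length(L) == 0 || all(K == 0) || length(M) == 0) {
    cx <- matrix(0, length(M), length(L),
                 dimnames = dimnames(K))
    return(new_speciation_result(M, L, cx, system, converged = TRUE,
                                 iterations = 0L))
  }
  scale_ref <- pmax(L, max(c(M, 1e-30)))

  # Phase 1: damped (geometric-mean) fixed point on the free ligands.
  x <- pmax(L, 1e-30)
  for (it in seq_len(max_iter)) {
    m_free <- M / (1 + as.numeric(K %*% x))
    x_new <- L / (1 + as.numeric(crossprod(K, m_free)))
    x_new <- pmax(x_new, 1e-300)
    x_damped <- sqrt(x * x_new)
    if (max(abs(x_damped - x) / pmax(x, 1e-300)) < 1e-6) { x <- x_damped; break }
    x <- x_damped
  }

  # Phase 2: Newton in log(free ligand) with step halving.
  u <- log(pmax(x, 1e-300))
  res <- speciation_residual(exp(u), system)
  fn <- max(abs(res$g) / scale_ref)
  for (it in seq_len(max_iter)) {
    if (fn < tol) break
    x <- exp(u)
    m_free <- res$m_free
    denom_m <- 1 + as.numeric(K %*% x)
    # d g_j / d x_l
    J <- diag(1 + as.numeric(crossprod(K, m_free)), length(x)) -
      crossprod(K * (m_free / denom_m), K) * tcrossprod(x, rep(1, length(x)))
    # correct: d g_j/d x_l = delta_jl (1 + sum_i K_ij m_i) -
    #          x_j sum_i K_ij K_il m_i / denom_i
    Ju <- J * matrix(x, nrow = length(x), ncol = length(x), byrow = TRUE)
    step <- tryCatch(solve(Ju, res$g), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      u_try <- u - lam * step
      res_try <- speciation_residual(exp(u_try), system)
      fn_try <- max(abs(res_try$g) / scale_ref)
      if (fn_try < fn || lam < 1e-4) break
      lam <- lam / 2
    }
    if (fn_try >= fn) break  # stalled at numerical precision
    u <- u_try; res <- res_try; fn <- fn_try
  }

  x <- exp(u)
  m_free <- res$m_free
  cx <- K * outer(m_free, x)
  dimnames(cx) <- dimnames(K)
  out <- new_speciation_result(m_free, x, cx, system,
                               converged = fn < 1e-10, iterations = it)
  if (!out$converged)
    stop("speciation solver did not converge: relative residual ",
         format(out$max_mass_balance_residual))
  out
}

new_speciation_result <- function(m_free, l_free, complexes, system,
                                  converged, iterations) {
  names(m_free) <- names(system$metals)
  names(l_free) <- names(system$ligands)
  res_m <- if (length(m_free))
    abs(m_free + rowSums(complexes) - system$metals) /
      pmax(system$metals, 1e-30) else numeric(0)
  res_l <- if (length(l_free))
    abs(l_free + colSums(complexes) - system$ligands) /
      pmax(system$ligands, 1e-30) else numeric(0)
  structure(list(free = m_free, free_ligand = l_free, complexes = complexes,
                 max_mass_balance_residual = max(c(res_m, res_l, 0)),
                 converged = converged, iterations = iterations,
                 pX = -log10(pmax(m_free, 1e-300)),
                 system = system),
            class = "speciation_result")
}

#' @export
print.speciation_result <- function(x, ...) {
  cat("Buffer speciation (apparent 1:1 constants, pH",
      x$system$pH, ")\n")
  for (m in names(x$free))
    cat(sprintf("  free %s: %.6g M (p%s = %.4g)\n", m, x$free[m], m,
                x$pX[m]))
  for (l in names(x$free_ligand))
    cat(sprintf("  free %s: %.6g M\n", l, x$free_ligand[l]))
  cat(sprintf("  max relative mass-balance residual: %.2g\n",
              x$max_mass_balance_residual))
  invisible(x)
}

#' Total metal needed to reach a target free concentration
#'
#' Inverts the forward speciation map, which is strictly increasing in the
#' metal's total, by bisection refined with monotone safeguarded steps
#' ([stats::uniroot]). The round trip `solve_free` at the returned total
#' reproduces `target_free` to 1e-9 relative.
#'
#' @param system a [buffer_system()]; the target metal's total is ignored,
#'   other totals are held fixed.
#' @param metal metal name.
#' @param target_free desired free concentration (mol/L, > 0).
#' @return Required total concentration (mol/L).
#' @examples
#' sys <- buffer_system(c(Mg = 0), c(EGTA = 2e-3, NTA = 5e-3))
#' total_for_free(sys, "Mg", 2e-3)  # ~4.6 mM
#' @export
total_for_free <- function(system, metal, target_free) {
  stopifnot(inherits(system, "buffer_system"), target_free > 0,
            metal %in% names(system$metals))
  f <- function(total) {
    sys2 <- system
    sys2$metals[metal] <- total
    solve_free(sys2)$free[[metal]] - target_free
  }
  upper <- target_free + sum(system$ligands) + 1e-12
  root <- stats::uniroot(f, c(target_free, upper),
                         tol = target_free * 1e-12, maxiter = 200)
  root$root
}

#' Negative decadic log of a free concentration
#'
#' `pX(free) = -log10(free)`: pCa 8--4 corresponds to 1e-8--1e-4 M free
#' Ca2+.
#'
#' @param free free concentration (mol/L, > 0).
#' @return Dimensionless pX value.
#' @export
pX <- function(free) {
  if (any(!is.finite(free) | free <= 0))
    stop("free concentration must be positive")
  -log10(free)
}
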