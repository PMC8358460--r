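# Single-site binding equilibria shared by the NMR titration and ITC
# modules, plus the thermodynamic identities used to decompose a fit.

#' Binding parameters for one site and up to two ligands
#'
#' @param kd_a Dissociation constant of ligand A (molar).
#' @param dh_a Binding enthalpy of A (kcal/mol).
#' @param kd_b,dh_b Optional competitor constants.
#' @param n Stoichiometry (sites per receptor); enters all solvers as the
#'   effective site concentration `n * P_tot`.
#' @return Object of class `binding_parameters`.
#' @export
binding_parameters <- function(kd_a, dh_a = NA_real_, kd_b = NULL,
                               dh_b = NULL, n = 1) {
  stopifnot(kd_a > 0, n > 0, is.null(kd_b) || kd_b > 0)
  structure(list(kd_a = kd_a, dh_a = dh_a, kd_b = kd_b, dh_b = dh_b, n = n),
            class = "binding_parameters")
}

#' Fraction of ligand bound in a 1:1 equilibrium
#'
#' Exact solution of the single-site mass balance
#' `P + L <-> PL`, `Kd = [P][L]/[PL]`: the physical root of the quadratic in
#' \[PL\], evaluated in the cancellation-safe form
#' `[PL] = 2 P L / (b + sqrt(b^2 - 4 P L))` with `b = P + L + Kd`.
#' Vectorised over `p_tot` (and `l_tot`).
#'
#' @param p_tot Total receptor-site concentration (molar); multiply by N
#'   upstream if stoichiometry differs from 1.
#' @param l_tot Total ligand concentration (molar).
#' @param kd Dissociation constant (molar).
#' @return Fraction of ligand bound, `[PL]/l_tot`, in \[0, 1\]; 0 where
#'   `l_tot` is 0.
#' @export
bound_fraction_1to1 <- function(p_tot, l_tot, kd) {
  if (any(p_tot < 0) || any(l_tot < 0)) stop("concentrations must be >= 0")
  if (any(kd <= 0)) stop("kd must be > 0")
  b <- p_tot + l_tot + kd
  pl <- 2 * p_tot * l_tot / (b + sqrt(b^2 - 4 * p_tot * l_tot))
  l <- rep_len(l_tot, length(pl))
  ifelse(l > 0, pl / l, 0)
}

#' Exact one-site, two-ligand competitive equilibrium
#'
#' Solves `P + A <-> PA` and `P + B <-> PB` sharing one site, by monotone
#' bracketing (then Newton polish) on the free-receptor concentration; the
#' mass-balance function is strictly increasing in \[P\]free, so the bracket
#' `(0, n*p_tot]` always contains exactly one root. Converges to a relative
#' mass-balance residual below 1e-9 (typically ~1e-15).
#'
#' @param p_tot,a_tot,b_tot Total receptor, ligand and competitor (molar).
#' @param kd_a,kd_b Dissociation constants (molar).
#' @param n Stoichiometry (sites per receptor).
#' @return Object of class `species_state`: list with `p_free`, `pa`, `pb`,
#'   the totals, and `residual` (relative mass-balance residual).
#' @export
competitive_equilibrium <- function(p_tot, a_tot, b_tot, kd_a, kd_b, n = 1) {
  stopifnot(p_tot >= 0, a_tot >= 0, b_tot >= 0, kd_a > 0, kd_b > 0, n > 0)
  p_eff <- n * p_tot
  out <- list(p_tot = p_tot, a_tot = a_tot, b_tot = b_tot, n = n)
  if (p_eff == 0) {
    out <- c(out, list(p_free = 0, pa = 0, pb = 0, residual = 0))
    return(structure(out, class = "species_state"))
  }
  f <- function(pf) {
    pf * (1 + a_tot / (kd_a + pf) + b_tot / (kd_b + pf)) - p_eff
  }
  pf <- stats::uniroot(f, lower = 0, upper = p_eff,
                       tol = .Machine$double.eps^0.75)$root
  # Newton polish to machine precision
  for (it in 1:5) {
    fp <- 1 + a_tot * kd_a / (kd_a + pf)^2 + b_tot * kd_b / (kd_b + pf)^2
    step <- f(pf) / fp
    pf_new <- min(max(pf - step, 0), p_eff)
    if (abs(pf_new - pf) <= 1e-16 * p_eff) { pf <- pf_new; break }
    pf <- pf_new
  }
  pa <- a_tot * pf / (kd_a + pf)
  pb <- b_tot * pf / (kd_b + pf)
  residual <- abs(pf + pa + pb - p_eff) / p_eff
  if (residual > 1e-9)
    stop(sprintf("competitive equilibrium failed to converge: relative residual %.3e",
                 residual))
  structure(c(out, list(p_free = pf, pa = pa, pb = pb, residual = residual)),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf(
    "<species_state> [P]free = %.4g, [PA] = %.4g, [PB] = %.4g (molar)\n",
    x$p_free, x$pa, x$pb))
  invisible(x)
}

#' Gibbs free energy from a dissociation constant
#'
#' `dG = R T ln(Kd)` with `R = 1.987204e-3` kcal/(mol K) and the implicit
#' 1 M standard state; negative for sub-molar Kd.
#'
#' @param kd Dissociation constant (molar).
#' @param temperature Kelvin (default 305.15 K, i.e. 32 C).
#' @return dG in kcal/mol.
#' @export
delta_g_from_kd <- function(kd, temperature = 305.15) {
  stopifnot(all(kd > 0), temperature > 0)
  1.987204e-3 * temperature * log(kd)
}

#' Entropic term of a binding free energy
#'
#' `-T dS = dG - dH`, exactly, so that `dG = dH + (-T dS)` holds by
#' construction wherever all three are reported.
#'
#' @param dg,dh Free energy and enthalpy (kcal/mol).
#' @return -T dS in kcal/mol.
#' @export
entropy_term <- function(dg, dh) {
  stopifnot(all(is.finite(dg)), all(is.finite(dh)))
  dg - dh
}
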