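# Independent oracles used across the suite. These re-derive quantities by
# routes deliberately different from the package implementation.

# 1:1 bound fraction by bisection on the mass-balance equation.
oracle_bound_fraction <- function(p_tot, l_tot, kd, tol = 1e-12) {
  if (l_tot == 0) return(0)
  f <- function(pl) (p_tot - pl) * (l_tot - pl) / kd - pl
  lo <- 0; hi <- min(p_tot, l_tot)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / l_tot
}

# Competitive one-site/two-ligand equilibrium via the cubic in free
# receptor solved by polyroot (entirely independent of the package's
# bracketing solver).
oracle_competitive <- function(p_tot, a_tot, b_tot, kd_a, kd_b) {
  # pf*(ka+pf)*(kb+pf) + a*pf*(kb+pf) + b*pf*(ka+pf) - p*(ka+pf)*(kb+pf) = 0
  # collect powers of pf:
  c3 <- 1
  c2 <- kd_a + kd_b + a_tot + b_tot - p_tot
  c1 <- kd_a * kd_b + a_tot * kd_b + b_tot * kd_a -
    p_tot * (kd_a + kd_b)
  c0 <- -p_tot * kd_a * kd_b
  roots <- polyroot(c(c0, c1, c2, c3))
  pf <- Re(roots[abs(Im(roots)) < 1e-8 * Mod(roots) &
                   Re(roots) > 0 & Re(roots) <= p_tot * (1 + 1e-9)])
  pf <- pf[1]
  list(p_free = pf, pa = a_tot * pf / (kd_a + pf),
       pb = b_tot * pf / (kd_b + pf))
}

# superposition RMSD via bio3d (independent implementation)
oracle_superpose_rmsd <- function(mobile, reference) {
  fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(reference)),
                                         mobile = as.vector(t(mobile))))
  sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - reference)^2)))
}

# small helper: bare peak list builder
mk_peaks <- function(residue, d_h, d_n, intensity = rep(1e5, length(residue)),
                     receptor = 0, competitor = 0) {
  peak_list(residue, d_h, d_n, intensity,
            receptor_conc = receptor, competitor_conc = competitor)
}

# toy 4-atom ensemble builder
mk_ens <- function(models, elety = NULL, resno = NULL, resid = NULL,
                   chain = "A") {
  n <- nrow(models[[1]])
  atoms <- data.frame(elety = elety %||% rep("CA", n),
                      resid = resid %||% rep("ALA", n),
                      resno = resno %||% seq_len(n),
                      chain = rep_len(chain, n))
  model_ensemble(atoms, models)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_rotation_matrix <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  r <- qr.Q(q) %*% diag(sign(diag(qr.R(q))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}
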