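# Simulation and fitting of single-site ITC thermograms, including
# competitive (displacement) experiments with a pre-bound cell competitor.
#
# Concentration bookkeeping uses the standard single-cell perfusion model:
# after a cumulative injected volume v into a cell of volume V0, cell-borne
# species are at C0 * (1 - v/2V0)/(1 + v/2V0) and the syringe species at
# Cs * (v/V0)/(1 + v/2V0). The observed heat of injection i is
#   h_i = Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1})/2,
# the last term compensating the heat content of the displaced volume, with
# Q = V0 * (dH_A [PA] + dH_B [PB]) the cumulative binding heat.

#' ITC injection schedule
#'
#' @param cell_volume Calorimeter cell volume in litres (default 200 uL,
#'   typical for a low-volume instrument).
#' @param cell_conc Total receptor concentration loaded in the cell (molar).
#' @param syringe_conc Titrant concentration in the syringe (molar).
#' @param pre_injection Volume of the initial small injection (litres); it
#'   updates concentrations but is excluded from the fitted data.
#' @param injection_volumes Vector of injection volumes (litres).
#' @param temperature Kelvin.
#' @param cell_competitor_conc Optional competitor concentration pre-loaded
#'   in the cell (molar; 0 for a direct titration).
#' @return Object of class `injection_schedule`.
#' @export
injection_schedule <- function(cell_volume = 200e-6,
                               cell_conc = 40e-6,
                               syringe_conc = 800e-6,
                               pre_injection = 0.4e-6,
                               injection_volumes = rep(3.22e-6, 12),
                               temperature = 305.15,
                               cell_competitor_conc = 0) {
  stopifnot(cell_volume > 0, cell_conc >= 0, syringe_conc >= 0,
            pre_injection >= 0, all(injection_volumes > 0),
            temperature > 0, cell_competitor_conc >= 0)
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc, pre_injection = pre_injection,
                 injection_volumes = injection_volumes,
                 temperature = temperature,
                 cell_competitor_conc = cell_competitor_conc),
            class = "injection_schedule")
}

# Deterministic heat model. Returns NDH (kcal per mol injectant) for the
# non-excluded injections, plus the per-state cumulative heats.
.itc_heats <- function(params, schedule) {
  v0 <- schedule$cell_volume
  dvs <- c(schedule$pre_injection, schedule$injection_volumes)
  excluded <- c(schedule$pre_injection > 0,
                rep(FALSE, length(schedule$injection_volumes)))
  dvs <- dvs[dvs > 0]
  excluded <- excluded[seq_along(dvs)]
  kd_b <- if (is.null(params$kd_b)) 1 else params$kd_b
  dh_b <- if (is.null(params$dh_b)) 0 else params$dh_b
  b0 <- schedule$cell_competitor_conc
  if (b0 > 0 && is.null(params$kd_b))
    stop("schedule has a cell competitor but params carry no kd_b")

  q_of <- function(m, x, b) {
    st <- competitive_equilibrium(m, x, b, params$kd_a, kd_b, n = params$n)
    v0 * (params$dh_a * st$pa + dh_b * st$pb)
  }
  q_prev <- q_of(schedule$cell_conc, 0, b0)
  v <- 0
  ndh <- numeric(0)
  q_all <- q_prev
  for (k in seq_along(dvs)) {
    v <- v + dvs[k]
    d <- v / (2 * v0)
    m <- schedule$cell_conc * (1 - d) / (1 + d)
    x <- schedule$syringe_conc * (v / v0) / (1 + d)
    b <- b0 * (1 - d) / (1 + d)
    q <- q_of(m, x, b)
    h <- q - q_prev + (dvs[k] / v0) * (q + q_prev) / 2
    if (!excluded[k])
      ndh <- c(ndh, h / (schedule$syringe_conc * dvs[k]))
    q_prev <- q
    q_all <- c(q_all, q)
  }
  list(ndh = ndh, q = q_all, volumes = dvs, excluded = excluded)
}

#' Simulate an ITC thermogram
#'
#' Forward-simulates per-injection normalized heats (NDH, kcal per mol of
#' injectant) for a 1:1 single-site titration, or a competitive displacement
#' titration when the schedule carries a cell competitor and `params` its
#' constants. Optional i.i.d. Gaussian noise is added under the given seed.
#'
#' @param params A [binding_parameters()] object (`kd_a`, `dh_a`, and
#'   `kd_b`/`dh_b` for the competitor where present).
#' @param schedule An [injection_schedule()].
#' @param noise_sd Standard deviation of additive Gaussian heat noise, in
#'   kcal/mol (0 for a noiseless trace).
#' @param seed Integer seed used when `noise_sd > 0`.
#' @return Object of class `thermogram`: data.frame with columns
#'   `injection`, `volume` (litres) and `ndh` (kcal/mol); the schedule,
#'   noise level and seed are kept as attributes.
#' @export
simulate_thermogram <- function(params, schedule = injection_schedule(),
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "binding_parameters"),
            inherits(schedule, "injection_schedule"), noise_sd >= 0)
  hm <- .itc_heats(params, schedule)
  ndh <- hm$ndh
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    ndh <- ndh + withr::with_seed(seed, stats::rnorm(length(ndh), 0, noise_sd))
  }
  tg <- data.frame(injection = seq_along(ndh),
                   volume = hm$volumes[!hm$excluded],
                   ndh = ndh)
  structure(tg, class = c("thermogram", "data.frame"),
            schedule = schedule, noise_sd = noise_sd, seed = seed)
}

#' Read/write thermogram CSV
#'
#' Plain CSV with columns `injection`, `volume_uL`, `ndh_kcal_per_mol`.
#'
#' @param tg A `thermogram`.
#' @param path File path.
#' @return `read_thermogram()` returns a data.frame of class `thermogram`
#'   (without schedule attributes); `write_thermogram()` returns `path`
#'   invisibly.
#' @export
write_thermogram <- function(tg, path) {
  out <- data.frame(injection = tg$injection,
                    volume_uL = tg$volume * 1e6,
                    ndh_kcal_per_mol = tg$ndh)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("injection", "volume_uL", "ndh_kcal_per_mol") %in% names(d)))
  structure(data.frame(injection = d$injection,
                       volume = d$volume_uL * 1e-6,
                       ndh = d$ndh_kcal_per_mol),
            class = c("thermogram", "data.frame"))
}

#' Fit a single-site binding model to a thermogram
#'
#' Least-squares fit of (Kd, dH, constant baseline) to per-injection
#' normalized heats, with the stoichiometry N fixed (default 1.0). The
#' baseline absorbs the heat of dilution as a constant offset. Start values
#' are deterministic: dH from the first fitted injection relative to the
#' last, Kd from the cell receptor concentration at the titration midpoint,
#' baseline from the final injection; the fit is therefore reproducible for
#' identical inputs. Kd is optimised on the log scale. When the schedule
#' carries a cell competitor, supply its known constants via `competitor`
#' and the displacement isotherm is fitted for the injectant's Kd and dH.
#'
#' @param tg A `thermogram` (simulated or read from CSV).
#' @param schedule The [injection_schedule()] the heats were collected
#'   under; defaults to the schedule attached to `tg`.
#' @param fix_n Stoichiometry, fixed (default 1.0).
#' @param competitor Optional [binding_parameters()] giving the cell
#'   competitor's `kd_a`/`dh_a` (used as the B-site constants).
#' @param weights Optional per-injection weights (default 1).
#' @return Object of class `itc_fit`: list with `kd`, `dh`, `baseline`,
#'   `n`, standard errors, `c_value` (= N * cell_conc / Kd), residuals and
#'   the convergence report from the Levenberg-Marquardt optimiser.
#' @export
fit_thermogram <- function(tg, schedule = attr(tg, "schedule"), fix_n = 1,
                           competitor = NULL, weights = NULL) {
  if (is.null(schedule))
    stop("no schedule attached to the thermogram; supply one")
  stopifnot(inherits(schedule, "injection_schedule"), fix_n > 0)
  ndh <- tg$ndh
  n_inj <- length(schedule$injection_volumes)
  if (length(ndh) != n_inj)
    stop(sprintf("thermogram has %d heats but schedule %d injections",
                 length(ndh), n_inj))
  if (n_inj < 4) stop("at least 4 injections are required")
  if (is.null(weights)) weights <- rep(1, n_inj)
  if (max(ndh) - min(ndh) < 1e-12 * max(1, max(abs(ndh))))
    stop("no binding signal: thermogram is flat")

  kd_b <- dh_b <- NULL
  if (schedule$cell_competitor_conc > 0) {
    if (is.null(competitor))
      stop("schedule has a cell competitor; supply its binding_parameters")
    kd_b <- competitor$kd_a
    dh_b <- competitor$dh_a
  }
  model_ndh <- function(kd, dh, baseline) {
    p <- binding_parameters(kd, dh, kd_b = kd_b, dh_b = dh_b, n = fix_n)
    .itc_heats(p, schedule)$ndh + baseline
  }
  # deterministic start heuristic
  v_mid <- schedule$pre_injection +
    sum(schedule$injection_volumes[seq_len(ceiling(n_inj / 2))])
  d_mid <- v_mid / (2 * schedule$cell_volume)
  kd0 <- max(schedule$cell_conc * (1 - d_mid) / (1 + d_mid), 1e-9)
  base0 <- ndh[n_inj]
  dh0 <- ndh[1] - base0
  if (abs(dh0) < 1e-12) dh0 <- sign(ndh[1] + 1e-300) * 1e-3

  resid_fn <- function(par) {
    sqrt(weights) * (ndh - model_ndh(exp(par[1]), par[2], par[3]))
  }
  fit <- minpack.lm::nls.lm(par = c(log(kd0), dh0, base0), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  if (fit$info %in% c(0, 9))
    stop(sprintf("thermogram fit did not converge: %s (residual norm %.3e)",
                 fit$message, sqrt(fit$deviance)))
  par <- fit$par
  kd <- exp(par[1])
  # standard errors from the Jacobian (delta method for kd = exp(par1))
  se <- rep(NA_real_, 3)
  dof <- n_inj - 3
  if (dof > 0) {
    covm <- tryCatch(fit$deviance / dof * solve(fit$hessian),
                     error = function(e) NULL)
    if (!is.null(covm)) se <- sqrt(pmax(diag(covm), 0))
  }
  structure(list(kd = kd, dh = par[2], baseline = par[3], n = fix_n,
                 se_kd = se[1] * kd, se_dh = se[2], se_baseline = se[3],
                 c_value = fix_n * schedule$cell_conc / kd,
                 residuals = ndh - model_ndh(kd, par[2], par[3]),
                 residual_norm = sqrt(fit$deviance),
                 schedule = schedule, info = fit$info,
                 message = fit$message),
            class = "itc_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf(
    "<itc_fit> Kd = %.4g uM, dH = %.3f kcal/mol, baseline = %.4f, N = %.2f (fixed), c = %.3g\n",
    x$kd * 1e6, x$dh, x$baseline, x$n, x$c_value))
  invisible(x)
}

#' Thermodynamic decomposition of an ITC fit
#'
#' One table row of (Kd, dH, dG, -TdS, N), with `dG = R T ln Kd` and
#' `-TdS = dG - dH` so the identity `dG = dH + (-TdS)` is exact.
#'
#' @param fit An `itc_fit`, or a list/`binding_parameters` with `kd`/`kd_a`
#'   and `dh`/`dh_a`.
#' @param temperature Kelvin (default 305.15).
#' @return data.frame with columns `kd_uM`, `dh`, `dg`, `minus_tds`, `n`
#'   (energies in kcal/mol).
#' @export
thermodynamic_summary <- function(fit, temperature = 305.15) {
  kd <- fit$kd %||% fit$kd_a
  dh <- fit$dh %||% fit$dh_a
  n <- fit$n %||% 1
  dg <- delta_g_from_kd(kd, temperature)
  data.frame(kd_uM = kd * 1e6, dh = dh, dg = dg,
             minus_tds = entropy_term(dg, dh), n = n)
}

#' Binding-signal suppression between two thermograms
#'
#' Ratio of binding-attributable heat amplitudes, used to quantify how far a
#' pre-bound competitor blocks the injectant's isotherm. Consistent with the
#' constant-offset treatment of heats of dilution, each trace's constant
#' offset is removed before comparing amplitudes: with `baseline =
#' "plateau"` (default) the offset is the median NDH of the last three
#' injections (the post-saturation plateau); `"none"` compares raw |NDH|,
#' which retains the endothermic re-equilibration heat of the diluting
#' competitor-receptor complex and therefore overstates the residual signal.
#'
#' @param tg_test Thermogram of the (suppressed) test titration.
#' @param tg_ref Reference (competitor-free) thermogram.
#' @param baseline `"plateau"` or `"none"`.
#' @return List with `ratio` (max corrected |NDH| of test over reference),
#'   `raw_ratio`, and the offsets removed.
#' @export
suppression_ratio <- function(tg_test, tg_ref, baseline = c("plateau", "none")) {
  baseline <- match.arg(baseline)
  plateau <- function(x) stats::median(utils::tail(x, 3))
  off_t <- if (baseline == "plateau") plateau(tg_test$ndh) else 0
  off_r <- if (baseline == "plateau") plateau(tg_ref$ndh) else 0
  list(ratio = max(abs(tg_test$ndh - off_t)) / max(abs(tg_ref$ndh - off_r)),
       raw_ratio = max(abs(tg_test$ndh)) / max(abs(tg_ref$ndh)),
       offset_test = off_t, offset_ref = off_r)
}
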