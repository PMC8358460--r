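# HSQC titration analysis: combined 1H/15N chemical-shift perturbations,
# intensity attenuation, mu/sigma significance thresholds, per-residue or
# global Kd fitting under fast exchange, and competitor-displacement
# recovery.

#' Amide peak list for one titration point
#'
#' @param residue Integer residue numbers (unique; prolines and unassigned
#'   residues simply absent).
#' @param d_h,d_n Amide 1H and 15N chemical shifts (ppm).
#' @param intensity Peak intensities (arbitrary units, >= 0).
#' @param receptor_conc,competitor_conc Labels identifying the titration
#'   point (molar).
#' @return data.frame of class `peak_list` with the concentrations stored as
#'   attributes.
#' @export
peak_list <- function(residue, d_h, d_n, intensity,
                      receptor_conc = 0, competitor_conc = 0) {
  stopifnot(length(residue) == length(d_h), length(d_h) == length(d_n),
            length(d_n) == length(intensity), all(intensity >= 0),
            !anyDuplicated(residue), receptor_conc >= 0, competitor_conc >= 0)
  structure(data.frame(residue = as.integer(residue), d_h = d_h, d_n = d_n,
                       intensity = intensity),
            class = c("peak_list", "data.frame"),
            receptor_conc = receptor_conc, competitor_conc = competitor_conc)
}

#' Read/write Sparky-style peak lists
#'
#' Whitespace-delimited columns `Assignment w2(1H) w1(15N) Height` with one
#' header line; the residue number is parsed from the digits of the
#' assignment token (e.g. `R36N-H` -> 36).
#'
#' @param pl A `peak_list`.
#' @param path File path.
#' @param residue_letters Optional one-letter codes used to build assignment
#'   tokens on write (defaults to `X`).
#' @param receptor_conc,competitor_conc Point labels attached on read.
#' @return `read_peak_list()` returns a `peak_list`; `write_peak_list()`
#'   returns `path` invisibly.
#' @export
write_peak_list <- function(pl, path, residue_letters = NULL) {
  lett <- if (is.null(residue_letters)) rep("X", nrow(pl)) else residue_letters
  lines <- c(sprintf("%-12s %9s %9s %12s", "Assignment", "w2", "w1", "Height"),
             sprintf("%-12s %9.4f %9.4f %12.1f",
                     paste0(lett, pl$residue, "N-H"), pl$d_h, pl$d_n,
                     pl$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path, receptor_conc = 0, competitor_conc = 0) {
  d <- utils::read.table(path, header = TRUE,
                         col.names = c("assignment", "w2", "w1", "height"))
  resno <- as.integer(sub("^[^0-9]*([0-9]+).*$", "\\1", d$assignment))
  if (anyNA(resno))
    stop("could not parse residue numbers from assignment column")
  peak_list(resno, d$w2, d$w1, d$height,
            receptor_conc = receptor_conc, competitor_conc = competitor_conc)
}

#' Titration series of peak lists
#'
#' @param observed_conc Concentration of the observed (labelled) species,
#'   constant across the titration (molar).
#' @param points List of `peak_list` objects carrying `receptor_conc` /
#'   `competitor_conc` attributes. Exactly one point with receptor 0 and
#'   competitor 0 serves as the reference; the competitor-free receptor
#'   ladder must be non-decreasing.
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(observed_conc, points) {
  stopifnot(observed_conc > 0, length(points) >= 1)
  rc <- vapply(points, function(p) attr(p, "receptor_conc"), numeric(1))
  cc <- vapply(points, function(p) attr(p, "competitor_conc"), numeric(1))
  if (any(rc < 0) || any(cc < 0)) stop("concentrations must be >= 0")
  ref <- which(rc == 0 & cc == 0)
  if (length(ref) == 0)
    stop("a reference point (receptor 0, competitor 0) is required")
  ref <- ref[1]
  ladder <- rc[cc == 0]
  if (is.unsorted(ladder))
    stop("competitor-free receptor ladder must be non-decreasing")
  structure(list(observed_conc = observed_conc, points = points,
                 receptor_conc = rc, competitor_conc = cc,
                 reference = ref),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> observed species %.3g M, %d points (receptor %s uM)\n",
    x$observed_conc, length(x$points),
    paste(signif(x$receptor_conc * 1e6, 3), collapse = "/")))
  invisible(x)
}

#' Combined amide chemical-shift perturbation
#'
#' Weighted combined CSP per residue,
#' `d = sqrt(dH^2 + (alpha * dN)^2)`, for residues present in both lists;
#' residues missing from either list are reported in the `absent` attribute,
#' never as zero. Invariant under a constant referencing offset applied to
#' both spectra and under sign flips of either shift change.
#'
#' @param reference,point `peak_list` objects.
#' @param alpha Nitrogen scaling weight (default 0.2).
#' @return data.frame (`residue`, `dd_h`, `dd_n`, `csp`) with attribute
#'   `absent`.
#' @export
combined_csp <- function(reference, point, alpha = 0.2) {
  shared <- intersect(reference$residue, point$residue)
  if (length(shared) == 0) stop("no residues shared between peak lists")
  i <- match(shared, reference$residue)
  j <- match(shared, point$residue)
  dd_h <- point$d_h[j] - reference$d_h[i]
  dd_n <- point$d_n[j] - reference$d_n[i]
  out <- data.frame(residue = shared, dd_h = dd_h, dd_n = dd_n,
                    csp = sqrt(dd_h^2 + (alpha * dd_n)^2))
  attr(out, "absent") <- sort(setdiff(union(reference$residue, point$residue),
                                      shared))
  out
}

#' Per-residue intensity ratios
#'
#' `I/I0` relative to the reference point. Residues present in the reference
#' but vanished at the titration point get ratio 0 with `lost = TRUE`
#' (exchange-broadened beyond detection); residues with zero reference
#' intensity are excluded with a warning.
#'
#' @param reference,point `peak_list` objects.
#' @return data.frame (`residue`, `ratio`, `lost`).
#' @export
intensity_ratio <- function(reference, point) {
  zero <- reference$residue[reference$intensity <= 0]
  if (length(zero) > 0)
    warning(sprintf("excluding residue(s) %s with zero reference intensity",
                    paste(zero, collapse = ", ")))
  keep <- reference[reference$intensity > 0, ]
  j <- match(keep$residue, point$residue)
  lost <- is.na(j)
  ratio <- ifelse(lost, 0, point$intensity[j] / keep$intensity)
  data.frame(residue = keep$residue, ratio = ratio, lost = lost)
}

#' Flag significantly perturbed residues by the mu/sigma rule
#'
#' Computes the mean `mu` and sample standard deviation `sigma` (n-1) over
#' all scored residues, with no trimming or iterative exclusion, and flags:
#' in `shift` mode, residues whose CSP exceeds `mu + sigma`; in `intensity`
#' mode, residues whose attenuation `1 - I/I0` exceeds the mean attenuation
#' plus one standard deviation (equivalently, I/I0 more than one sd below
#' its mean). Vanished peaks enter intensity mode as attenuation 1.
#'
#' @param values Named numeric vector (names = residue numbers): combined
#'   CSPs in `shift` mode, I/I0 ratios in `intensity` mode.
#' @param mode `"shift"` or `"intensity"`.
#' @return List with `flagged` (integer residue numbers), `mu`, `sigma`,
#'   `threshold` (on the scored change), and `scores` (the per-residue
#'   change values the rule was applied to).
#' @export
flag_significant <- function(values, mode = c("shift", "intensity")) {
  mode <- match.arg(mode)
  if (length(values) < 3) stop("at least 3 scored residues are required")
  if (is.null(names(values))) stop("values must be named by residue number")
  scores <- if (mode == "shift") values else 1 - values
  mu <- mean(scores)
  sigma <- stats::sd(scores)
  thr <- mu + sigma
  flagged <- as.integer(names(scores)[scores > thr])
  list(flagged = sort(flagged), mu = mu, sigma = sigma, threshold = thr,
       mode = mode, scores = scores)
}

#' Full CSP analysis of a titration series
#'
#' Scores the final competitor-free titration point against the free
#' reference: combined CSPs and intensity ratios per residue, with
#' significance flags from [flag_significant()]. Intermediate points are
#' retained (in the returned matrices) for Kd fitting.
#'
#' @param series A [titration_series()].
#' @param alpha CSP nitrogen weight.
#' @return Object of class `csp_result`: list with `csp` and `ratio`
#'   matrices (residue x point, competitor-free points), `shift_flags`,
#'   `intensity_flags`, the two threshold reports, and the index of the
#'   scored point.
#' @export
analyze_titration <- function(series, alpha = 0.2) {
  stopifnot(inherits(series, "titration_series"))
  ref <- series$points[[series$reference]]
  free_idx <- which(series$competitor_conc == 0)
  final_idx <- free_idx[which.max(series$receptor_conc[free_idx])]
  if (series$receptor_conc[final_idx] == 0)
    stop("series has no non-reference titration point")

  residues <- sort(ref$residue)
  csp_m <- ratio_m <- matrix(
    NA_real_, length(residues), length(free_idx),
    dimnames = list(residues, signif(series$receptor_conc[free_idx] * 1e6, 6)))
  lost_m <- matrix(FALSE, length(residues), length(free_idx))
  for (k in seq_along(free_idx)) {
    pt <- series$points[[free_idx[k]]]
    cs <- combined_csp(ref, pt, alpha = alpha)
    csp_m[match(cs$residue, residues), k] <- cs$csp
    ir <- intensity_ratio(ref, pt)
    ratio_m[match(ir$residue, residues), k] <- ir$ratio
    lost_m[match(ir$residue, residues), k] <- ir$lost
  }
  fk <- match(final_idx, free_idx)
  shift_vals <- csp_m[, fk]
  shift_vals <- shift_vals[!is.na(shift_vals)]
  int_vals <- ratio_m[, fk]
  int_vals <- int_vals[!is.na(int_vals)]
  shift_flags <- flag_significant(shift_vals, "shift")
  intensity_flags <- flag_significant(int_vals, "intensity")
  structure(list(residues = residues, alpha = alpha,
                 csp = csp_m, ratio = ratio_m, lost = lost_m,
                 scored_point = final_idx,
                 scored_receptor_conc = series$receptor_conc[final_idx],
                 shift_flags = shift_flags,
                 intensity_flags = intensity_flags),
            class = "csp_result")
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf(
    "<csp_result> %d residues scored at %.3g uM receptor\n  shift-perturbed: %s\n  intensity-perturbed: %s\n",
    length(x$residues), x$scored_receptor_conc * 1e6,
    paste(x$shift_flags$flagged, collapse = ", "),
    paste(x$intensity_flags$flagged, collapse = ", ")))
  invisible(x)
}

#' Fit a dissociation constant from fast-exchange shift trajectories
#'
#' Under fast exchange the observed CSP is `d_obs = d_max * f_bound`, with
#' `f_bound` the bound fraction of the observed species from
#' [bound_fraction_1to1()]. The fit minimises the summed squared residuals
#' over all competitor-free points; for each trial Kd the per-residue
#' `d_max` has the closed-form least-squares solution, so only Kd is
#' searched (1-D minimisation on log Kd). `mode = "global"` shares one Kd
#' across residues; `mode = "per-residue"` fits each residue separately.
#'
#' @param series A [titration_series()].
#' @param residues Residue subset to fit (default: all residues whose CSP
#'   trajectory is complete and not all zero).
#' @param mode `"global"` or `"per-residue"`.
#' @param alpha CSP nitrogen weight.
#' @param kd_range Log-search bracket (molar).
#' @return For `global`: list with `kd`, `d_max` (named vector), `rss` and
#'   `n_points`; for `per-residue`: data.frame of per-residue fits.
#' @export
fit_kd_from_shifts <- function(series, residues = NULL,
                               mode = c("global", "per-residue"),
                               alpha = 0.2, kd_range = c(1e-9, 1)) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "titration_series"))
  free_idx <- setdiff(which(series$competitor_conc == 0), series$reference)
  if (length(free_idx) < 2) stop("at least 2 non-reference points required")
  ref <- series$points[[series$reference]]
  p_tot <- series$receptor_conc[free_idx]
  f_of_kd <- function(kd) bound_fraction_1to1(p_tot, series$observed_conc, kd)

  traj <- sapply(free_idx, function(i)
    combined_csp(ref, series$points[[i]], alpha = alpha)$csp)
  rownames(traj) <- combined_csp(ref, series$points[[free_idx[1]]],
                                 alpha = alpha)$residue
  if (is.null(residues)) {
    ok <- apply(traj, 1, function(v) all(is.finite(v)) && any(v > 0))
    residues <- as.integer(rownames(traj)[ok])
  }
  traj <- traj[as.character(residues), , drop = FALSE]
  if (nrow(traj) == 0 || all(traj == 0))
    stop("all-zero shift trajectories: nothing to fit")

  rss_profile <- function(kd, rows) {
    f <- f_of_kd(kd)
    ss <- 0
    dmax <- numeric(nrow(rows))
    for (r in seq_len(nrow(rows))) {
      dmax[r] <- sum(rows[r, ] * f) / sum(f^2)
      ss <- ss + sum((rows[r, ] - dmax[r] * f)^2)
    }
    list(rss = ss, d_max = dmax)
  }
  fit_rows <- function(rows) {
    opt <- stats::optimize(function(lk) rss_profile(exp(lk), rows)$rss,
                           interval = log(kd_range), tol = 1e-12)
    kd <- exp(opt$minimum)
    pr <- rss_profile(kd, rows)
    list(kd = kd, d_max = stats::setNames(pr$d_max, rownames(rows)),
         rss = pr$rss)
  }
  if (mode == "global") {
    out <- fit_rows(traj)
    out$n_points <- length(free_idx)
    out$residues <- residues
    out
  } else {
    res <- lapply(seq_len(nrow(traj)), function(r)
      fit_rows(traj[r, , drop = FALSE]))
    data.frame(residue = residues,
               kd = vapply(res, `[[`, numeric(1), "kd"),
               d_max = vapply(res, function(x) unname(x$d_max), numeric(1)),
               rss = vapply(res, `[[`, numeric(1), "rss"))
  }
}

#' Competitor-displacement recovery analysis
#'
#' Quantifies how far a competitor returns the observed species' spectrum to
#' its free state. For each competitor point matched to a receptor-only
#' point at the same receptor concentration, the per-residue recovery is
#' `1 - csp(competitor)/csp(receptor only)`, clipped to \[0, 1\]. The
#' verdict is `"recovered"` when the mean CSP over the residues flagged in
#' the competitor-free analysis falls below that analysis' significance
#' threshold `mu + sigma`. When the ligand and competitor dissociation
#' constants are supplied, the expected occupancy suppression is
#' cross-checked with [competitive_equilibrium()].
#'
#' @param series A [titration_series()] containing at least one competitor
#'   point whose receptor concentration matches a competitor-free point.
#' @param csp_result Optional precomputed [analyze_titration()] result.
#' @param alpha CSP nitrogen weight.
#' @param kd_ligand,kd_competitor Optional dissociation constants (molar)
#'   for the equilibrium cross-check.
#' @return List with `recovery` (data.frame residue/recovery per competitor
#'   point), `mean_flagged_csp`, `threshold`, `verdict`, and `predicted`
#'   (occupancies with and without competitor, when Kds are given).
#' @export
competition_recovery <- function(series, csp_result = NULL, alpha = 0.2,
                                 kd_ligand = NULL, kd_competitor = NULL) {
  stopifnot(inherits(series, "titration_series"))
  comp_idx <- which(series$competitor_conc > 0)
  if (length(comp_idx) == 0) stop("series has no competitor points")
  if (is.null(csp_result)) csp_result <- analyze_titration(series, alpha)
  ref <- series$points[[series$reference]]

  out <- list()
  for (ci in comp_idx) {
    rc <- series$receptor_conc[ci]
    match_idx <- which(series$competitor_conc == 0 &
                         series$receptor_conc == rc)
    if (length(match_idx) == 0)
      stop(sprintf("no receptor-only point matches competitor point at %.3g uM receptor",
                   rc * 1e6))
    cs_only <- combined_csp(ref, series$points[[match_idx[1]]], alpha)
    cs_comp <- combined_csp(ref, series$points[[ci]], alpha)
    shared <- intersect(cs_only$residue, cs_comp$residue)
    a <- cs_only$csp[match(shared, cs_only$residue)]
    b <- cs_comp$csp[match(shared, cs_comp$residue)]
    rec <- pmin(pmax(ifelse(a > 0, 1 - b / a, NA_real_), 0), 1)
    out[[length(out) + 1]] <- data.frame(
      residue = shared, recovery = rec,
      competitor_conc = series$competitor_conc[ci],
      csp_receptor_only = a, csp_competitor = b)
  }
  recovery <- do.call(rbind, out)

  flagged <- csp_result$shift_flags$flagged
  last <- out[[length(out)]]
  mean_flagged <- mean(last$csp_competitor[last$residue %in% flagged])
  thr <- csp_result$shift_flags$threshold
  verdict <- if (is.finite(mean_flagged) && mean_flagged < thr)
    "recovered" else "not recovered"

  predicted <- NULL
  if (!is.null(kd_ligand) && !is.null(kd_competitor)) {
    ci <- comp_idx[length(comp_idx)]
    with_comp <- competitive_equilibrium(
      series$receptor_conc[ci], series$observed_conc,
      series$competitor_conc[ci], kd_ligand, kd_competitor)
    without <- bound_fraction_1to1(series$receptor_conc[ci],
                                   series$observed_conc, kd_ligand) *
      series$observed_conc
    predicted <- list(occupancy_with_competitor = with_comp$pa,
                      occupancy_without = without,
                      suppression = with_comp$pa / without)
  }
  list(recovery = recovery, mean_flagged_csp = mean_flagged,
       threshold = thr, verdict = verdict, predicted = predicted)
}
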