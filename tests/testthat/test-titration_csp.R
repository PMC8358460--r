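test_that("combined CSP follows the weighted quadrature formula", {
  ref <- mk_peaks(1:3, c(8.0, 8.5, 9.0), c(110, 120, 125))
  pt <- mk_peaks(1:3, c(8.0, 8.6, 9.0), c(110, 120.5, 125),
                 receptor = 125e-6)
  cs <- combined_csp(ref, pt, alpha = 0.2)
  expect_equal(cs$csp[1], 0)
  expect_equal(cs$csp[2], sqrt(0.1^2 + (0.2 * 0.5)^2), tolerance = 1e-12)
  expect_equal(cs$csp[2], 0.14142, tolerance = 1e-4)

  # even in each shift change: sign flips leave the CSP unchanged
  pt_neg <- mk_peaks(1:3, c(8.0, 8.4, 9.0), c(110, 119.5, 125))
  expect_equal(combined_csp(ref, pt_neg)$csp, cs$csp)

  # referencing invariance: constant ppm offset on both spectra
  off <- function(pl, dh, dn) mk_peaks(pl$residue, pl$d_h + dh,
                                       pl$d_n + dn, pl$intensity)
  expect_equal(combined_csp(off(ref, 0.3, -1), off(pt, 0.3, -1))$csp,
               cs$csp, tolerance = 1e-12)

  # residues missing from either list are absent, not zero
  cs2 <- combined_csp(ref, mk_peaks(2:4, c(8.5, 9.0, 7.7),
                                    c(120, 125, 115)))
  expect_equal(cs2$residue, 2:3)
  expect_equal(attr(cs2, "absent"), c(1L, 4L))
  expect_error(combined_csp(ref, mk_peaks(7:8, c(8, 8), c(115, 115))),
               "no residues shared")
})

test_that("intensity ratios handle vanished and zero-reference peaks", {
  ref <- mk_peaks(1:3, rep(8, 3), rep(115, 3), c(1e5, 2e5, 1e5))
  same <- intensity_ratio(ref, ref)
  expect_equal(same$ratio, rep(1, 3))
  half <- mk_peaks(1:3, rep(8, 3), rep(115, 3), c(5e4, 1e5, 5e4))
  expect_equal(intensity_ratio(ref, half)$ratio, rep(0.5, 3))
  gone <- mk_peaks(c(1, 3), rep(8, 2), rep(115, 2), c(1e5, 1e5))
  ir <- intensity_ratio(ref, gone)
  expect_equal(ir$ratio[ir$residue == 2], 0)
  expect_true(ir$lost[ir$residue == 2])
  ref0 <- mk_peaks(1:3, rep(8, 3), rep(115, 3), c(0, 2e5, 1e5))
  expect_warning(ir0 <- intensity_ratio(ref0, half), "zero reference")
  expect_false(1 %in% ir0$residue)
})

test_that("mu/sigma significance flags follow the stated rule", {
  v <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 0, `5` = 1)
  fl <- flag_significant(v, "shift")
  expect_equal(fl$mu, 0.2)
  expect_equal(fl$sigma, sqrt(0.2), tolerance = 1e-12)  # sd with n-1
  expect_equal(fl$flagged, 5L)

  allsame <- c(`1` = 0.3, `2` = 0.3, `3` = 0.3)
  expect_length(flag_significant(allsame, "shift")$flagged, 0)

  # intensity mode scores the attenuation 1 - I/I0; a vanished peak
  # (ratio 0) scores 1 and is flaggable
  r <- c(`1` = 1, `2` = 0.95, `3` = 1.02, `4` = 0, `5` = 0.9)
  fi <- flag_significant(r, "intensity")
  expect_equal(unname(fi$scores["4"]), 1)
  expect_equal(fi$flagged, 4L)

  expect_error(flag_significant(c(a = 1, b = 2), "shift"), "at least 3")
  expect_error(flag_significant(unname(v), "shift"), "named")
})

test_that("flags are reproducible from stored scores and thresholds", {
  s <- make_titration_fixture()
  res <- analyze_titration(s)
  for (fl in list(res$shift_flags, res$intensity_flags)) {
    re <- as.integer(names(fl$scores)[fl$scores > fl$threshold])
    expect_equal(sort(re), fl$flagged)
  }
})

test_that("the synthetic titration recovers the ground-truth interfaces", {
  s <- make_titration_fixture()
  res <- analyze_titration(s)
  expect_equal(res$shift_flags$flagged,
               c(2L, 20L, 21L, 23L, 25L, 26L, 28L, 29L, 34L))
  expect_equal(res$intensity_flags$flagged,
               c(2L, 25L, 26L, 27L, 28L, 35L, 36L))
})

test_that("Kd is recovered from noiseless fast-exchange trajectories", {
  set.seed(17)
  for (k in 1:20) {
    kd <- runif(1, 10e-6, 500e-6)
    tr <- titration_ground_truth(kd = kd, shift_noise_h = 0,
                                 shift_noise_n = 0, intensity_noise = 0,
                                 seed = k)
    s <- make_titration_fixture(tr, competitor_points = NULL)
    fit <- fit_kd_from_shifts(s)
    expect_equal(fit$kd, kd, tolerance = 0.01)
  }
})

test_that("Kd fit is invariant to scaling all maximal shifts", {
  tr <- titration_ground_truth(shift_noise_h = 0, shift_noise_n = 0,
                               intensity_noise = 0)
  s <- make_titration_fixture(tr, competitor_points = NULL)
  f1 <- fit_kd_from_shifts(s)
  tr2 <- titration_ground_truth(shift_noise_h = 0, shift_noise_n = 0,
                                intensity_noise = 0,
                                dmax_h_range = 2 * tr$dmax_h_range,
                                dmax_n_range = 2 * tr$dmax_n_range)
  s2 <- make_titration_fixture(tr2, competitor_points = NULL)
  f2 <- fit_kd_from_shifts(s2)
  expect_equal(f2$kd, f1$kd, tolerance = 1e-4)
  # per-residue fits agree with the global fit on shared-Kd data
  pr <- fit_kd_from_shifts(s, mode = "per-residue")
  expect_equal(unname(stats::median(pr$kd)), f1$kd, tolerance = 1e-4)
})

test_that("all-zero trajectories are rejected", {
  ref <- mk_peaks(1:5, rep(8, 5), rep(115, 5))
  pts <- lapply(c(0, 21e-6, 45e-6), function(p)
    mk_peaks(1:5, rep(8, 5), rep(115, 5), receptor = p))
  s <- titration_series(55e-6, pts)
  expect_error(fit_kd_from_shifts(s), "all-zero|nothing to fit")
})

test_that("competitor displacement yields full recovery under the study conditions", {
  s <- make_titration_fixture()
  cr <- competition_recovery(s, kd_ligand = 143.3e-6,
                             kd_competitor = 7.9e-6)
  expect_equal(cr$verdict, "recovered")
  expect_lt(cr$mean_flagged_csp, cr$threshold)
  # predicted occupancy from the equilibrium solver: < 10% of the
  # competitor-free occupancy at 125 uM receptor / 413 uM competitor
  expect_lt(cr$predicted$suppression, 0.10)
  # flagged residues largely return to their free positions
  flagged <- analyze_titration(s)$shift_flags$flagged
  rec <- cr$recovery[cr$recovery$residue %in% flagged, ]
  expect_gt(mean(rec$recovery), 0.9)
})

test_that("competition recovery edge cases behave by convention", {
  ref <- mk_peaks(1:4, c(8, 8.5, 9, 7.8), c(110, 115, 120, 125))
  bound <- mk_peaks(1:4, c(8.2, 8.7, 9, 7.8), c(111, 116, 120, 125),
                    receptor = 125e-6)
  # competitor point identical to the free reference: recovery 1 for all
  # residues that moved
  comp_full <- mk_peaks(1:4, ref$d_h, ref$d_n, receptor = 125e-6,
                        competitor = 413e-6)
  s <- titration_series(55e-6, list(ref, bound, comp_full))
  cr <- suppressWarnings(competition_recovery(s))
  moved <- cr$recovery[cr$recovery$csp_receptor_only > 0, ]
  expect_equal(moved$recovery, rep(1, nrow(moved)))
  # competitor point identical to the bound point: recovery 0
  comp_none <- mk_peaks(1:4, bound$d_h, bound$d_n, receptor = 125e-6,
                        competitor = 1e-9)
  s2 <- titration_series(55e-6, list(ref, bound, comp_none))
  cr2 <- suppressWarnings(competition_recovery(s2))
  moved2 <- cr2$recovery[cr2$recovery$csp_receptor_only > 0, ]
  expect_equal(moved2$recovery, rep(0, nrow(moved2)))
  # no matched receptor-only point -> rejection
  comp_odd <- mk_peaks(1:4, ref$d_h, ref$d_n, receptor = 95e-6,
                       competitor = 413e-6)
  s3 <- titration_series(55e-6, list(ref, bound, comp_odd))
  expect_error(competition_recovery(s3), "no receptor-only point")
})

test_that("peak lists round-trip through the Sparky-style format", {
  pl <- mk_peaks(c(2, 20, 36), c(8.123, 7.456, 9.001),
                 c(115.32, 108.2, 130.11), c(12345.6, 200.1, 9.9),
                 receptor = 21e-6)
  f <- withr::local_tempfile(fileext = ".list")
  write_peak_list(pl, f, residue_letters = c("C", "C", "R"))
  back <- read_peak_list(f, receptor_conc = 21e-6)
  expect_equal(back$residue, pl$residue)
  expect_equal(back$d_h, pl$d_h, tolerance = 1e-3)
  expect_equal(back$d_n, pl$d_n, tolerance = 1e-3)
  expect_equal(attr(back, "receptor_conc"), 21e-6)
})

test_that("series validation enforces the reference and ladder contracts", {
  p0 <- mk_peaks(1:3, rep(8, 3), rep(115, 3))
  p1 <- mk_peaks(1:3, rep(8.1, 3), rep(115.2, 3), receptor = 21e-6)
  expect_error(titration_series(55e-6, list(p1)), "reference")
  bad <- list(p0, p1, mk_peaks(1:3, rep(8, 3), rep(115, 3),
                               receptor = 10e-6))
  expect_error(titration_series(55e-6, bad), "non-decreasing")
})
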