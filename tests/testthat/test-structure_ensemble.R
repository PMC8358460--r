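test_that("superposition recovers rigid motions and matches the oracle", {
  set.seed(2)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  # identity case
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-10)
  # applied rigid motion is inverted exactly
  th <- 37 * pi / 180
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  b <- sweep(a %*% rot, 2, c(5, -3, 11), "+")
  sp <- superpose(b, a)
  expect_equal(sp$rmsd, 0, tolerance = 1e-10)
  expect_equal(sp$fitted, a, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-12)
  # random non-congruent pairs match the independent implementation
  for (k in 1:5) {
    m <- matrix(rnorm(18), 6, 3); r <- matrix(rnorm(18), 6, 3)
    expect_equal(superpose(m, r)$rmsd, oracle_superpose_rmsd(m, r),
                 tolerance = 1e-6)
  }
  # 4-point toy with one atom displaced after optimal fit
  base <- matrix(rnorm(12, sd = 5), 4, 3)
  mod <- base; mod[1, ] <- mod[1, ] + c(1, 0, 0)
  expect_equal(superpose(mod, base)$rmsd, oracle_superpose_rmsd(mod, base),
               tolerance = 1e-6)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("ensemble RMSD to the mean matches the closed-form two-model case", {
  set.seed(3)
  base <- matrix(rnorm(12, sd = 5), 4, 3)
  ens0 <- mk_ens(list(base, base))
  r0 <- mean_coordinate_rmsd(ens0, "all")
  expect_equal(r0$mean, 0, tolerance = 1e-10)
  expect_equal(r0$sd, 0, tolerance = 1e-10)
  # displace one atom radially by 2d: after mutual superposition each model
  # sits d*sqrt(n-1)/n from the mean (translation d/n absorbed, rotation
  # identity by symmetry of the radial displacement)
  d <- 0.7; n <- 4
  ctr <- colMeans(base)
  u <- (base[2, ] - ctr) / sqrt(sum((base[2, ] - ctr)^2))
  m2 <- base; m2[2, ] <- m2[2, ] + 2 * d * u
  r <- mean_coordinate_rmsd(mk_ens(list(base, m2)), "all")
  expect_equal(r$per_model, rep(d * sqrt(n - 1) / n, 2), tolerance = 1e-8)
})

test_that("ensemble RMSD is invariant under common rigid motion", {
  ens <- make_toy_ensemble(seed = 4, n_models = 4, perturbation_sd = 0.3)
  r1 <- mean_coordinate_rmsd(ens)
  set.seed(8)
  rot <- random_rotation_matrix()
  xyz2 <- t(apply(ens$xyz, 1, function(v) {
    m <- matrix(v, ncol = 3, byrow = TRUE)
    as.vector(t(sweep(m %*% rot, 2, c(7, -2, 13), "+")))
  }))
  r2 <- mean_coordinate_rmsd(model_ensemble(ens$atoms, xyz2))
  expect_equal(r2$mean, r1$mean, tolerance = 1e-9)
  expect_equal(r2$sd, r1$sd, tolerance = 1e-9)
})

test_that("disulfide detection pairs mutual nearest SG contacts only", {
  sg_xyz <- rbind(c(0, 0, 0), c(2.05, 0, 0),      # pair 1
                  c(10, 0, 0), c(10, 2.05, 0))    # pair 2
  ens <- mk_ens(list(sg_xyz), elety = rep("SG", 4),
                resid = rep("CYS", 4), resno = c(2, 19, 5, 28))
  dt <- detect_disulfides(ens)
  expect_equal(dt$pairs[, "i"], c(2, 5), ignore_attr = TRUE)
  expect_equal(dt$pairs[, "j"], c(19, 28), ignore_attr = TRUE)
  expect_equal(dt$framework, "1-3,2-4")  # cys ranks: 2->1, 5->2, 19->3, 28->4
  # atom-order invariance
  perm <- c(3, 1, 4, 2)
  ens_p <- mk_ens(list(sg_xyz[perm, ]), elety = rep("SG", 4),
                  resid = rep("CYS", 4), resno = c(2, 19, 5, 28)[perm])
  expect_equal(detect_disulfides(ens_p)$pairs, dt$pairs)
  # no cysteines -> empty topology
  none <- mk_ens(list(sg_xyz), elety = rep("CA", 4),
                 resid = rep("ALA", 4), resno = 1:4)
  expect_equal(detect_disulfides(none)$framework, "")
  # ambiguous: SG with two sub-cutoff partners, neither mutual
  amb_xyz <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(0.9, 1.9, 0))
  ens_a <- mk_ens(list(amb_xyz), elety = rep("SG", 3),
                  resid = rep("CYS", 3), resno = c(1, 5, 9))
  da <- detect_disulfides(ens_a)
  expect_equal(nrow(da$pairs), 1)
  expect_equal(attr(da, "ambiguous"), 9)
})

test_that("toy ensemble realises the engineered disulfide framework and patches", {
  ens <- make_toy_ensemble(seed = 1, n_models = 3, perturbation_sd = 0.1)
  dt <- detect_disulfides(ens)
  expect_equal(dt$framework, "1-4,2-6,3-7,5-8")
  expect_equal(dt$pairs[, "i"], c(2, 5, 16, 20), ignore_attr = TRUE)
  expect_equal(dt$pairs[, "j"], c(19, 28, 33, 35), ignore_attr = TRUE)
  basic <- find_patches(ens, kind = "basic")
  expect_length(basic, 2)
  expect_equal(basic[[1]]$members, c(14, 15, 23))
  expect_equal(basic[[2]]$members, c(25, 27, 36))
  hyd <- find_patches(ens, kind = "hydrophobic")
  expect_length(hyd, 1)
  expect_equal(hyd[[1]]$members, c(6, 7, 8, 10))
})

test_that("patch clustering respects the linkage cutoff", {
  # two basic triplets 6 A wide, 25 A apart
  pts <- rbind(c(0, 0, 0), c(6, 0, 0), c(3, 5, 0),
               c(25, 0, 0), c(31, 0, 0), c(28, 5, 0))
  ens <- mk_ens(list(pts), elety = rep("NZ", 6), resid = rep("LYS", 6),
                resno = c(1, 2, 3, 11, 12, 13))
  ps <- find_patches(ens, kind = "basic", link_cutoff = 10)
  expect_length(ps, 2)
  expect_equal(ps[[1]]$members, 1:3)
  expect_equal(ps[[2]]$members, 11:13)
  # cutoff below every pairwise distance: no patches
  expect_length(find_patches(ens, kind = "basic", link_cutoff = 2), 0)
  # merging monotonicity: an all-inclusive cutoff yields one patch of 6
  ps_all <- find_patches(ens, kind = "basic", link_cutoff = 30)
  expect_length(ps_all, 1)
  expect_equal(ps_all[[1]]$members, c(1, 2, 3, 11, 12, 13))
  # membership invariant to residue input order
  perm <- c(5, 1, 6, 2, 4, 3)
  ens_p <- mk_ens(list(pts[perm, ]), elety = rep("NZ", 6),
                  resid = rep("LYS", 6), resno = c(1, 2, 3, 11, 12, 13)[perm])
  ps_p <- find_patches(ens_p, kind = "basic", link_cutoff = 10)
  expect_equal(lapply(ps_p, `[[`, "members"), lapply(ps, `[[`, "members"))
})

test_that("restraint classification matches an exhaustive recount", {
  # the study's restraint bookkeeping: 533 distance + 12 disulfide + 57
  # dihedral over 36 residues -> 16.7 restraints per residue
  mk_bin <- function(n, sep_min, sep_max) {
    i <- sample(1:(36 - sep_min), n, replace = TRUE)
    sep <- if (sep_max > sep_min)
      sample(sep_min:sep_max, n, replace = TRUE) else rep(sep_min, n)
    j <- pmin(i + sep, 36)
    i <- j - sep
    data.frame(i = i, j = j)
  }
  set.seed(6)
  parts <- rbind(cbind(mk_bin(147, 0, 0), category = "distance"),
                 cbind(mk_bin(154, 1, 1), category = "distance"),
                 cbind(mk_bin(134, 2, 4), category = "distance"),
                 cbind(mk_bin(98, 5, 30), category = "distance"),
                 cbind(mk_bin(12, 5, 30), category = "disulfide"),
                 cbind(mk_bin(57, 0, 0), category = "dihedral"))
  rl <- restraint_records(parts$i, parts$j, category = parts$category)
  st <- classify_restraints(rl, 36)
  expect_equal(st$total, 533)
  expect_equal(st$intra, 147)
  expect_equal(st$sequential, 154)
  expect_equal(st$medium, 134)
  expect_equal(st$long, 98)
  expect_equal(st$intra + st$sequential + st$medium + st$long, st$total)
  expect_equal(round(st$per_residue, 1), 16.7)

  # random list vs a per-record brute-force recount
  set.seed(12)
  n <- 500
  i <- sample(1:36, n, replace = TRUE); j <- sample(1:36, n, replace = TRUE)
  cat_ <- sample(c("distance", "disulfide", "dihedral"), n, replace = TRUE,
                 prob = c(0.8, 0.1, 0.1))
  rl2 <- restraint_records(i, j, category = cat_)
  st2 <- classify_restraints(rl2, 36)
  brute <- table(cut(abs(i - j)[cat_ == "distance"],
                     c(-0.5, 0.5, 1.5, 4.5, Inf)))
  expect_equal(st2$intra, unname(brute[1]), ignore_attr = TRUE)
  expect_equal(st2$sequential, unname(brute[2]), ignore_attr = TRUE)
  expect_equal(st2$medium, unname(brute[3]), ignore_attr = TRUE)
  expect_equal(st2$long, unname(brute[4]), ignore_attr = TRUE)

  expect_equal(classify_restraints(rl2[0, ], 36)$total, 0)
  expect_error(classify_restraints(restraint_records(1, 40), 36),
               "outside")
})

test_that("restraint lists round-trip through TSV", {
  rl <- restraint_records(c(1, 5, 2), c(1, 12, 19),
                          atom_i = c("HA", "HN", "SG"),
                          atom_j = c("HB2", "HA", "SG"),
                          lower = c(1.8, 1.8, 2.0),
                          upper = c(2.7, 5.0, 2.1),
                          category = c("distance", "distance", "disulfide"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_restraints(rl, f)
  back <- read_restraints(f)
  expect_equal(as.data.frame(back), as.data.frame(rl))
})

test_that("multi-model PDB IO preserves the ensemble and checks consistency", {
  ens <- make_toy_ensemble(seed = 2, n_models = 3, perturbation_sd = 0.2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, f)
  back <- read_pdb_ensemble(f)
  expect_equal(back$n_models, 3)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_equal(back$atoms$resno, ens$atoms$resno)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)  # PDB format precision
  # single-model file (no MODEL records) -> one-model ensemble
  one <- model_ensemble(ens$atoms, ens$xyz[1, , drop = FALSE])
  f1 <- withr::local_tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f1, xyz = one$xyz[1, ], resno = one$atoms$resno,
                   resid = one$atoms$resid, elety = one$atoms$elety,
                   chain = one$atoms$chain)
  expect_equal(read_pdb_ensemble(f1)$n_models, 1)
  # inconsistent atom sets across models are rejected
  lines <- readLines(f)
  drop <- grep("^ATOM", lines)
  bad <- lines[-drop[length(drop)]]  # remove last atom of last model
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bad, f2)
  expect_error(read_pdb_ensemble(f2), "inconsistent")
})

test_that("ensemble spread grows with the generator's perturbation level", {
  spread <- function(sd) mean(vapply(1:10, function(s)
    mean_coordinate_rmsd(make_toy_ensemble(seed = s, n_models = 3,
                                           perturbation_sd = sd))$mean,
    numeric(1)))
  s1 <- spread(0.05); s2 <- spread(0.15); s3 <- spread(0.4)
  expect_lt(s1, s2)
  expect_lt(s2, s3)
  # zero perturbation -> exactly superimposable models
  r0 <- mean_coordinate_rmsd(make_toy_ensemble(seed = 1, n_models = 3,
                                               perturbation_sd = 0))
  expect_equal(r0$mean, 0, tolerance = 1e-8)
})
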