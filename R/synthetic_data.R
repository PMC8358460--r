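# Seeded synthetic-data generators with known ground truth: HSQC titration
# series under fast exchange with exchange broadening, ITC thermograms, and
# toy coordinate ensembles. All generators are pure functions of
# (parameters, seed): regenerating from a manifest reproduces byte-identical
# files.

#' Ground truth for a synthetic HSQC titration
#'
#' Defines the generating model of [make_titration_fixture()]: a 1:1
#' fast-exchange titration of a fixed observed species by a receptor, with
#' per-residue maximal shift changes on a shift interface, exchange
#' broadening (intensity attenuation factor `beta`) on an intensity
#' interface, and a displacing competitor. Defaults reproduce the ClTx /
#' NRP1-b1 study conditions: Kd 143.3 uM, shift interface
#' \{2,20,21,23,25,26,28,29,34\}, intensity interface
#' \{2,25,26,27,28,35,36\}, competitor Kd 7.9 uM.
#'
#' @param kd Ligand-receptor dissociation constant (molar).
#' @param competitor_kd Competitor dissociation constant (molar).
#' @param shift_interface,intensity_interface Ground-truth residue sets.
#' @param dmax_h_range,dmax_n_range Ranges (ppm) from which per-residue
#'   maximal 1H and 15N shift changes are drawn (random sign).
#' @param beta_range Range of the residual-intensity factor `beta` for
#'   broadened residues (`beta = 1`: no broadening; intensity at full
#'   saturation is `I0 * beta`).
#' @param shift_noise_h,shift_noise_n Additive Gaussian shift noise (ppm).
#' @param intensity_noise Multiplicative log-normal intensity noise
#'   (sdlog, as a fraction).
#' @param drop_threshold Peaks below this fraction of the reference
#'   intensity are omitted (vanished-peak emulation).
#' @param sequence One-letter sequence of the observed peptide; prolines
#'   and residue 1 carry no observable amide and are excluded.
#' @param seed Integer seed.
#' @return Object of class `titration_ground_truth`.
#' @export
titration_ground_truth <- function(kd = 143.3e-6,
                                   competitor_kd = 7.9e-6,
                                   shift_interface = c(2, 20, 21, 23, 25,
                                                       26, 28, 29, 34),
                                   intensity_interface = c(2, 25, 26, 27,
                                                           28, 35, 36),
                                   dmax_h_range = c(0.28, 0.34),
                                   dmax_n_range = c(1.3, 1.6),
                                   beta_range = c(0.10, 0.25),
                                   shift_noise_h = 0.003,
                                   shift_noise_n = 0.015,
                                   intensity_noise = 0.02,
                                   drop_threshold = 0.05,
                                   sequence = cltx_sequence(),
                                   seed = 42) {
  stopifnot(kd > 0, competitor_kd > 0, all(beta_range >= 0),
            all(beta_range <= 1), shift_noise_h >= 0, intensity_noise >= 0)
  structure(as.list(environment()), class = "titration_ground_truth")
}

# Deterministic per-residue generating parameters (draws 1..k of the seed).
.truth_table <- function(truth) {
  seq_obj <- parse_sequence(truth$sequence)
  letters1 <- strsplit(seq_obj$residues, "")[[1]]
  observed <- setdiff(which(letters1 != "P"), 1L)
  n <- length(observed)
  tab <- data.frame(
    residue = observed,
    letter = letters1[observed],
    d_h = stats::runif(n, 7.5, 9.5),
    d_n = stats::runif(n, 105, 130),
    i0 = stats::runif(n, 0.8, 1.2) * 1e5,
    dmax_h = 0, dmax_n = 0, beta = 1)
  si <- tab$residue %in% truth$shift_interface
  ns <- sum(si)
  tab$dmax_h[si] <- stats::runif(ns, truth$dmax_h_range[1],
                                 truth$dmax_h_range[2]) *
    sample(c(-1, 1), ns, replace = TRUE)
  tab$dmax_n[si] <- stats::runif(ns, truth$dmax_n_range[1],
                                 truth$dmax_n_range[2]) *
    sample(c(-1, 1), ns, replace = TRUE)
  bi <- tab$residue %in% truth$intensity_interface
  tab$beta[bi] <- stats::runif(sum(bi), truth$beta_range[1],
                               truth$beta_range[2])
  tab
}

#' Generate a synthetic HSQC titration series
#'
#' Fast-exchange forward model: at each titration point the observed shift
#' is `d_free + f_bound * dmax` (per dimension) and the intensity is
#' `I0 * (1 - f_bound * (1 - beta))`, with `f_bound` from
#' [bound_fraction_1to1()] (or [competitive_equilibrium()] at competitor
#' points), plus additive shift noise and multiplicative log-normal
#' intensity noise. Peaks falling below the drop threshold are omitted.
#' With `dir` set, one Sparky-style peak list per point plus a manifest CSV
#' (filename, receptor_conc_uM, competitor_conc_uM) are written.
#'
#' @param truth A [titration_ground_truth()].
#' @param ladder Receptor concentrations (molar), non-decreasing, starting
#'   at 0; default the study ladder 0/21/34/45/57/95/125 uM.
#' @param observed_conc Observed-species concentration (molar; default
#'   55 uM).
#' @param competitor_points data.frame with columns `receptor_conc`,
#'   `competitor_conc` (molar) appended after the ladder; default one point
#'   at 125 uM receptor + 413 uM competitor. Use NULL for none.
#' @param dir Optional output directory for peak-list files + manifest.
#' @return A [titration_series()]; attributes `truth_table` (the generating
#'   per-residue parameters) and, when written, `manifest`.
#' @export
make_titration_fixture <- function(truth = titration_ground_truth(),
                                   ladder = c(0, 21, 34, 45, 57, 95,
                                              125) * 1e-6,
                                   observed_conc = 55e-6,
                                   competitor_points = data.frame(
                                     receptor_conc = 125e-6,
                                     competitor_conc = 413e-6),
                                   dir = NULL) {
  stopifnot(inherits(truth, "titration_ground_truth"),
            length(ladder) >= 1, ladder[1] == 0, !is.unsorted(ladder))
  pts_conc <- data.frame(receptor_conc = ladder, competitor_conc = 0)
  if (!is.null(competitor_points))
    pts_conc <- rbind(pts_conc, competitor_points)

  series <- withr::with_seed(truth$seed, {
    tab <- .truth_table(truth)
    points <- vector("list", nrow(pts_conc))
    for (k in seq_len(nrow(pts_conc))) {
      p <- pts_conc$receptor_conc[k]
      b <- pts_conc$competitor_conc[k]
      f <- if (b > 0) {
        st <- competitive_equilibrium(p, observed_conc, b,
                                      truth$kd, truth$competitor_kd)
        st$pa / observed_conc
      } else {
        bound_fraction_1to1(p, observed_conc, truth$kd)
      }
      d_h <- tab$d_h + f * tab$dmax_h +
        stats::rnorm(nrow(tab), 0, truth$shift_noise_h)
      d_n <- tab$d_n + f * tab$dmax_n +
        stats::rnorm(nrow(tab), 0, truth$shift_noise_n)
      inten <- tab$i0 * (1 - f * (1 - tab$beta)) *
        exp(stats::rnorm(nrow(tab), 0, truth$intensity_noise))
      keep <- inten >= truth$drop_threshold * tab$i0
      points[[k]] <- peak_list(tab$residue[keep], d_h[keep], d_n[keep],
                               inten[keep], receptor_conc = p,
                               competitor_conc = b)
    }
    s <- titration_series(observed_conc, points)
    attr(s, "truth_table") <- tab
    s
  })

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tab <- attr(series, "truth_table")
    files <- sprintf("point_%02d.list", seq_along(series$points))
    for (k in seq_along(series$points)) {
      pl <- series$points[[k]]
      write_peak_list(pl, file.path(dir, files[k]),
                      residue_letters = tab$letter[match(pl$residue,
                                                         tab$residue)])
    }
    manifest <- data.frame(
      filename = files,
      receptor_conc_uM = series$receptor_conc * 1e6,
      competitor_conc_uM = series$competitor_conc * 1e6)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
    params <- unclass(truth)
    writeLines(jsonlite::toJSON(c(list(generator = "make_titration_fixture",
                                       observed_conc = observed_conc),
                                  params),
                                auto_unbox = TRUE, digits = NA),
               file.path(dir, "manifest.json"))
    attr(series, "manifest") <- manifest
  }
  series
}

#' Read a titration series from a manifest
#'
#' Reads the peak-list files named by a manifest CSV (columns `filename`,
#' `receptor_conc_uM`, `competitor_conc_uM`) into a [titration_series()].
#'
#' @param manifest_path Path to the manifest CSV; peak-list paths are
#'   resolved relative to its directory.
#' @param observed_conc Observed-species concentration (molar).
#' @return A [titration_series()].
#' @export
read_titration_series <- function(manifest_path, observed_conc = 55e-6) {
  man <- utils::read.csv(manifest_path)
  dir <- dirname(manifest_path)
  points <- lapply(seq_len(nrow(man)), function(k)
    read_peak_list(file.path(dir, man$filename[k]),
                   receptor_conc = man$receptor_conc_uM[k] * 1e-6,
                   competitor_conc = man$competitor_conc_uM[k] * 1e-6))
  titration_series(observed_conc, points)
}

#' Generate a synthetic ITC thermogram fixture
#'
#' Wraps [simulate_thermogram()]; with `path` set, persists the thermogram
#' CSV plus a JSON manifest recording generator, seed and parameters.
#'
#' @param params A [binding_parameters()].
#' @param schedule An [injection_schedule()] (default: the study schedule —
#'   800 uM syringe into a 200 uL cell at 40 uM, 0.4 uL pre-injection plus
#'   12 x 3.22 uL, 305.15 K).
#' @param noise_sd Gaussian heat noise sd (kcal/mol).
#' @param seed Integer seed (used when `noise_sd > 0`).
#' @param path Optional CSV output path (manifest written alongside).
#' @return The simulated `thermogram`.
#' @export
make_thermogram_fixture <- function(params,
                                    schedule = injection_schedule(),
                                    noise_sd = 0, seed = 1, path = NULL) {
  tg <- simulate_thermogram(params, schedule, noise_sd = noise_sd,
                            seed = seed)
  if (!is.null(path)) {
    write_thermogram(tg, path)
    writeLines(jsonlite::toJSON(
      list(generator = "make_thermogram_fixture", seed = seed,
           noise_sd = noise_sd, params = unclass(params),
           schedule = unclass(schedule)),
      auto_unbox = TRUE, digits = NA),
      paste0(path, ".manifest.json"))
  }
  tg
}

# random proper rotation from a seeded QR decomposition
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  r <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

#' Generate a toy multi-model ensemble with known structural features
#'
#' Builds a 36-residue ClTx-like chain whose engineered coordinates
#' realise, by construction: four disulfide SG pairs at 2.05 A following
#' the ClTx connectivity (framework 1-4,2-6,3-7,5-8); two basic surface
#' clusters (\{14,15,23\} and \{25,27,36\}, ~4 A internally, 30 A apart)
#' and one hydrophobic cluster (\{6,7,8,10\}); backbone N/CA/C/O atoms on a
#' smooth helical curve. Each model adds Gaussian coordinate jitter of
#' `perturbation_sd` and an arbitrary rigid motion, so ensemble statistics
#' must superpose to recover the construction. Geometry is schematic: only
#' the features the analysis operators measure are realistic.
#'
#' @param seed Integer seed.
#' @param n_models Number of models (>= 1).
#' @param perturbation_sd Per-atom Gaussian jitter (Angstrom).
#' @param path Optional multi-model PDB output path (manifest JSON written
#'   alongside).
#' @return A `model_ensemble`.
#' @export
make_toy_ensemble <- function(seed = 1, n_models = 3, perturbation_sd = 0.1,
                              path = NULL) {
  stopifnot(n_models >= 1, perturbation_sd >= 0)
  seq_obj <- parse_sequence(cltx_sequence())
  letters1 <- strsplit(seq_obj$residues, "")[[1]]
  ss_pairs <- cltx_disulfides()

  atoms <- NULL; base <- NULL
  add_atom <- function(elety, resno, xyz) {
    atoms <<- rbind(atoms, data.frame(
      elety = elety, resid = bio3d::aa123(letters1[resno]),
      resno = resno, chain = "A"))
    base <<- rbind(base, xyz)
  }
  basic1 <- c(14, 15, 23); basic2 <- c(25, 27, 36)
  hydro <- c(6, 7, 8, 10)
  offs <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0), c(3, 3, 0))
  for (rn in seq_len(seq_obj$length)) {
    th <- 0.35 * rn
    ca <- c(10 * cos(th), 10 * sin(th), 2.0 * rn)
    add_atom("N", rn, ca + c(-0.8, -0.9, -0.5))
    add_atom("CA", rn, ca)
    add_atom("C", rn, ca + c(1.2, 0.4, 0.3))
    add_atom("O", rn, ca + c(1.5, 1.5, 0.5))
    if (letters1[rn] != "G") {
      cb <- if (rn %in% hydro)
        c(-60, -20, 0) + offs[match(rn, hydro), ]
      else ca + c(0, 0, 1.5)
      add_atom("CB", rn, cb)
    }
    if (letters1[rn] == "C") {
      p <- which(ss_pairs == rn, arr.ind = TRUE)
      ctr <- c(40 + 14 * p[1, "row"], -30, 10)
      sg <- ctr + c(if (p[1, "col"] == 1) -1.025 else 1.025, 0, 0)
      add_atom("SG", rn, sg)
    }
    if (rn %in% c(basic1, basic2)) {
      ctr <- if (rn %in% basic1) c(-30, 40, 0) else c(-30, 70, 0)
      k <- if (rn %in% basic1) match(rn, basic1) else match(rn, basic2)
      nm <- if (letters1[rn] == "R") "CZ" else "NZ"
      add_atom(nm, rn, ctr + offs[k, ])
    }
  }
  rownames(atoms) <- NULL

  xyz <- withr::with_seed(seed, {
    t(vapply(seq_len(n_models), function(m) {
      co <- base + matrix(stats::rnorm(length(base), 0, perturbation_sd),
                          nrow(base), 3)
      rot <- .random_rotation()
      shift <- stats::runif(3, -20, 20)
      as.vector(t(sweep(co %*% rot, 2, shift, "+")))
    }, numeric(3 * nrow(base))))
  })
  ens <- model_ensemble(atoms, xyz)
  if (!is.null(path)) {
    write_ensemble_pdb(ens, path)
    writeLines(jsonlite::toJSON(
      list(generator = "make_toy_ensemble", seed = seed,
           n_models = n_models, perturbation_sd = perturbation_sd),
      auto_unbox = TRUE, digits = NA),
      paste0(path, ".manifest.json"))
  }
  ens
}

#' Write a multi-model ensemble as PDB
#'
#' Each model is emitted between MODEL/ENDMDL records (bio3d writes the
#' ATOM records).
#'
#' @param ens A `model_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "model_ensemble"))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  out <- character(0)
  for (m in seq_len(ens$n_models)) {
    bio3d::write.pdb(file = tmp, xyz = ens$xyz[m, ],
                     resno = ens$atoms$resno, resid = ens$atoms$resid,
                     elety = ens$atoms$elety, chain = ens$atoms$chain)
    lines <- readLines(tmp)
    lines <- lines[grepl("^ATOM|^HETATM|^TER", lines)]
    out <- c(out, sprintf("MODEL     %4d", m), lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
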