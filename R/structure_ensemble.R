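# Multi-model ensemble statistics: superposition, RMSD to the mean
# coordinates, disulfide detection, surface-patch clustering and restraint
# bookkeeping. PDB I/O goes through bio3d; the Kabsch superposition itself
# is implemented here (base SVD) so its numerical behaviour is the
# package's own.

#' Read a multi-model PDB file as an ensemble
#'
#' Parses ATOM records (via bio3d), with MODEL/ENDMDL blocks giving one
#' model each; a file without MODEL records yields a one-model ensemble.
#' All models must share the same residue numbering and atom-name set; a
#' discrepancy is rejected with the differing models listed.
#'
#' @param path PDB file path.
#' @return Object of class `model_ensemble`: list with `atoms` (data.frame
#'   `elety`, `resid`, `resno`, `chain` shared by all models), `xyz`
#'   (matrix, one row of length 3*n_atoms per model) and `n_models`.
#' @export
read_pdb_ensemble <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  if (length(starts) > 1) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records")
    keys <- lapply(seq_along(starts), function(k) {
      blk <- lines[starts[k]:ends[k]]
      at <- blk[grepl("^ATOM|^HETATM", blk)]
      paste(substr(at, 13, 27))  # atom name, resname, chain, resno
    })
    bad <- which(vapply(keys, function(k) !identical(k, keys[[1]]),
                        logical(1)))
    if (length(bad) > 0)
      stop(sprintf(
        "inconsistent atom sets across models: model(s) %s differ from model 1",
        paste(bad + 1L, collapse = ", ")))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  sel <- which(pdb$atom$type %in% c("ATOM", "HETATM"))
  atoms <- pdb$atom[sel, c("elety", "resid", "resno", "chain")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms,
                 xyz = xyz[, as.vector(rbind(sel * 3 - 2, sel * 3 - 1,
                                             sel * 3)), drop = FALSE],
                 n_models = nrow(xyz)),
            class = "model_ensemble")
}

#' Build an ensemble from in-memory coordinates
#'
#' @param atoms data.frame with columns `elety`, `resid`, `resno`, `chain`.
#' @param xyz Matrix with one row per model, columns `x1,y1,z1,x2,...`, or a
#'   list of n_atoms x 3 coordinate matrices.
#' @return A `model_ensemble`.
#' @export
model_ensemble <- function(atoms, xyz) {
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.vector(t(m))))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  stopifnot(ncol(xyz) == 3 * nrow(atoms), all(is.finite(xyz)))
  structure(list(atoms = atoms, xyz = xyz, n_models = nrow(xyz)),
            class = "model_ensemble")
}

#' @export
print.model_ensemble <- function(x, ...) {
  cat(sprintf("<model_ensemble> %d model(s), %d atoms, residues %d-%d\n",
              x$n_models, nrow(x$atoms), min(x$atoms$resno),
              max(x$atoms$resno)))
  invisible(x)
}

# n_atoms x 3 coordinate matrix of one model
model_coords <- function(ens, model = 1) {
  matrix(ens$xyz[model, ], ncol = 3, byrow = TRUE)
}

#' Select atoms of an ensemble
#'
#' @param ens A `model_ensemble`.
#' @param selection `"backbone"` (N, CA, C, O), `"heavy"` (all
#'   non-hydrogen), `"all"`, or a character vector of atom names.
#' @param resno Optional residue-number subset.
#' @param chain Optional chain subset.
#' @return Integer atom indices.
#' @export
atom_select <- function(ens, selection = "backbone", resno = NULL,
                        chain = NULL) {
  a <- ens$atoms
  idx <- switch(selection[1],
    backbone = which(a$elety %in% c("N", "CA", "C", "O")),
    heavy = which(!grepl("^[0-9]*H", a$elety)),
    all = seq_len(nrow(a)),
    which(a$elety %in% selection))
  if (!is.null(resno)) idx <- idx[a$resno[idx] %in% resno]
  if (!is.null(chain)) idx <- idx[a$chain[idx] %in% chain]
  idx
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation (det = +1) and translation minimising the RMSD
#' between paired coordinate sets, via SVD of the covariance matrix.
#' Requires at least 3 non-collinear atom pairs.
#'
#' @param mobile,reference n x 3 coordinate matrices (paired rows).
#' @return List with `rotation` (3 x 3, applied as `x %*% rotation`),
#'   `translation`, `rmsd` (post-fit, in the same units), and `fitted` (the
#'   transformed mobile coordinates).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  if (nrow(mobile) < 3) stop("at least 3 atom pairs are required")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  mm <- sweep(mobile, 2, cm); rr <- sweep(reference, 2, cr)
  sv <- svd(crossprod(mm, rr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate (collinear) geometry: superposition is not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- sweep(mm %*% rot, 2, cr, "+")
  list(rotation = rot, translation = cr - drop(cm %*% rot),
       rmsd = sqrt(mean(rowSums((fitted - reference)^2))),
       fitted = fitted)
}

#' RMSD of an ensemble to its mean coordinates
#'
#' Iteratively superposes every model onto the running mean over the
#' selected atoms, recomputing the mean until it shifts by less than `tol`
#' (RMS over selected coordinates), then reports the per-model RMSDs to the
#' converged mean as mean +/- sample standard deviation (n-1).
#'
#' @param ens A `model_ensemble` with at least 2 models.
#' @param selection,resno,chain Passed to [atom_select()].
#' @param tol Convergence tolerance on the mean coordinates (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return List with `mean` and `sd` of the per-model RMSDs, `per_model`,
#'   the converged `mean_xyz` (n_sel x 3) and `iterations`.
#' @export
mean_coordinate_rmsd <- function(ens, selection = "backbone", resno = NULL,
                                 chain = NULL, tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(ens, "model_ensemble"))
  if (ens$n_models < 2) stop("at least 2 models are required")
  idx <- atom_select(ens, selection, resno, chain)
  if (length(idx) < 3) stop("selection has fewer than 3 atoms")
  coords <- lapply(seq_len(ens$n_models),
                   function(m) model_coords(ens, m)[idx, , drop = FALSE])
  ref <- coords[[1]]
  for (it in seq_len(max_iter)) {
    fitted <- lapply(coords, function(x) superpose(x, ref)$fitted)
    new_mean <- Reduce(`+`, fitted) / length(fitted)
    shift <- sqrt(mean((new_mean - ref)^2))
    ref <- new_mean
    if (shift < tol) {
      per_model <- vapply(fitted, function(x)
        sqrt(mean(rowSums((x - ref)^2))), numeric(1))
      return(list(mean = mean(per_model), sd = stats::sd(per_model),
                  per_model = per_model, mean_xyz = ref, iterations = it))
    }
  }
  stop(sprintf(
    "mean coordinates did not converge in %d iterations (last shift %.3e)",
    max_iter, shift))
}

#' Detect disulfide bonds from SG-SG contacts
#'
#' Pairs cysteine SG atoms that are mutual nearest neighbours below the
#' cutoff (default 2.5 A: covalent S-S is ~2.05 A, with margin for
#' coordinate noise). An SG with more than one sub-cutoff partner none of
#' which is mutual is reported in `ambiguous` rather than silently
#' assigned. The result is independent of atom ordering.
#'
#' @param ens A `model_ensemble`.
#' @param model Model index to analyse.
#' @param cutoff SG-SG distance cutoff in Angstrom.
#' @return A `disulfide_topology` (residue-number pairs + ordinal framework
#'   string over the model's cysteines), with an `ambiguous` attribute
#'   listing unresolved SG residue numbers (empty when clean).
#' @export
detect_disulfides <- function(ens, model = 1, cutoff = 2.5) {
  stopifnot(inherits(ens, "model_ensemble"))
  a <- ens$atoms
  sg <- which(a$elety == "SG" & a$resid %in% c("CYS", "CYX"))
  cys_resno <- sort(unique(a$resno[a$resid %in% c("CYS", "CYX")]))
  empty <- structure(list(pairs = matrix(integer(0), 0, 2,
                                         dimnames = list(NULL, c("i", "j"))),
                          framework = ""),
                     class = "disulfide_topology")
  attr(empty, "ambiguous") <- integer(0)
  if (length(sg) < 2) return(empty)
  xyz <- model_coords(ens, model)[sg, , drop = FALSE]
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  nearest <- apply(dm, 1, which.min)
  pairs <- list()
  ambiguous <- integer(0)
  for (i in seq_along(sg)) {
    j <- nearest[i]
    if (dm[i, j] >= cutoff) next
    if (nearest[j] == i) {
      if (i < j) pairs[[length(pairs) + 1]] <- c(a$resno[sg[i]],
                                                 a$resno[sg[j]])
    } else if (sum(dm[i, ] < cutoff) >= 2) {
      ambiguous <- c(ambiguous, a$resno[sg[i]])
    }
  }
  if (length(pairs) == 0) {
    attr(empty, "ambiguous") <- unique(ambiguous)
    return(empty)
  }
  pm <- do.call(rbind, pairs)
  pm <- t(apply(pm, 1, sort))
  ord <- matrix(match(pm, cys_resno), ncol = 2)
  o <- order(ord[, 1])
  pm <- pm[o, , drop = FALSE]; ord <- ord[o, , drop = FALSE]
  colnames(pm) <- c("i", "j")
  out <- structure(list(pairs = pm,
                        framework = paste(ord[, 1], ord[, 2],
                                          sep = "-", collapse = ",")),
                   class = "disulfide_topology")
  attr(out, "ambiguous") <- unique(ambiguous)
  out
}

#' Restraint records
#'
#' A restraint list is a data.frame with columns `i`, `j` (residue
#' numbers), `atom_i`, `atom_j` (optional, NA allowed), `lower`, `upper`
#' (Angstrom) and `category` (`"distance"`, `"disulfide"` or
#' `"dihedral"`). `read_restraints()`/`write_restraints()` exchange it as
#' TSV with exactly those columns.
#'
#' @param i,j Residue numbers.
#' @param atom_i,atom_j Atom names (PDB convention) or NA.
#' @param lower,upper Bounds in Angstrom, `0 <= lower <= upper`.
#' @param category Category tag per record.
#' @return data.frame of class `restraint_list`.
#' @export
restraint_records <- function(i, j, atom_i = NA, atom_j = NA,
                              lower = 0, upper = Inf,
                              category = "distance") {
  d <- data.frame(i = as.integer(i), j = as.integer(j),
                  atom_i = atom_i, atom_j = atom_j,
                  lower = lower, upper = upper, category = category)
  if (any(d$lower < 0) || any(d$lower > d$upper))
    stop("bounds must satisfy 0 <= lower <= upper")
  if (!all(d$category %in% c("distance", "disulfide", "dihedral")))
    stop("unknown restraint category")
  class(d) <- c("restraint_list", "data.frame")
  d
}

#' @rdname restraint_records
#' @param path TSV path.
#' @export
read_restraints <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  restraint_records(d$i, d$j, d$atom_i, d$atom_j, d$lower, d$upper,
                    d$category)
}

#' @rdname restraint_records
#' @param restraints A `restraint_list`.
#' @export
write_restraints <- function(restraints, path) {
  utils::write.table(restraints, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Classify restraints by sequence separation
#'
#' Bins distance restraints by `|i - j|`: intra-residue (0), sequential
#' (1), medium range (2-4) and long range (>= 5); the four bins partition
#' the distance restraints exactly. Restraints per residue is the total
#' over all categories (distance + disulfide + dihedral) divided by the
#' sequence length.
#'
#' @param restraints A `restraint_list` (or data.frame with its columns).
#' @param seq_length Number of residues.
#' @return Object of class `restraint_stats`: list of counts (`total`,
#'   `intra`, `sequential`, `medium`, `long`, `disulfide`, `dihedral`) and
#'   `per_residue`.
#' @export
classify_restraints <- function(restraints, seq_length) {
  stopifnot(seq_length >= 1)
  if (nrow(restraints) > 0 &&
      (any(restraints$i < 1) || any(restraints$i > seq_length) ||
       any(restraints$j < 1) || any(restraints$j > seq_length)))
    stop("restraint references a residue outside 1..seq_length")
  dist <- restraints[restraints$category == "distance", , drop = FALSE]
  sep <- abs(dist$i - dist$j)
  counts <- list(total = nrow(dist),
                 intra = sum(sep == 0),
                 sequential = sum(sep == 1),
                 medium = sum(sep > 1 & sep < 5),
                 long = sum(sep >= 5),
                 disulfide = sum(restraints$category == "disulfide"),
                 dihedral = sum(restraints$category == "dihedral"))
  counts$per_residue <- (counts$total + counts$disulfide + counts$dihedral) /
    seq_length
  structure(counts, class = "restraint_stats")
}

#' @export
print.restraint_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<restraint_stats>\n  distance: %d (intra %d, sequential %d, ",
    "medium %d, long %d)\n  disulfide: %d, dihedral: %d\n",
    "  restraints per residue: %.1f\n"),
    x$total, x$intra, x$sequential, x$medium, x$long, x$disulfide,
    x$dihedral, x$per_residue))
  invisible(x)
}

# Representative point per residue for patch clustering: Arg CZ / Lys NZ
# for the basic class; side-chain heavy-atom centroid otherwise.
.patch_points <- function(ens, model, kind, residue_classes) {
  a <- ens$atoms
  xyz <- model_coords(ens, model)
  classes3 <- vapply(residue_classes, function(x)
    if (nchar(x) == 1) bio3d::aa123(x) else toupper(x), character(1))
  members <- unique(a$resno[a$resid %in% classes3])
  pts <- NULL; resnos <- integer(0)
  for (rn in sort(members)) {
    ri <- which(a$resno == rn)
    resid <- a$resid[ri[1]]
    if (kind == "basic") {
      rep_name <- if (resid == "ARG") "CZ" else "NZ"
      k <- ri[a$elety[ri] == rep_name]
      if (length(k) == 0) {
        warning(sprintf("residue %d (%s) lacks atom %s; skipped",
                        rn, resid, rep_name))
        next
      }
      p <- xyz[k[1], ]
    } else {
      sc <- ri[!a$elety[ri] %in% c("N", "CA", "C", "O") &
                 !grepl("^[0-9]*H", a$elety[ri])]
      if (length(sc) == 0) {
        warning(sprintf("residue %d (%s) has no side-chain atoms; skipped",
                        rn, resid))
        next
      }
      p <- colMeans(xyz[sc, , drop = FALSE])
    }
    pts <- rbind(pts, p); resnos <- c(resnos, rn)
  }
  list(points = pts, resno = resnos)
}

#' Find surface patches by single-linkage clustering
#'
#' Clusters representative side-chain points of a residue class (basic:
#' Arg CZ / Lys NZ; hydrophobic: side-chain heavy-atom centroids) by single
#' linkage; groups of two or more residues within `link_cutoff` of a chain
#' of neighbours form a patch. Patches are ordered by first residue;
#' membership is invariant to residue input order, and shrinking the gap
#' between two patches below the cutoff merges them without splitting
#' existing clusters (single-linkage monotonicity).
#'
#' @param ens A `model_ensemble`.
#' @param model Model index.
#' @param kind `"basic"` or `"hydrophobic"`.
#' @param residue_classes One- or three-letter residue codes defining the
#'   class; defaults: basic `R`, `K`; hydrophobic `F`, `T`, `H`.
#' @param link_cutoff Single-linkage distance cutoff in Angstrom
#'   (default 10).
#' @return List of `surface_patch` objects (each: `kind`, `members`
#'   residue numbers, `centroid`).
#' @export
find_patches <- function(ens, model = 1, kind = c("basic", "hydrophobic"),
                         residue_classes = NULL, link_cutoff = 10) {
  kind <- match.arg(kind)
  if (is.null(residue_classes))
    residue_classes <- if (kind == "basic") c("R", "K") else c("F", "T", "H")
  pp <- .patch_points(ens, model, kind, residue_classes)
  if (is.null(pp$points) || nrow(pp$points) < 2) return(list())
  cl <- if (nrow(pp$points) == 2) {
    if (stats::dist(pp$points)[1] <= link_cutoff) c(1, 1) else c(1, 2)
  } else {
    stats::cutree(stats::hclust(stats::dist(pp$points), method = "single"),
                  h = link_cutoff)
  }
  patches <- list()
  for (g in unique(cl)) {
    m <- which(cl == g)
    if (length(m) < 2) next
    patches[[length(patches) + 1]] <- structure(
      list(kind = kind, members = sort(pp$resno[m]),
           centroid = colMeans(pp$points[m, , drop = FALSE])),
      class = "surface_patch")
  }
  patches[order(vapply(patches, function(p) min(p$members), numeric(1)))]
}

#' @export
print.surface_patch <- function(x, ...) {
  cat(sprintf("<surface_patch> %s: residues %s\n", x$kind,
              paste(x$members, collapse = ", ")))
  invisible(x)
}
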