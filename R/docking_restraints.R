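# Derivation, CNS/HADDOCK-style export and geometric checking of docking
# restraints from a CSP interface map.

#' Unambiguous distance restraints
#'
#' @param segid_i,resid_i,atom_i First partner (segid, residue number, atom
#'   name in PDB convention).
#' @param segid_j,resid_j,atom_j Second partner.
#' @param lower,upper Distance bounds in Angstrom, `lower < upper`.
#' @return data.frame of class `unambiguous_restraints`.
#' @export
unambiguous_restraints <- function(segid_i, resid_i, atom_i,
                                   segid_j, resid_j, atom_j,
                                   lower, upper) {
  stopifnot(all(lower < upper), all(lower >= 0))
  if (any(!grepl("^[A-Z0-9']+$", c(atom_i, atom_j))))
    stop("invalid atom name")
  structure(data.frame(segid_i = segid_i, resid_i = as.integer(resid_i),
                       atom_i = atom_i, segid_j = segid_j,
                       resid_j = as.integer(resid_j), atom_j = atom_j,
                       lower = lower, upper = upper),
            class = c("unambiguous_restraints", "data.frame"))
}

#' The ClTx/NRP1-b1 unambiguous restraint set
#'
#' The three unambiguous distance restraints that orient the toxin's basic
#' residues against the receptor's conserved C-terminal-arginine pocket,
#' plus the toxin segments treated as flexible during semi-flexible
#' refinement (residues 24-28 and 35-36, the stretches whose glycine and
#' cysteine amides suggest conformational exchange):
#' \itemize{
#'   \item ClTx Arg36 carbonyl C to receptor Trp301 indole NE1, 4.0-5.5 A;
#'   \item ClTx Arg36 CZ to receptor residue 319 side-chain CG, 5.0-7.0 A;
#'   \item ClTx Lys27 NZ to receptor residue 319 side-chain CG, bounds
#'     configurable (default 3.0-5.0 A, a salt-bridge-compatible range; no
#'     reference bounds exist for this contact).
#' }
#' ClTx is segid A and the receptor segid B by default.
#'
#' @param k27_bounds Length-2 numeric: bounds of the Lys27 NZ restraint.
#' @param segid_ligand,segid_receptor Segid mapping.
#' @return List with `unambiguous` (an [unambiguous_restraints()] table)
#'   and `flexible` (a named list of residue-range matrices per segid).
#' @export
cltx_nrp1_restraints <- function(k27_bounds = c(3.0, 5.0),
                                 segid_ligand = "A", segid_receptor = "B") {
  stopifnot(length(k27_bounds) == 2, k27_bounds[1] < k27_bounds[2])
  un <- unambiguous_restraints(
    segid_i = segid_ligand, resid_i = c(36L, 36L, 27L),
    atom_i = c("C", "CZ", "NZ"),
    segid_j = segid_receptor, resid_j = c(301L, 319L, 319L),
    atom_j = c("NE1", "CG", "CG"),
    lower = c(4.0, 5.0, k27_bounds[1]),
    upper = c(5.5, 7.0, k27_bounds[2]))
  flex <- stats::setNames(
    list(matrix(c(24L, 28L, 35L, 36L), ncol = 2, byrow = TRUE,
                dimnames = list(NULL, c("first", "last")))),
    segid_ligand)
  list(unambiguous = un, flexible = flex)
}

#' Ambiguous interaction restraints
#'
#' One active residue restrained to any member of a candidate target set on
#' the partner molecule, with the conventional 2.0 A effective upper bound
#' between any atoms of the selections.
#'
#' @param active data.frame with columns `segid`, `resid` (one row per
#'   active residue).
#' @param targets List (parallel to the rows of `active`) of data.frames
#'   with columns `segid`, `resid` giving the candidate set; a single
#'   data.frame is recycled for all active residues.
#' @param upper Effective upper bound (Angstrom).
#' @return Object of class `ambiguous_restraints`.
#' @export
ambiguous_restraints <- function(active, targets, upper = 2.0) {
  if (is.data.frame(targets)) targets <- rep(list(targets), nrow(active))
  stopifnot(nrow(active) == length(targets), upper > 0,
            all(vapply(targets, nrow, integer(1)) > 0))
  structure(list(active = active, targets = targets, upper = upper),
            class = "ambiguous_restraints")
}

#' Derive active and passive residues from a CSP interface map
#'
#' Active residues are the significance-flagged residues (union of the
#' shift- and intensity-perturbed sets) that pass a surface-exposure proxy:
#' the number of heavy atoms within `neighbor_radius` of the residue's
#' side-chain centroid must stay below `exposure_cutoff` (buried residues
#' have crowded neighbourhoods). Passive residues are the exposed sequence
#' neighbours (+/- 2) of active residues that are not themselves active.
#'
#' @param csp A `csp_result` from [analyze_titration()], or a list with
#'   `flagged` residue numbers.
#' @param ens A `model_ensemble` of the free ligand.
#' @param model Model index used for the exposure proxy.
#' @param exposure_cutoff Neighbour-count threshold (default 35).
#' @param neighbor_radius Radius of the neighbour count in Angstrom
#'   (default 8).
#' @return List with `active` and `passive` integer residue vectors and the
#'   per-residue `neighbor_counts`.
#' @export
derive_active_passive <- function(csp, ens, model = 1, exposure_cutoff = 35,
                                  neighbor_radius = 8) {
  flagged <- if (inherits(csp, "csp_result"))
    sort(union(csp$shift_flags$flagged, csp$intensity_flags$flagged))
  else sort(unique(csp$flagged))
  if (length(flagged) == 0)
    return(list(active = integer(0), passive = integer(0),
                neighbor_counts = integer(0)))
  a <- ens$atoms
  missing <- setdiff(flagged, unique(a$resno))
  if (length(missing) > 0)
    stop(sprintf("model lacks flagged residue(s) %s",
                 paste(missing, collapse = ", ")))
  xyz <- model_coords(ens, model)
  heavy <- atom_select(ens, "heavy")
  resnos <- sort(unique(a$resno))
  counts <- vapply(resnos, function(rn) {
    ri <- which(a$resno == rn)
    sc <- ri[!a$elety[ri] %in% c("N", "C", "O") &
               !grepl("^[0-9]*H", a$elety[ri])]
    if (length(sc) == 0) sc <- ri
    ctr <- colMeans(xyz[sc, , drop = FALSE])
    sum(sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - ctr)^2)) <=
          neighbor_radius)
  }, numeric(1))
  names(counts) <- resnos
  exposed <- resnos[counts < exposure_cutoff]
  active <- intersect(flagged, exposed)
  passive <- setdiff(
    intersect(unique(unlist(lapply(active, function(r) r + (-2:2)))),
              exposed),
    active)
  list(active = sort(active), passive = sort(passive),
       neighbor_counts = counts)
}

.fmt_unambiguous <- function(r) {
  d <- (r$lower + r$upper) / 2
  dm <- (r$upper - r$lower) / 2
  sprintf(
    "assign (segid %s and resid %d and name %s) (segid %s and resid %d and name %s) %.2f %.2f %.2f",
    r$segid_i, r$resid_i, r$atom_i, r$segid_j, r$resid_j, r$atom_j,
    d, dm, dm)
}

#' Write restraints in CNS/HADDOCK table syntax
#'
#' Unambiguous restraints become `assign (sel_i) (sel_j) d dminus dplus`
#' with `d = (lower+upper)/2` and `dminus = dplus = (upper-lower)/2` (two
#' decimals); ambiguous restraints OR their target selections. The file
#' round-trips through [parse_tbl()] byte-identically.
#'
#' @param unambiguous An [unambiguous_restraints()] table (or NULL).
#' @param ambiguous An [ambiguous_restraints()] object (or NULL).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tbl <- function(unambiguous = NULL, ambiguous = NULL, path) {
  lines <- character(0)
  if (!is.null(unambiguous) && nrow(unambiguous) > 0) {
    if (length(unambiguous$active %||% NULL))
      stop("unambiguous must be an unambiguous_restraints table")
    lines <- c(lines, vapply(seq_len(nrow(unambiguous)), function(k)
      .fmt_unambiguous(unambiguous[k, ]), character(1)))
  }
  if (!is.null(ambiguous)) {
    if (nrow(ambiguous$active) == 0) stop("no interface: no active residues")
    for (k in seq_len(nrow(ambiguous$active))) {
      tg <- ambiguous$targets[[k]]
      sel <- paste(sprintf("(segid %s and resid %d)", tg$segid, tg$resid),
                   collapse = " or ")
      lines <- c(lines, sprintf(
        "assign (segid %s and resid %d) (%s) %.2f %.2f 0.00",
        ambiguous$active$segid[k], ambiguous$active$resid[k], sel,
        ambiguous$upper, ambiguous$upper))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Parse a CNS/HADDOCK restraint table written by [write_tbl()]
#'
#' @param path File path.
#' @return List with `unambiguous` and `ambiguous` components (either may
#'   be NULL).
#' @export
parse_tbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  un_pat <- paste0(
    "^assign \\(segid (\\S+) and resid (\\d+) and name (\\S+)\\) ",
    "\\(segid (\\S+) and resid (\\d+) and name (\\S+)\\) ",
    "([0-9.]+) ([0-9.]+) ([0-9.]+)$")
  amb_pat <- "^assign \\(segid (\\S+) and resid (\\d+)\\) \\((.*)\\) ([0-9.]+) ([0-9.]+) ([0-9.]+)$"
  un_rows <- list(); amb_active <- list(); amb_targets <- list()
  amb_upper <- NA_real_
  for (ln in lines) {
    m <- regmatches(ln, regexec(un_pat, ln))[[1]]
    if (length(m) == 10) {
      d <- as.numeric(m[8]); dm <- as.numeric(m[9]); dp <- as.numeric(m[10])
      un_rows[[length(un_rows) + 1]] <- data.frame(
        segid_i = m[2], resid_i = as.integer(m[3]), atom_i = m[4],
        segid_j = m[5], resid_j = as.integer(m[6]), atom_j = m[7],
        lower = d - dm, upper = d + dp)
      next
    }
    m <- regmatches(ln, regexec(amb_pat, ln))[[1]]
    if (length(m) == 7) {
      amb_active[[length(amb_active) + 1]] <-
        data.frame(segid = m[2], resid = as.integer(m[3]))
      tg <- regmatches(m[4],
                       gregexpr("segid (\\S+) and resid (\\d+)", m[4]))[[1]]
      parts <- do.call(rbind, strsplit(sub("segid ", "", tg), " and resid "))
      amb_targets[[length(amb_targets) + 1]] <-
        data.frame(segid = parts[, 1], resid = as.integer(parts[, 2]))
      amb_upper <- as.numeric(m[5])
      next
    }
    stop(sprintf("unparseable restraint line: %s", ln))
  }
  un <- if (length(un_rows) > 0) {
    d <- do.call(rbind, un_rows)
    unambiguous_restraints(d$segid_i, d$resid_i, d$atom_i, d$segid_j,
                           d$resid_j, d$atom_j, d$lower, d$upper)
  }
  amb <- if (length(amb_active) > 0)
    ambiguous_restraints(do.call(rbind, amb_active), amb_targets, amb_upper)
  list(unambiguous = un, ambiguous = amb)
}

#' Check restraint satisfaction on complex models
#'
#' Measures the Euclidean distance of every unambiguous restraint in every
#' model of a complex ensemble; the violation is
#' `max(0, d - upper, lower - d)`. Segids map to PDB chains. A missing atom
#' yields an error entry for that restraint while the others are still
#' evaluated. Distances are invariant under any rigid motion of the whole
#' complex.
#'
#' @param ens A `model_ensemble` of the complex (chains matching the
#'   restraint segids).
#' @param restraints An [unambiguous_restraints()] table.
#' @return data.frame with columns `model`, `restraint`, `distance`,
#'   `satisfied`, `violation`, `error`.
#' @export
check_violations <- function(ens, restraints) {
  stopifnot(inherits(ens, "model_ensemble"))
  a <- ens$atoms
  find_atom <- function(segid, resid, atom) {
    which(a$chain == segid & a$resno == resid & a$elety == atom)
  }
  out <- list()
  for (m in seq_len(ens$n_models)) {
    xyz <- model_coords(ens, m)
    for (k in seq_len(nrow(restraints))) {
      r <- restraints[k, ]
      i <- find_atom(r$segid_i, r$resid_i, r$atom_i)
      j <- find_atom(r$segid_j, r$resid_j, r$atom_j)
      if (length(i) != 1 || length(j) != 1) {
        out[[length(out) + 1]] <- data.frame(
          model = m, restraint = k, distance = NA_real_, satisfied = NA,
          violation = NA_real_,
          error = sprintf("atom %s not found",
                          if (length(i) != 1) r$atom_i else r$atom_j))
        next
      }
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      out[[length(out) + 1]] <- data.frame(
        model = m, restraint = k, distance = d,
        satisfied = d >= r$lower && d <= r$upper,
        violation = max(0, d - r$upper, r$lower - d), error = NA_character_)
    }
  }
  do.call(rbind, out)
}
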