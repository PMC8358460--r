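# Elemental composition bookkeeping for peptide masses.
#
# Monoisotopic masses: CODATA/IUPAC values to >= 5 decimals. Average masses:
# IUPAC standard atomic weights. 15N/13C labelling is modelled as 100%
# enrichment (labelled growth medium), so a label simply swaps the mass of
# every N (or C) atom.

.ELEMENTS <- c("C", "H", "N", "O", "S")

.MONO_MASS <- c(C = 12.0000000, H = 1.0078250, N = 14.0030740,
                O = 15.9949146, S = 31.9720707)
.AVG_MASS <- c(C = 12.0107, H = 1.00794, N = 14.0067,
               O = 15.9994, S = 32.065)
.MASS_15N <- 15.0001089
.MASS_13C <- 13.0033548

# Residue (= amino acid - H2O) elemental compositions, canonical 20.
.RESIDUE_COMP <- local({
  tab <- rbind(
    A = c(3, 5, 1, 1, 0),  R = c(6, 12, 4, 1, 0), N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),  C = c(3, 5, 1, 1, 1),  E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),  G = c(2, 3, 1, 1, 0),  H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0), L = c(6, 11, 1, 1, 0), K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),  F = c(9, 9, 1, 1, 0),  P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),  T = c(4, 7, 1, 2, 0),  W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),  V = c(5, 9, 1, 1, 0))
  colnames(tab) <- .ELEMENTS
  tab
})

#' Parse a one-letter peptide sequence
#'
#' Accepts a raw one-letter amino-acid string or the text of a single-record
#' FASTA entry (a leading `>` header line is stripped). Case-insensitive;
#' whitespace is ignored. Non-canonical letters are rejected with the
#' offending position named.
#'
#' @param text Character scalar: one-letter sequence, or single-record FASTA
#'   text (possibly multi-line).
#' @return An object of class `peptide_sequence`: a list with elements
#'   `residues` (upper-case one-letter string), `length`, and
#'   `cys_positions` (ordered 1-based residue numbers of cysteines).
#' @examples
#' seq <- parse_sequence(cltx_sequence())
#' seq$cys_positions
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) > 0 && startsWith(trimws(lines[1]), ">")) {
    lines <- lines[-1]
    if (any(startsWith(trimws(lines), ">")))
      stop("only single-record FASTA input is supported")
  }
  res <- toupper(gsub("[[:space:]]", "", paste(lines, collapse = "")))
  if (nchar(res) < 1L) stop("empty sequence")
  letters1 <- strsplit(res, "")[[1]]
  bad <- which(!letters1 %in% rownames(.RESIDUE_COMP))
  if (length(bad) > 0)
    stop(sprintf("non-canonical residue '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  structure(list(residues = res,
                 length = nchar(res),
                 cys_positions = which(letters1 == "C")),
            class = "peptide_sequence")
}

#' @export
print.peptide_sequence <- function(x, ...) {
  cat(sprintf("<peptide_sequence> %d residues, %d cysteines\n  %s\n",
              x$length, length(x$cys_positions), x$residues))
  invisible(x)
}

#' The chlorotoxin primary sequence
#'
#' The 36-residue chlorotoxin (ClTx) sequence, with cysteines at positions
#' 2, 5, 16, 19, 20, 28, 33 and 35.
#'
#' @return Character scalar (one-letter code).
#' @export
cltx_sequence <- function() "MCMPCFTTDHQMARKCDDCCGGKGRGKCYGPQCLCR"

#' The chlorotoxin disulfide connectivity
#'
#' Residue-number pairs Cys2-Cys19, Cys5-Cys28, Cys16-Cys33 and Cys20-Cys35,
#' i.e. a 1-4, 2-6, 3-7, 5-8 cystine framework.
#'
#' @return Two-column integer matrix of residue-number pairs.
#' @export
cltx_disulfides <- function() {
  cbind(i = c(2L, 5L, 16L, 20L), j = c(19L, 28L, 33L, 35L))
}

#' Isotope-labelling and terminus scheme
#'
#' @param label_15N,label_13C Logical; uniform 100% enrichment.
#' @param c_terminal_amide Logical; `TRUE` for a C-terminal amide, `FALSE`
#'   (default) for the free acid (the "deamidated" form).
#' @return An object of class `isotope_scheme`.
#' @export
isotope_scheme <- function(label_15N = FALSE, label_13C = FALSE,
                           c_terminal_amide = FALSE) {
  stopifnot(is.logical(label_15N), is.logical(label_13C),
            is.logical(c_terminal_amide))
  structure(list(label_15N = label_15N, label_13C = label_13C,
                 c_terminal_amide = c_terminal_amide),
            class = "isotope_scheme")
}

# Elemental composition of the whole (oxidised, possibly amidated) peptide.
peptide_composition <- function(seq, scheme = isotope_scheme(),
                                n_disulfides = 0) {
  seq <- as_peptide_sequence(seq)
  if (2L * n_disulfides > length(seq$cys_positions))
    stop(sprintf("%d disulfides require %d cysteines but sequence has %d",
                 n_disulfides, 2L * n_disulfides, length(seq$cys_positions)))
  letters1 <- strsplit(seq$residues, "")[[1]]
  comp <- colSums(.RESIDUE_COMP[letters1, , drop = FALSE])
  comp <- comp + c(C = 0, H = 2, N = 0, O = 1, S = 0)  # + H2O
  comp["H"] <- comp["H"] - 2 * n_disulfides            # each S-S loses 2 H
  if (scheme$c_terminal_amide)                          # -OH +NH2
    comp <- comp + c(C = 0, H = 1, N = 1, O = -1, S = 0)
  comp
}

as_peptide_sequence <- function(x) {
  if (inherits(x, "peptide_sequence")) x else parse_sequence(x)
}

.comp_mass <- function(comp, masses, scheme) {
  m <- sum(comp * masses[names(comp)])
  if (scheme$label_15N) m <- m + comp["N"] * (.MASS_15N - masses["N"])
  if (scheme$label_13C) m <- m + comp["C"] * (.MASS_13C - masses["C"])
  unname(m)
}

#' Neutral peptide mass
#'
#' Mass of the neutral peptide from a per-residue elemental-composition
#' table: sum of residue compositions plus H2O, minus two hydrogens per
#' disulfide, with the C-terminal amide (if any) as the elemental
#' substitution -OH +NH2. Uniform 15N and/or 13C labelling replaces the mass
#' of every nitrogen/carbon atom.
#'
#' `monoisotopic_mass()` uses monoisotopic atomic masses and
#' `average_mass()` standard average atomic weights; for a labelled peptide
#' the enriched isotope's exact mass is used in both conventions.
#'
#' @param seq A `peptide_sequence` or one-letter string.
#' @param scheme An [isotope_scheme()].
#' @param n_disulfides Number of disulfide bonds formed.
#' @return Neutral mass in Da.
#' @examples
#' monoisotopic_mass("G")  # glycine, 75.03203
#' monoisotopic_mass(cltx_sequence(), isotope_scheme(label_15N = TRUE),
#'                   n_disulfides = 4)
#' @export
monoisotopic_mass <- function(seq, scheme = isotope_scheme(),
                              n_disulfides = 0) {
  .comp_mass(peptide_composition(seq, scheme, n_disulfides),
             .MONO_MASS, scheme)
}

#' @rdname monoisotopic_mass
#' @export
average_mass <- function(seq, scheme = isotope_scheme(), n_disulfides = 0) {
  .comp_mass(peptide_composition(seq, scheme, n_disulfides),
             .AVG_MASS, scheme)
}

#' Mass report across conventions
#'
#' Convenience table of monoisotopic and average neutral and \[M+H\]+ masses
#' for the free-acid and amide forms of a peptide, useful when a printed
#' "calculated mass" does not state its convention.
#'
#' @inheritParams monoisotopic_mass
#' @param label_15N,label_13C Logical labelling flags.
#' @return data.frame with one row per (convention, terminus) combination.
#' @export
mass_report <- function(seq, label_15N = FALSE, label_13C = FALSE,
                        n_disulfides = 0) {
  proton <- .MONO_MASS[["H"]] - 5.48579909e-4  # proton = H minus electron
  rows <- expand.grid(convention = c("monoisotopic", "average"),
                      terminus = c("free acid", "amide"),
                      stringsAsFactors = FALSE)
  rows$neutral <- mapply(function(conv, term) {
    sch <- isotope_scheme(label_15N, label_13C, term == "amide")
    if (conv == "monoisotopic") monoisotopic_mass(seq, sch, n_disulfides)
    else average_mass(seq, sch, n_disulfides)
  }, rows$convention, rows$terminus)
  rows$m_plus_h <- rows$neutral + proton
  rows
}

#' Cystine framework of a disulfide pairing
#'
#' Converts residue-number disulfide pairs into the ordinal "framework"
#' notation of the disulfide-rich peptide field: each cysteine is replaced by
#' its 1-based rank along the sequence, and the ordinal pairs are listed
#' sorted by first ordinal (e.g. `"1-4,2-6,3-7,5-8"`).
#'
#' @param seq A `peptide_sequence` or one-letter string.
#' @param pairs Two-column matrix (or list of length-2 vectors) of residue
#'   numbers; every residue must be a cysteine and may appear in only one
#'   pair.
#' @return An object of class `disulfide_topology`: list with `pairs`
#'   (two-column matrix, i < j, sorted) and `framework` (string, empty when
#'   there are no pairs).
#' @examples
#' cysteine_framework(cltx_sequence(), cltx_disulfides())$framework
#' @export
cysteine_framework <- function(seq, pairs) {
  seq <- as_peptide_sequence(seq)
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0) {
    return(structure(list(pairs = matrix(integer(0), 0, 2,
                                         dimnames = list(NULL, c("i", "j"))),
                          framework = ""),
                     class = "disulfide_topology"))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("i", "j")))
  resnos <- as.vector(pairs)
  bad <- setdiff(resnos, seq$cys_positions)
  if (length(bad) > 0)
    stop(sprintf("residue %d is not a cysteine of the sequence", bad[1]))
  if (anyDuplicated(resnos))
    stop(sprintf("residue %d appears in more than one disulfide pair",
                 resnos[duplicated(resnos)][1]))
  pairs <- t(apply(pairs, 1, sort))
  colnames(pairs) <- c("i", "j")
  ord <- matrix(match(pairs, seq$cys_positions), ncol = 2)
  o <- order(ord[, 1])
  pairs <- pairs[o, , drop = FALSE]
  ord <- ord[o, , drop = FALSE]
  structure(list(pairs = pairs,
                 framework = paste(ord[, 1], ord[, 2],
                                   sep = "-", collapse = ",")),
            class = "disulfide_topology")
}

#' @export
print.disulfide_topology <- function(x, ...) {
  cat(sprintf("<disulfide_topology> %d pair(s)", nrow(x$pairs)))
  if (nzchar(x$framework)) cat(", framework", x$framework)
  cat("\n")
  if (nrow(x$pairs) > 0)
    cat(paste(sprintf("  Cys%d-Cys%d", x$pairs[, 1], x$pairs[, 2]),
              collapse = "\n"), "\n")
  invisible(x)
}
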