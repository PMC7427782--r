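#' Crystallographic structure container
#'
#' A `structure3d` is a light wrapper around a flat atom table, the natural
#' representation for crystallographic models in R (the same shape as the
#' `atom` table of a `bio3d` pdb object). Each row is one atom record with its
#' author chain identifier, author residue number and insertion code, residue
#' and atom names, element, alternate-location label (`""` when unique),
#' fractional occupancy, B-factor and Cartesian coordinates in Angstrom.
#'
#' Author numbering is used throughout: residue numbers printed in structure
#' papers (e.g. Arg264 of AdipoR1 helix V) are author numbers, so every
#' analysis function in this package selects residues by that scheme.
#'
#' @param atom data.frame with columns `type` ("ATOM"/"HETATM"), `eleno`,
#'   `elety` (atom name), `alt` (altloc label, `""` if none), `resid`
#'   (3-letter residue code), `chain`, `resno` (author number), `insert`
#'   (insertion code, `""` if none), `x`, `y`, `z`, `o` (occupancy), `b`
#'   (B-factor), `elesy` (element symbol).
#' @param id entry identifier string.
#' @param source_format `"pdb"`, `"mmcif"` or `"synthetic"`.
#' @return An object of class `structure3d`.
#' @export
structure3d <- function(atom, id = "", source_format = "synthetic") {
  needed <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
              "insert", "x", "y", "z", "o", "b", "elesy")
  miss <- setdiff(needed, names(atom))
  if (length(miss) > 0)
    stop("atom table is missing column(s): ", paste(miss, collapse = ", "))
  atom <- as.data.frame(atom[, needed], stringsAsFactors = FALSE)
  rownames(atom) <- NULL
  s <- structure(list(id = id, atom = atom, source_format = source_format),
                 class = "structure3d")
  validate_structure3d(s)
  s
}

#' Validate a structure3d object
#'
#' Checks the container invariants: finite coordinates, occupancies in
#' \[0, 1\], non-empty element symbols, and at most one atom per
#' (residue, atom name, altloc) combination.
#'
#' @param s a `structure3d`.
#' @return `s`, invisibly; errors on violation.
#' @export
validate_structure3d <- function(s) {
  a <- s$atom
  if (nrow(a) == 0) return(invisible(s))
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    stop("non-finite atom coordinates")
  if (any(is.na(a$o)) || any(a$o < 0 | a$o > 1))
    stop("occupancies must lie in [0, 1]")
  if (any(is.na(a$elesy) | a$elesy == ""))
    stop("empty element symbol")
  key <- paste(a$chain, a$resno, a$insert, a$elety, a$alt)
  if (anyDuplicated(key))
    stop("duplicate atom for the same (residue, name, altloc): ",
         key[duplicated(key)][1])
  invisible(s)
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atom
  cat(sprintf("structure3d '%s' (%s): %d atoms, %d chain(s)\n",
              x$id, x$source_format, nrow(a),
              length(unique(a$chain[nzchar(a$chain)]))))
  if (nrow(a) > 0) {
    for (ch in chain_ids(x)) {
      sub <- a[a$chain == ch, ]
      nres <- length(unique(paste(sub$resno, sub$insert)))
      nalt <- sum(nzchar(sub$alt))
      cat(sprintf("  chain %s: %d residues, %d atoms%s\n", ch, nres, nrow(sub),
                  if (nalt > 0) sprintf(" (%d altloc records)", nalt) else ""))
    }
  }
  invisible(x)
}

#' Chain identifiers of a structure
#' @param s a `structure3d`.
#' @return character vector of chain ids, in order of first appearance.
#' @export
chain_ids <- function(s) unique(s$atom$chain)

#' Extract one chain as an atom table
#'
#' Returns the atom records of a single chain, ordered by author residue
#' number and insertion code. A single-conformer view can be requested by
#' `conformer`: blank-altloc atoms plus atoms of that label only.
#'
#' @param s a `structure3d` or an atom data.frame.
#' @param chain chain identifier; may be omitted for single-chain structures.
#' @param conformer optional altloc label for a single-conformer view.
#' @return atom data.frame (one chain).
#' @export
get_chain <- function(s, chain = NULL, conformer = NULL) {
  a <- as_atom_table(s)
  if (is.null(chain)) {
    ids <- unique(a$chain)
    if (length(ids) > 1)
      stop("structure has ", length(ids), " chains; specify `chain`")
    chain <- ids
  }
  a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in chain '", chain, "'")
  if (!is.null(conformer)) {
    a <- a[a$alt == "" | a$alt == conformer, , drop = FALSE]
    a$alt <- ""
  }
  ord <- order(a$resno, a$insert, match(a$alt, sort(unique(a$alt))))
  a <- a[ord, , drop = FALSE]
  rownames(a) <- NULL
  a
}

#' Guess the biological role of each chain
#'
#' Heuristic classification used for bookkeeping when reading deposited
#' entries that contain, besides the receptor, antibody fragments, lipids,
#' ions and waters: protein chains (>= 20 standard residues) are labelled
#' `polymer`, single metal heteroatoms `ion`, water chains `water`, anything
#' else `ligand`. Receptor vs antibody cannot be told apart from coordinates
#' alone, so all analyses take explicit chain selections.
#'
#' @param s a `structure3d`.
#' @return data.frame with columns `chain`, `role`, `n_residues`.
#' @export
chain_roles <- function(s) {
  a <- s$atom
  std <- .standard_aa()
  out <- lapply(chain_ids(s), function(ch) {
    sub <- a[a$chain == ch, ]
    res <- unique(paste(sub$resno, sub$insert, sub$resid))
    resid <- unique(sub$resid)
    naa <- sum(unique(paste(sub$resno, sub$insert))
               %in% unique(paste(sub$resno, sub$insert)[sub$resid %in% std]))
    role <-
      if (all(resid %in% .water_resids())) "water"
      else if (naa >= 20) "polymer"
      else if (length(res) == 1 && all(sub$type == "HETATM") &&
               nrow(sub) <= 2 && all(!sub$elesy %in% c("C", "N", "O", "H"))) "ion"
      else if (naa > 0) "polymer"
      else "ligand"
    data.frame(chain = ch, role = role, n_residues = length(res),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- internal helpers -------------------------------------------------------

as_atom_table <- function(x) {
  if (inherits(x, "structure3d")) return(x$atom)
  if (is.data.frame(x)) return(x)
  stop("expected a structure3d or an atom data.frame")
}

.standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "MSE")
}

.water_resids <- function() c("HOH", "WAT", "DOD", "H2O")

# coordinates of one named atom; NULL if absent
.atom_xyz <- function(atoms, resno, elety, insert = "") {
  i <- which(atoms$resno == resno & atoms$insert == insert &
               atoms$elety == elety)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

.xyz_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("cannot normalise a near-zero vector")
  v / n
}

.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# IUPAC-signed torsion angle a-b-c-d in degrees (convention checked against
# bio3d::torsion.xyz in the test suite)
.torsion <- function(a, b, c3, d) {
  b0 <- a - b
  b1 <- .unit(c3 - b)
  b2 <- d - c3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  ang <- .rad2deg(atan2(sum(.cross(b1, v) * w), sum(v * w)))
  if (ang <= -180) ang + 360 else ang   # keep the (-180, 180] convention
}

.angle_deg <- function(a, b, c3) {
  u <- .unit(a - b); v <- .unit(c3 - b)
  .rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Rodrigues rotation matrix for unit axis u and angle (degrees)
.rotation_about <- function(u, angle_deg) {
  u <- .unit(u)
  th <- .deg2rad(angle_deg)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
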