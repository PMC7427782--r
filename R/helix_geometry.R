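#' Residue-range scheme of the mobile helix IV-ICL2-helix V unit
#'
#' Named author-residue ranges used throughout the closed/open analysis of
#' AdipoR1: intracellular loop 2 (ICL2, Trp255-His263) and the partition of
#' helix V (Arg264-Ala288) into its N-terminal (NT), middle (M1, M2) and
#' C-terminal (CT) regions, plus the mobile region excluded from
#' superposition frames and the dual-conformer region of the mixed
#' closed/open model. The NT range is the non-overlapping 264-267 partition
#' (NT/M1/M2/CT tile helix V exactly); all ranges can be overridden.
#'
#' @param ... named integer vectors replacing or extending the defaults.
#' @return named list of integer ranges.
#' @export
region_scheme <- function(...) {
  defaults <- list(ICL2 = 255:263, NT = 264:267, M1 = 268:272, M2 = 273:280,
                   CT = 281:288, helixV = 264:288, mobile_region = 250:288,
                   dual_region = 250:279)
  over <- list(...)
  if (length(over) > 0) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("region overrides must be named")
    for (nm in names(over)) {
      if (length(over[[nm]]) == 0) stop("empty region: ", nm)
      defaults[[nm]] <- as.integer(over[[nm]])
    }
  }
  defaults
}

#' Backbone dihedral angles
#'
#' Computes per-residue (phi, psi, omega) with IUPAC signs: phi is
#' C(i-1)-N-CA-C, psi is N-CA-C-N(i+1), omega is the torsion of the peptide
#' bond preceding residue i (CA(i-1)-C(i-1)-N(i)-CA(i)). The first residue
#' has no phi or omega and the last no psi; a chain break (C(i)...N(i+1)
#' distance of 2 Angstrom or more, or missing atoms) yields NA across the
#' break rather than an error.
#'
#' @param atoms single-conformer, single-chain atom data.frame.
#' @return data.frame with columns `resno`, `resid`, `phi`, `psi`, `omega`
#'   (degrees in (-180, 180\]).
#' @export
backbone_dihedrals <- function(atoms) {
  atoms <- as_atom_table(atoms)
  res <- .residue_table(atoms)
  n <- nrow(res)
  get <- function(i, el) if (i < 1 || i > n) NULL else
    .atom_xyz(atoms, res$resno[i], el, res$insert[i])
  bonded <- function(i) {   # peptide bond between residue i and i+1 intact?
    C <- get(i, "C"); N <- get(i + 1, "N")
    !is.null(C) && !is.null(N) && .dist3(C, N) < 2.0
  }
  phi <- psi <- omega <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    N <- get(i, "N"); CA <- get(i, "CA"); C <- get(i, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (i > 1 && bonded(i - 1)) {
      Cp <- get(i - 1, "C"); CAp <- get(i - 1, "CA")
      phi[i] <- .torsion(Cp, N, CA, C)
      if (!is.null(CAp)) omega[i] <- .torsion(CAp, Cp, N, CA)
    }
    if (i < n && bonded(i)) {
      Nn <- get(i + 1, "N")
      psi[i] <- .torsion(N, CA, C, Nn)
    }
  }
  data.frame(resno = res$resno, resid = res$resid, phi = phi, psi = psi,
             omega = omega, stringsAsFactors = FALSE)
}

#' Helix axis by quadruplet-midpoint smoothing
#'
#' Estimates the local helix axis over a residue range: the running averages
#' of consecutive CA quadruplets cancel the helical wobble (each midpoint
#' sits on the axis of an ideal helix), and a total-least-squares line is
#' fitted through them. The axis is oriented from the first towards the last
#' residue of the range as given, so passing a reversed range yields the
#' antiparallel axis. With exactly 4 CA atoms (a single midpoint) the line
#' is fitted to the raw CA positions instead.
#'
#' @param atoms single-conformer, single-chain atom data.frame.
#' @param residue_range author residue numbers (>= 4 with CA present).
#' @return list with unit `axis`, `centroid` and `n_ca`.
#' @export
helix_axis <- function(atoms, residue_range) {
  atoms <- as_atom_table(atoms)
  ca <- atoms[atoms$elety == "CA" & atoms$resno %in% residue_range, ,
              drop = FALSE]
  ca <- ca[match(residue_range, ca$resno), , drop = FALSE]
  ca <- ca[!is.na(ca$resno), , drop = FALSE]
  if (nrow(ca) < 4)
    stop("helix_axis needs at least 4 CA atoms in the range")
  P <- .xyz_matrix(ca)
  pts <- if (nrow(P) >= 5) .quad_midpoints(P) else P
  # a second averaging pass cancels the residual phase wobble the first
  # pass leaves on short segments (the midpoints of an ideal helix still
  # trace a faint helix of ~0.1 x the CA radius)
  if (nrow(pts) >= 5) pts <- .quad_midpoints(pts)
  fit <- .pca_axis(pts)
  dir <- fit$dir
  span <- pts[nrow(pts), ] - pts[1, ]
  if (sum(dir * span) < 0) dir <- -dir
  list(axis = dir, centroid = fit$centroid, n_ca = nrow(P))
}

#' Angle between two helix axes
#'
#' @param axis_a,axis_b unit 3-vectors or results of [helix_axis()].
#' @return angle in degrees, in \[0, 180\].
#' @export
interaxis_angle <- function(axis_a, axis_b) {
  a <- if (is.list(axis_a)) axis_a$axis else axis_a
  b <- if (is.list(axis_b)) axis_b$axis else axis_b
  a <- .unit(a); b <- .unit(b)
  .rad2deg(acos(max(-1, min(1, sum(a * b)))))
}

#' Helical advance over a residue span
#'
#' The straight-line CA(start) to CA(start + span) distance, the simple
#' extension metric by which a stretched 3(10)-helical segment (11.4-12.5
#' Angstrom over 7 residues in AdipoR1's M2 region) is distinguished from
#' the standard alpha-helix (10.5 Angstrom over 7 residues).
#'
#' @param atoms single-conformer, single-chain atom data.frame.
#' @param start_residue author number of the first residue.
#' @param span number of residues advanced.
#' @param digits decimals of the reported value (default 1).
#' @return distance in Angstrom.
#' @export
helical_advance <- function(atoms, start_residue, span, digits = 1) {
  atoms <- as_atom_table(atoms)
  a <- .atom_xyz(atoms, start_residue, "CA")
  if (is.null(a)) stop("missing CA of residue ", start_residue)
  b <- .atom_xyz(atoms, start_residue + span, "CA")
  if (is.null(b)) stop("missing CA of residue ", start_residue + span)
  round(.dist3(a, b), digits)
}
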