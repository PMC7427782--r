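#' Specification of a synthetic helix
#'
#' Collects the ground-truth parameters of a generated backbone: length,
#' backbone dihedrals, sequence, an optional kink and optional Gaussian
#' coordinate noise. The defaults build the ideal alpha-helix
#' (phi = -57, psi = -47 degrees); the ideal 3(10)-helix is obtained with
#' phi = -49, psi = -26.
#'
#' @param n_residues number of residues (>= 4, so that at least one full
#'   (phi, psi) pair exists on an interior residue).
#' @param phi,psi,omega backbone dihedrals in degrees applied uniformly.
#' @param sequence character vector of 3-letter residue codes, recycled to
#'   `n_residues`; default poly-Ala. Proline is allowed (its special amide,
#'   lacking the H atom, is handled downstream by the hydrogen builder).
#' @param kink_residue,kink_angle optional kink: residues after
#'   `kink_residue` are rigidly rotated by `kink_angle` degrees (see
#'   [make_kinked_helix()]).
#' @param noise_sigma standard deviation (Angstrom) of isotropic Gaussian
#'   noise added to every coordinate; 0 for exact geometry.
#' @param seed integer seed driving the noise.
#' @return an object of class `helix_spec`.
#' @export
helix_spec <- function(n_residues, phi = -57, psi = -47, omega = 180,
                       sequence = NULL, kink_residue = NULL,
                       kink_angle = NULL, noise_sigma = 0, seed = 1L) {
  if (n_residues < 4) stop("n_residues must be >= 4")
  if (!all(is.finite(c(phi, psi, omega))))
    stop("dihedrals must be finite")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (is.null(sequence)) sequence <- "ALA"
  sequence <- toupper(rep_len(sequence, n_residues))
  if (!is.null(kink_residue)) {
    if (kink_residue <= 1 || kink_residue >= n_residues)
      stop("kink_residue must lie strictly inside the chain")
  }
  structure(list(n_residues = as.integer(n_residues), phi = phi, psi = psi,
                 omega = omega, sequence = sequence,
                 kink_residue = kink_residue, kink_angle = kink_angle,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "helix_spec")
}

# Standard backbone internal coordinates used by the builder. Bond lengths
# and the angles at C and N follow library values (N-CA 1.458, CA-C 1.525,
# C-N 1.329 A; CA-C-N 116.2, C-N-CA 121.7 deg; C=O 1.231 A, CA-C-O 120.8
# deg). The angle at CA is the classical tetrahedral 109.5 deg of the
# Pauling helix construction: this is what gives the canonical alpha-helix
# its 1.5 A rise per residue, and hence the standard 10.5 A Ca(i)->Ca(i+7)
# advance, as an emergent property rather than a painted-on number.
.bb_geom <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 109.5, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.8)

#' Build an ideal helix backbone
#'
#' Sequential internal-coordinate (NeRF-style) chain extension: every
#' backbone atom is placed from the three previously placed atoms using a
#' standard bond length, bond angle and the requested torsion. The carbonyl
#' oxygen lies in the peptide plane, trans to the next residue's nitrogen.
#' At `noise_sigma = 0` the measured (phi, psi) of every interior residue
#' reproduce the specification to better than 1e-3 degrees; with noise, the
#' stated sigma is applied with the stated seed (same seed, same
#' coordinates, bit for bit).
#'
#' @param spec a [helix_spec()].
#' @param chain_id chain identifier of the generated model.
#' @return a single-chain [structure3d] with N, CA, C, O atoms per residue.
#' @export
make_ideal_helix <- function(spec, chain_id = "A") {
  stopifnot(inherits(spec, "helix_spec"))
  bb <- .build_backbone(spec$n_residues, spec$phi, spec$psi, spec$omega)
  .backbone_to_structure(bb, spec, chain_id)
}

#' Build a kinked helix with known bend angle
#'
#' Starts from the ideal helix of `spec` and rigidly rotates everything
#' C-terminal of the kink residue (including that residue's carbonyl group,
#' so no bond is stretched at the hinge — the rotation re-derives the hinge
#' residue's psi) about an axis through the kink residue's CA, perpendicular
#' to the pre-kink helix axis and chosen so the helix bends in the plane
#' containing the axis and the CA's radial direction. Because the rotation
#' axis is perpendicular to the helix axis, the angle between the pre- and
#' post-kink helix axes equals the requested kink angle exactly, which makes
#' the construction a ground truth for bend estimators.
#'
#' @param spec a [helix_spec()] with `kink_residue` and `kink_angle` set;
#'   `kink_angle` must lie in (-90, 90) degrees.
#' @param chain_id chain identifier.
#' @return a single-chain [structure3d].
#' @export
make_kinked_helix <- function(spec, chain_id = "A") {
  stopifnot(inherits(spec, "helix_spec"))
  if (is.null(spec$kink_residue) || is.null(spec$kink_angle))
    stop("spec must carry kink_residue and kink_angle")
  if (abs(spec$kink_angle) >= 90)
    stop("kink_angle must lie inside (-90, 90) degrees")
  k <- spec$kink_residue
  bb <- .build_backbone(spec$n_residues, spec$phi, spec$psi, spec$omega)

  if (spec$kink_angle != 0) {
    pre <- seq_len(k)
    ca_pre <- bb$CA[pre, , drop = FALSE]
    axis <- .pca_axis(if (nrow(ca_pre) >= 5) .quad_midpoints(ca_pre) else ca_pre)
    axis <- axis$dir * sign(sum(axis$dir * (ca_pre[k, ] - ca_pre[1, ])))
    cen <- colMeans(ca_pre)
    radial <- bb$CA[k, ] - cen
    radial <- radial - sum(radial * axis) * axis
    if (sqrt(sum(radial^2)) < 1e-6) radial <- .any_perpendicular(axis)
    u <- .unit(.cross(axis, .unit(radial)))   # perpendicular to helix axis
    R <- .rotation_about(u, spec$kink_angle)
    pivot <- bb$CA[k, ]
    rot <- function(M, rows) {
      M[rows, ] <- t(R %*% (t(M[rows, , drop = FALSE]) - pivot) + pivot)
      M
    }
    post <- (k + 1):spec$n_residues
    bb$N <- rot(bb$N, post)
    bb$CA <- rot(bb$CA, post)
    bb$C <- rot(bb$C, c(k, post))
    bb$O <- rot(bb$O, c(k, post))
  }
  .backbone_to_structure(bb, spec, chain_id)
}

#' Build a dual-conformer (altloc) model
#'
#' Emulates a crystallographic dual-conformation deposition: residues in
#' `alt_range` are duplicated under altloc labels A and B, the B copy is
#' rigidly displaced by `displacement` Angstrom perpendicular to the helix
#' axis, and the two copies carry the given fractional occupancies. Residues
#' outside the range stay unique with occupancy 1.
#'
#' @param spec a [helix_spec()] for the base (conformer A) helix.
#' @param alt_range author residue numbers to model in two conformations.
#' @param displacement rigid displacement of conformer B, Angstrom.
#' @param occupancies numeric pair (A, B); must sum to 1 within 1e-6.
#' @param chain_id chain identifier.
#' @return a single-chain [structure3d] bearing altlocs.
#' @export
make_dual_conformer_file <- function(spec, alt_range, displacement,
                                     occupancies = c(0.44, 0.56),
                                     chain_id = "A") {
  stopifnot(inherits(spec, "helix_spec"))
  if (abs(sum(occupancies) - 1) > 1e-6)
    stop("occupancies must sum to 1")
  if (!all(alt_range %in% seq_len(spec$n_residues)))
    stop("alt_range lies outside the chain (1..", spec$n_residues, ")")
  base <- make_ideal_helix(spec, chain_id = chain_id)
  a <- base$atom
  ca <- .xyz_matrix(a[a$elety == "CA", ])
  axis <- .pca_axis(.quad_midpoints(ca))$dir
  dir <- .unit(.any_perpendicular(axis))

  in_range <- a$resno %in% alt_range
  aa <- a[in_range, , drop = FALSE]
  ab <- aa
  aa$alt <- "A"; aa$o <- occupancies[1]
  ab$alt <- "B"; ab$o <- occupancies[2]
  shift <- displacement * dir
  ab$x <- ab$x + shift[1]; ab$y <- ab$y + shift[2]; ab$z <- ab$z + shift[3]
  out <- rbind(a[!in_range, , drop = FALSE], aa, ab)
  out <- out[order(out$resno, out$insert, out$alt, out$eleno), , drop = FALSE]
  out$eleno <- seq_len(nrow(out))
  structure3d(out, id = paste0(base$id, "_dual"), source_format = "synthetic")
}

#' Build a toy metal coordination site
#'
#' One zinc heteroatom at the origin with `n_ligands` histidine side-chain
#' nitrogens placed along tetrahedral directions at the stated distance —
#' the geometry of the tetrahedrally coordinated zinc found in the receptor
#' cavity (three conserved His residues plus a solvent position).
#'
#' @param n_ligands 0 to 4 coordinating nitrogens.
#' @param distance metal-nitrogen distance, Angstrom.
#' @return a [structure3d] with a `ZN` heteroatom and `n_ligands` HIS NE2
#'   atoms.
#' @export
make_metal_site <- function(n_ligands, distance = 2.1) {
  if (n_ligands < 0 || n_ligands > 4)
    stop("n_ligands must be between 0 and 4")
  t4 <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  rows <- list(data.frame(
    type = "HETATM", eleno = 1L, elety = "ZN", alt = "", resid = "ZN",
    chain = "M", resno = 401L, insert = "", x = 0, y = 0, z = 0, o = 1,
    b = 0, elesy = "ZN", stringsAsFactors = FALSE))
  if (n_ligands > 0) {
    for (i in seq_len(n_ligands)) {
      p <- t4[i, ] * distance
      rows[[i + 1]] <- data.frame(
        type = "ATOM", eleno = i + 1L, elety = "NE2", alt = "",
        resid = "HIS", chain = "L", resno = 100L + i, insert = "",
        x = p[1], y = p[2], z = p[3], o = 1, b = 0, elesy = "N",
        stringsAsFactors = FALSE)
    }
  }
  structure3d(do.call(rbind, rows), id = "metal_site",
              source_format = "synthetic")
}

# ---- internal ---------------------------------------------------------------

# place atom D bonded to c3 given frame atoms a-b-c3, bond length,
# bond angle b-c3-D (deg) and IUPAC torsion a-b-c3-D (deg)
.place_atom <- function(a, b, c3, len, ang, tor) {
  ang <- .deg2rad(ang); tor <- .deg2rad(tor)
  bc <- .unit(c3 - b)
  n <- .unit(.cross(b - a, bc))
  m <- .cross(n, bc)
  d <- c(-len * cos(ang), len * sin(ang) * cos(tor), len * sin(ang) * sin(tor))
  c3 + d[1] * bc + d[2] * m + d[3] * n
}

.build_backbone <- function(n, phi, psi, omega) {
  g <- .bb_geom
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  th <- .deg2rad(g$ang_n_ca_c)
  C[1, ] <- CA[1, ] + g$ca_c * c(-cos(pi - th), sin(pi - th), 0)
  for (i in 2:n) {
    N[i, ]  <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], g$c_n,
                           g$ang_ca_c_n, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], g$n_ca,
                           g$ang_c_n_ca, omega)
    C[i, ]  <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], g$ca_c,
                           g$ang_n_ca_c, phi)
  }
  for (i in seq_len(n)) {
    O[i, ] <- if (i < n) {
      .place_atom(N[i + 1, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, 180)
    } else {
      .place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o, psi + 180)
    }
  }
  list(N = N, CA = CA, C = C, O = O)
}

.backbone_to_structure <- function(bb, spec, chain_id) {
  n <- spec$n_residues
  coords <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])))
  set.seed(spec$seed)
  if (spec$noise_sigma > 0)
    coords <- coords + matrix(stats::rnorm(length(coords), 0, spec$noise_sigma),
                              ncol = 3)
  atom <- data.frame(
    type = "ATOM", eleno = seq_len(4L * n),
    elety = rep(c("N", "CA", "C", "O"), n), alt = "",
    resid = rep(spec$sequence, each = 4L), chain = chain_id,
    resno = rep(seq_len(n), each = 4L), insert = "",
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    o = 1, b = 0, elesy = rep(c("N", "C", "C", "O"), n),
    stringsAsFactors = FALSE)
  structure3d(atom, id = sprintf("helix_phi%+.0f_psi%+.0f", spec$phi, spec$psi),
              source_format = "synthetic")
}

# total-least-squares direction through a set of points
.pca_axis <- function(P) {
  cen <- colMeans(P)
  sv <- svd(sweep(P, 2, cen))
  list(dir = sv$v[, 1], centroid = cen)
}

# running averages of consecutive CA quadruplets: local-origin smoothing
# that cancels the helical wobble before a line fit
.quad_midpoints <- function(ca) {
  n <- nrow(ca)
  if (n < 4) stop("need >= 4 CA atoms")
  k <- n - 3
  out <- matrix(NA_real_, k, 3)
  for (j in seq_len(k)) out[j, ] <- colMeans(ca[j:(j + 3), , drop = FALSE])
  out
}

.any_perpendicular <- function(v) {
  v <- .unit(v)
  w <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(w - sum(w * v) * v)
}
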