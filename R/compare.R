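#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired coordinate sets, via the SVD of the covariance matrix with the
#' determinant correction that excludes reflections: a mirror image is never
#' fitted by an improper rotation, it simply scores the best achievable
#' proper-rotation RMSD. The transform maps set B onto set A:
#' `x' = R x + t`.
#'
#' @param coords_a,coords_b n x 3 matrices of paired coordinates (n >= 3,
#'   not collinear).
#' @return object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` (Angstrom), `n_atoms`, and per-pair `deviations`
#'   after the fit.
#' @export
kabsch_fit <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3)
    stop("coordinate sets must be paired n x 3 matrices")
  n <- nrow(A)
  if (n < 3) stop("need at least 3 paired atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- t(Bc) %*% Ac
  sv <- svd(H)
  # rank check: a degenerate (collinear) set leaves the rotation undetermined
  if (svd(Ac)$d[2] < 1e-8 || svd(Bc)$d[2] < 1e-8)
    stop("degenerate coordinate set: atoms are collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Bfit <- Bc %*% t(R)
  dev <- unname(sqrt(rowSums((Ac - Bfit)^2)))
  structure(list(rotation = R, translation = as.numeric(ca - R %*% cb),
                 rmsd = sqrt(mean(dev^2)), n_atoms = n, deviations = dev),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d atoms, rmsd %.3f A\n", x$n_atoms, x$rmsd))
  invisible(x)
}

#' Whole-chain CA RMSD between two chains
#'
#' Pairs atoms by author residue number (and insertion code) over the
#' residues modeled in both chains, superposes, and reports the RMSD — the
#' quantity printed when crystallographically independent molecules of the
#' same protein are compared.
#'
#' @param chain_a,chain_b single-conformer atom data.frames (or
#'   [structure3d] objects with one chain).
#' @param elety atom name used for pairing (default `"CA"`).
#' @param residue_range optional restriction of the paired residues.
#' @return a `superposition` (see [kabsch_fit()]) with the paired residue
#'   numbers in `$resno`.
#' @export
chain_rmsd <- function(chain_a, chain_b, elety = "CA", residue_range = NULL) {
  pa <- .ca_table(chain_a, elety, residue_range)
  pb <- .ca_table(chain_b, elety, residue_range)
  common <- intersect(paste(pa$resno, pa$insert), paste(pb$resno, pb$insert))
  if (length(common) < 3)
    stop("fewer than 3 residues in common (", length(common), ")")
  ia <- match(common, paste(pa$resno, pa$insert))
  ib <- match(common, paste(pb$resno, pb$insert))
  fit <- kabsch_fit(.xyz_matrix(pa[ia, ]), .xyz_matrix(pb[ib, ]))
  fit$resno <- pa$resno[ia]
  fit
}

#' Per-atom displacement after a declared fit
#'
#' Superposes chain B onto chain A on a fit selection (by default the CA
#' atoms of all common residues excluding the mobile region, so the moving
#' parts are measured in the frame of the static body) and reports how far
#' each target atom moved — e.g. the ~11 and 13.5 Angstrom repositioning of
#' the helix V N-terminus and ICL2 between the closed and open forms.
#'
#' @param chain_a,chain_b single-conformer atom data.frames.
#' @param fit_exclude author residue numbers excluded from the fit frame
#'   (default: the mobile region 250-288); ignored when `fit_resnos` given.
#' @param fit_resnos explicit fit selection (author numbers), optional.
#' @param targets data.frame with columns `resno` and `elety`, or an integer
#'   vector of residue numbers (then CA).
#' @return data.frame `resno`, `elety`, `displacement` (Angstrom; NA with a
#'   warning for targets missing in either chain), with the fit as
#'   `attr(, "fit")`.
#' @export
atom_displacement <- function(chain_a, chain_b,
                              fit_exclude = 250:288, fit_resnos = NULL,
                              targets) {
  a <- as_atom_table(chain_a); b <- as_atom_table(chain_b)
  pa <- .ca_table(a, "CA", NULL); pb <- .ca_table(b, "CA", NULL)
  common <- intersect(pa$resno, pb$resno)
  sel <- if (is.null(fit_resnos)) setdiff(common, fit_exclude) else
    intersect(fit_resnos, common)
  if (length(sel) < 3) stop("fit selection has fewer than 3 residues")
  fit <- kabsch_fit(.xyz_matrix(pa[match(sel, pa$resno), ]),
                    .xyz_matrix(pb[match(sel, pb$resno), ]))
  if (is.numeric(targets) && is.null(dim(targets)))
    targets <- data.frame(resno = as.integer(targets), elety = "CA")
  disp <- rep(NA_real_, nrow(targets))
  for (k in seq_len(nrow(targets))) {
    xa <- .atom_xyz(a, targets$resno[k], targets$elety[k])
    xb <- .atom_xyz(b, targets$resno[k], targets$elety[k])
    if (is.null(xa) || is.null(xb)) next
    disp[k] <- .dist3(xa, as.numeric(fit$rotation %*% xb + fit$translation))
  }
  if (anyNA(disp))
    warning("target atom(s) missing in one chain: ",
            paste(targets$resno[is.na(disp)], collapse = ", "))
  out <- data.frame(resno = targets$resno, elety = targets$elety,
                    displacement = disp, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Per-residue deviations after a region-restricted fit
#'
#' Fits on the CA atoms of `fit_range` only and reports the per-residue CA
#' deviations over `measure_range` — the operation behind comparisons such
#' as "superimpose the CT region, measure how the M1/M2 regions deviate".
#'
#' @param chain_a,chain_b single-conformer atom data.frames.
#' @param fit_range,measure_range author residue numbers.
#' @return data.frame `resno`, `deviation` (Angstrom); the fit is attached
#'   as `attr(, "fit")`.
#' @export
region_superpose_deviation <- function(chain_a, chain_b, fit_range,
                                       measure_range) {
  a <- as_atom_table(chain_a); b <- as_atom_table(chain_b)
  fit <- chain_rmsd(a, b, residue_range = fit_range)
  pa <- .ca_table(a, "CA", measure_range)
  pb <- .ca_table(b, "CA", measure_range)
  common <- intersect(pa$resno, pb$resno)
  dev <- vapply(common, function(r) {
    xa <- .atom_xyz(a, r, "CA"); xb <- .atom_xyz(b, r, "CA")
    .dist3(xa, as.numeric(fit$rotation %*% xb + fit$translation))
  }, numeric(1))
  out <- data.frame(resno = common, deviation = dev)
  attr(out, "fit") <- fit
  out
}

#' Assign the conformers of a dual model to reference states
#'
#' Splits a dual-conformation (altloc-bearing) model into its single
#' conformers, computes the whole-chain CA RMSD of every conformer against
#' every reference structure, and assigns each conformer the label of its
#' closest reference. This resolves, at run time, which deposited altloc
#' label corresponds to which physical state — a convention the deposition
#' itself does not guarantee.
#'
#' @param dual a [structure3d] with altlocs (e.g. in the dual region).
#' @param references named list of single-conformer references
#'   ([structure3d] or atom data.frames).
#' @param chain chain id of the receptor within `dual` (default: the single
#'   chain).
#' @param mapping optional altloc-to-conformer-name mapping passed to
#'   [split_conformers()].
#' @return list with `rmsd` (conformer x reference matrix, Angstrom) and
#'   `assignment` (named character: conformer -> reference label).
#' @export
compare_dual_model <- function(dual, references, chain = NULL,
                               mapping = NULL) {
  if (length(references) == 0) stop("need at least one reference")
  if (is.null(names(references)))
    stop("references must be a named list")
  confs <- split_conformers(dual, mapping = mapping)
  confs <- lapply(confs, function(s) get_chain(s, chain))
  refs <- lapply(references, function(r)
    if (inherits(r, "structure3d")) get_chain(r) else as_atom_table(r))
  M <- matrix(NA_real_, length(confs), length(refs),
              dimnames = list(names(confs), names(refs)))
  for (i in seq_along(confs))
    for (j in seq_along(refs))
      M[i, j] <- chain_rmsd(confs[[i]], refs[[j]])$rmsd
  assignment <- apply(M, 1, function(r) colnames(M)[which.min(r)])
  list(rmsd = M, assignment = assignment)
}

# ---- internal ---------------------------------------------------------------

.ca_table <- function(x, elety = "CA", residue_range = NULL) {
  a <- as_atom_table(x)
  a <- a[a$elety == elety, , drop = FALSE]
  if (!is.null(residue_range)) a <- a[a$resno %in% residue_range, , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$insert)), , drop = FALSE]
  a[order(a$resno, a$insert), , drop = FALSE]
}
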