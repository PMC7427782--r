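# shared fixtures and independent oracles, built in code at test time

# a minimal structure with arbitrary atom positions
toy_structure <- function(pos, elety = NULL, resno = NULL, resid = "ALA",
                          chain = "A", elesy = NULL, o = 1, alt = "",
                          type = "ATOM") {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  if (is.null(elety)) elety <- rep("CA", n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(elesy)) elesy <- substr(elety, 1, 1)
  structure3d(data.frame(
    type = rep_len(type, n), eleno = seq_len(n), elety = elety,
    alt = rep_len(alt, n), resid = rep_len(resid, n),
    chain = rep_len(chain, n), resno = resno, insert = "",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    o = rep_len(o, n), b = 0, elesy = elesy,
    stringsAsFactors = FALSE), id = "toy")
}

dist3 <- function(a, b) sqrt(sum((a - b)^2))

atom_xyz <- function(atoms, resno, elety) {
  i <- which(atoms$resno == resno & atoms$elety == elety)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

xyz_mat <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

rot_z <- function(deg) {
  t <- deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

euler_rot <- function(a, b, c) {
  ra <- rot_z(a)
  t <- b * pi / 180
  ry <- matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  ra %*% ry %*% rot_z(c)
}

# independent superposition oracle: coarse grid over Euler angles followed
# by a Nelder-Mead refinement of the best cell; no SVD involved
brute_force_rmsd <- function(A, B) {
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  score <- function(p) {
    R <- euler_rot(p[1], p[2], p[3])
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  best <- NULL; best_val <- Inf
  for (a in seq(0, 345, by = 15))
    for (b in seq(0, 180, by = 15))
      for (c in seq(0, 345, by = 15)) {
        v <- score(c(a, b, c))
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  opt <- stats::optim(best, score, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

# torsion of four stacked points via bio3d (the convention authority)
bio3d_torsion <- function(a, b, c, d) bio3d::torsion.xyz(c(a, b, c, d))
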