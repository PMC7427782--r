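test_that("identical sets superpose with zero rmsd and identity rotation", {
  set.seed(1)
  A <- matrix(rnorm(18), 6)
  fit <- kabsch_fit(A, A)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$deviations, rep(0, 6), tolerance = 1e-9)
})

test_that("a constructed rigid motion is recovered exactly", {
  set.seed(4)
  A <- matrix(rnorm(15), 5)
  R0 <- euler_rot(37, 0, 0)          # 37 degrees about z
  B <- sweep(A %*% t(R0), 2, c(2, -1, 4), "+")
  fit <- kabsch_fit(A, B)
  expect_lt(fit$rmsd, 1e-6)
  expect_lt(max(abs(fit$rotation %*% R0 - diag(3))), 1e-6)
  # transform maps B back onto A
  back <- sweep(B %*% t(fit$rotation), 2, fit$translation, "+")
  expect_lt(max(abs(back - A)), 1e-6)
})

test_that("reflections are never fitted", {
  set.seed(5)
  A <- matrix(rnorm(15), 5)
  M <- A; M[, 1] <- -M[, 1]
  fit <- kabsch_fit(A, M)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(fit$rmsd, 0.1)
})

test_that("kabsch rmsd matches a rotation-space brute force on 5-atom toys", {
  set.seed(6)
  for (case in 1:3) {
    A <- matrix(rnorm(15), 5)
    B <- matrix(rnorm(15), 5)           # unrelated: nonzero optimum
    fit <- kabsch_fit(A, B)
    expect_equal(fit$rmsd, brute_force_rmsd(A, B), tolerance = 1e-3)
  }
})

test_that("kabsch agrees with bio3d's superposition on a real-size pair", {
  a <- get_chain(make_ideal_helix(helix_spec(15, noise_sigma = 0.3, seed = 3)))
  b <- get_chain(make_kinked_helix(helix_spec(15, kink_residue = 8,
                                              kink_angle = 12)))
  A <- xyz_mat(a[a$elety == "CA", ]); B <- xyz_mat(b[b$elety == "CA", ])
  fit <- kabsch_fit(A, B)
  ref <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(A)), mobile = as.vector(t(B)),
                   fixed.inds = 1:45, mobile.inds = 1:45))
  rmsd_ref <- sqrt(mean(rowSums((A - matrix(ref, ncol = 3, byrow = TRUE))^2)))
  expect_equal(fit$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("degenerate coordinate sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line + 1), "collinear")
  expect_error(kabsch_fit(matrix(rnorm(6), 2), matrix(rnorm(6), 2)), "3")
})

test_that("chain_rmsd pairs by author number and is a metric", {
  a <- get_chain(make_ideal_helix(helix_spec(15)))
  b <- a
  P <- xyz_mat(b) %*% t(euler_rot(15, 25, 35))
  b$x <- P[, 1] + 3; b$y <- P[, 2]; b$z <- P[, 3] - 2
  expect_equal(chain_rmsd(a, b)$rmsd, 0, tolerance = 1e-9)

  nz <- get_chain(make_ideal_helix(helix_spec(15, noise_sigma = 0.4,
                                              seed = 9)))
  expect_equal(chain_rmsd(a, nz)$rmsd, chain_rmsd(nz, a)$rmsd,
               tolerance = 1e-9)
  expect_gt(chain_rmsd(a, nz)$rmsd, 0)
  # residues modeled in only one chain are dropped from the pairing
  trunc <- nz[nz$resno <= 12, ]
  fit <- chain_rmsd(a, trunc)
  expect_equal(fit$n_atoms, 12)
  expect_error(chain_rmsd(a, nz[nz$resno > 13, ]), "common")
})

test_that("displacements are measured in the static-body frame", {
  base <- get_chain(make_ideal_helix(helix_spec(20)))
  kinked <- get_chain(make_kinked_helix(helix_spec(20, kink_residue = 12,
                                                   kink_angle = 30)))
  d <- atom_displacement(base, kinked, fit_resnos = 1:12,
                         targets = c(14, 17, 20))
  expect_true(all(is.finite(d$displacement)))
  expect_true(all(diff(d$displacement) > 0))   # grows away from the hinge
  ident <- atom_displacement(base, base, fit_resnos = 1:12,
                             targets = c(5, 14))
  expect_equal(ident$displacement, c(0, 0), tolerance = 1e-9)
  expect_warning(
    miss <- atom_displacement(base, kinked, fit_resnos = 1:12,
                              targets = c(14, 99)),
    "99")
  expect_true(is.na(miss$displacement[2]) && is.finite(miss$displacement[1]))
})

test_that("rigid pre-motion of either input changes nothing", {
  a <- get_chain(make_ideal_helix(helix_spec(16, noise_sigma = 0.2, seed = 2)))
  b <- get_chain(make_ideal_helix(helix_spec(16, noise_sigma = 0.2, seed = 3)))
  r0 <- chain_rmsd(a, b)$rmsd
  d0 <- atom_displacement(a, b, fit_resnos = 1:10, targets = 13:16)
  bm <- b
  P <- xyz_mat(b) %*% t(euler_rot(80, 10, 150))
  bm$x <- P[, 1] - 4; bm$y <- P[, 2] + 9; bm$z <- P[, 3]
  expect_equal(chain_rmsd(a, bm)$rmsd, r0, tolerance = 1e-6)
  dm <- atom_displacement(a, bm, fit_resnos = 1:10, targets = 13:16)
  expect_equal(dm$displacement, d0$displacement, tolerance = 1e-6)
})

test_that("region-restricted deviations behave like the figure comparison", {
  straight <- get_chain(make_ideal_helix(helix_spec(20)))
  kinked <- get_chain(make_kinked_helix(helix_spec(20, kink_residue = 10,
                                                   kink_angle = 30)))
  dev <- region_superpose_deviation(straight, kinked, fit_range = 1:9,
                                    measure_range = 11:20)
  # grows with distance from the hinge (sampled at one-turn spacing, since
  # per-residue values carry the helical wobble)
  turn <- dev$deviation[dev$resno %in% c(11, 14, 17, 20)]
  expect_true(all(diff(turn) > 0))
  expect_gt(mean(dev$deviation[dev$resno >= 16]),
            mean(dev$deviation[dev$resno <= 14]))
  # fitting and measuring the whole chain reproduces chain_rmsd deviations
  nz <- get_chain(make_ideal_helix(helix_spec(20, noise_sigma = 0.3,
                                              seed = 12)))
  whole <- region_superpose_deviation(straight, nz, 1:20, 1:20)
  expect_equal(whole$deviation, chain_rmsd(straight, nz)$deviations,
               tolerance = 1e-9)
})

test_that("dual models are assigned to their nearest reference", {
  du <- make_dual_conformer_file(helix_spec(20), 8:14, displacement = 11)
  sp <- split_conformers(du)
  res <- compare_dual_model(du, references = list(one = sp$A, two = sp$B))
  expect_equal(unname(res$assignment[c("A", "B")]), c("one", "two"))
  expect_equal(res$rmsd["A", "one"], 0, tolerance = 1e-9)
  expect_equal(res$rmsd["B", "two"], 0, tolerance = 1e-9)
  expect_gt(res$rmsd["A", "two"], 1)
  # invariant under reference ordering
  res2 <- compare_dual_model(du, references = list(two = sp$B, one = sp$A))
  expect_equal(unname(res2$assignment[c("A", "B")]), c("one", "two"))
  expect_error(compare_dual_model(du, references = list()), "reference")
  expect_error(compare_dual_model(du, references = list(sp$A)), "named")
})
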