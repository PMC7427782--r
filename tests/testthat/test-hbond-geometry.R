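test_that("rebuilt amide hydrogens have the declared geometry", {
  ch <- get_chain(make_ideal_helix(helix_spec(10)))
  withH <- build_amide_hydrogens(ch)
  hs <- withH[withH$elety == "H", ]
  expect_equal(nrow(hs), 9)                 # all but the first residue
  for (r in hs$resno) {
    N <- atom_xyz(withH, r, "N")
    H <- atom_xyz(withH, r, "H")
    CA <- atom_xyz(withH, r, "CA")
    Cp <- atom_xyz(withH, r - 1, "C")
    expect_equal(dist3(N, H), 1.00, tolerance = 1e-9)
    # coplanar with C(i-1), N, CA: zero volume of the tetrahedron
    vol <- abs(det(rbind(Cp - N, CA - N, H - N)))
    expect_lt(vol, 1e-9)
    # opposite the bisector: equal angles to both neighbours
    a1 <- acos(sum((Cp - N) * (H - N)) / (dist3(Cp, N) * 1.00))
    a2 <- acos(sum((CA - N) * (H - N)) / (dist3(CA, N) * 1.00))
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})

test_that("proline and chain starts receive no amide hydrogen", {
  sp <- helix_spec(10, sequence = c(rep("ALA", 5), "PRO", rep("ALA", 4)))
  withH <- build_amide_hydrogens(get_chain(make_ideal_helix(sp)))
  expect_false(any(withH$resno[withH$elety == "H"] %in% c(1, 6)))

  one <- toy_structure(rbind(c(0, 0, 0), c(1.46, 0, 0), c(2, 1.2, 0)),
                       elety = c("N", "CA", "C"), resno = c(1, 1, 1))
  wh <- build_amide_hydrogens(get_chain(one))
  expect_equal(sum(wh$elety == "H"), 0)
})

test_that("hydrogens already present in the input are discarded and rebuilt", {
  ch <- get_chain(make_ideal_helix(helix_spec(8)))
  fake <- ch[1, ]
  fake$elety <- "H"; fake$elesy <- "H"; fake$resno <- 4
  fake$x <- 99; fake$y <- 99; fake$z <- 99
  withH <- build_amide_hydrogens(rbind(ch, fake))
  H4 <- atom_xyz(withH, 4, "H")
  expect_lt(dist3(H4, atom_xyz(withH, 4, "N")), 1.01)
})

test_that("the helical scan matches a brute-force geometric recomputation", {
  for (pp in list(c(-57, -47), c(-49, -26))) {
    ch <- get_chain(make_ideal_helix(helix_spec(12, phi = pp[1], psi = pp[2])))
    withH <- build_amide_hydrogens(ch)
    rec <- scan_helical_hbonds(withH, 2:8)
    cfg <- geometry_config()
    for (k in seq_len(nrow(rec))) {
      O <- atom_xyz(withH, rec$i[k], "O")
      N <- atom_xyz(withH, rec$j[k], "N")
      expect_equal(rec$d_ON[k], dist3(O, N), tolerance = 1e-9)
      H <- atom_xyz(withH, rec$j[k], "H")
      ang <- acos(sum((O - H) * (N - H)) /
                    (dist3(O, H) * dist3(N, H))) * 180 / pi
      expect_equal(rec$angle_OHN[k], ang, tolerance = 1e-6)
      expect_identical(rec$is_bond[k],
                       round(rec$d_ON[k], 1) <= cfg$hbond_max_ON &&
                         !is.na(rec$angle_OHN[k]) &&
                         rec$angle_OHN[k] >= cfg$hbond_min_angle &&
                         !rec$donor_is_proline[k])
    }
  }
})

test_that("ideal helices are told apart by offset and verdict", {
  cha <- get_chain(make_ideal_helix(helix_spec(12)))
  rec <- scan_helical_hbonds(cha, 3:7)
  r4 <- rec[rec$offset == 4, ]; r3 <- rec[rec$offset == 3, ]
  expect_true(all(r4$is_bond))
  expect_true(all(r4$d_ON < r3$d_ON))      # alpha: i+4 partner is the nearer
  expect_false(any(r3$is_bond))            # rejected by the at-H angle

  ch3 <- get_chain(make_ideal_helix(helix_spec(12, phi = -49, psi = -26)))
  rec3 <- scan_helical_hbonds(ch3, 3:7)
  expect_true(all(rec3$d_ON[rec3$offset == 3] < rec3$d_ON[rec3$offset == 4]))
  expect_true(all(rec3$is_bond[rec3$offset == 3]))
  expect_false(any(rec3$is_bond[rec3$offset == 4]))
})

test_that("classification labels ideal helices correctly", {
  cha <- get_chain(make_ideal_helix(helix_spec(12)))
  cla <- classify_helix(cha, 2:11)
  expect_true(all(cla$label == "alpha"))
  ch3 <- get_chain(make_ideal_helix(helix_spec(12, phi = -49, psi = -26)))
  cl3 <- classify_helix(ch3, 2:11)
  expect_true(all(cl3$label == "three10"))
  # every non-trivial label is supported by at least one recorded bond
  rec <- attr(cla, "records")
  for (r in cla$resno[cla$label != "turn_or_none"])
    expect_true(any(rec$i == r | rec$j == r))
})

test_that("an extended chain classifies as neither helix", {
  ext <- get_chain(make_ideal_helix(helix_spec(12, phi = -120, psi = 130)))
  cl <- classify_helix(ext, 2:11)
  expect_true(all(cl$label == "turn_or_none"))
})

test_that("proline donors never form a bond", {
  # place PRO where it would receive the alpha i+4 bond
  for (pos in 6:8) {
    seqs <- rep("ALA", 14); seqs[pos] <- "PRO"
    ch <- get_chain(make_ideal_helix(helix_spec(14, sequence = seqs)))
    rec <- scan_helical_hbonds(ch, 2:10)
    pro <- rec[rec$res_j == "PRO", ]
    expect_gt(nrow(pro), 0)
    expect_false(any(pro$is_bond))
    expect_true(all(pro$donor_is_proline))
  }
})

test_that("the verdict is a pure function of rounded distance and angle", {
  cfg <- geometry_config()
  v <- hbond_verdict(c(3.54, 3.56, 3.449, 2.0, 3.2), c(150, 150, 129.9, 150, 131),
                     config = cfg)
  expect_identical(v$is_bond, c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(v$is_weak, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  # raw-distance mode flips the 3.54 case
  raw <- geometry_config(round_distances = FALSE)
  expect_false(hbond_verdict(3.54, 150, config = raw)$is_bond)
  # proline always loses
  expect_false(hbond_verdict(2.9, 170, donor_is_proline = TRUE)$is_bond)
})

test_that("count_bonds filters by offset and acceptor range", {
  ch <- get_chain(make_ideal_helix(helix_spec(14)))
  rec <- scan_helical_hbonds(ch, 2:9)
  expect_equal(count_bonds(rec, 4, 2:9), 8)
  expect_equal(count_bonds(rec, 3, 2:9), 0)
  expect_equal(count_bonds(rec, 4, 2:5), 4)
  empty <- rec[0, ]
  expect_equal(count_bonds(empty, 3), 0)
})

test_that("named atom distances are exact and errors name the atom", {
  s <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)), elety = c("CA", "CA"),
                     resno = c(1, 2))
  ch <- get_chain(s)
  expect_equal(named_atom_distance(ch, 1, "CA", 2, "CA"), 5.0)
  expect_equal(named_atom_distance(ch, 1, "CA", 1, "CA"), 0.0)
  expect_error(named_atom_distance(ch, 1, "CB", 2, "CA"), "CB")
})

test_that("residue contacts are symmetric and the cutoff is inclusive", {
  s <- toy_structure(rbind(c(0, 0, 0), c(4, 0, 0), c(9, 0, 0)),
                     elety = c("CA", "CA", "CA"), resno = 1:3)
  a <- s$atom[1, , drop = FALSE]
  b <- s$atom[2:3, , drop = FALSE]
  fwd <- residue_contacts(a, b, cutoff = 4.0)
  expect_equal(nrow(fwd), 1)                 # exactly at the cutoff: included
  expect_equal(fwd$resno_b, 2)
  expect_equal(fwd$dist, 4.0)
  rev <- residue_contacts(b, a, cutoff = 4.0)
  expect_equal(rev$resno_a, fwd$resno_b)
  expect_equal(rev$dist, fwd$dist)
  none <- residue_contacts(a, s$atom[3, , drop = FALSE], cutoff = 4.0)
  expect_equal(nrow(none), 0)
  expect_error(residue_contacts(a[0, ], b), "empty")
})

test_that("contacts report the minimal heavy-atom distance, hydrogens excluded", {
  ha <- toy_structure(rbind(c(0, 0, 0), c(0, 1, 0)), elety = c("CA", "CB"),
                      resno = c(1, 1), elesy = c("C", "C"))
  hb <- toy_structure(rbind(c(3, 0, 0), c(2, 0, 0)), elety = c("CA", "H"),
                      resno = c(9, 9), elesy = c("C", "H"), chain = "B")
  out <- residue_contacts(ha$atom, hb$atom, cutoff = 4)
  expect_equal(nrow(out), 1)
  expect_equal(out$dist, 3)                  # the H at 2 A is ignored
})
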