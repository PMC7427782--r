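#' Geometry thresholds and conventions
#'
#' Every threshold the hydrogen-bond and contact analyses depend on, in one
#' explicit object. The defaults implement the criteria used to assign the
#' 3(10)-helical stretch of AdipoR1 helix V: a main-chain CO(i)...HN(j) pair
#' counts as a hydrogen bond when the O...N distance, rounded to one decimal,
#' is at most `hbond_max_ON` (3.5 Angstrom) and the O...H-N angle measured at
#' the hydrogen is at least `hbond_min_angle` (130 degrees; 180 is a linear
#' bond, and candidates at 102-125 degrees are rejected). Bonds whose rounded
#' distance falls in `weak_band` (3.2-3.5) are flagged weak.
#'
#' The distance criterion is applied to the rounded value because printed
#' hydrogen-bond tables quote one decimal and count 3.5-Angstrom pairs as
#' bonds; set `round_distances = FALSE` to threshold the raw value instead.
#'
#' @param hbond_max_ON maximal O...N distance, Angstrom.
#' @param hbond_min_angle minimal O...H-N angle at the hydrogen, degrees.
#' @param NH_length rebuilt amide N-H bond length, Angstrom.
#' @param weak_band distance band (Angstrom pair) marking weak bonds.
#' @param contact_cutoff heavy-atom contact cutoff, Angstrom.
#' @param coordination_cutoff metal coordination cutoff, Angstrom.
#' @param round_distances apply the distance threshold to the one-decimal
#'   rounded O...N distance (default `TRUE`).
#' @return an object of class `geometry_config`.
#' @export
geometry_config <- function(hbond_max_ON = 3.5, hbond_min_angle = 130,
                            NH_length = 1.00, weak_band = c(3.2, 3.5),
                            contact_cutoff = 4.0, coordination_cutoff = 2.6,
                            round_distances = TRUE) {
  if (any(c(hbond_max_ON, NH_length, contact_cutoff, coordination_cutoff) <= 0))
    stop("all cutoffs must be positive")
  if (length(weak_band) != 2 || weak_band[1] <= 0 ||
      weak_band[2] > hbond_max_ON || weak_band[1] > weak_band[2])
    stop("weak_band must lie within (0, hbond_max_ON]")
  structure(list(hbond_max_ON = hbond_max_ON,
                 hbond_min_angle = hbond_min_angle,
                 NH_length = NH_length, weak_band = weak_band,
                 contact_cutoff = contact_cutoff,
                 coordination_cutoff = coordination_cutoff,
                 round_distances = round_distances),
            class = "geometry_config")
}

#' Rebuild main-chain amide hydrogens
#'
#' X-ray structures at typical membrane-protein resolution carry no
#' experimental hydrogens, so the amide H of every residue is rebuilt from
#' heavy-atom geometry: at `NH_length` from N, in the C(i-1)-N-CA plane,
#' along the direction opposite the bisector of the unit vectors N->C(i-1)
#' and N->CA. The first residue of a chain (or after a chain break, detected
#' as C(i-1)...N(i) >= 2 Angstrom) and proline — whose ring nitrogen has no
#' amide hydrogen — get none. Hydrogens already present in the input are
#' discarded first, so verdicts never depend on deposition practice.
#'
#' @param atoms single-conformer, single-chain atom data.frame.
#' @param config a [geometry_config()].
#' @return the atom table with one `H` row added per eligible residue; the
#'   residues skipped for missing backbone atoms are listed in
#'   `attr(, "gap_report")`.
#' @export
build_amide_hydrogens <- function(atoms, config = geometry_config()) {
  atoms <- as_atom_table(atoms)
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  res <- .residue_table(atoms)
  gaps <- list()
  hrows <- list()
  for (i in seq_len(nrow(res))) {
    if (i == 1) next
    ri <- res$resno[i]; ins <- res$insert[i]
    if (res$resid[i] == "PRO") next
    sel <- atoms$resno == ri & atoms$insert == ins
    N <- .atom_xyz(atoms, ri, "N", ins)
    CA <- .atom_xyz(atoms, ri, "CA", ins)
    Cprev <- .atom_xyz(atoms, res$resno[i - 1], "C", res$insert[i - 1])
    if (is.null(N) || is.null(CA) || is.null(Cprev)) {
      gaps[[length(gaps) + 1]] <- data.frame(resno = ri, insert = ins,
        reason = "missing backbone atom", stringsAsFactors = FALSE)
      next
    }
    if (.dist3(Cprev, N) >= 2.0) next   # chain break: treated as a new start
    hdir <- -(.unit(Cprev - N) + .unit(CA - N))
    H <- N + config$NH_length * .unit(hdir)
    tmpl <- atoms[which(sel)[1], , drop = FALSE]
    tmpl$type <- "ATOM"; tmpl$elety <- "H"; tmpl$elesy <- "H"
    tmpl$x <- H[1]; tmpl$y <- H[2]; tmpl$z <- H[3]
    hrows[[length(hrows) + 1]] <- tmpl
  }
  out <- rbind(atoms, do.call(rbind, hrows))
  out <- out[order(out$resno, out$insert), , drop = FALSE]
  out$eleno <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "gap_report") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(resno = integer(0), insert = character(0),
               reason = character(0))
  out
}

#' Scan helical main-chain hydrogen-bond candidates
#'
#' For every acceptor residue i in `residue_range`, evaluates the
#' CO(i)...HN(j) candidates at the two helical offsets j - i = 3 (the
#' 3(10)-helical bond) and j - i = 4 (the alpha-helical bond): O(i)...N(j)
#' distance, O...H-N angle at the rebuilt hydrogen of j, and the bond
#' verdict under `config`. A proline donor can never form the bond (it has
#' no amide hydrogen); the record is kept with `is_bond = FALSE` so the
#' missing partner is visible in reports.
#'
#' @param atoms single-conformer, single-chain atom data.frame; amide
#'   hydrogens are rebuilt automatically if absent.
#' @param residue_range author residue numbers of the acceptors (CO side).
#' @param config a [geometry_config()].
#' @return data.frame with one row per (acceptor, offset): columns `chain`,
#'   `i`, `res_i`, `j`, `res_j`, `offset`, `d_ON`, `angle_OHN`, `is_bond`,
#'   `is_weak`, `donor_is_proline`.
#' @export
scan_helical_hbonds <- function(atoms, residue_range,
                                config = geometry_config()) {
  atoms <- as_atom_table(atoms)
  if (!any(atoms$elety == "H"))
    atoms <- build_amide_hydrogens(atoms, config)
  present <- unique(atoms$resno)
  if (!any(residue_range %in% present))
    stop("residue_range lies outside the chain")
  ch <- atoms$chain[1]
  rows <- list()
  for (i in sort(intersect(residue_range, present))) {
    O <- .atom_xyz(atoms, i, "O")
    if (is.null(O)) next
    for (off in c(3L, 4L)) {
      j <- i + off
      N <- .atom_xyz(atoms, j, "N")
      if (is.null(N)) next
      H <- .atom_xyz(atoms, j, "H")
      resj <- atoms$resid[atoms$resno == j][1]
      d <- .dist3(O, N)
      ang <- if (is.null(H)) NA_real_ else .angle_deg(O, H, N)
      rows[[length(rows) + 1]] <- data.frame(
        chain = ch, i = i, res_i = atoms$resid[atoms$resno == i][1],
        j = j, res_j = resj, offset = off, d_ON = d, angle_OHN = ang,
        donor_is_proline = identical(resj, "PRO"),
        stringsAsFactors = FALSE)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chain = character(0), i = integer(0), res_i = character(0),
               j = integer(0), res_j = character(0), offset = integer(0),
               d_ON = numeric(0), angle_OHN = numeric(0),
               donor_is_proline = logical(0))
  verdict <- hbond_verdict(rec$d_ON, rec$angle_OHN, rec$donor_is_proline,
                           config)
  rec$is_bond <- verdict$is_bond
  rec$is_weak <- verdict$is_weak
  rec[, c("chain", "i", "res_i", "j", "res_j", "offset", "d_ON",
          "angle_OHN", "is_bond", "is_weak", "donor_is_proline")]
}

#' Hydrogen-bond verdict as a pure function of the geometry
#'
#' @param d_ON O...N distance(s), Angstrom.
#' @param angle_OHN O...H-N angle(s) at the hydrogen, degrees (NA when the
#'   donor has no hydrogen).
#' @param donor_is_proline logical vector.
#' @param config a [geometry_config()].
#' @return list with logical vectors `is_bond` and `is_weak`.
#' @export
hbond_verdict <- function(d_ON, angle_OHN, donor_is_proline = FALSE,
                          config = geometry_config()) {
  d_eff <- if (config$round_distances) round(d_ON, 1) else d_ON
  is_bond <- !donor_is_proline & !is.na(angle_OHN) &
    d_eff <= config$hbond_max_ON & angle_OHN >= config$hbond_min_angle
  is_weak <- is_bond & d_eff >= config$weak_band[1]
  list(is_bond = is_bond, is_weak = is_weak)
}

#' Count hydrogen bonds at one offset over an acceptor range
#'
#' @param records output of [scan_helical_hbonds()].
#' @param offset 3 or 4.
#' @param acceptor_range author residue numbers of the acceptors to count;
#'   default: all.
#' @return integer bond count.
#' @export
count_bonds <- function(records, offset, acceptor_range = NULL) {
  keep <- records$is_bond & records$offset == offset
  if (!is.null(acceptor_range)) keep <- keep & records$i %in% acceptor_range
  sum(keep)
}

#' Classify residues as alpha-, 3(10)-helical or neither
#'
#' A residue participating (as CO acceptor or HN donor) only in offset-4
#' bonds is labelled `alpha`; only in offset-3 bonds, `three10`; in both,
#' by the bond with the shorter O...N distance (ties resolve to alpha, the
#' more common geometry); in neither, `turn_or_none`.
#'
#' @param atoms single-conformer, single-chain atom data.frame.
#' @param residue_range author residue numbers to classify.
#' @param config a [geometry_config()].
#' @return data.frame with columns `resno`, `resid`, `label`; the supporting
#'   bond records are attached as `attr(, "records")`.
#' @export
classify_helix <- function(atoms, residue_range, config = geometry_config()) {
  atoms <- as_atom_table(atoms)
  scan_from <- (min(residue_range) - 4L):max(residue_range)
  rec <- scan_helical_hbonds(atoms, scan_from, config)
  bonds <- rec[rec$is_bond, , drop = FALSE]
  res <- .residue_table(atoms)
  res <- res[res$resno %in% residue_range, , drop = FALSE]
  lab <- vapply(res$resno, function(r) {
    mine <- bonds[bonds$i == r | bonds$j == r, , drop = FALSE]
    if (nrow(mine) == 0) return("turn_or_none")
    offs <- unique(mine$offset)
    if (all(offs == 3L)) return("three10")
    if (all(offs == 4L)) return("alpha")
    d3 <- min(mine$d_ON[mine$offset == 3])
    d4 <- min(mine$d_ON[mine$offset == 4])
    if (d4 <= d3) "alpha" else "three10"
  }, character(1))
  out <- data.frame(resno = res$resno, resid = res$resid, label = lab,
                    stringsAsFactors = FALSE)
  attr(out, "records") <- bonds
  out
}

#' Distance between two named atoms
#'
#' @param atoms atom data.frame.
#' @param res_a,res_b author residue numbers.
#' @param atom_a,atom_b atom names (e.g. `"O"`, `"N"`).
#' @param digits decimals in the reported value (default 1, matching the
#'   reporting precision of structure papers).
#' @return distance in Angstrom.
#' @export
named_atom_distance <- function(atoms, res_a, atom_a, res_b, atom_b,
                                digits = 1) {
  atoms <- as_atom_table(atoms)
  a <- .atom_xyz(atoms, res_a, atom_a)
  if (is.null(a)) stop("atom not found: residue ", res_a, " ", atom_a)
  b <- .atom_xyz(atoms, res_b, atom_b)
  if (is.null(b)) stop("atom not found: residue ", res_b, " ", atom_b)
  round(.dist3(a, b), digits)
}

#' Residue-level contacts between two atom selections
#'
#' Lists every residue pair with any heavy-atom pair within the cutoff
#' (inclusive), with the minimal heavy-atom distance, sorted by distance.
#' Hydrogens are excluded; ligand selections are permitted.
#'
#' @param sel_a,sel_b atom data.frames (e.g. subsets of a chain, or a
#'   ligand's atoms).
#' @param cutoff heavy-atom distance cutoff in Angstrom; defaults to the
#'   `contact_cutoff` of `config`.
#' @param config a [geometry_config()].
#' @return data.frame: `chain_a`, `resno_a`, `resid_a`, `chain_b`,
#'   `resno_b`, `resid_b`, `dist`.
#' @export
residue_contacts <- function(sel_a, sel_b, cutoff = NULL,
                             config = geometry_config()) {
  sel_a <- as_atom_table(sel_a); sel_b <- as_atom_table(sel_b)
  sel_a <- sel_a[!(sel_a$elesy %in% c("H", "D")), , drop = FALSE]
  sel_b <- sel_b[!(sel_b$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(sel_a) == 0 || nrow(sel_b) == 0)
    stop("empty atom selection")
  if (is.null(cutoff)) cutoff <- config$contact_cutoff
  A <- .xyz_matrix(sel_a); B <- .xyz_matrix(sel_b)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2 + 1e-9, arr.ind = TRUE)
  if (nrow(hit) == 0)
    return(data.frame(chain_a = character(0), resno_a = integer(0),
                      resid_a = character(0), chain_b = character(0),
                      resno_b = integer(0), resid_b = character(0),
                      dist = numeric(0)))
  df <- data.frame(
    chain_a = sel_a$chain[hit[, 1]], resno_a = sel_a$resno[hit[, 1]],
    resid_a = sel_a$resid[hit[, 1]],
    chain_b = sel_b$chain[hit[, 2]], resno_b = sel_b$resno[hit[, 2]],
    resid_b = sel_b$resid[hit[, 2]],
    dist = sqrt(d2[hit]), stringsAsFactors = FALSE)
  key <- paste(df$chain_a, df$resno_a, df$chain_b, df$resno_b)
  best <- tapply(seq_len(nrow(df)), key, function(ix) ix[which.min(df$dist[ix])])
  out <- df[as.integer(best), , drop = FALSE]
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coordination sphere of a metal
#'
#' For every atom of `center_element`, lists the potential coordinating
#' atoms within the cutoff: carbons, hydrogens and waters are excluded, and
#' each partner is reported with its parent residue — e.g. the three
#' conserved histidine nitrogens around the receptor's zinc.
#'
#' @param s a [structure3d] or atom data.frame.
#' @param center_element element symbol of the metal (default `"ZN"`).
#' @param cutoff coordination cutoff, Angstrom; defaults to
#'   `coordination_cutoff` of `config`.
#' @param config a [geometry_config()].
#' @return data.frame: metal identification plus partner `chain`, `resno`,
#'   `resid`, `elety`, `elesy`, `dist`. Empty (with a warning) when the
#'   element is absent.
#' @export
coordination_sphere <- function(s, center_element = "ZN", cutoff = NULL,
                                config = geometry_config()) {
  a <- as_atom_table(s)
  if (is.null(cutoff)) cutoff <- config$coordination_cutoff
  centers <- which(toupper(a$elesy) == toupper(center_element))
  empty <- data.frame(metal_chain = character(0), metal_resno = integer(0),
                      chain = character(0), resno = integer(0),
                      resid = character(0), elety = character(0),
                      elesy = character(0), dist = numeric(0))
  if (length(centers) == 0) {
    warning("no atoms of element '", center_element, "' present")
    return(empty)
  }
  partners <- which(!(toupper(a$elesy) %in%
                        c("C", "H", "D", toupper(center_element))) &
                      !(a$resid %in% .water_resids()))
  rows <- list()
  for (m in centers) {
    p0 <- as.numeric(a[m, c("x", "y", "z")])
    for (p in partners) {
      d <- .dist3(p0, as.numeric(a[p, c("x", "y", "z")]))
      if (d <= cutoff + 1e-9)
        rows[[length(rows) + 1]] <- data.frame(
          metal_chain = a$chain[m], metal_resno = a$resno[m],
          chain = a$chain[p], resno = a$resno[p], resid = a$resid[p],
          elety = a$elety[p], elesy = a$elesy[p], dist = d,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$dist), , drop = FALSE]
}

# ---- internal ---------------------------------------------------------------

# one row per residue, in storage order
.residue_table <- function(atoms) {
  key <- paste(atoms$resno, atoms$insert, sep = "\r")
  first <- !duplicated(key)
  data.frame(resno = atoms$resno[first], insert = atoms$insert[first],
             resid = atoms$resid[first], stringsAsFactors = FALSE)
}
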