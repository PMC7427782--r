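#' Read a structure from PDB or mmCIF
#'
#' Parses a coordinate file into a [structure3d]. Author numbering, alternate
#' location labels and occupancies are preserved exactly as deposited; this
#' matters for dual-conformation models in which part of the chain was
#' refined as a mixture of two states under altloc labels with fractional
#' occupancies. Hydrogens present in the file are kept on read but every
#' geometry routine in this package rebuilds amide hydrogens itself, so
#' deposition practice does not influence hydrogen-bond verdicts.
#'
#' Parsing of both formats is delegated to \pkg{bio3d}
#' (`read.pdb`/`read.cif`) with altloc removal disabled. Gzip-compressed
#' files (`.gz`) are decompressed transparently.
#'
#' @param path file path (`.pdb`, `.ent`, `.cif`, `.mmcif`, optionally `.gz`).
#' @param format `"pdb"` or `"mmcif"`; by default inferred from the
#'   extension.
#' @param drop_water remove water residues on read (default `FALSE`, so
#'   modeled-atom counts match depositions).
#' @return a [structure3d].
#' @export
read_structure <- function(path, format = NULL, drop_water = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  real <- path
  if (grepl("\\.gz$", path, ignore.case = TRUE)) {
    real <- tempfile(fileext = paste0(".", .strip_gz_ext(path)))
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    writeLines(readLines(con), real)
  }
  if (is.null(format)) format <- .guess_format(real)
  format <- match.arg(format, c("pdb", "mmcif"))

  parsed <- tryCatch(
    if (format == "pdb") {
      suppressWarnings(bio3d::read.pdb(real, rm.alt = FALSE, verbose = FALSE))
    } else {
      suppressWarnings(bio3d::read.cif(real, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) stop("failed to parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))

  a <- parsed$atom
  atom <- data.frame(
    type  = a$type,
    eleno = a$eleno,
    elety = a$elety,
    alt   = ifelse(is.na(a$alt), "", a$alt),
    resid = a$resid,
    chain = ifelse(is.na(a$chain), "", a$chain),
    resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    b = ifelse(is.na(a$b), 0, a$b),
    elesy = .fill_element(a$elesy, a$elety),
    stringsAsFactors = FALSE
  )
  if (nrow(atom) == 0) {
    # distinguish an empty model from an unrecognisable file
    head <- tryCatch(readLines(real, n = 100, warn = FALSE),
                     error = function(e) character(0))
    known <- c("^(ATOM|HETATM|HEADER|REMARK|CRYST1|MODEL|TER|END)",
               "^(data_|loop_|#|_atom_site)")
    if (length(head) > 0 && !any(grepl(paste(known, collapse = "|"), head)))
      stop("failed to parse '", path, "' as ", format,
           ": no recognisable records", call. = FALSE)
  }
  if (drop_water) atom <- atom[!atom$resid %in% .water_resids(), , drop = FALSE]
  structure3d(atom, id = sub("\\.(gz)$", "",
                             sub("\\.(pdb|ent|cif|mmcif)(\\.gz)?$", "",
                                 basename(path), ignore.case = TRUE)),
              source_format = format)
}

#' Write a structure to PDB or mmCIF
#'
#' Coordinates, author numbering, altloc labels and occupancies survive a
#' write/read round trip (to the 3-decimal precision of the formats, i.e.
#' 1e-3 Angstrom). PDB output goes through `bio3d::write.pdb`; mmCIF output
#' is an `atom_site` loop written directly.
#'
#' @param s a [structure3d].
#' @param path output file path.
#' @param format `"pdb"` or `"mmcif"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = NULL) {
  validate_structure3d(s)
  if (is.null(format)) format <- .guess_format(path)
  format <- match.arg(format, c("pdb", "mmcif"))
  a <- s$atom
  if (nrow(a) > 0 && format == "pdb") {
    bad <- unique(a$elety[nchar(a$elety) > 4])
    if (length(bad) > 0)
      stop("atom name(s) too long for PDB columns: ",
           paste(bad, collapse = ", "))
  }
  if (format == "pdb") {
    if (nrow(a) == 0) { writeLines("END", path); return(invisible(path)) }
    xyz <- as.vector(t(.xyz_matrix(a)))
    bio3d::write.pdb(pdb = NULL, file = path, xyz = xyz,
                     type = a$type, resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = ifelse(a$chain == "", " ", a$chain),
                     insert = ifelse(a$insert == "", "", a$insert),
                     alt = ifelse(a$alt == "", "", a$alt),
                     o = a$o, b = a$b, elesy = a$elesy, end = TRUE)
  } else {
    .write_mmcif(s, path)
  }
  invisible(path)
}

#' Split a dual-conformation model into single-conformer structures
#'
#' Crystallographic models that were refined as a mixture of two states carry
#' the state-specific atoms under alternate-location labels. This function
#' produces one complete single-conformer structure per label: each output
#' contains all blank-altloc atoms plus the atoms of exactly one label;
#' residues never modeled in alternates contribute their shared atoms to both
#' outputs (`fill_rule = "shared"`). The label-specific atoms of the outputs
#' partition the input's altloc atoms.
#'
#' Which label corresponds to which physical state is a deposition
#' convention, not a law: the default mapping keeps the labels as conformer
#' names; to resolve states, compare each conformer against reference models
#' with [compare_dual_model()].
#'
#' @param s a [structure3d] (may have zero altlocs, in which case every
#'   output equals the input).
#' @param mapping named character vector `c(A = "closed", B = "open", ...)`
#'   from altloc label to conformer name. Default: identity over the labels
#'   present (or a single unnamed output `"full"` when there are none).
#' @param fill_rule only `"shared"` is implemented: residues lacking a label
#'   use their blank-altloc atoms.
#' @return named list of single-conformer [structure3d] objects.
#' @export
split_conformers <- function(s, mapping = NULL, fill_rule = "shared") {
  fill_rule <- match.arg(fill_rule, "shared")
  a <- s$atom
  labels <- sort(unique(a$alt[nzchar(a$alt)]))
  if (is.null(mapping)) {
    mapping <- if (length(labels) == 0) c(full = "full") else
      stats::setNames(labels, labels)
  }
  if (length(labels) > 0) {
    unmapped <- setdiff(labels, names(mapping))
    if (length(unmapped) > 0)
      stop("altloc label(s) not covered by mapping: ",
           paste(unmapped, collapse = ", "))
  }
  out <- list()
  for (lab in names(mapping)) {
    keep <- a$alt == "" | a$alt == lab
    # a residue modeled only in other altlocs would vanish: that is an error
    res_all <- unique(paste(a$chain, a$resno, a$insert))
    res_kept <- unique(paste(a$chain, a$resno, a$insert)[keep])
    lost <- setdiff(res_all, res_kept)
    if (length(lost) > 0)
      stop("residue(s) with neither altloc '", lab, "' nor blank atoms: ",
           paste(lost, collapse = "; "))
    sub <- a[keep, , drop = FALSE]
    # single-conformer model: labels removed, state-specific atoms fully occupied
    was_alt <- nzchar(sub$alt)
    sub$alt <- ""
    sub$o[was_alt] <- 1
    out[[mapping[[lab]]]] <- structure3d(sub, id = paste0(s$id, ":", mapping[[lab]]),
                                         source_format = s$source_format)
  }
  out
}

#' Mean occupancy per altloc label over a residue range
#'
#' Averages the deposited occupancies of altloc-bearing atoms, per label,
#' over a residue range — the bookkeeping behind statements like "the model
#' is a 44:56 mixture of two forms". Reported to 2 decimals.
#'
#' @param s a [structure3d].
#' @param residue_range integer vector of author residue numbers.
#' @param chain optional chain id restriction.
#' @return named numeric vector (label -> mean occupancy); empty when the
#'   range contains no altloc atoms.
#' @export
conformer_occupancies <- function(s, residue_range, chain = NULL) {
  a <- s$atom
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  a <- a[nzchar(a$alt) & a$resno %in% residue_range, , drop = FALSE]
  if (nrow(a) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(a$o, a$alt, mean)
  round(stats::setNames(as.numeric(out), names(out)), 2)
}

# ---- internal ---------------------------------------------------------------

.guess_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", p))
  if (ext %in% c("pdb", "ent")) "pdb"
  else if (ext %in% c("cif", "mmcif")) "mmcif"
  else stop("cannot infer format from '", path, "'; pass `format`")
}

.strip_gz_ext <- function(path) {
  tolower(sub(".*\\.", "", sub("\\.gz$", "", path, ignore.case = TRUE)))
}

.fill_element <- function(elesy, elety) {
  out <- ifelse(is.na(elesy) | elesy == "", NA_character_, trimws(elesy))
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", trimws(elety)), 1, 1))
  ifelse(is.na(out), guess, out)
}

.write_mmcif <- function(s, path) {
  a <- s$atom
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(paste0("data_", ifelse(nzchar(s$id), s$id, "model")),
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  if (nrow(a) > 0) {
    lines <- sprintf(
      "%-6s %-6d %-2s %-4s %s %-3s %-2s 1 %-5d %s %8.3f %8.3f %8.3f %5.2f %6.2f %-5d %-3s %-2s %-4s 1",
      a$type, seq_len(nrow(a)), a$elesy, a$elety,
      ifelse(a$alt == "", ".", a$alt), a$resid,
      ifelse(a$chain == "", "A", a$chain), a$resno,
      ifelse(a$insert == "", "?", a$insert),
      a$x, a$y, a$z, a$o, a$b, a$resno, a$resid,
      ifelse(a$chain == "", "A", a$chain), a$elety)
    writeLines(lines, con)
  }
  writeLines("#", con)
  invisible(path)
}
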