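#' Run the full closed/open helix analysis
#'
#' Orchestrates every stage over the selected receptor chains of one
#' structure: amide hydrogen rebuilding, the helical hydrogen-bond scan over
#' helix V, per-residue alpha/3(10) classification, backbone dihedrals,
#' region axes with the M1-CT bend angle, the helical advance across the M2
#' region, the pairwise inter-chain CA RMSD matrix, per-residue CA
#' displacements of the mobile region between chain pairs (static-body fit),
#' and the metal coordination sphere. Deterministic given inputs and
#' configuration; stages that fail on a given chain (e.g. a range outside a
#' truncated model) are reported as `NULL` with the error message recorded,
#' and the remaining stages still run.
#'
#' A simple conformational-state call is included: a chain whose M2
#' acceptors form >= 3 offset-3 bonds is called `closed-like` (the bent,
#' 3(10)-stabilised geometry), <= 1 `open-like`, otherwise `intermediate`.
#'
#' @param s a [structure3d].
#' @param chains receptor chain ids (default: all chains classified
#'   `polymer` by [chain_roles()]).
#' @param regions a [region_scheme()].
#' @param config a [geometry_config()].
#' @param m2_acceptors acceptor residues of the diagnostic offset-3 count
#'   (default 274:277).
#' @param advance_start,advance_span residues of the advance metric
#'   (default 273 and 7, spanning the M2 region).
#' @param metal_element element scanned by [coordination_sphere()]
#'   (`NULL` to skip; default `"ZN"` with a silent skip when absent).
#' @return an `analysis_report` list; see [write_analysis_report()].
#' @export
analyze <- function(s, chains = NULL, regions = region_scheme(),
                    config = geometry_config(), m2_acceptors = 274:277,
                    advance_start = 273, advance_span = 7,
                    metal_element = "ZN") {
  stopifnot(inherits(s, "structure3d"))
  if (is.null(chains)) {
    roles <- chain_roles(s)
    chains <- roles$chain[roles$role == "polymer"]
  }
  if (length(chains) == 0) stop("no chains to analyse")
  try_stage <- function(expr) tryCatch(expr, error = function(e)
    structure(list(error = conditionMessage(e)), class = "stage_error"))

  per_chain <- lapply(chains, function(ch) {
    atoms <- get_chain(s, ch, conformer = if (any(nzchar(s$atom$alt))) "A")
    hv <- regions$helixV
    hb <- try_stage(scan_helical_hbonds(atoms, hv, config))
    cls <- try_stage(classify_helix(atoms, hv, config))
    dih <- try_stage(backbone_dihedrals(atoms))
    adv <- try_stage(helical_advance(atoms, advance_start, advance_span))
    axes <- try_stage({
      ax <- lapply(regions[c("M1", "CT")], function(rr) helix_axis(atoms, rr))
      list(M1 = ax$M1, CT = ax$CT,
           M1_CT_angle = interaxis_angle(ax$M1, ax$CT))
    })
    n3 <- if (inherits(hb, "stage_error")) NA_integer_ else
      count_bonds(hb, 3L, m2_acceptors)
    form <- if (is.na(n3)) NA_character_
      else if (n3 >= 3) "closed-like"
      else if (n3 <= 1) "open-like" else "intermediate"
    list(chain = ch, hbonds = hb, classification = cls, dihedrals = dih,
         advance = adv, axes = axes, m2_offset3_bonds = n3,
         form_call = form)
  })
  names(per_chain) <- chains

  comparisons <- list()
  if (length(chains) >= 2) {
    rmsd <- matrix(NA_real_, length(chains), length(chains),
                   dimnames = list(chains, chains))
    disp <- list()
    for (i in seq_along(chains)) {
      for (j in seq_along(chains)) {
        if (i >= j) next
        a <- get_chain(s, chains[i], conformer = if (any(nzchar(s$atom$alt))) "A")
        b <- get_chain(s, chains[j], conformer = if (any(nzchar(s$atom$alt))) "A")
        fit <- tryCatch(chain_rmsd(a, b), error = function(e) NULL)
        if (!is.null(fit)) rmsd[i, j] <- rmsd[j, i] <- fit$rmsd
        dd <- tryCatch(suppressWarnings(
          atom_displacement(a, b, fit_exclude = regions$mobile_region,
                            targets = regions$mobile_region)),
          error = function(e) NULL)
        disp[[paste(chains[i], chains[j], sep = "-")]] <- dd
      }
    }
    diag(rmsd) <- 0
    comparisons <- list(rmsd_matrix = rmsd, displacements = disp)
  }

  coord <- if (!is.null(metal_element) &&
               any(toupper(s$atom$elesy) == toupper(metal_element))) {
    coordination_sphere(s, metal_element, config = config)
  } else NULL

  structure(list(
    id = s$id,
    chains = per_chain,
    comparisons = comparisons,
    coordination = coord,
    provenance = list(
      input = s$id, source_format = s$source_format,
      tool = "helixstates",
      version = as.character(utils::packageVersion("helixstates")),
      config = unclass(config), regions = regions,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("analysis_report '%s': %d chain(s)\n", x$id, length(x$chains)))
  for (ch in x$chains)
    cat(sprintf("  chain %s: M2 offset-3 bonds %s -> %s\n", ch$chain,
                ch$m2_offset3_bonds, ch$form_call))
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' Serialises an `analysis_report` to JSON. Two runs with identical inputs
#' and configuration produce byte-identical files apart from the provenance
#' timestamp.
#'
#' @param report an `analysis_report` from [analyze()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_analysis_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  invisible(path)
}

#' Write a hydrogen-bond table as TSV
#'
#' Column layout mirrors the printed hydrogen-bond tables of structure
#' papers: chain, acceptor, donor, offset, O...N distance, O...H-N angle,
#' verdict.
#'
#' @param records output of [scan_helical_hbonds()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hbond_table <- function(records, path) {
  out <- records
  out$d_ON <- round(out$d_ON, 1)
  out$angle_OHN <- round(out$angle_OHN)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Locate or fetch a deposited PDB entry
#'
#' Looks for `<id>.pdb` / `<id>.cif` (optionally gzipped) in `dir` (default:
#' option `helixstates.pdb_dir`, falling back to `~/.helixstates`), and
#' otherwise attempts a one-time download from the RCSB archive into `dir`.
#' Errors when the entry is neither cached nor downloadable, so analyses of
#' deposited entries fail loudly instead of silently proceeding.
#'
#' @param id 4-character PDB accession, e.g. `"6KRZ"`.
#' @param dir cache directory.
#' @param timeout download timeout, seconds.
#' @return path to the coordinate file.
#' @export
fetch_pdb_entry <- function(id,
                            dir = getOption("helixstates.pdb_dir",
                                            file.path(path.expand("~"),
                                                      ".helixstates")),
                            timeout = 30) {
  id <- tolower(id)
  cand <- file.path(dir, c(paste0(id, ".pdb"), paste0(id, ".pdb.gz"),
                           paste0(id, ".cif"), paste0(id, ".cif.gz"),
                           paste0(toupper(id), ".pdb"),
                           paste0(toupper(id), ".cif")))
  hit <- cand[file.exists(cand)]
  if (length(hit) > 0) return(hit[1])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(dir, paste0(id, ".pdb"))
  url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
  old <- getOption("timeout"); options(timeout = timeout)
  on.exit(options(timeout = old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("PDB entry '", toupper(id), "' is not cached under '", dir,
         "' and could not be downloaded")
  }
  dest
}
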