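#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) into a [new_structure()]
#' `Structure`. Atoms keep file order and author residue numbering. When
#' alternate locations are present, the highest-occupancy altloc of each
#' atom is retained (ties broken alphabetically by altloc identifier).
#' Waters and other heteroatoms are retained, flagged by the `het` column.
#'
#' @param path path to a PDB file.
#' @return a `Structure`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  structure_from_bio3d(pdb, frame = 1L)
}

# convert a bio3d pdb object (one model) into a Structure, resolving altlocs
structure_from_bio3d <- function(pdb, frame = 1L) {
  at <- pdb$atom
  if (nrow(at) == 0L) stop("PDB contains no ATOM/HETATM records")
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = guess_element(at$elesy, at$elety),
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = ifelse(is.na(at$chain), "", at$chain),
    occupancy = ifelse(is.na(at$o), 1, pmin(pmax(at$o, 0), 1)),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    bfactor = ifelse(is.na(at$b), 0, at$b),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE)
  keep <- resolve_altlocs(atoms)
  xyz <- matrix(pdb$xyz[frame, ], ncol = 3L, byrow = TRUE)
  new_structure(atoms[keep, , drop = FALSE], xyz[keep, , drop = FALSE])
}

# indices to keep: per (chain, resid, name) group the highest-occupancy
# altloc, ties -> alphabetically first altloc
resolve_altlocs <- function(atoms) {
  grp <- paste(atoms$chain, atoms$resid, atoms$name, atoms$altloc != "")
  has_alt <- atoms$altloc != ""
  if (!any(has_alt)) return(seq_len(nrow(atoms)))
  keep <- rep(TRUE, nrow(atoms))
  grp <- paste(atoms$chain, atoms$resid, atoms$name)
  for (g in unique(grp[has_alt])) {
    idx <- which(grp == g & has_alt)
    if (length(idx) <= 1L) next
    best <- idx[order(-atoms$occupancy[idx], atoms$altloc[idx])][1L]
    keep[setdiff(idx, best)] <- FALSE
  }
  which(keep)
}

guess_element <- function(elesy, elety) {
  el <- trimws(ifelse(is.na(elesy), "", elesy))
  fallback <- sub("^[0-9]*", "", trimws(elety))
  fallback <- toupper(substr(fallback, 1L, 1L))
  out <- ifelse(nzchar(el), el, fallback)
  # normalize case: "FE" -> "Fe", single letters upper
  ifelse(nchar(out) == 2L,
         paste0(substr(out, 1, 1), tolower(substr(out, 2, 2))), toupper(out))
}

#' Write a structure to a PDB file
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @param bfactor optional numeric vector (length M) written into the
#'   B-factor column, e.g. a per-atom metric for surface heatmap rendering.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, bfactor = NULL) {
  a <- structure$atoms
  b <- if (is.null(bfactor)) a$bfactor else {
    stopifnot(length(bfactor) == nrow(a))
    bfactor
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(structure$xyz)),
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resid, o = a$occupancy,
                   b = b, elesy = a$element)
  invisible(path)
}

#' Read an ensemble (topology + frames)
#'
#' The mandatory frame format is multi-model PDB (MODEL/ENDMDL records);
#' the topology defines atom metadata and the frames supply coordinates.
#' Burn-in defaults to the first half of the frames, matching analysis of
#' the equilibrated tail of a trajectory.
#'
#' @param topology_path PDB file defining the topology.
#' @param frames_path multi-model PDB file with the frames. If omitted,
#'   `topology_path` is read as a multi-model PDB providing both.
#' @param burn_in_fraction fraction of initial frames excluded from
#'   analysis (default 0.5).
#' @return an `Ensemble`.
#' @export
read_ensemble <- function(topology_path, frames_path = NULL,
                          burn_in_fraction = 0.5) {
  topo <- read_structure(topology_path)
  src <- if (is.null(frames_path)) topology_path else frames_path
  multi <- suppressWarnings(bio3d::read.pdb(src, multi = TRUE, rm.alt = FALSE,
                                            verbose = FALSE))
  nf <- nrow(multi$xyz)
  m_frames <- ncol(multi$xyz) / 3L
  if (m_frames != n_atoms(topo))
    stop("atom-count mismatch: topology has ", n_atoms(topo),
         " atoms but frames have ", m_frames)
  new_ensemble(topo, multi$xyz, burn_in_fraction = burn_in_fraction)
}

#' Write an ensemble as topology PDB + multi-model PDB frames
#'
#' @param ensemble an `Ensemble`.
#' @param topology_path output PDB path for the topology (frame 1
#'   coordinates); `NULL` to skip.
#' @param frames_path output path for the multi-model PDB holding every
#'   frame.
#' @return `frames_path`, invisibly.
#' @export
write_ensemble <- function(ensemble, topology_path, frames_path) {
  topo <- ensemble$topology
  if (!is.null(topology_path)) write_structure(topo, topology_path)
  a <- topo$atoms
  bio3d::write.pdb(file = frames_path, xyz = ensemble$xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resid, o = a$occupancy,
                   b = a$bfactor, elesy = a$element)
  invisible(frames_path)
}

#' Download a deposited structure from the RCSB PDB
#'
#' Convenience fetch for validation against deposited experimental models
#' (requires network access).
#'
#' @param accession 4-character PDB accession, e.g. `"5U09"`.
#' @param dir download directory (default: session temp dir).
#' @return path to the downloaded PDB file.
#' @export
fetch_pdb <- function(accession, dir = tempdir()) {
  stopifnot(grepl("^[0-9][A-Za-z0-9]{3}$", accession))
  dest <- file.path(dir, paste0(toupper(accession), ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", toupper(accession), ".pdb")
    status <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
                       error = function(e) 1L, warning = function(w) 1L)
    if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) == 0) {
      unlink(dest)
      stop("could not download ", accession, " from RCSB (network required)")
    }
  }
  dest
}
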