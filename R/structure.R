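#' Structure: a single protein (or complex) conformation
#'
#' A `Structure` holds one conformation as an atom table plus an `M x 3`
#' coordinate matrix in Angstrom. Atom metadata follow PDB conventions:
#' author residue numbering is preserved verbatim, chain identifiers are
#' case-sensitive, and hydrogens (if present) are kept but excluded from all
#' downstream distance criteria.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `occupancy`, `altloc`, `bfactor`, `het`
#'   (logical, HETATM record).
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#'
#' @return An object of class `Structure` with elements `atoms` and `xyz`.
#' @export
new_structure <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms), is.matrix(xyz), ncol(xyz) == 3L)
  if (nrow(atoms) == 0L) stop("Structure must contain at least one atom")
  if (nrow(atoms) != nrow(xyz))
    stop("atom table (", nrow(atoms), ") and coordinates (", nrow(xyz),
         ") disagree in atom count")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  needed <- c("serial", "name", "element", "resname", "resid", "chain",
              "occupancy", "altloc", "bfactor", "het")
  missing <- setdiff(needed, names(atoms))
  if (length(missing)) stop("atoms lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  if (any(!nzchar(atoms$element))) stop("every atom needs an element symbol")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1))
    stop("occupancy must lie in [0, 1]")
  rownames(atoms) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  rk <- residue_keys(x)
  cat("Structure:", nrow(x$atoms), "atoms,", length(rk), "residues,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Residue keys of a structure
#'
#' Residues are identified by `chain:resid`; the key order is the order of
#' first appearance in the atom table.
#'
#' @param structure a `Structure`.
#' @return character vector of unique `chain:resid` keys.
#' @export
residue_keys <- function(structure) {
  unique(atom_residue_key(structure))
}

# per-atom residue key (chain:resid), length M
atom_residue_key <- function(structure) {
  paste(structure$atoms$chain, structure$atoms$resid, sep = ":")
}

#' Residue table of a structure
#' @param structure a `Structure`.
#' @return data.frame with one row per residue: `key`, `chain`, `resid`,
#'   `resname` (residue name of its first atom).
#' @export
residue_table <- function(structure) {
  key <- atom_residue_key(structure)
  first <- !duplicated(key)
  data.frame(key = key[first],
             chain = structure$atoms$chain[first],
             resid = structure$atoms$resid[first],
             resname = structure$atoms$resname[first],
             stringsAsFactors = FALSE)
}

# logical mask of heavy (non-hydrogen) atoms
heavy_mask <- function(structure) {
  !(toupper(structure$atoms$element) %in% c("H", "D"))
}

# atom indices (1-based) of a residue key, optionally heavy only
residue_atoms <- function(structure, key, heavy = TRUE) {
  idx <- which(atom_residue_key(structure) == key)
  if (heavy) idx <- idx[heavy_mask(structure)[idx]]
  idx
}

BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")

# mode atoms of given atom indices: "sidechain" (non-backbone heavy; CA
# stands in when a residue has no sidechain heavy atom, e.g. Gly) or
# "backbone" (N, CA, C, O)
mode_atoms <- function(structure, idx, mode = c("sidechain", "backbone")) {
  mode <- match.arg(mode)
  idx <- idx[heavy_mask(structure)[idx]]
  nm <- structure$atoms$name[idx]
  if (mode == "backbone") return(idx[nm %in% BACKBONE_NAMES])
  sc <- idx[!(nm %in% BACKBONE_NAMES)]
  if (length(sc) == 0L) sc <- idx[nm == "CA"]
  sc
}
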