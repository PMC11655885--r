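#' Match atoms between two structures
#'
#' Pairs atoms across structures by identical `(chain, residue number,
#' atom name)`; atoms present in only one structure are dropped and their
#' count reported via message. Useful for C-alpha pairings between
#' deposited models of the same protein.
#'
#' @param mobile,reference `Structure`s.
#' @param expression selection applied to both structures before matching
#'   (default `"calpha"`).
#' @return list of two equal-length `AtomIndexSet`s `mobile`/`reference`.
#' @export
match_atoms <- function(mobile, reference, expression = "calpha") {
  im <- select_atoms(mobile, expression)$indices
  ir <- select_atoms(reference, expression)$indices
  keym <- paste(mobile$atoms$chain[im], mobile$atoms$resid[im],
                mobile$atoms$name[im])
  keyr <- paste(reference$atoms$chain[ir], reference$atoms$resid[ir],
                reference$atoms$name[ir])
  common <- intersect(keym, keyr)
  dropped <- (length(keym) - length(common)) + (length(keyr) - length(common))
  if (dropped > 0)
    message(dropped, " unmatched atom(s) dropped from the pairing")
  list(mobile = new_atom_index_set(im[match(common, keym)], expression),
       reference = new_atom_index_set(ir[match(common, keyr)], expression))
}

#' Optimal rigid superposition of matched atoms
#'
#' Least-squares (Kabsch) fit of the mobile structure's matched atoms onto
#' the reference's; the returned rotation is proper (determinant +1).
#'
#' @param mobile,reference `Structure`s.
#' @param pairing matched index sets, as from [match_atoms()]: list with
#'   `mobile` and `reference` `AtomIndexSet`s of equal length (>= 3,
#'   non-collinear). *Order defines the atom pairing.*
#' @return a `SuperpositionResult`: list with `rotation` (3x3),
#'   `translation` (3-vector, A), `rmsd` (A), `n_atoms_used`, and
#'   `transformed` (the mobile `Structure` after fitting).
#' @export
superpose <- function(mobile, reference, pairing) {
  im <- pairing_indices(pairing, "mobile", mobile)
  ir <- pairing_indices(pairing, "reference", reference)
  if (length(im) != length(ir))
    stop("pairing index sets differ in length (", length(im), " vs ",
         length(ir), ")")
  fit <- kabsch_fit(mobile$xyz[im, , drop = FALSE],
                    reference$xyz[ir, , drop = FALSE],
                    check_degenerate = TRUE)
  transformed <- mobile
  transformed$xyz <- apply_transform(mobile$xyz, fit)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_atoms_used = length(im),
                 transformed = transformed),
            class = "SuperpositionResult")
}

pairing_indices <- function(pairing, side, structure) {
  x <- pairing[[side]]
  if (is.null(x)) stop("pairing needs a '", side, "' index set")
  idx <- if (inherits(x, "AtomIndexSet")) x$indices else as.integer(x)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_atoms(structure)))
    stop("pairing indices out of range for the ", side, " structure")
  idx
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition: rmsd %.3f A over %d atoms\n",
              x$rmsd, x$n_atoms_used))
  invisible(x)
}

#' Rotation angle of a domain between two structures
#'
#' Measures how far a domain (e.g. a fusion module) has rotated between
#' two structures, after removing the global pose difference: (1) the
#' second structure is superposed onto the first on `align_pairing`
#' (typically all receptor C-alphas); (2) the optimal rotation mapping the
#' first structure's domain atoms onto the transformed second structure's
#' domain atoms is computed; (3) the rotation's angle is extracted from
#' its trace (clamped into [-1, 1] for numerical safety).
#'
#' @param struct_a,struct_b `Structure`s.
#' @param align_pairing matched index sets (`a`, `b` or `mobile` applied
#'   to b / `reference` applied to a) used for the global alignment.
#' @param domain_pairing matched index sets for the domain.
#' @return rotation angle in degrees, in [0, 180].
#' @export
domain_rotation <- function(struct_a, struct_b, align_pairing,
                            domain_pairing) {
  norm_pair <- function(p) {
    if (!is.null(p$a) && !is.null(p$b)) list(reference = p$a, mobile = p$b)
    else p
  }
  ap <- norm_pair(align_pairing)
  dp <- norm_pair(domain_pairing)
  sup <- superpose(struct_b, struct_a, ap)
  ia <- pairing_indices(dp, "reference", struct_a)
  ib <- pairing_indices(dp, "mobile", struct_b)
  if (length(ia) != length(ib)) stop("domain pairing sets differ in length")
  fit <- kabsch_fit(struct_a$xyz[ia, , drop = FALSE],
                    sup$transformed$xyz[ib, , drop = FALSE],
                    check_degenerate = TRUE)
  rotation_angle_deg(fit$rotation)
}

#' Ligand contact shell
#'
#' All receptor residues with at least one heavy atom within `cutoff` of
#' at least one ligand heavy atom, with each residue's minimum distance
#' and the realizing atom pair; rows sorted by increasing distance.
#'
#' @param structure a `Structure`.
#' @param ligand_selection `AtomIndexSet` of the ligand (non-empty).
#' @param cutoff contact cutoff in A (default 4.0).
#' @return a `ContactTable` data.frame: `chain`, `resid`, `resname`,
#'   `min_distance`, `ligand_atom`, `residue_atom`.
#' @export
ligand_contacts <- function(structure, ligand_selection, cutoff = 4.0) {
  lig <- as_indices(ligand_selection, structure)
  lig <- lig[heavy_mask(structure)[lig]]
  if (length(lig) == 0L) stop("empty ligand selection")
  key <- atom_residue_key(structure)
  lig_res <- unique(key[lig])
  rec <- which(heavy_mask(structure) & !(key %in% lig_res))
  if (length(rec) == 0L) return(empty_contact_table())
  XL <- structure$xyz[lig, , drop = FALSE]
  XR <- structure$xyz[rec, , drop = FALSE]
  D2 <- outer(rowSums(XR^2), rowSums(XL^2), "+") - 2 * XR %*% t(XL)
  D <- sqrt(pmax(D2, 0))
  mind <- apply(D, 1L, min)
  hit <- mind <= cutoff
  if (!any(hit)) return(empty_contact_table())
  rows <- lapply(unique(key[rec[hit]]), function(res) {
    sel <- which(key[rec] == res & hit)
    j <- sel[which.min(mind[sel])]
    l <- which.min(D[j, ])
    i_res <- rec[j]
    data.frame(chain = structure$atoms$chain[i_res],
               resid = structure$atoms$resid[i_res],
               resname = structure$atoms$resname[i_res],
               min_distance = mind[j],
               ligand_atom = structure$atoms$name[lig[l]],
               residue_atom = structure$atoms$name[i_res],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$min_distance), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ContactTable", "data.frame")
  out
}

empty_contact_table <- function() {
  out <- data.frame(chain = character(), resid = integer(),
                    resname = character(), min_distance = numeric(),
                    ligand_atom = character(), residue_atom = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("ContactTable", "data.frame")
  out
}

#' Minimum heavy-atom distance between two selections
#'
#' @param structure a `Structure`.
#' @param sel_a,sel_b non-overlapping, non-empty `AtomIndexSet`s.
#' @return list with `distance` (A), `atom_a`, `atom_b` (1-based indices
#'   of the realizing pair; ties resolved to the lowest index pair).
#' @export
min_distance <- function(structure, sel_a, sel_b) {
  ia <- as_indices(sel_a, structure)
  ib <- as_indices(sel_b, structure)
  ia <- ia[heavy_mask(structure)[ia]]
  ib <- ib[heavy_mask(structure)[ib]]
  if (length(ia) == 0L || length(ib) == 0L)
    stop("both selections must contain heavy atoms")
  if (length(intersect(ia, ib)))
    stop("selections overlap in ", length(intersect(ia, ib)), " atom(s)")
  XA <- structure$xyz[ia, , drop = FALSE]
  XB <- structure$xyz[ib, , drop = FALSE]
  D2 <- outer(rowSums(XA^2), rowSums(XB^2), "+") - 2 * XA %*% t(XB)
  D <- sqrt(pmax(D2, 0))
  best <- which(D == min(D), arr.ind = TRUE)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(distance = min(D), atom_a = ia[best[1L]], atom_b = ib[best[2L]])
}
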