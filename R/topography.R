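#' Surface-topography parameters
#'
#' The topography score of atom k is the time average, over the analyzed
#' frames, of the mean exponential-contact density of its neighborhood:
#' \deqn{F_k = \langle N_{\Omega_k(t)}^{-1} \sum_{i \in \Omega_k(t)}
#'   \sum_{j \ne i}^{M} A_i e^{-B_i r_{ij}(t)} \rangle_t}
#' where \eqn{\Omega_k(t)} is the set of heavy atoms within distance `d` of
#' atom k at time t, and the inner sum runs over all M heavy atoms of the
#' molecule. Atoms buried in deep, narrow pockets accumulate many short
#' contacts and score high; exposed protuberances score low, so the score
#' grades local concavity versus convexity (the construction follows
#' exponential contact models for fast solvent-accessible-area estimates).
#'
#' `A` and `B` are atom-dependent parameters of that contact model. No
#' published table is assumed: the default is uniform `A = 1`, `B = 0.5`
#' 1/A for every element, which preserves the concavity ordering the score
#' is used for comparatively; supply `atom_params` to override per element.
#' The neighborhood radius `d` defaults to 6 A, commensurate with
#' first-shell heavy-atom contact distances. Both defaults are echoed in
#' result metadata.
#'
#' @param neighborhood_radius d, in A (> 0).
#' @param atom_params data.frame with columns `element`, `A`
#'   (dimensionless, > 0), `B` (1/A, > 0); elements not listed fall back to
#'   `default_A`/`default_B`.
#' @param default_A,default_B fallback parameters.
#' @param include_self logical; whether the central atom k belongs to its
#'   own neighborhood (default TRUE, which makes the two-atom closed form
#'   symmetric).
#' @return a `TopographyParams` list.
#' @export
topography_params <- function(neighborhood_radius = 6.0, atom_params = NULL,
                              default_A = 1.0, default_B = 0.5,
                              include_self = TRUE) {
  if (neighborhood_radius <= 0) stop("neighborhood_radius must be > 0")
  if (default_A <= 0 || default_B <= 0) stop("A and B must be > 0")
  if (!is.null(atom_params)) {
    stopifnot(is.data.frame(atom_params),
              all(c("element", "A", "B") %in% names(atom_params)))
    if (any(atom_params$A <= 0 | atom_params$B <= 0))
      stop("A and B must be > 0")
  }
  structure(list(neighborhood_radius = neighborhood_radius,
                 atom_params = atom_params,
                 default_A = default_A, default_B = default_B,
                 include_self = isTRUE(include_self)),
            class = "TopographyParams")
}

# per-atom A and B vectors for the heavy atoms given
ab_for_atoms <- function(structure, idx, params) {
  A <- rep(params$default_A, length(idx))
  B <- rep(params$default_B, length(idx))
  if (!is.null(params$atom_params)) {
    pos <- match(structure$atoms$element[idx], params$atom_params$element)
    hit <- !is.na(pos)
    A[hit] <- params$atom_params$A[pos[hit]]
    B[hit] <- params$atom_params$B[pos[hit]]
  }
  list(A = A, B = B)
}

# core: F for each atom in atom_idx (must be heavy atoms), over analyzed
# frames. The per-atom inner sum S_i(t) = A_i * sum_{j != i} exp(-B_i r_ij)
# is shared by every neighborhood, so it is computed once per frame.
topography_atoms <- function(ensemble, atom_idx, params) {
  topo <- ensemble$topology
  heavy <- which(heavy_mask(topo))
  if (!all(atom_idx %in% heavy))
    stop("topography is defined for heavy atoms only")
  ab <- ab_for_atoms(topo, heavy, params)
  pos_in_heavy <- match(atom_idx, heavy)
  frames <- analyzed_frames(ensemble)
  acc <- numeric(length(atom_idx))
  warned <- FALSE
  for (t in frames) {
    X <- frame_xyz(ensemble, t)[heavy, , drop = FALSE]
    D <- as.matrix(stats::dist(X))
    E <- exp(-D * ab$B)            # row i scaled by B_i (column recycling)
    S <- ab$A * (rowSums(E) - 1)   # drop the j = i self term (exp(0))
    within <- D <= params$neighborhood_radius
    if (!params$include_self) diag(within) <- FALSE
    for (q in seq_along(atom_idx)) {
      omega <- which(within[pos_in_heavy[q], ])
      if (length(omega) == 0L) {
        if (!warned) {
          warning("empty neighborhood for atom ", atom_idx[q], " in frame ",
                  t, "; frame contributes 0")
          warned <- TRUE
        }
      } else acc[q] <- acc[q] + mean(S[omega])
    }
  }
  acc / length(frames)
}

#' Topography score of a single atom
#'
#' @param ensemble an `Ensemble`.
#' @param k 1-based atom index (heavy atom).
#' @param params a [topography_params()] object.
#' @return the scalar score F_k.
#' @export
atom_topography <- function(ensemble, k, params = topography_params()) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > n_atoms(ensemble$topology))
    stop("invalid atom index: ", k)
  topography_atoms(ensemble, k, params)
}

#' Per-residue topography map
#'
#' Computes [atom_topography()] for every heavy atom of the selection and
#' averages within residues; residues contributing no heavy atom to the
#' selection are omitted.
#'
#' @param ensemble an `Ensemble`.
#' @param selection an `AtomIndexSet` (e.g. the intracellular surface
#'   region).
#' @param params a [topography_params()] object.
#' @return a `ResidueScalarMap`: data.frame with `chain`, `resid`,
#'   `resname`, `value`, plus attributes `metric` and `params_digest`.
#' @export
topography_map <- function(ensemble, selection,
                           params = topography_params()) {
  topo <- ensemble$topology
  idx <- as_indices(selection, topo)
  idx <- idx[heavy_mask(topo)[idx]]
  if (length(idx) == 0L) stop("empty selection")
  f <- topography_atoms(ensemble, idx, params)
  residue_scalar_map(topo, idx, f, metric = "topography",
                     digest = params_digest(params))
}

# aggregate per-atom values into a per-residue map
residue_scalar_map <- function(structure, atom_idx, values, metric, digest) {
  key <- atom_residue_key(structure)[atom_idx]
  agg <- tapply(values, key, mean)
  rt <- residue_table(structure)
  rt <- rt[rt$key %in% names(agg), , drop = FALSE]
  out <- data.frame(chain = rt$chain, resid = rt$resid, resname = rt$resname,
                    value = as.numeric(agg[rt$key]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  attr(out, "params_digest") <- digest
  class(out) <- c("ResidueScalarMap", "data.frame")
  out
}

# canonical, human-readable parameter digest recorded with every output
params_digest <- function(params) {
  flat <- unlist(params, use.names = TRUE)
  paste0(class(params)[1], "{",
         paste(names(flat), unname(flat), sep = "=", collapse = ";"), "}")
}
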