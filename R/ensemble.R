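#' Ensemble: ordered conformational frames over one topology
#'
#' An `Ensemble` stores a trajectory (or any ordered set of conformations)
#' as a frames-by-3M coordinate matrix sharing one `Structure` topology.
#' All dynamics metrics consume the *analyzed* frames: the frames remaining
#' after discarding the initial `burn_in_fraction` of the trajectory, which
#' by default drops the first half (analyses run on the equilibrated tail).
#'
#' @param topology a [new_structure()] `Structure`.
#' @param xyz numeric matrix, one row per frame, `3 * M` columns in
#'   x1,y1,z1,x2,... order (the layout used by bio3d trajectories).
#' @param frame_times optional numeric vector of frame times (ns).
#' @param burn_in_fraction fraction in `[0, 1)` of initial frames excluded
#'   from analysis.
#'
#' @return An object of class `Ensemble`.
#' @export
new_ensemble <- function(topology, xyz, frame_times = NULL,
                         burn_in_fraction = 0.5) {
  stopifnot(inherits(topology, "Structure"))
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1L)
  m <- n_atoms(topology)
  if (ncol(xyz) != 3L * m)
    stop("each frame must have exactly ", m, " coordinate triplets; got ",
         ncol(xyz) / 3)
  if (nrow(xyz) < 1L) stop("ensemble needs at least one frame")
  if (!all(is.finite(xyz))) stop("frame coordinates must be finite")
  if (!is.null(frame_times) && length(frame_times) != nrow(xyz))
    stop("frame_times length must equal the frame count")
  if (burn_in_fraction < 0 || burn_in_fraction >= 1)
    stop("burn_in_fraction must lie in [0, 1)")
  if (length(analyzed_idx(nrow(xyz), burn_in_fraction)) == 0L)
    stop("burn-in leaves no analyzed frames")
  structure(list(topology = topology, xyz = unname(xyz),
                 frame_times = frame_times,
                 burn_in_fraction = burn_in_fraction),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", n_frames(x), "frames x", n_atoms(x$topology), "atoms;",
      length(analyzed_frames(x)), "analyzed (burn-in",
      x$burn_in_fraction, ")\n")
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble an `Ensemble`.
#' @return integer frame count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

analyzed_idx <- function(n, burn_in) seq.int(floor(n * burn_in) + 1L, n)

#' Indices of the analyzed (post burn-in) frames
#' @param ensemble an `Ensemble`.
#' @return integer vector of frame indices.
#' @export
analyzed_frames <- function(ensemble) {
  analyzed_idx(n_frames(ensemble), ensemble$burn_in_fraction)
}

#' Coordinates of one frame
#' @param ensemble an `Ensemble`.
#' @param i frame index.
#' @return `M x 3` coordinate matrix.
#' @export
frame_xyz <- function(ensemble, i) {
  if (i < 1L || i > n_frames(ensemble)) stop("frame index out of range: ", i)
  matrix(ensemble$xyz[i, ], ncol = 3L, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Concatenate ensembles sharing a topology
#'
#' Pools several runs into a single ensemble for analysis (e.g. independent
#' trajectories of one complex). Burn-in must already have been applied per
#' run: the pooled ensemble has `burn_in_fraction = 0`.
#'
#' @param ... `Ensemble` objects with identical atom counts.
#' @return a pooled `Ensemble` containing each input's analyzed frames.
#' @export
concat_ensembles <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "Ensemble")) parts <- parts[[1]]
  stopifnot(length(parts) >= 1L, all(vapply(parts, inherits, TRUE, "Ensemble")))
  m <- n_atoms(parts[[1]]$topology)
  for (p in parts) if (n_atoms(p$topology) != m)
    stop("ensembles disagree in atom count")
  xyz <- do.call(rbind, lapply(parts, function(p)
    p$xyz[analyzed_frames(p), , drop = FALSE]))
  new_ensemble(parts[[1]]$topology, xyz, burn_in_fraction = 0)
}

#' Build a one-structure ensemble (single frame, no burn-in)
#' @param structure a `Structure`.
#' @return an `Ensemble` with one frame.
#' @export
as_ensemble <- function(structure) {
  new_ensemble(structure, matrix(t(structure$xyz), nrow = 1L),
               burn_in_fraction = 0)
}
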