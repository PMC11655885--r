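#' Pairwise superposition RMSD matrix over frames
#'
#' Entry (s, t) is the minimum RMSD, over rigid superpositions
#' (optimal rotation + translation), between the selected atoms of frames
#' s and t -- the clustering metric for substate identification (typically
#' the C-alpha atoms of a region of interest, e.g. the intracellular
#' portion of a receptor with a flexible loop excluded; the region is
#' always an explicit selection, never guessed).
#'
#' @param ensemble an `Ensemble`.
#' @param selection `AtomIndexSet` with >= 3 atoms.
#' @param stride keep every stride-th analyzed frame (default 1).
#' @return symmetric matrix (A) with zero diagonal; attribute `frames`
#'   maps matrix rows to original frame indices.
#' @export
pairwise_rmsd <- function(ensemble, selection, stride = 1L) {
  topo <- ensemble$topology
  idx <- as_indices(selection, topo)
  if (length(idx) < 3L) stop("selection needs at least 3 atoms")
  frames <- analyzed_frames(ensemble)
  frames <- frames[seq(1L, length(frames), by = as.integer(stride))]
  n <- length(frames)
  if (n < 2L) stop("need at least 2 sampled frames")
  centered <- vector("list", n)
  for (q in seq_len(n)) {
    X <- frame_xyz(ensemble, frames[q])[idx, , drop = FALSE]
    centered[[q]] <- sweep(X, 2L, colMeans(X))
  }
  D <- matrix(0, n, n)
  for (s in seq_len(n - 1L)) for (t in seq.int(s + 1L, n)) {
    D[s, t] <- D[t, s] <- superposed_rmsd_centered(centered[[s]],
                                                   centered[[t]])
  }
  attr(D, "frames") <- frames
  D
}

#' Substate-clustering parameters
#'
#' @param radius cluster radius R in A (default 1.2): frames with distance
#'   `< R` from a centroid are structural fluctuations around it.
#' @param min_density density gate (default 0.05): only clusters holding
#'   more than this fraction of all sampled frames count as substates;
#'   everything else is thermal noise.
#' @return a `ClusterParams` list.
#' @export
cluster_params <- function(radius = 1.2, min_density = 0.05) {
  if (radius <= 0) stop("radius must be > 0")
  if (min_density < 0 || min_density >= 1) stop("min_density must lie in [0, 1)")
  structure(list(radius = radius, min_density = min_density),
            class = "ClusterParams")
}

#' Identify conformational substates from a distance matrix
#'
#' A density-based clustering in the spirit of DBSCAN, tailored to
#' spherical clusters on a frame-frame RMSD metric: repeatedly (1) count,
#' for every unassigned frame, the unassigned frames within `radius`;
#' (2) take the frame with the largest count as the next centroid (ties
#' broken by lowest frame index); (3) assign its ball as a cluster and
#' remove it; (4) stop when the best remaining ball's density -- members
#' relative to *all* sampled frames -- no longer exceeds `min_density`.
#' Frames never claimed by a qualifying cluster are thermal noise. The
#' procedure is deterministic, every member lies within `radius` of its
#' medoid centroid (the spherical constraint), and densities come out in
#' non-increasing order.
#'
#' @param dist_matrix symmetric non-negative matrix from
#'   [pairwise_rmsd()].
#' @param params a [cluster_params()] object.
#' @return a `SubstatePartition`: list with `substates` (each
#'   `centroid_frame`, `member_frames`, `density`), `noise_frames`,
#'   `n_frames`. Frame numbers refer to original ensemble frames when the
#'   matrix carries a `frames` attribute, else to matrix rows.
#' @export
cluster_substates <- function(dist_matrix, params = cluster_params()) {
  D <- dist_matrix
  if (!is.matrix(D) || nrow(D) != ncol(D) ||
      max(abs(D - t(D))) > 1e-8 || any(D < 0))
    stop("dist_matrix must be a symmetric non-negative matrix")
  n <- nrow(D)
  frame_ids <- attr(dist_matrix, "frames")
  if (is.null(frame_ids)) frame_ids <- seq_len(n)
  within <- D < params$radius          # strict: d < R counts as same substate
  unassigned <- rep(TRUE, n)
  substates <- list()
  repeat {
    live <- which(unassigned)
    if (length(live) == 0L) break
    counts <- colSums(within[live, live, drop = FALSE])
    best <- live[which.max(counts)]    # which.max: lowest index on ties
    density <- max(counts) / n
    if (density <= params$min_density) break
    members <- live[within[best, live]]
    substates[[length(substates) + 1L]] <- list(
      centroid_frame = frame_ids[best],
      member_frames = frame_ids[members],
      density = density)
    unassigned[members] <- FALSE
  }
  noise <- frame_ids[unassigned]
  structure(list(substates = substates, noise_frames = noise, n_frames = n,
                 params_digest = params_digest(params)),
            class = "SubstatePartition")
}

#' @export
print.SubstatePartition <- function(x, ...) {
  cat("SubstatePartition:", length(x$substates), "substate(s),",
      length(x$noise_frames), "noise frame(s) of", x$n_frames, "\n")
  for (s in seq_along(x$substates))
    cat(sprintf("  substate %d: centroid frame %d, density %.3f\n",
                s, x$substates[[s]]$centroid_frame, x$substates[[s]]$density))
  invisible(x)
}

#' Identify substates directly from an ensemble
#'
#' Convenience wrapper: [pairwise_rmsd()] on the selection followed by
#' [cluster_substates()].
#'
#' @inheritParams pairwise_rmsd
#' @param params a [cluster_params()] object.
#' @return a `SubstatePartition`.
#' @export
find_substates <- function(ensemble, selection, params = cluster_params(),
                           stride = 1L) {
  cluster_substates(pairwise_rmsd(ensemble, selection, stride), params)
}

# per-frame substate labels (0 = noise) keyed by original frame id
partition_labels <- function(partition) {
  ids <- sort(c(unlist(lapply(partition$substates, `[[`, "member_frames")),
                partition$noise_frames))
  lab <- stats::setNames(integer(length(ids)), ids)
  for (s in seq_along(partition$substates))
    lab[as.character(partition$substates[[s]]$member_frames)] <- s
  lab
}
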