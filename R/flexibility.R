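#' Local-fluctuation parameters
#'
#' The local flexibility of residue K is the width of the distribution of
#' its environment's RMS displacement: with \eqn{\Omega_{K,0}} the
#' mode-atoms (sidechain or backbone, heavy) of every residue having at
#' least one heavy atom within `d` of K in the reference frame,
#' \deqn{G_K(t) = \{ N^{-1} \sum_{i \in \Omega_{K,0}} r_i^2(t) \}^{1/2},
#'   \quad H_K = \langle (G_K(t) - \bar G_K)^2 \rangle_t^{1/2}}
#' where \eqn{r_i(t)} is the displacement of atom i from its reference
#' position after the frame has been rigidly superposed onto the reference
#' using the C-alpha atoms of all residues contributing to
#' \eqn{\Omega_{K,0}}. The superposition removes rigid-body motion, so H
#' measures genuinely local disorder: the environment is treated as a
#' liquid-like region with random atomic fluctuations, and H is the width
#' of that (assumed normal) displacement distribution, computed
#' nonparametrically.
#'
#' @param environment_radius d, in A (> 0; default 6, commensurate with
#'   first-shell contact distances).
#' @param mode `"sidechain"` (default) or `"backbone"`.
#' @param reference_frame 1-based frame index defining the t = 0
#'   environment and reference positions (default 1).
#' @param sd_denominator `"population"` (default; divide by N) or
#'   `"sample"` (divide by N - 1) for the width.
#' @return a `FluctuationParams` list.
#' @export
fluctuation_params <- function(environment_radius = 6.0,
                               mode = c("sidechain", "backbone"),
                               reference_frame = 1L,
                               sd_denominator = c("population", "sample")) {
  if (environment_radius <= 0) stop("environment_radius must be > 0")
  structure(list(environment_radius = environment_radius,
                 mode = match.arg(mode),
                 reference_frame = as.integer(reference_frame),
                 sd_denominator = match.arg(sd_denominator)),
            class = "FluctuationParams")
}

#' Local fluctuation H of one residue
#'
#' @param ensemble an `Ensemble` with at least 2 analyzed frames.
#' @param K residue key `"chain:resid"` (see [residue_keys()]).
#' @param params a [fluctuation_params()] object.
#' @return the scalar width H (A, >= 0).
#' @export
residue_fluctuation <- function(ensemble, K, params = fluctuation_params()) {
  env <- fluctuation_environment(ensemble, K, params)
  fluctuation_from_environment(ensemble, env, params)
}

# resolve Omega_{K,0} and the superposition C-alpha set for residue K
fluctuation_environment <- function(ensemble, K, params) {
  topo <- ensemble$topology
  key <- atom_residue_key(topo)
  if (!K %in% key) stop("residue not found: ", K)
  ref_t <- params$reference_frame
  if (!ref_t %in% seq_len(n_frames(ensemble)))
    stop("reference_frame out of range")
  X0 <- frame_xyz(ensemble, ref_t)
  hv <- heavy_mask(topo)
  atoms_K <- which(key == K & hv)
  if (length(atoms_K) == 0L) stop("residue ", K, " has no heavy atoms")

  # residues with >= 1 heavy atom within d of >= 1 heavy atom of K at t=0
  d <- params$environment_radius
  other <- which(hv)
  dmin <- vapply(atoms_K, function(a)
    sqrt(rowSums(sweep(X0[other, , drop = FALSE], 2L, X0[a, ])^2)),
    numeric(length(other)))
  near <- other[rowSums(dmin <= d) > 0]
  contributing <- unique(key[near])

  omega <- unlist(lapply(contributing, function(res)
    mode_atoms(topo, which(key == res), params$mode)))
  if (length(omega) == 0L)
    stop("residue ", K, ": no ", params$mode, " atoms in its environment")
  ca <- which(topo$atoms$name == "CA" & hv & key %in% contributing)
  if (length(unique(key[ca])) < 3L)
    stop("residue ", K, ": environment has fewer than 3 residues with ",
         "C-alpha atoms; superposition is ill-posed")
  list(K = K, omega = omega, ca = ca, ref_t = ref_t)
}

fluctuation_from_environment <- function(ensemble, env, params) {
  frames <- analyzed_frames(ensemble)
  if (length(frames) < 2L)
    stop("fluctuation width is undefined on fewer than 2 analyzed frames")
  X0 <- frame_xyz(ensemble, env$ref_t)
  ca0 <- X0[env$ca, , drop = FALSE]
  om0 <- X0[env$omega, , drop = FALSE]
  G <- vapply(frames, function(t) {
    Xt <- frame_xyz(ensemble, t)
    if (identical(Xt, X0)) return(0)   # unmoved frame: exactly zero
    fit <- kabsch_fit(Xt[env$ca, , drop = FALSE], ca0)
    omt <- apply_transform(Xt[env$omega, , drop = FALSE], fit)
    sqrt(mean(rowSums((omt - om0)^2)))
  }, numeric(1))
  dev2 <- (G - mean(G))^2
  denom <- if (params$sd_denominator == "population") length(G) else length(G) - 1L
  sqrt(sum(dev2) / denom)
}

#' Per-residue local-fluctuation map
#'
#' Computes [residue_fluctuation()] for every residue represented in the
#' selection. Residues whose environment makes the superposition ill-posed
#' are recorded as `NA` with a warning rather than aborting the map.
#'
#' @param ensemble an `Ensemble`.
#' @param selection an `AtomIndexSet`; one H value is produced per residue
#'   with at least one selected atom (regions such as a flexible loop or
#'   tethered helix ends can be excluded simply by excluding them here).
#' @param params a [fluctuation_params()] object.
#' @return a `ResidueScalarMap` (`chain`, `resid`, `resname`, `value`).
#' @export
fluctuation_map <- function(ensemble, selection,
                            params = fluctuation_params()) {
  topo <- ensemble$topology
  idx <- as_indices(selection, topo)
  if (length(idx) == 0L) stop("empty selection")
  if (length(analyzed_frames(ensemble)) < 2L)
    stop("fluctuation width is undefined on fewer than 2 analyzed frames")
  keys <- unique(atom_residue_key(topo)[idx])
  vals <- vapply(keys, function(K) {
    tryCatch(residue_fluctuation(ensemble, K, params),
             error = function(e) {
               warning("residue ", K, " skipped: ", conditionMessage(e),
                       call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  rt <- residue_table(topo)
  rt <- rt[rt$key %in% keys, , drop = FALSE]
  out <- data.frame(chain = rt$chain, resid = rt$resid, resname = rt$resname,
                    value = as.numeric(vals[rt$key]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "metric") <- paste0("flexibility_", params$mode)
  attr(out, "params_digest") <- params_digest(params)
  class(out) <- c("ResidueScalarMap", "data.frame")
  out
}
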