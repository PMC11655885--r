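# Synthetic structures and ensembles with planted ground truth.
#
# These generators emulate the statistical structure of receptor MD
# ensembles -- a mixture of discrete substates, per-residue Gaussian
# fluctuation amplitudes, and on/off donor-acceptor contact occupancies --
# so every ensemble metric can be validated against known truth without
# external data. They make no claim to physical realism (no force field,
# membrane or solvent). Generated ensembles carry burn_in_fraction = 0:
# they represent only the production portion a study would analyze.

# evaluate code under a fixed seed without disturbing the session RNG
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# single sidechain pseudo-atom per residue type (name, element); GLY none
SC_PSEUDO <- list(
  ASP = c("OD1", "O"), GLU = c("OE1", "O"), SER = c("OG", "O"),
  THR = c("OG1", "O"), TYR = c("OH", "O"), ASN = c("ND2", "N"),
  GLN = c("NE2", "N"), ARG = c("NH1", "N"), LYS = c("NZ", "N"),
  HIS = c("NE2", "N"), TRP = c("NE1", "N"), CYS = c("SG", "S"),
  MET = c("SD", "S"))

#' Generate an idealized helix-bundle structure
#'
#' Builds `n_helices` ideal alpha-helices (rise 1.5 A, 100 degrees per
#' residue, C-alpha radius 2.3 A) arranged antiparallel on a circle -- a
#' deliberately simple stand-in for a transmembrane helix bundle. Each
#' residue carries backbone N/CA/C/O plus one sidechain pseudo-atom whose
#' name and element follow the residue type (e.g. ASP gets a carboxylate
#' oxygen `OD1`, ARG a guanidinium nitrogen `NH1`; the default ALA gets a
#' carbon `CB`; GLY gets none). A small seeded coordinate perturbation
#' (sd 0.05 A) breaks exact geometric symmetry; output is bit-identical
#' for a fixed seed.
#'
#' @param n_helices number of helices (>= 1).
#' @param residues_per_helix residues in each helix (>= 4).
#' @param seed integer RNG seed.
#' @param sequence 3-letter residue codes recycled along the chain
#'   (default `"ALA"`).
#' @return a `Structure` (single chain `A`, residues numbered 1..n).
#' @export
make_bundle <- function(n_helices, residues_per_helix, seed = 0,
                        sequence = "ALA") {
  if (n_helices < 1 || residues_per_helix < 4)
    stop("need n_helices >= 1 and residues_per_helix >= 4")
  n_res <- n_helices * residues_per_helix
  resnames <- rep_len(toupper(sequence), n_res)

  rows <- list()
  xyz <- list()
  res_counter <- 0L
  for (h in seq_len(n_helices)) {
    # helix center on a circle; single helix at the origin
    if (n_helices == 1L) {
      cx <- cy <- 0
    } else {
      rc <- 10 / (2 * sin(pi / n_helices))
      cx <- rc * cos(2 * pi * (h - 1) / n_helices)
      cy <- rc * sin(2 * pi * (h - 1) / n_helices)
    }
    updown <- if (h %% 2L == 1L) 1 else -1     # antiparallel packing
    for (i in seq_len(residues_per_helix)) {
      res_counter <- res_counter + 1L
      rn <- resnames[res_counter]
      helix_pt <- function(t, radius) {
        th <- (t - 1) * 100 * pi / 180
        c(cx + radius * cos(th), cy + radius * sin(th),
          updown * (t - 1) * 1.5)
      }
      ca <- helix_pt(i, 2.3)
      npos <- helix_pt(i - 0.35, 2.0)
      cpos <- helix_pt(i + 0.35, 2.0)
      out_dir <- c(ca[1] - cx, ca[2] - cy, 0) / 2.3   # radial, unit
      opos <- cpos + c(0.4 * out_dir[1], 0.4 * out_dir[2], updown * -0.6)
      names_i <- c("N", "CA", "C", "O")
      elems_i <- c("N", "C", "C", "O")
      coords_i <- rbind(npos, ca, cpos, opos)
      if (rn != "GLY") {
        ps <- SC_PSEUDO[[rn]]
        if (is.null(ps)) ps <- c("CB", "C")
        names_i <- c(names_i, ps[1])
        elems_i <- c(elems_i, ps[2])
        coords_i <- rbind(coords_i, ca + 1.5 * out_dir)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        name = names_i, element = elems_i, resname = rn,
        resid = res_counter, stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- coords_i
    }
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at))
  at$chain <- "A"
  at$occupancy <- 1
  at$altloc <- ""
  at$bfactor <- 0
  at$het <- FALSE
  coords <- do.call(rbind, xyz)
  coords <- coords + with_seed(seed, matrix(stats::rnorm(length(coords), sd = 0.05),
                                            ncol = 3L))
  new_structure(at, unname(coords))
}

#' Specify planted substate truth
#'
#' @param n_states number of discrete substates (>= 1).
#' @param weights state populations, summing to 1.
#' @param centroid_displacement pairwise inter-centroid C-alpha RMSD (A)
#'   planted between every pair of substate centroids.
#' @param within_sigma isotropic per-coordinate Gaussian jitter (A) around
#'   each centroid.
#' @return a `SubstateTruth` list.
#' @export
substate_truth <- function(n_states, weights, centroid_displacement = 5,
                           within_sigma = 0.2) {
  weights <- as.numeric(weights)
  if (length(weights) != n_states) stop("need one weight per state")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  if (n_states >= 2 && centroid_displacement <= 2 * within_sigma)
    stop("separability requires centroid_displacement > 2 * within_sigma")
  structure(list(n_states = as.integer(n_states), weights = weights,
                 centroid_displacement = centroid_displacement,
                 within_sigma = within_sigma),
            class = "SubstateTruth")
}

#' Generate an ensemble around planted conformational substates
#'
#' Each frame is drawn as one of `n_states` centroids (chosen by the truth
#' weights) plus iid Gaussian jitter on the mobile atoms. Centroids are the
#' input structure displaced by mutually orthogonal per-residue fields with
#' net translation removed, scaled so the raw inter-centroid C-alpha RMSD
#' equals `centroid_displacement` for every centroid pair. Atoms outside
#' `mobile` are bit-identical across all frames.
#'
#' @param structure base `Structure`.
#' @param truth a [substate_truth()] object.
#' @param n_frames number of frames (>= n_states).
#' @param seed integer RNG seed.
#' @param mobile `AtomIndexSet` of mobile atoms (default: all atoms).
#' @return list with `ensemble` (burn-in 0), and `truth` augmented with
#'   per-frame `labels` and the emitted `centroids` (list of M x 3
#'   matrices).
#' @export
make_substate_ensemble <- function(structure, truth, n_frames, seed = 0,
                                   mobile = NULL) {
  stopifnot(inherits(structure, "Structure"), inherits(truth, "SubstateTruth"))
  if (n_frames < truth$n_states) stop("need n_frames >= n_states")
  if (abs(sum(truth$weights) - 1) > 1e-8) stop("weights must sum to 1")
  m <- n_atoms(structure)
  mob <- if (is.null(mobile)) seq_len(m) else as_indices(mobile, structure)
  k <- truth$n_states

  key <- atom_residue_key(structure)
  mob_res <- unique(key[mob])
  ca_all <- which(structure$atoms$name == "CA" & heavy_mask(structure))
  ca_mob <- ca_all[key[ca_all] %in% mob_res]
  if (k >= 2 && length(ca_mob) < k)
    stop("too few mobile C-alpha atoms to plant ", k, " separated centroids")

  out <- with_seed(seed, {
    # per-residue displacement fields, orthonormal over the mobile C-alpha
    # block with net translation projected out
    centroids <- replicate(k, structure$xyz, simplify = FALSE)
    if (k >= 2) {
      nca <- length(ca_mob)
      V <- matrix(stats::rnorm(3L * nca * k), ncol = k)
      V <- apply(V, 2L, function(v) {
        vm <- matrix(v, ncol = 3L)
        as.vector(sweep(vm, 2L, colMeans(vm)))   # remove net translation
      })
      E <- qr.Q(qr(V))[, seq_len(k), drop = FALSE]
      E <- sweep(E, 1L, rowMeans(E))             # center across states
      a <- truth$centroid_displacement * sqrt(length(ca_all)) / sqrt(2)
      for (s in seq_len(k)) {
        disp_ca <- matrix(a * E[, s], ncol = 3L)      # one vector per mobile residue's CA
        res_of <- match(key[mob], key[ca_mob])
        if (anyNA(res_of))
          stop("every mobile residue needs a C-alpha atom")
        centroids[[s]][mob, ] <- centroids[[s]][mob, ] + disp_ca[res_of, ]
      }
    }
    labels <- sample.int(k, n_frames, replace = TRUE, prob = truth$weights)
    xyz <- matrix(0, n_frames, 3L * m)
    for (t in seq_len(n_frames)) {
      fr <- centroids[[labels[t]]]
      if (truth$within_sigma > 0)
        fr[mob, ] <- fr[mob, ] +
          matrix(stats::rnorm(3L * length(mob), sd = truth$within_sigma),
                 ncol = 3L)
      xyz[t, ] <- as.vector(t(fr))
    }
    list(xyz = xyz, labels = labels, centroids = centroids)
  })
  truth$labels <- out$labels
  truth$centroids <- out$centroids
  list(ensemble = new_ensemble(structure, out$xyz, burn_in_fraction = 0),
       truth = truth)
}

#' Generate an ensemble with a planted per-residue fluctuation profile
#'
#' Frame t is the base structure plus iid Gaussian noise with each
#' residue's sigma on the targeted atoms (sidechain heavy atoms in
#' `"sidechain"` mode, backbone in `"backbone"` mode, every atom in
#' `"all"` mode). Optionally each frame additionally receives a random
#' rigid-body rotation+translation, which exercises the superposition step
#' of downstream local-fluctuation analysis.
#'
#' @param structure base `Structure`.
#' @param sigma_profile numeric vector, one sigma (A, >= 0) per residue in
#'   [residue_keys()] order.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param mode which atoms fluctuate: `"sidechain"`, `"backbone"`, `"all"`.
#' @param rigid_jitter logical; apply a random global rotation (<= 8
#'   degrees) and translation (<= 2 A) per frame.
#' @return an `Ensemble` with burn-in 0.
#' @export
make_fluctuation_ensemble <- function(structure, sigma_profile, n_frames,
                                      seed = 0,
                                      mode = c("sidechain", "backbone", "all"),
                                      rigid_jitter = FALSE) {
  mode <- match.arg(mode)
  rk <- residue_keys(structure)
  if (length(sigma_profile) != length(rk))
    stop("sigma_profile needs one value per residue (", length(rk), ")")
  if (any(sigma_profile < 0)) stop("sigma values must be >= 0")
  key <- atom_residue_key(structure)
  target <- if (mode == "all") seq_len(n_atoms(structure))
            else unlist(lapply(rk, function(k)
              mode_atoms(structure, which(key == k), mode)))
  sigma_atom <- sigma_profile[match(key[target], rk)]
  m <- n_atoms(structure)
  xyz <- with_seed(seed, {
    out <- matrix(0, n_frames, 3L * m)
    for (t in seq_len(n_frames)) {
      fr <- structure$xyz
      if (length(target))
        fr[target, ] <- fr[target, ] +
          matrix(stats::rnorm(3L * length(target)) * sigma_atom, ncol = 3L)
      if (rigid_jitter) {
        axis <- stats::rnorm(3L)
        Rm <- rotation_about_axis(axis, stats::runif(1, -8, 8))
        ctr <- colMeans(structure$xyz)
        shift <- stats::runif(3L, -2, 2)
        fr <- sweep(sweep(fr, 2L, ctr) %*% t(Rm), 2L, ctr + shift, "+")
      }
      out[t, ] <- as.vector(t(fr))
    }
    out
  })
  new_ensemble(structure, xyz, burn_in_fraction = 0)
}

#' Specify a planted donor-acceptor occupancy schedule
#'
#' @param donor_atom,acceptor_atom 1-based atom indices; the acceptor atom
#'   is moved along the donor-acceptor axis to realize the distances.
#' @param occupancy fraction of frames in contact, in `[0, 1]`.
#' @param contact_distance donor-acceptor distance (A) in contact frames
#'   (< 3).
#' @param apart_distance distance (A) in non-contact frames (> 3).
#' @return an `OccupancySchedule` row (data.frame).
#' @export
occupancy_schedule <- function(donor_atom, acceptor_atom, occupancy,
                               contact_distance = 2.8, apart_distance = 6.0) {
  if (occupancy < 0 || occupancy > 1) stop("occupancy must lie in [0, 1]")
  if (!(contact_distance < 3.0 && apart_distance > 3.0))
    stop("need contact_distance < 3 A < apart_distance")
  data.frame(donor_atom = as.integer(donor_atom),
             acceptor_atom = as.integer(acceptor_atom),
             occupancy = occupancy, contact_distance = contact_distance,
             apart_distance = apart_distance)
}

#' Generate an ensemble with planted contact occupancies
#'
#' For each schedule row, exactly `round(occupancy * n_frames)` frames --
#' chosen as the first entries of a seeded random frame order -- place the
#' acceptor atom at `contact_distance` from its donor along the original
#' donor-acceptor direction; all other frames use `apart_distance`.
#' Occupancies are realized by exact frame counts, so downstream
#' persistence assertions are exact.
#'
#' @param structure base `Structure`.
#' @param schedule one or more [occupancy_schedule()] rows (rbind them).
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @return an `Ensemble` (burn-in 0) with attribute `contact_frames`: a
#'   list of the planted contact-frame indices per schedule row.
#' @export
make_interaction_ensemble <- function(structure, schedule, n_frames,
                                      seed = 0) {
  stopifnot(inherits(structure, "Structure"), is.data.frame(schedule))
  m <- n_atoms(structure)
  if (any(schedule$donor_atom < 1 | schedule$donor_atom > m |
          schedule$acceptor_atom < 1 | schedule$acceptor_atom > m))
    stop("schedule atom indices out of range [1, ", m, "]")
  if (anyDuplicated(schedule$acceptor_atom) ||
      any(schedule$acceptor_atom %in% schedule$donor_atom))
    stop("each acceptor atom may appear in only one schedule row")
  contact_frames <- with_seed(seed, lapply(seq_len(nrow(schedule)), function(r) {
    n_c <- round(schedule$occupancy[r] * n_frames)
    sample.int(n_frames)[seq_len(n_c)]
  }))
  xyz <- matrix(rep(as.vector(t(structure$xyz)), n_frames),
                nrow = n_frames, byrow = TRUE)
  for (r in seq_len(nrow(schedule))) {
    don <- structure$xyz[schedule$donor_atom[r], ]
    acc <- structure$xyz[schedule$acceptor_atom[r], ]
    u <- acc - don
    nu <- sqrt(sum(u^2))
    u <- if (nu < 1e-9) c(0, 0, 1) else u / nu
    cols <- 3L * (schedule$acceptor_atom[r] - 1L) + 1:3
    for (t in seq_len(n_frames)) {
      dst <- if (t %in% contact_frames[[r]]) schedule$contact_distance[r]
             else schedule$apart_distance[r]
      xyz[t, cols] <- don + dst * u
    }
  }
  ens <- new_ensemble(structure, xyz, burn_in_fraction = 0)
  attr(ens, "contact_frames") <- contact_frames
  ens
}

#' Rotate a domain of a structure about an axis
#'
#' Rotates the selected atoms by `angle` degrees about `axis` through the
#' selection centroid, leaving all other atoms unchanged. Used to plant
#' known inter-structure domain rotations (e.g. a fusion-domain swing-out)
#' for validating rotation-angle recovery.
#'
#' @param structure a `Structure`.
#' @param domain_selection `AtomIndexSet` of the domain.
#' @param angle rotation angle in degrees, in `[-180, 180]`.
#' @param axis 3-vector rotation axis (non-zero).
#' @return the rotated `Structure`.
#' @export
make_rotated_complex <- function(structure, domain_selection, angle, axis) {
  if (abs(angle) > 180) stop("angle must lie in [-180, 180] degrees")
  idx <- as_indices(domain_selection, structure)
  if (length(idx) == 0L) stop("empty domain selection")
  Rm <- rotation_about_axis(axis, angle)   # errors on zero axis
  ctr <- colMeans(structure$xyz[idx, , drop = FALSE])
  out <- structure
  out$xyz[idx, ] <- sweep(sweep(structure$xyz[idx, , drop = FALSE], 2L, ctr) %*%
                            t(Rm), 2L, ctr, "+")
  out
}
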