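#' Interaction-detection parameters
#'
#' Contacts are detected per frame from distance-only ("soft") criteria:
#' a polar contact (H-bond/salt-bridge class) exists between two residues
#' or groups when the minimum distance between their donor/acceptor atoms
#' is strictly below `polar_cutoff` (default 3.0 A); a nonpolar
#' (hydrophobic/dispersion) contact when the minimum distance between
#' their sidechain carbon atoms is strictly below `nonpolar_cutoff`
#' (default 4.8 A). No angular term is applied anywhere. Ligand halogens
#' (F, Cl, Br, I) count as polar partners when `treat_halogens_as_polar`
#' is set, folding possible halogen bonding into the general polar class
#' without modeling its geometry.
#'
#' Donor/acceptor atoms of protein residues are typed from a
#' residue-template table covering the 20 standard amino acids (Ser OG,
#' Thr OG1, Tyr OH, Asn OD1/ND2, Gln OE1/NE2, Asp OD1/OD2, Glu OE1/OE2,
#' Lys NZ, Arg NE/NH1/NH2, His ND1/NE2, Trp NE1; Cys SG excluded).
#' Heteroatom groups (ligands, waters) are typed by element (N, O, plus
#' halogens per the flag). With `scope = "include-backbone"` the backbone
#' N/O (polar) and backbone carbons (nonpolar) also participate.
#'
#' @param polar_cutoff donor-acceptor distance cutoff, A.
#' @param nonpolar_cutoff carbon-carbon distance cutoff, A.
#' @param treat_halogens_as_polar logical (default TRUE).
#' @param scope `"sidechain-only"` (default) or `"include-backbone"`.
#' @return an `InteractionParams` list.
#' @export
interaction_params <- function(polar_cutoff = 3.0, nonpolar_cutoff = 4.8,
                               treat_halogens_as_polar = TRUE,
                               scope = c("sidechain-only", "include-backbone")) {
  if (polar_cutoff <= 0 || nonpolar_cutoff <= 0) stop("cutoffs must be > 0")
  structure(list(polar_cutoff = polar_cutoff,
                 nonpolar_cutoff = nonpolar_cutoff,
                 treat_halogens_as_polar = isTRUE(treat_halogens_as_polar),
                 scope = match.arg(scope)),
            class = "InteractionParams")
}

STANDARD_RES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

DONOR_ACCEPTOR <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = c("OD1", "ND2"),
  GLN = c("OE1", "NE2"), ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1")

HALOGENS <- c("F", "Cl", "Br", "I")

# polar (donor/acceptor) atoms among idx; warns once per unknown protein
# residue template and skips it
polar_atoms <- function(structure, idx, params) {
  a <- structure$atoms
  hv <- heavy_mask(structure)
  keep <- logical(length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    if (!hv[i]) next
    if (a$het[i] || !(a$resname[i] %in% STANDARD_RES)) {
      if (!a$het[i]) next    # unknown protein residue: handled below
      keep[q] <- a$element[i] %in% c("N", "O") ||
        (params$treat_halogens_as_polar && a$element[i] %in% HALOGENS)
    } else {
      da <- DONOR_ACCEPTOR[[a$resname[i]]]
      keep[q] <- (!is.null(da) && a$name[i] %in% da) ||
        (params$scope == "include-backbone" && a$name[i] %in% c("N", "O"))
    }
  }
  unknown <- unique(a$resname[idx][!a$het[idx] &
                                     !(a$resname[idx] %in% STANDARD_RES)])
  if (length(unknown))
    warning("no donor/acceptor template for residue type(s) ",
            paste(unknown, collapse = ", "), "; skipped", call. = FALSE)
  idx[keep]
}

# nonpolar (carbon) atoms among idx
nonpolar_atoms <- function(structure, idx, params) {
  a <- structure$atoms
  hv <- heavy_mask(structure)
  carbon <- a$element[idx] == "C" & hv[idx]
  side <- !(a$name[idx] %in% BACKBONE_NAMES)
  keep <- if (params$scope == "include-backbone") carbon
          else carbon & (side | a$het[idx])
  idx[keep]
}

# min distance per residue pair between two typed atom sets in one frame
pair_min_dists <- function(X, key, set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L)
    return(data.frame(partner_a = character(), partner_b = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  D2 <- outer(rowSums(X[set_a, , drop = FALSE]^2),
              rowSums(X[set_b, , drop = FALSE]^2), "+") -
    2 * X[set_a, , drop = FALSE] %*% t(X[set_b, , drop = FALSE])
  D <- sqrt(pmax(D2, 0))
  ka <- key[set_a]; kb <- key[set_b]
  df <- data.frame(a = rep(ka, times = length(kb)),
                   b = rep(kb, each = length(ka)),
                   d = as.vector(D), stringsAsFactors = FALSE)
  df <- df[df$a != df$b, , drop = FALSE]
  if (nrow(df) == 0L)
    return(data.frame(partner_a = character(), partner_b = character(),
                      min_distance = numeric(), stringsAsFactors = FALSE))
  # store unordered pair once
  swap <- df$a > df$b
  tmp <- df$a[swap]; df$a[swap] <- df$b[swap]; df$b[swap] <- tmp
  agg <- stats::aggregate(d ~ a + b, data = df, FUN = min)
  data.frame(partner_a = agg$a, partner_b = agg$b, min_distance = agg$d,
             stringsAsFactors = FALSE)
}

#' Contacts between two groups in one frame
#'
#' Detects polar and nonpolar residue-pair (or residue-group) contacts in
#' a single frame by the strict distance criteria of
#' [interaction_params()].
#'
#' @param ensemble an `Ensemble`.
#' @param frame frame index.
#' @param group_a,group_b `AtomIndexSet`s (may be identical for
#'   within-group networks).
#' @param params an [interaction_params()] object.
#' @return data.frame with `partner_a`, `partner_b` (residue keys,
#'   unordered pair stored once), `class` (`"polar"`/`"nonpolar"`) and
#'   `min_distance` (A).
#' @export
frame_contacts <- function(ensemble, frame, group_a, group_b,
                           params = interaction_params()) {
  topo <- ensemble$topology
  ia <- as_indices(group_a, topo)
  ib <- as_indices(group_b, topo)
  if (length(ia) == 0L || length(ib) == 0L) stop("contact groups must be non-empty")
  X <- frame_xyz(ensemble, frame)
  key <- atom_residue_key(topo)
  pol <- pair_min_dists(X, key, polar_atoms(topo, ia, params),
                        suppressWarnings(polar_atoms(topo, ib, params)))
  pol <- pol[pol$min_distance < params$polar_cutoff, , drop = FALSE]
  np <- pair_min_dists(X, key, nonpolar_atoms(topo, ia, params),
                       nonpolar_atoms(topo, ib, params))
  np <- np[np$min_distance < params$nonpolar_cutoff, , drop = FALSE]
  out <- rbind(cbind(pol, class = rep("polar", nrow(pol))),
               cbind(np, class = rep("nonpolar", nrow(np))))
  out <- out[, c("partner_a", "partner_b", "class", "min_distance")]
  rownames(out) <- NULL
  out
}

#' Persistence-weighted interaction network over an ensemble
#'
#' Aggregates per-frame contacts over the analyzed frames into edges whose
#' persistence -- the fraction of analyzed frames in which the contact
#' satisfies its distance criterion -- serves as a proxy for interaction
#' strength. Covers receptor-receptor, receptor-ligand and ligand-water
#' group pairs alike.
#'
#' @param ensemble an `Ensemble`.
#' @param group_pairs a list of pairs, each `list(a = AtomIndexSet,
#'   b = AtomIndexSet)`; a single pair may be given directly.
#' @param params an [interaction_params()] object.
#' @return an `InteractionNetwork`: list with `edges` (data.frame
#'   `partner_a`, `partner_b`, `class`, `persistence`,
#'   `mean_min_distance` over the frames where the edge is present),
#'   `n_frames_analyzed`, `params_digest`.
#' @export
persistence_network <- function(ensemble, group_pairs,
                                params = interaction_params()) {
  if (!is.null(group_pairs$a)) group_pairs <- list(group_pairs)
  frames <- analyzed_frames(ensemble)
  if (length(frames) == 0L) stop("no analyzed frames")
  per_frame <- lapply(frames, function(t) {
    eds <- lapply(group_pairs, function(gp)
      frame_contacts(ensemble, t, gp$a, gp$b, params))
    ed <- do.call(rbind, eds)
    unique(ed)
  })
  all_edges <- do.call(rbind, per_frame)
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    edges <- data.frame(partner_a = character(), partner_b = character(),
                        class = character(), persistence = numeric(),
                        mean_min_distance = numeric(), stringsAsFactors = FALSE)
  } else {
    id <- paste(all_edges$partner_a, all_edges$partner_b, all_edges$class,
                sep = "|")
    cnt <- table(id)
    md <- tapply(all_edges$min_distance, id, mean)
    first <- !duplicated(id)
    edges <- data.frame(
      partner_a = all_edges$partner_a[first],
      partner_b = all_edges$partner_b[first],
      class = all_edges$class[first],
      persistence = as.numeric(cnt[id[first]]) / length(frames),
      mean_min_distance = as.numeric(md[id[first]]),
      stringsAsFactors = FALSE)
    edges <- edges[order(-edges$persistence, edges$partner_a), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(edges = edges, n_frames_analyzed = length(frames),
                 params_digest = params_digest(params)),
            class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat("InteractionNetwork:", nrow(x$edges), "edges over",
      x$n_frames_analyzed, "analyzed frames\n")
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Salt-bridge persistence for named residue pairs
#'
#' Convenience wrapper restricted to charged pairs: Asp/Glu carboxylate
#' oxygens versus Arg/Lys/His sidechain nitrogens, under the same strict
#' `polar_cutoff` criterion. Pairs that never form are still reported with
#' persistence 0.
#'
#' @param ensemble an `Ensemble`.
#' @param pairs list of 2-vectors of residue keys, e.g.
#'   `list(c("A:338", "A:214"))`.
#' @param params an [interaction_params()] object.
#' @return data.frame `res_a`, `res_b`, `persistence`,
#'   `mean_min_distance` (mean over all analyzed frames).
#' @export
salt_bridge_report <- function(ensemble, pairs,
                               params = interaction_params()) {
  topo <- ensemble$topology
  key <- atom_residue_key(topo)
  a <- topo$atoms
  acidic <- function(K) which(key == K & a$resname %in% c("ASP", "GLU") &
                                a$name %in% c("OD1", "OD2", "OE1", "OE2"))
  basic <- function(K) which(key == K &
                               ((a$resname == "ARG" & a$name %in% c("NE", "NH1", "NH2")) |
                                  (a$resname == "LYS" & a$name == "NZ") |
                                  (a$resname == "HIS" & a$name %in% c("ND1", "NE2"))))
  missing <- unique(unlist(lapply(pairs, function(p) p[!(p %in% key)])))
  if (length(missing))
    stop("residue(s) not found: ", paste(missing, collapse = ", "))
  frames <- analyzed_frames(ensemble)
  rows <- lapply(pairs, function(p) {
    sets <- list(acidic(p[1]), basic(p[2]))
    if (length(sets[[1]]) == 0L || length(sets[[2]]) == 0L)
      sets <- list(acidic(p[2]), basic(p[1]))
    if (length(sets[[1]]) == 0L || length(sets[[2]]) == 0L)
      stop("pair ", p[1], " / ", p[2],
           " is not an Asp/Glu vs Arg/Lys/His pair with charged sidechain atoms")
    dmin <- vapply(frames, function(t) {
      X <- frame_xyz(ensemble, t)
      min(pair_min_dists(X, key, sets[[1]], sets[[2]])$min_distance)
    }, numeric(1))
    data.frame(res_a = p[1], res_b = p[2],
               persistence = mean(dmin < params$polar_cutoff),
               mean_min_distance = mean(dmin), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
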