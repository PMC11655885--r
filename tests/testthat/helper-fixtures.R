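# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (explicit loops, third-party fits) and
# never call the code paths they check.

# quick structure from a coordinate matrix
toy_structure <- function(xyz, element = "C", name = NULL, resid = NULL,
                          resname = "ALA", chain = "A", het = FALSE) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n),
    name = if (is.null(name)) paste0(rep_len(element, n), seq_len(n)) else
      rep_len(name, n),
    element = rep_len(element, n),
    resname = rep_len(resname, n),
    resid = if (is.null(resid)) rep(1L, n) else rep_len(resid, n),
    chain = rep_len(chain, n),
    occupancy = 1, altloc = "", bfactor = 0,
    het = rep_len(het, n), stringsAsFactors = FALSE)
  new_structure(atoms, unname(as.matrix(xyz)))
}

# ensemble from a list of M x 3 frames (burn-in 0)
toy_ensemble <- function(structure, frames) {
  new_ensemble(structure,
               do.call(rbind, lapply(frames, function(f) as.vector(t(f)))),
               burn_in_fraction = 0)
}

# ---- independent oracles ---------------------------------------------------

# naive triple-loop topography for one frame set (all atoms heavy)
oracle_topography <- function(frames, k, d, A, B, include_self = TRUE) {
  vals <- vapply(frames, function(X) {
    M <- nrow(X)
    dij <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
    omega <- integer(0)
    for (i in seq_len(M)) {
      if (i == k && !include_self) next
      if (dij(i, k) <= d) omega <- c(omega, i)
    }
    if (length(omega) == 0L) return(0)
    tot <- 0
    for (i in omega) {
      for (j in seq_len(M)) if (j != i) tot <- tot + A[i] * exp(-B[i] * dij(i, j))
    }
    tot / length(omega)
  }, numeric(1))
  mean(vals)
}

# superposed RMSD via numerical optimization over Euler angles (multi-start)
oracle_rmsd_optim <- function(A, B, n_starts = 30, seed = 42) {
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  euler <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1])
    cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(p) sqrt(mean(rowSums((A %*% t(euler(p)) - B)^2)))
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    p0 <- runif(3, -pi, pi)
    r <- optim(p0, f, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# superposed RMSD via bio3d's fit (independent Kabsch implementation);
# bio3d::rmsd rounds its output, so the residual is computed here
oracle_rmsd_bio3d <- function(A, B) {
  n <- nrow(A)
  fitted <- matrix(suppressWarnings(bio3d::fit.xyz(
    fixed = as.vector(t(B)), mobile = as.vector(t(A)),
    fixed.inds = seq_len(3 * n), mobile.inds = seq_len(3 * n))),
    ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums((fitted - B)^2)))
}

# naive per-frame contact detection between two atom index sets, with the
# same typing rules spelled out longhand
oracle_contacts <- function(structure, X, idx_a, idx_b,
                            polar_cutoff = 3.0, nonpolar_cutoff = 4.8) {
  da_table <- list(SER = "OG", THR = "OG1", TYR = "OH",
                   ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
                   ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                   LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"), TRP = "NE1")
  a <- structure$atoms
  is_polar <- function(i) {
    if (a$element[i] == "H") return(FALSE)
    if (a$het[i]) return(a$element[i] %in% c("N", "O", "F", "Cl", "Br", "I"))
    nm <- da_table[[a$resname[i]]]
    !is.null(nm) && a$name[i] %in% nm
  }
  is_np <- function(i) {
    if (a$het[i]) return(a$element[i] == "C")
    a$element[i] == "C" && !(a$name[i] %in% c("N", "CA", "C", "O", "OXT"))
  }
  key <- paste(a$chain, a$resid, sep = ":")
  hits <- list()
  for (i in idx_a) for (j in idx_b) {
    if (key[i] == key[j]) next
    dij <- sqrt(sum((X[i, ] - X[j, ])^2))
    pr <- sort(c(key[i], key[j]))
    if (is_polar(i) && is_polar(j) && dij < polar_cutoff)
      hits[[paste(pr[1], pr[2], "polar")]] <- TRUE
    if (is_np(i) && is_np(j) && dij < nonpolar_cutoff)
      hits[[paste(pr[1], pr[2], "nonpolar")]] <- TRUE
  }
  as.character(sort(names(hits)))
}

# dense random cloud of typed residues (CA + template polar atom + one
# sidechain carbon each), guaranteed to exhibit both contact classes
contact_cloud <- function(n_res = 18, seed = 8, spread = 4.5) {
  tmpl <- list(SER = c("OG", "O"), LYS = c("NZ", "N"), ASP = c("OD1", "O"),
               ARG = c("NH1", "N"), LEU = c("CD1", "C"), PHE = c("CZ", "C"),
               THR = c("OG1", "O"), TYR = c("OH", "O"))
  set.seed(seed)
  resn <- sample(names(tmpl), n_res, replace = TRUE)
  rows <- list(); xyz <- list()
  for (r in seq_len(n_res)) {
    ca <- runif(3, -spread, spread)
    u1 <- rnorm(3); u1 <- 1.5 * u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- 1.5 * u2 / sqrt(sum(u2^2))
    t <- tmpl[[resn[r]]]
    rows[[r]] <- data.frame(name = c("CA", t[1], "CG2"),
                            element = c("C", t[2], "C"),
                            resname = resn[r], resid = r,
                            stringsAsFactors = FALSE)
    xyz[[r]] <- rbind(ca, ca + u1, ca + u2)
  }
  at <- do.call(rbind, rows)
  at$serial <- seq_len(nrow(at)); at$chain <- "A"; at$occupancy <- 1
  at$altloc <- ""; at$bfactor <- 0; at$het <- FALSE
  new_structure(at, unname(do.call(rbind, xyz)))
}

# canonical edge labels of a frame_contacts result, for oracle comparison
edge_labels <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  sort(paste(edges$partner_a, edges$partner_b, edges$class))
}

# agreement between a recovered partition and planted labels: fraction of
# all frames whose cluster maps to their true label under majority vote
# (noise frames count as disagreement)
membership_agreement <- function(partition, labels) {
  assigned <- rep(NA_integer_, length(labels))
  for (s in seq_along(partition$substates)) {
    mem <- partition$substates[[s]]$member_frames
    assigned[mem] <- as.integer(names(which.max(table(labels[mem]))))
  }
  mean(!is.na(assigned) & assigned == labels)
}
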