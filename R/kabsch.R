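# Least-squares rigid superposition (Kabsch, via 3x3 SVD).
#
# Finds the proper rotation Rm and translation tv minimizing
# || mobile %*% t(Rm) + tv - ref ||; returns the transform, the fitted
# coordinates and the post-fit RMSD.
kabsch_fit <- function(mobile, ref, check_degenerate = FALSE) {
  stopifnot(is.matrix(mobile), is.matrix(ref),
            ncol(mobile) == 3L, ncol(ref) == 3L,
            nrow(mobile) == nrow(ref))
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 matched atoms")
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(ref, 2L, cr)
  if (check_degenerate) {
    for (X in list(A, B)) {
      sv <- svd(X, nu = 0, nv = 0)$d
      if (sv[2] < 1e-8 * max(sv[1], 1e-12))
        stop("degenerate point set (collinear or coincident atoms); ",
             "superposition is ill-posed")
    }
  }
  H <- crossprod(A, B)                       # 3x3
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)  # proper rotation
  fitted <- A %*% t(Rm)
  rmsd <- sqrt(sum((fitted - B)^2) / n)
  list(rotation = Rm,
       translation = as.numeric(cr - Rm %*% cm),
       fitted = sweep(fitted, 2L, cr, "+"),
       rmsd = rmsd)
}

# apply a kabsch_fit transform to arbitrary coordinates (rows)
apply_transform <- function(xyz, fit) {
  sweep(xyz %*% t(fit$rotation), 2L, fit$translation, "+")
}

# RMSD after optimal superposition of pre-centered coordinate blocks.
# The residual is evaluated from the explicit rotation (rather than the
# singular-value trace identity) to avoid catastrophic cancellation when
# the frames nearly coincide.
superposed_rmsd_centered <- function(A, B) {
  if (identical(A, B)) return(0)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(Rm) - B)^2)))
}

# rotation angle (degrees, in [0, 180]) of a 3x3 rotation matrix
rotation_angle_deg <- function(Rm) {
  tr <- sum(diag(Rm))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

# Rodrigues rotation matrix: angle (degrees) about unit axis
rotation_about_axis <- function(axis, angle_deg) {
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
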