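test_that("static and rigidly jittered ensembles have zero width", {
  b <- make_bundle(2, 8, seed = 0)
  static <- toy_ensemble(b, replicate(5, b$xyz, simplify = FALSE))
  expect_identical(residue_fluctuation(static, "A:5"), 0)
  rigid <- make_fluctuation_ensemble(b, rep(0, 16), 10, seed = 2,
                                     rigid_jitter = TRUE)
  expect_lt(residue_fluctuation(rigid, "A:5"), 1e-9)
})

test_that("hand-built case matches a step-by-step bio3d oracle", {
  # 4 single-C-alpha residues + a sidechain atom on residue 2
  set.seed(5)
  base <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 1, 0), c(11, 2, 1),
                c(4.2, 1.4, 0.3))
  s <- toy_structure(base, name = c("CA", "CA", "CA", "CA", "CB"),
                     resid = c(1, 2, 3, 4, 2))
  frames <- lapply(1:3, function(t)
    base + matrix(rnorm(15, sd = 0.35), ncol = 3))
  frames[[1]] <- base                      # reference frame kept exact
  ens <- toy_ensemble(s, frames)
  p <- fluctuation_params(environment_radius = 20, mode = "sidechain")
  h <- residue_fluctuation(ens, "A:2", p)

  # oracle: superpose each frame's C-alphas onto frame 1 with bio3d, then
  # follow the definition arithmetically. Omega_{K,0} holds the sidechain
  # mode-atoms: CB of residue 2 plus the stand-in CAs of residues 1, 3, 4.
  ca <- 1:4
  omega <- c(1, 3, 4, 5)
  G <- vapply(1:3, function(t) {
    fitted <- matrix(bio3d::fit.xyz(
      fixed = as.vector(t(base)), mobile = as.vector(t(frames[[t]])),
      fixed.inds = bio3d::atom2xyz(ca), mobile.inds = bio3d::atom2xyz(ca)),
      ncol = 3, byrow = TRUE)
    sqrt(mean(rowSums((fitted[omega, ] - base[omega, ])^2)))
  }, numeric(1))
  h_oracle <- sqrt(mean((G - mean(G))^2))
  expect_equal(h, h_oracle, tolerance = 1e-10)
})

test_that("a graded planted sigma profile is recovered in rank order", {
  b <- make_bundle(1, 24, seed = 1)
  sigma <- seq(0.2, 1.0, length.out = 24)
  ens <- make_fluctuation_ensemble(b, sigma, 500, seed = 3)
  m <- fluctuation_map(ens, select_atoms(b, "protein"))
  expect_gte(cor(sigma, m$value, method = "spearman"), 0.9)
})

test_that("two-level 0.2/1.0 A groups separate cleanly", {
  b <- make_bundle(2, 10, seed = 1)
  sigma <- rep(c(0.2, 1.0), each = 10)
  ens <- make_fluctuation_ensemble(b, sigma, 500, seed = 3)
  m <- fluctuation_map(ens, select_atoms(b, "protein"))
  expect_gt(mean(m$value[11:20]), 2 * mean(m$value[1:10]))
})

test_that("doubling the planted amplitudes doubles H within 10%", {
  # the reference frame is kept at the exact base geometry so that both
  # ensembles resolve the identical t = 0 environment
  b <- make_bundle(1, 12, seed = 2)
  sigma <- seq(0.3, 0.8, length.out = 12)
  mk <- function(sig, seed, n = 1000) {
    noisy <- make_fluctuation_ensemble(b, sig, n - 1, seed = seed)
    new_ensemble(b, rbind(as.vector(t(b$xyz)), noisy$xyz),
                 burn_in_fraction = 0)
  }
  m1 <- fluctuation_map(mk(sigma, 7), select_atoms(b, "protein"))
  m2 <- fluctuation_map(mk(2 * sigma, 8), select_atoms(b, "protein"))
  ratio <- m2$value / m1$value
  expect_true(all(abs(ratio - 2) < 0.2))
})

test_that("each mode isolates the motion of its own atom class", {
  b <- make_bundle(2, 8, seed = 3)
  # sidechain-only noise: backbone geometry is static, so the C-alpha fit
  # is exact and the backbone width vanishes while sidechains register
  ens_sc <- make_fluctuation_ensemble(b, rep(0.6, 16), 300, seed = 5,
                                      mode = "sidechain")
  expect_lt(residue_fluctuation(ens_sc, "A:4",
                                fluctuation_params(mode = "backbone")), 1e-9)
  expect_gt(residue_fluctuation(ens_sc, "A:4",
                                fluctuation_params(mode = "sidechain")), 0.01)
  # backbone-only noise: backbone registers; the sidechain width is the
  # residual apparent motion of static atoms under the noisy C-alpha fit
  ens_bb <- make_fluctuation_ensemble(b, rep(0.6, 16), 300, seed = 5,
                                      mode = "backbone")
  expect_gt(residue_fluctuation(ens_bb, "A:4",
                                fluctuation_params(mode = "backbone")), 0.01)
  expect_gt(residue_fluctuation(ens_bb, "A:4",
                                fluctuation_params(mode = "sidechain")), 0)
})

test_that("H is invariant to the order of non-reference frames", {
  b <- make_bundle(1, 10, seed = 4)
  ens <- make_fluctuation_ensemble(b, rep(0.5, 10), 20, seed = 6)
  h1 <- residue_fluctuation(ens, "A:5")
  set.seed(99)
  perm <- c(1, sample(2:20))
  ens2 <- new_ensemble(b, ens$xyz[perm, ], burn_in_fraction = 0)
  expect_equal(residue_fluctuation(ens2, "A:5"), h1, tolerance = 1e-12)
})

test_that("ill-posed environments error by name but not in maps", {
  # three mutually close residues plus one isolated far from everything
  xyz <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3, 0), c(500, 0, 0),
               c(501.5, 0, 0))
  s <- toy_structure(xyz, name = c("CA", "CA", "CA", "CA", "CB"),
                     resid = c(1, 2, 3, 4, 4))
  ens <- toy_ensemble(s, list(xyz, xyz + 0.1, xyz - 0.05))
  expect_error(residue_fluctuation(ens, "A:4"), "A:4")
  expect_warning(m <- fluctuation_map(ens, select_atoms(s, "protein")),
                 "skipped")
  expect_true(is.na(m$value[m$resid == 4]))
  expect_false(anyNA(m$value[m$resid %in% 1:3]))
})

test_that("width is undefined on a single analyzed frame", {
  b <- make_bundle(1, 5, seed = 0)
  expect_error(residue_fluctuation(as_ensemble(b), "A:3"),
               "fewer than 2 analyzed frames")
})
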