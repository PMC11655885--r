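test_that("self- and translated superpositions are exact identities", {
  b <- make_bundle(2, 6, seed = 0)
  ca <- select_atoms(b, "calpha")
  fit <- superpose(b, b, list(mobile = ca, reference = ca))
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  moved <- b
  moved$xyz <- sweep(b$xyz, 2, c(10, -4, 2), "+")
  fit2 <- superpose(moved, b, list(mobile = ca, reference = ca))
  expect_equal(fit2$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit2$translation, c(-10, 4, -2), tolerance = 1e-9)
  expect_equal(fit2$n_atoms_used, 12L)
})

test_that("superposition RMSD is symmetric and rigid-motion invariant", {
  set.seed(17)
  b <- make_bundle(2, 6, seed = 3)
  noisy <- b
  noisy$xyz <- b$xyz + matrix(rnorm(3 * n_atoms(b), sd = 0.5), ncol = 3)
  ca <- select_atoms(b, "calpha")
  pairing <- list(mobile = ca, reference = ca)
  r_ab <- superpose(b, noisy, pairing)$rmsd
  r_ba <- superpose(noisy, b, pairing)$rmsd
  expect_equal(r_ab, r_ba, tolerance = 1e-9)
  spun <- make_rotated_complex(noisy, select_atoms(b, "protein"), 117, c(1, 1, 0))
  expect_equal(superpose(b, spun, pairing)$rmsd, r_ab, tolerance = 1e-9)
})

test_that("4-point fit matches optimizer and bio3d oracles", {
  A <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0), c(1, 1, 5))
  set.seed(23)
  B <- A + matrix(rnorm(12, sd = 0.4), ncol = 3)
  Rm <- trajscape:::rotation_about_axis(c(2, -1, 4), 61)
  B <- sweep(B %*% t(Rm), 2, c(3, 3, -7), "+")
  sa <- toy_structure(A, name = "CA", resid = 1:4)
  sb <- toy_structure(B, name = "CA", resid = 1:4)
  pairing <- list(mobile = 1:4, reference = 1:4)
  r <- superpose(sb, sa, pairing)$rmsd
  expect_equal(r, oracle_rmsd_optim(B, A), tolerance = 1e-3)
  expect_equal(r, oracle_rmsd_bio3d(B, A), tolerance = 1e-9)
})

test_that("degenerate point sets are rejected", {
  line <- toy_structure(cbind(1:4, 0, 0), name = "CA", resid = 1:4)
  expect_error(superpose(line, line, list(mobile = 1:4, reference = 1:4)),
               "degenerate|collinear")
  b <- make_bundle(1, 4, seed = 0)
  expect_error(superpose(b, b, list(mobile = 1:2, reference = 1:2)),
               "at least 3")
})

test_that("planted domain rotations are recovered across the sweep", {
  b <- make_bundle(3, 6, seed = 4)
  dom <- select_atoms(b, "resid 13-18")
  rec <- setdiff(seq_len(n_atoms(b)), dom$indices)
  align <- list(mobile = rec, reference = rec)
  domp <- list(reference = dom$indices, mobile = dom$indices)
  expect_equal(domain_rotation(b, b, align, domp), 0, tolerance = 1e-9)
  for (theta in seq(5, 175, by = 17)) {
    rot <- make_rotated_complex(b, dom, theta, c(0.3, -1, 0.8))
    expect_equal(domain_rotation(b, rot, align, domp), theta,
                 tolerance = 1e-6)
  }
})

test_that("domain angle ignores global rigid motion of either input", {
  b <- make_bundle(3, 6, seed = 4)
  dom <- select_atoms(b, "resid 13-18")
  rec <- setdiff(seq_len(n_atoms(b)), dom$indices)
  align <- list(mobile = rec, reference = rec)
  domp <- list(reference = dom$indices, mobile = dom$indices)
  rot <- make_rotated_complex(b, dom, 64, c(0, 1, 0))
  all_atoms <- select_atoms(b, "protein")
  rot_moved <- make_rotated_complex(rot, all_atoms, 45, c(1, 0, 1))
  rot_moved$xyz <- sweep(rot_moved$xyz, 2, c(-8, 2, 6), "+")
  expect_equal(domain_rotation(b, rot_moved, align, domp), 64,
               tolerance = 1e-6)
})

test_that("ligand contact shells list residues by minimum distance", {
  b <- make_bundle(2, 6, seed = 5)
  # two-atom ligand: one atom planted 3.3 A radially out from residue 3's
  # CB, so that CB is its nearest receptor atom
  cb3 <- which(b$atoms$name == "CB" & b$atoms$resid == 3)
  ca3 <- which(b$atoms$name == "CA" & b$atoms$resid == 3)
  u <- b$xyz[cb3, ] - b$xyz[ca3, ]
  u <- u / sqrt(sum(u^2))
  pos <- b$xyz[cb3, ] + 3.3 * u
  lig_xyz <- rbind(pos, pos + 0.5 * u)
  lig <- toy_structure(lig_xyz, name = c("L1", "L2"), element = "C",
                       resname = "LIG", resid = 99, het = TRUE)
  combo <- new_structure(rbind(b$atoms,
                               transform(lig$atoms, serial = serial + n_atoms(b))),
                         rbind(b$xyz, lig$xyz))
  lig_sel <- select_atoms(combo, "het")
  tab <- ligand_contacts(combo, lig_sel, cutoff = 4.0)
  expect_true(3 %in% tab$resid)
  r3 <- tab[tab$resid == 3, ]
  expect_equal(r3$min_distance, 3.3, tolerance = 1e-6)
  expect_identical(tab$min_distance, sort(tab$min_distance))
  expect_true(all(tab$min_distance <= 4.0))
  # brute-force check of the full shell
  got <- sort(unique(paste(tab$chain, tab$resid)))
  rec_min <- apply(as.matrix(dist(rbind(b$xyz, lig$xyz)))[
    seq_len(n_atoms(b)), n_atoms(b) + 1:2, drop = FALSE], 1, min)
  want <- sort(unique(paste(b$atoms$chain, b$atoms$resid)[rec_min <= 4.0]))
  expect_identical(got, want)

  far <- ligand_contacts(b, new_atom_index_set(1), cutoff = 0.1)
  expect_equal(nrow(far), 0L)
})

test_that("minimum distances enumerate exactly with deterministic ties", {
  xyz <- rbind(c(0, 0, 0), c(50, 0, 0),
               c(2.5, 0, 0), c(50, 3.7, 0), c(9, 9, 9))
  s <- toy_structure(xyz, resid = 1:5)
  res <- min_distance(s, new_atom_index_set(1:2), new_atom_index_set(3:5))
  expect_equal(res$distance, 2.5, tolerance = 1e-12)
  expect_equal(c(res$atom_a, res$atom_b), c(1L, 3L))
  # coincident coordinates across selections give zero
  s2 <- toy_structure(rbind(c(1, 1, 1), c(1, 1, 1)), resid = 1:2)
  expect_equal(min_distance(s2, new_atom_index_set(1),
                            new_atom_index_set(2))$distance, 0)
  expect_error(min_distance(s, new_atom_index_set(1:3),
                            new_atom_index_set(3:4)), "overlap")
})

test_that("atom matching pairs by chain, residue and name", {
  a <- make_bundle(1, 6, seed = 0)
  b <- make_bundle(1, 6, seed = 1)
  sub <- select_atoms(b, "not resid 4")
  b_sub <- new_structure(b$atoms[sub$indices, ], b$xyz[sub$indices, ])
  expect_message(pairing <- match_atoms(b_sub, a, "calpha"), "unmatched")
  expect_length(pairing$mobile$indices, 5L)
  expect_identical(a$atoms$resid[pairing$reference$indices],
                   b_sub$atoms$resid[pairing$mobile$indices])
})
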