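# two residues with polar (SER OG / LYS NZ) and carbon sidechain atoms at
# controllable separations
polar_pair_structure <- function(d_polar, d_carbon = 10) {
  xyz <- rbind(
    c(0, 0, 0), c(1.5, 0, 0), c(0, 5, 0),                 # res 1: CA, OG, CB2
    c(d_polar + 1.5, 0, 10), c(d_polar + 1.5, 0, 0),
    c(d_carbon, 5, 0))                                    # res 2: CA, NZ, CG
  toy_structure(xyz,
                name = c("CA", "OG", "CB2", "CA", "NZ", "CG"),
                element = c("C", "O", "C", "C", "N", "C"),
                resname = rep(c("SER", "LYS"), each = 3),
                resid = rep(1:2, each = 3))
}

test_that("polar cutoff is strict at 3.0 A and ignores geometry", {
  p <- interaction_params()
  s29 <- polar_pair_structure(2.9)
  e29 <- frame_contacts(as_ensemble(s29), 1,
                        select_atoms(s29, "resid 1"),
                        select_atoms(s29, "resid 2"), p)
  expect_true("polar" %in% e29$class)      # distance-only: no angle term
  s30 <- polar_pair_structure(3.0)
  e30 <- frame_contacts(as_ensemble(s30), 1,
                        select_atoms(s30, "resid 1"),
                        select_atoms(s30, "resid 2"), p)
  expect_false("polar" %in% e30$class)     # exactly at cutoff: absent
})

test_that("nonpolar carbon contacts are detected independently", {
  s <- polar_pair_structure(d_polar = 5, d_carbon = 4.7)   # C...C 4.7, N...O 5
  ed <- frame_contacts(as_ensemble(s), 1, select_atoms(s, "resid 1"),
                       select_atoms(s, "resid 2"))
  expect_equal(ed$class, "nonpolar")
  expect_equal(ed$min_distance, 4.7, tolerance = 1e-9)
})

test_that("per-frame detection matches the brute-force oracle", {
  s <- contact_cloud(n_res = 18, seed = 8)
  ens <- as_ensemble(s)
  ga <- select_atoms(s, "resid 1-9")
  gb <- select_atoms(s, "resid 10-18")
  got <- edge_labels(frame_contacts(ens, 1, ga, gb))
  want <- oracle_contacts(s, s$xyz, ga$indices, gb$indices)
  expect_identical(got, want)
  expect_true(any(grepl(" polar$", got)) && any(grepl(" nonpolar$", got)))
  # within-group network against itself
  got2 <- edge_labels(frame_contacts(ens, 1, ga, ga))
  want2 <- oracle_contacts(s, s$xyz, ga$indices, ga$indices)
  expect_identical(got2, want2)
})

test_that("ligand halogens join the polar class only when enabled", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 3, 0), c(2.8, 0, 0))
  s <- toy_structure(xyz,
                     name = c("CA", "OG", "CB2", "CL1"),
                     element = c("C", "O", "C", "Cl"),
                     resname = c("SER", "SER", "SER", "LIG"),
                     resid = c(1, 1, 1, 2),
                     het = c(FALSE, FALSE, FALSE, TRUE))
  rec <- select_atoms(s, "protein")
  lig <- select_atoms(s, "het")
  on <- frame_contacts(as_ensemble(s), 1, rec, lig, interaction_params())
  expect_true("polar" %in% on$class)       # Cl...OG at 1.3 A of OG
  off <- frame_contacts(as_ensemble(s), 1, rec, lig,
                        interaction_params(treat_halogens_as_polar = FALSE))
  expect_false("polar" %in% off$class)
})

test_that("unknown protein residue templates warn and are skipped", {
  s <- toy_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)),
                     name = c("OX1", "OG"), element = "O",
                     resname = c("XYZ", "SER"), resid = 1:2)
  expect_warning(
    ed <- frame_contacts(as_ensemble(s), 1, select_atoms(s, "resid 1"),
                         select_atoms(s, "resid 2")),
    "XYZ")
  expect_equal(nrow(ed), 0L)
})

test_that("persistence equals planted occupancy exactly", {
  b <- make_bundle(1, 6, seed = 0, sequence = c("SER", "LYS"))
  don <- which(b$atoms$name == "OG")[1]
  acc <- which(b$atoms$name == "NZ")[1]
  grp <- select_atoms(b, "protein")
  for (occ in c(0.4, 1.0)) {
    ens <- make_interaction_ensemble(b, occupancy_schedule(don, acc, occ),
                                     100, seed = 5)
    net <- persistence_network(ens, list(a = grp, b = grp))
    pol <- net$edges[net$edges$class == "polar", ]
    expect_equal(nrow(pol), 1L)
    expect_identical(pol$persistence, occ)
    expect_equal(net$n_frames_analyzed, 100L)
  }
})

test_that("independent planted pairs keep independent exact persistences", {
  b <- make_bundle(1, 12, seed = 0,
                   sequence = c("SER", "LYS", "ALA", "THR", "ARG", "ALA"))
  sch <- rbind(
    occupancy_schedule(which(b$atoms$name == "OG")[1],
                       which(b$atoms$name == "NZ")[1], 0.25),
    occupancy_schedule(which(b$atoms$name == "OG1")[1],
                       which(b$atoms$name == "NH1")[1], 0.75))
  ens <- make_interaction_ensemble(b, sch, 80, seed = 9)
  net <- persistence_network(ens, list(a = select_atoms(b, "protein"),
                                       b = select_atoms(b, "protein")))
  pol <- net$edges[net$edges$class == "polar", ]
  expect_setequal(pol$persistence, c(0.25, 0.75))
})

test_that("persistence is frame-order invariant and concatenation-linear", {
  b <- make_bundle(1, 6, seed = 0, sequence = c("SER", "LYS"))
  don <- which(b$atoms$name == "OG")[1]
  acc <- which(b$atoms$name == "NZ")[1]
  grp <- select_atoms(b, "protein")
  e1 <- make_interaction_ensemble(b, occupancy_schedule(don, acc, 0.3),
                                  40, seed = 2)
  e2 <- make_interaction_ensemble(b, occupancy_schedule(don, acc, 0.9),
                                  60, seed = 3)
  perm <- rev(seq_len(40))
  e1p <- new_ensemble(b, e1$xyz[perm, ], burn_in_fraction = 0)
  p_of <- function(e) {
    net <- persistence_network(e, list(a = grp, b = grp))
    net$edges$persistence[net$edges$class == "polar"]
  }
  expect_identical(p_of(e1p), p_of(e1))
  expect_equal(p_of(concat_ensembles(e1, e2)),
               (40 * 0.3 + 60 * 0.9) / 100, tolerance = 1e-12)
})

test_that("salt bridges report planted, alternating and absent pairs", {
  b <- make_bundle(1, 8, seed = 0, sequence = c("ASP", "ARG", "ALA", "LYS"))
  don <- which(b$atoms$name == "OD1")[1]
  acc <- which(b$atoms$name == "NH1")[1]
  always <- make_interaction_ensemble(b, occupancy_schedule(don, acc, 1.0),
                                      10, seed = 1)
  expect_identical(
    salt_bridge_report(always, list(c("A:1", "A:2")))$persistence, 1)

  # alternating 2.8 / 6.0 A every other frame
  frames <- lapply(1:10, function(t) {
    X <- b$xyz
    u <- (X[acc, ] - X[don, ]) / sqrt(sum((X[acc, ] - X[don, ])^2))
    X[acc, ] <- X[don, ] + (if (t %% 2 == 1) 2.8 else 6.0) * u
    X
  })
  alt <- toy_ensemble(b, frames)
  tab <- salt_bridge_report(alt, list(c("A:1", "A:2"), c("A:1", "A:8")))
  expect_equal(tab$persistence, c(0.5, 0))   # never-formed pair still listed
  expect_equal(tab$mean_min_distance[1], mean(c(2.8, 6.0)), tolerance = 1e-9)

  expect_error(salt_bridge_report(always, list(c("A:1", "A:99"))), "A:99")
  expect_error(salt_bridge_report(always, list(c("A:3", "A:5"))),
               "not an Asp/Glu")
})
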