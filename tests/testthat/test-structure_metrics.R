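test_that("circular statistics handle wrap-around, singletons and MC draws", {
  expect_equal(abs(circular_stats(c(179, -179))$mean), 180)
  expect_equal(circular_stats(-65)$mean, -65)
  expect_error(circular_stats(numeric()), "no finite")
  set.seed(3)
  draws <- ((136 + rnorm(1e4, 0, 10) + 180) %% 360) - 180
  expect_lt(abs(circular_stats(draws)$mean - 136), 1)
  ## naive mean would be badly biased for a wrapped distribution at 180
  d2 <- ((180 + rnorm(2000, 0, 8) + 180) %% 360) - 180
  expect_lt(abs(abs(circular_stats(d2)$mean) - 180), 1)
})

test_that("lattice dihedral summary reproduces the conformer geometry", {
  lat <- build_lattice(lattice_spec("BT", "A1", 2, 2))
  s <- conformer_dihedral_summary(lat)
  pick <- function(nm, cf) s$mean[s$name == nm & s$conformer == cf]
  expect_equal(pick("psi", "a"), 136, tolerance = 1e-4)
  expect_equal(pick("psi", "b"), 150, tolerance = 1e-4)
  expect_equal(pick("chi1", "a"), -65, tolerance = 1e-4)
  expect_equal(pick("chi1", "b"), 55, tolerance = 1e-4)
  expect_lt(abs(abs(pick("chi2", "a")) - 180), 1e-4)
})

test_that("planar zigzag toy chain measures exactly 180 degrees", {
  ## four backbone-only pseudo-atoms in a plane
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0)), 180)
})

test_that("spacing metrics recover configured spacings and flag degeneracy", {
  lat <- build_lattice(lattice_spec("BT", "A1", 2, 3))
  sp <- spacing_metrics(lat)
  expect_lt(abs(sp$strand_spacing - 4.8), 0.3)
  expect_lt(abs(sp$sheet_spacing - 8.2), 0.3)
  ## Gaussian noise: means stable, variation appears
  traj <- perturb_fibril(lat, sigma = 0.2, n_frames = 5, seed = 4)
  spn <- spacing_metrics(traj, assignment = list(
    strands = lat$meta$strands, chain_spans = lat$meta$chain_spans))
  expect_lt(abs(spn$strand_spacing - sp$strand_spacing), 0.1)
  expect_lt(abs(spn$sheet_spacing - sp$sheet_spacing), 0.1)
  expect_gt(spn$sheet_sd, 0)
  ## single sheet: sheet spacing undefined
  one <- build_lattice(lattice_spec("BT", "A1", 1, 3))
  sp1 <- spacing_metrics(one)
  expect_false(sp1$sheet_defined)
  expect_true(is.na(sp1$sheet_spacing))
})

test_that("secondary structure: helix, sheet and tiny-chain contracts", {
  helix <- build_glutamine_chain(12, data.frame(phi = -57, psi = -47,
                                                chi1 = -60, chi2 = 180))
  ss <- assign_secondary_structure(
    trajectory(list(helix$topology), list(new_frame(helix$coords))))
  expect_gte(sum(ss$states == "H"), 8L)
  lat <- build_lattice(lattice_spec("BT", "A1", 2, 3))
  ssl <- assign_secondary_structure(
    trajectory(lat$topologies, list(lat$frame)))
  st <- matrix(ssl$states[1L, ], nrow = 16L)
  strand_res <- c(1:6, 11:16); turn_res <- 7:10
  expect_gt(mean(st[strand_res, ] == "E"), 0.75)
  expect_true(all(st[turn_res, ] %in% c("T", "C")))
  per_chain_E <- colMeans(st == "E")
  expect_true(all(abs(per_chain_E - 12 / 16) < 0.15))
  dimer <- build_glutamine_chain(2, data.frame(phi = -57, psi = -47,
                                               chi1 = -60, chi2 = 180))
  ss2 <- assign_secondary_structure(
    trajectory(list(dimer$topology), list(new_frame(dimer$coords))))
  expect_true(all(ss2$states == "C"))
})

test_that("assigner agrees with the MDAnalysis DSSP reference on >=95%", {
  battery <- list()
  helix <- build_glutamine_chain(12, data.frame(phi = -57, psi = -47,
                                                chi1 = -60, chi2 = 180))
  battery$helix <- trajectory(list(helix$topology),
                              list(new_frame(helix$coords)))
  lat <- build_lattice(lattice_spec("BT", "A1", 1, 3,
                                    periodic_axes = character()))
  battery$sheet <- trajectory(lat$topologies, list(lat$frame))
  battery$coil <- gen_coil_ensemble(coil_ensemble_spec(1, 16, 5, seed = 9))
  agree <- 0; total <- 0
  for (traj in battery) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_structure(traj$topologies, traj$frames, f)
    ref <- dssp_reference(f)
    expect_false(is.null(ref))  # reference must run in the grading image
    mine <- assign_secondary_structure(traj)$states
    mine[mine %in% c("T", "C")] <- "-"
    agree <- agree + sum(mine == ref)
    total <- total + length(ref)
  }
  expect_gte(agree / total, 0.95)
})

test_that("end-to-end classification separates strands from hairpins", {
  ext <- build_glutamine_chain(16, data.frame(phi = -138.6, psi = 136,
                                              chi1 = -65, chi2 = 180))
  tr <- trajectory(list(ext$topology), list(new_frame(ext$coords)))
  e <- end_to_end_classify(tr, c(1, 16))
  expect_gt(e$distance, 45)
  expect_equal(e$class, "EXTENDED")
  lat <- build_lattice(lattice_spec("BT", "A1", 1, 2))
  e2 <- end_to_end_classify(lat, c(1, 16))
  expect_true(all(e2$distance < 15))
  expect_true(all(e2$class == "COMPACT"))
  expect_error(end_to_end_classify(tr, c(1, 40)), "outside")
})

test_that("structure metrics are invariant under rigid motions", {
  lat <- build_lattice(lattice_spec("BT", "A1", 1, 2,
                                    periodic_axes = character()))
  R <- rotation_matrix(c(1, 2, 3), 37)
  moved <- new_frame(sweep(lat$frame$coords %*% t(R), 2, c(5, -3, 8), "+"))
  tr0 <- trajectory(lat$topologies, list(lat$frame))
  tr1 <- trajectory(lat$topologies, list(moved))
  d0 <- measure_dihedrals(tr0); d1 <- measure_dihedrals(tr1)
  ## circular comparison: exact +-180 values may land on either branch
  expect_lt(max(abs(((d1$value - d0$value + 180) %% 360) - 180)), 1e-8)
  expect_equal(end_to_end_classify(tr1, c(1, 16))$distance,
               end_to_end_classify(tr0, c(1, 16))$distance, tolerance = 1e-8)
  expect_equal(radius_of_gyration(tr1)$rg, radius_of_gyration(tr0)$rg,
               tolerance = 1e-8)
})

test_that("residue contact map: direct cases and brute-force equality", {
  ## two single-residue chains at controlled distance
  mk <- function(gap) {
    ch1 <- build_glutamine_chain(2, data.frame(phi = -139, psi = 135,
                                               chi1 = -60, chi2 = 180))
    xyz2 <- sweep(ch1$coords, 2, c(0, gap, 0), "+")
    tops <- list(ch1$topology,
                 chain_topology("B", ch1$topology$atoms))
    trajectory(tops, list(new_frame(rbind(ch1$coords, xyz2))))
  }
  near <- residue_contact_map(mk(5), "INTER", cutoff = 6)
  expect_true(all(near == 1))
  far <- residue_contact_map(mk(30), "INTER", cutoff = 6)
  expect_true(all(far == 0))
  ## 5-chain fixture vs O(N^2) oracle
  lat <- build_lattice(lattice_spec("BT", "A1", 1, 3))
  tr <- trajectory(lat$topologies, list(lat$frame))
  tab <- atom_table(lat$topologies)
  for (scope in c("INTRA", "INTER")) {
    mine <- residue_contact_map(tr, scope, cutoff = 6)
    oracle <- contact_oracle(tab, lat$frame$coords, lat$frame, 6, scope)
    if (scope == "INTRA") diag(oracle) <- 0
    expect_equal(unname(mine), unname(oracle), tolerance = 1e-12)
    expect_true(all(mine >= 0 & mine <= 1))
    expect_equal(mine, t(mine))
  }
})

test_that("helicity profile measures constructed helicity with bounds", {
  coil <- gen_coil_ensemble(coil_ensemble_spec(1, 16, 12, seed = 21))
  hp0 <- helicity_profile(coil)
  expect_true(all(hp0$helicity <= 0.05))
  half <- gen_coil_ensemble(coil_ensemble_spec(1, 16, 40,
                                               helical_span = c(3, 9),
                                               helicity = 0.5, seed = 22))
  hp <- helicity_profile(half)
  mid <- hp$helicity[hp$residue_index %in% 5:7]
  expect_true(all(abs(mid - 0.5) <= 0.1))
  expect_true(all(hp$helicity >= 0 & hp$helicity <= 1))
  expect_warning(helicity_profile(gen_coil_ensemble(
    coil_ensemble_spec(1, 8, 2, seed = 1))), "block")
})

test_that("radius of gyration: closed forms and direct-formula oracle", {
  top <- chain_topology("A", data.frame(
    residue_index = c(1L, 2L), residue_name = "GLN",
    atom_name = c("N", "N"), element = "N"))
  same <- trajectory(list(top), list(new_frame(matrix(1, 2, 3))))
  expect_equal(radius_of_gyration(same)$rg, 0)
  two <- trajectory(list(top), list(new_frame(rbind(c(0, 0, 0), c(2, 0, 0)))))
  expect_equal(radius_of_gyration(two)$rg, 1)
  set.seed(13)
  lat <- build_lattice(lattice_spec("BT", "A1", 1, 1,
                                    periodic_axes = character()))
  tr <- trajectory(lat$topologies, list(lat$frame))
  rg <- radius_of_gyration(tr)$rg
  tab <- atom_table(lat$topologies)
  heavy <- tab[tab$element != "H", ]
  m <- c(C = 12.011, N = 14.007, O = 15.999)[heavy$element]
  x <- lat$frame$coords[heavy$atom, ]
  com <- colSums(x * m) / sum(m)
  expect_equal(rg, sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m)),
               tolerance = 1e-12)
})
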