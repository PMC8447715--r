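test_that("generators are deterministic per seed", {
  sp <- random_plant_spec(5L)
  g1 <- generate_planted_structure(sp)
  g2 <- generate_planted_structure(sp)
  expect_identical(g1, g2)
  d1 <- simulate_endo_hydrolysis(digest_spec(n_chains = 30L, seed = 9L))
  d2 <- simulate_endo_hydrolysis(digest_spec(n_chains = 30L, seed = 9L))
  expect_identical(d1, d2)
  d3 <- simulate_endo_hydrolysis(digest_spec(n_chains = 30L, seed = 10L))
  expect_false(identical(d1$census, d3$census))
  t1 <- generate_trajectory(n_res = 5L, n_frames = 10L, seed = 3L)
  t2 <- generate_trajectory(n_res = 5L, n_frames = 10L, seed = 3L)
  expect_identical(t1, t2)
  k1 <- generate_kinetics(seed = 4L)
  k2 <- generate_kinetics(seed = 4L)
  expect_identical(k1, k2)
})

test_that("plant specifications enforce cutoff and decoy-margin invariants", {
  expect_error(plant_spec(planted = data.frame(kind = "salt_bridge",
                                               distance = 4.1)),
               "inside the kind cutoff")
  expect_error(plant_spec(planted = data.frame(kind = "hbond",
                                               distance = 2.0)),
               "inside the kind cutoff")
  expect_error(plant_spec(decoys = data.frame(kind = "pi_pi",
                                              distance = 7.3)),
               "0.2 angstrom")
  expect_error(plant_spec(planted = data.frame(kind = "nonsense",
                                               distance = 3)),
               "unknown interaction kind")
  expect_error(generate_planted_structure(
    plant_spec(n_filler = 0L)), "empty spec")
})

test_that("single planted interactions are found at their exact distance", {
  g <- generate_planted_structure(plant_spec(
    planted = data.frame(kind = "salt_bridge", distance = 3.9), seed = 2L))
  rec <- detect_salt_bridges(select_polymer(g$model))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$distance, 3.9, tolerance = 1e-6)

  g2 <- generate_planted_structure(plant_spec(
    planted = data.frame(kind = rep("pi_pi", 3L), distance = 6.8),
    decoys = data.frame(kind = rep("pi_pi", 2L), distance = 7.5),
    seed = 3L))
  expect_equal(nrow(detect_pi_pi(select_polymer(g2$model))), 3L)
})

test_that("the digest simulator conserves monomers and never merges chains", {
  ds <- simulate_endo_hydrolysis(digest_spec(
    n_chains = 60L, lengths = 12L, archetype = "iagal_like",
    times = c(0.05, 0.2, 1, 5, Inf), seed = 11L))
  expect_true(all(ds$truth$monomer_total == ds$truth$monomer_total[1L]))
  expect_true(all(diff(ds$truth$n_chains) >= 0))
  doh <- compute_doh(ds$samples)
  expect_true(all(diff(doh) >= 0))
})

test_that("the fungal archetype digests to galactose and galactobiose only", {
  ds <- simulate_endo_hydrolysis(digest_spec(
    n_chains = 40L, lengths = 12L, archetype = "fungal", times = Inf,
    seed = 13L))
  final <- ds$census[[1L]]
  expect_setequal(which(final > 0L), c(1L, 2L))
})

test_that("an inert-length-3 enzyme splits G4 into {1,3} or {2,2} only", {
  # exhaustive enumeration of single-cut outcomes of a 4-mer: (1,3), (2,2),
  # (3,1); all leave fragments at or below the inert length, so the final
  # census has no chain of length >= 4 and equal counts of 1s and 3s
  ds <- simulate_endo_hydrolysis(digest_spec(
    n_chains = 50L, lengths = 4L, archetype = "iagal_like", times = Inf,
    seed = 17L))
  final <- ds$census[[1L]]
  expect_true(all(which(final > 0L) <= 3L))
  expect_equal(final[1L], final[3L])
  expect_equal(sum(seq_along(final) * final), 200L)
})

test_that("geometric chain lengths respect the requested mean", {
  ds <- simulate_endo_hydrolysis(digest_spec(
    n_chains = 4000L, lengths = list(type = "geometric", mean = 8),
    archetype = "fungal", times = 0, seed = 23L))
  lens <- rep(seq_along(ds$census[[1L]]), ds$census[[1L]])
  expect_equal(mean(lens), 8, tolerance = 0.1)
})

test_that("synthetic kinetics follow the rate law exactly at zero noise", {
  k <- generate_kinetics(km = 0.5, kcat = 20, enzyme_conc = 2e-3,
                         enzyme_mw = 50000, noise_cv = 0, seed = 1L)
  e <- 2e-3 / 50000
  expect_equal(k$v, 20 * e * k$s / (0.5 + k$s), tolerance = 1e-12)
  # single saturating level: v = Vmax * 10/11
  k10 <- generate_kinetics(km = 0.5, kcat = 20, enzyme_conc = 2e-3,
                           enzyme_mw = 50000, s_levels = 5.0,
                           noise_cv = 0, seed = 1L)
  expect_equal(k10$v, 20 * e * 10 / 11, tolerance = 1e-12)
})

test_that("planted structures survive the I/O round trip and detector checks", {
  for (seed in c(31L, 32L)) {
    g <- generate_planted_structure(random_plant_spec(seed))
    m2 <- parse_structure(write_structure(g$model))
    expect_equal(nrow(m2$atoms), nrow(g$model$atoms))
    rec <- detect_interactions(select_polymer(m2))
    expect_equal(nrow(rec), nrow(g$truth))
  }
})
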