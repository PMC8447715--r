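# boundary-geometry cases for each detector, hand-built from minimal atoms

test_that("salt bridges respect the 4.0 A nitrogen-oxygen cutoff", {
  lys <- res_atoms("LYS", 1L, atom_spec(c("NZ", "CE"), c("N", "C"),
                                        c(0, -1.5), c(0, 0), c(0, 0)))
  glu_in <- res_atoms("GLU", 5L, atom_spec(c("OE1", "CD"), c("O", "C"),
                                           c(3.9, 5.0), c(0, 0.8), c(0, 0)))
  hit <- detect_salt_bridges(mk_model(lys, glu_in))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 3.9)
  expect_equal(hit$atom_a, "NZ")
  expect_equal(hit$atom_b, "OE1")

  glu_out <- res_atoms("GLU", 5L, atom_spec(c("OE1", "CD"), c("O", "C"),
                                            c(4.05, 5.2), c(0, 0.8), c(0, 0)))
  expect_equal(nrow(detect_salt_bridges(mk_model(lys, glu_out))), 0L)
})

test_that("basic/acidic residues lacking side-chain atoms are skipped with a warning", {
  lys_stub <- res_atoms("LYS", 1L, atom_spec("CA", "C", 0, 0, 0))
  glu <- res_atoms("GLU", 5L, atom_spec("OE1", "O", 3.0, 0, 0))
  expect_warning(out <- detect_salt_bridges(mk_model(lys_stub, glu)),
                 "missing basic")
  expect_equal(nrow(out), 0L)
})

test_that("hydrogen bonds use the 3.5 A cutoff and exclude near-diagonal backbone pairs", {
  donor <- res_atoms("ALA", 5L, atom_spec("N", "N", 0, 0, 0))
  acceptor <- res_atoms("ALA", 1L, atom_spec("O", "O", 2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(mk_model(donor, acceptor))), 1L)

  far <- res_atoms("ALA", 1L, atom_spec("O", "O", 3.6, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(mk_model(donor, far))), 0L)

  adjacent <- res_atoms("ALA", 4L, atom_spec("O", "O", 2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(mk_model(donor, adjacent))), 0L)

  # side-chain donors are not subject to the backbone adjacency exclusion
  ser <- res_atoms("SER", 4L, atom_spec("OG", "O", 2.9, 0, 0))
  expect_equal(nrow(detect_hydrogen_bonds(mk_model(donor, ser))), 1L)
})

test_that("ring descriptors give the centroid mean, unit normals, and two rings for Trp", {
  phe <- flat_phe(1L)
  d <- compute_ring_descriptors(phe)
  expect_length(d, 1L)
  expect_equal(d[[1L]]$centroid, c(0, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(abs(d[[1L]]$normal[3L]), 1, tolerance = 1e-9)
  expect_equal(sqrt(sum(d[[1L]]$normal^2)), 1, tolerance = 1e-9)

  trp <- thermogal:::.residue_template("TRP")
  trp_res <- res_atoms("TRP", 2L, trp)
  expect_length(compute_ring_descriptors(trp_res), 2L)

  incomplete <- phe[phe$name != "CZ", ]
  expect_warning(d2 <- compute_ring_descriptors(incomplete), "incomplete")
  expect_length(d2, 0L)
})

test_that("pi-pi stacking respects the 7.2 A centroid cutoff and adjacency exclusion", {
  m_in <- mk_model(flat_phe(1L), flat_phe(5L, cx = 7.1))
  hit <- detect_pi_pi(m_in)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 7.1, tolerance = 1e-9)

  m_out <- mk_model(flat_phe(1L), flat_phe(5L, cx = 7.3))
  expect_equal(nrow(detect_pi_pi(m_out)), 0L)

  m_adj <- mk_model(flat_phe(1L), flat_phe(2L, cx = 6.0))
  expect_equal(nrow(detect_pi_pi(m_adj)), 0L)
})

test_that("cation-pi needs the cation over the ring face", {
  lys_axial <- res_atoms("LYS", 9L, atom_spec("NZ", "N", 0, 0, 4.0))
  hit <- detect_cation_pi(mk_model(flat_phe(1L), lys_axial))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 4.0, tolerance = 1e-9)
  expect_equal(hit$angle, 0, tolerance = 1e-6)

  lys_planar <- res_atoms("LYS", 9L, atom_spec("NZ", "N", 5.0, 0, 0))
  expect_equal(nrow(detect_cation_pi(mk_model(flat_phe(1L), lys_planar))), 0L)
})

test_that("disulfides pair Cys SG atoms within 2.5 A", {
  c1 <- res_atoms("CYS", 1L, atom_spec("SG", "S", 0, 0, 0))
  c2 <- res_atoms("CYS", 8L, atom_spec("SG", "S", 2.05, 0, 0))
  hit <- detect_disulfides(mk_model(c1, c2))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$distance, 2.05)
  c3 <- res_atoms("CYS", 8L, atom_spec("SG", "S", 3.5, 0, 0))
  expect_equal(nrow(detect_disulfides(mk_model(c1, c3))), 0L)
})

test_that("metal coordination counts O/N ligands within the cutoff", {
  g <- generate_planted_structure(plant_spec(
    metal_sites = data.frame(n_inner = 4L, inner_distance = 2.4,
                             n_outer = 1L, outer_distance = 3.4),
    n_filler = 1L, seed = 3L))
  rep <- metal_coordination(g$model)
  expect_length(rep, 1L)
  expect_equal(rep[[1L]]$n, 4L)
  expect_true(all(rep[[1L]]$ligands$element == "O"))
  # no metal of the requested element -> empty report, not an error
  expect_length(metal_coordination(g$model, metal_element = "ZN"), 0L)
})

test_that("bidentate carboxylate oxygens count separately in metal coordination", {
  ca <- res_atoms("CA", 100L, atom_spec("CA", "CA", 0, 0, 0), hetero = TRUE)
  glu <- res_atoms("GLU", 7L, atom_spec(c("OE1", "OE2", "CD"),
                                        c("O", "O", "C"),
                                        c(2.4, 0.3, 1.5),
                                        c(0, 2.4, 1.4), c(0, 0, 0)))
  rep <- metal_coordination(mk_model(ca, glu))
  expect_equal(rep[[1L]]$n, 2L)
  expect_setequal(rep[[1L]]$ligands$name, c("OE1", "OE2"))
})

test_that("detectors match the planted manifest and the brute-force oracle on fuzzed fixtures", {
  for (seed in 1:12) {
    g <- generate_planted_structure(random_plant_spec(seed))
    m <- select_polymer(g$model)
    truth <- g$truth
    det <- list(salt_bridge = detect_salt_bridges(m),
                hbond = detect_hydrogen_bonds(m),
                pi_pi = detect_pi_pi(m),
                cation_pi = detect_cation_pi(m),
                disulfide = detect_disulfides(m))
    ora <- list(salt_bridge = oracle_salt_bridges(m),
                hbond = oracle_hbonds(m),
                pi_pi = oracle_pi_pi(m),
                cation_pi = oracle_cation_pi(m),
                disulfide = oracle_disulfides(m))
    for (k in names(det)) {
      got <- pair_set(det[[k]]$res_a, det[[k]]$res_b)
      want <- with(truth[truth$kind == k, ], pair_set(res_a, res_b))
      expect_identical(got, want,
                       label = sprintf("%s pairs (seed %d)", k, seed))
      expect_identical(got, sort(ora[[k]]$pair),
                       label = sprintf("%s vs oracle (seed %d)", k, seed))
      if (nrow(det[[k]]) > 0L) {
        expect_equal(sort(det[[k]]$distance), sort(ora[[k]]$distance),
                     tolerance = 1e-9)
      }
    }
    # planted distances are realized exactly
    for (k in unique(truth$kind)) {
      expect_equal(sort(det[[k]]$distance),
                   sort(truth$distance[truth$kind == k]),
                   tolerance = 1e-6)
    }
  }
})

test_that("detector output is invariant under rigid rotation and translation", {
  g <- generate_planted_structure(random_plant_spec(99L))
  m <- select_polymer(g$model)
  m2 <- rigid_move(m)
  for (f in list(detect_salt_bridges, detect_hydrogen_bonds, detect_pi_pi,
                 detect_cation_pi, detect_disulfides)) {
    r1 <- f(m)
    r2 <- f(m2)
    expect_equal(r1$res_a, r2$res_a)
    expect_equal(r1$res_b, r2$res_b)
    expect_equal(r1$distance, r2$distance, tolerance = 1e-6)
  }
  rep1 <- metal_coordination(g$model)
  rep2 <- metal_coordination(rigid_move(g$model))
  expect_equal(vapply(rep1, `[[`, integer(1L), "n"),
               vapply(rep2, `[[`, integer(1L), "n"))
})

test_that("interaction records export as TSV with the expected columns", {
  m <- mk_model(flat_phe(1L), flat_phe(5L, cx = 6.0))
  tf <- tempfile(fileext = ".tsv")
  write_interactions(detect_pi_pi(m), tf, structure_id = "demo")
  got <- read.delim(tf)
  expect_named(got, c("structure_id", "kind", "res_a", "resname_a", "res_b",
                      "resname_b", "atom_a", "atom_b", "distance_A",
                      "angle_deg"))
  expect_equal(got$structure_id, "demo")
  unlink(tf)
})
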