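test_that("a minimal single-atom record parses to one chain/residue/atom", {
  m <- parse_structure(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$name, "CA")
  expect_equal(m$atoms$resname, "ALA")
  expect_equal(m$atoms$chain, "A")
  expect_equal(m$atoms$resno, 1L)
  expect_equal(c(m$atoms$x, m$atoms$y, m$atoms$z), c(11.104, 6.134, -6.504))
  expect_false(m$atoms$hetero)
  expect_true(m$atoms$polymer)
})

test_that("altloc resolution keeps the highest occupancy, ties to smallest altloc", {
  two <- c(
    "ATOM      1  CA AGLU A   2       1.000   2.000   3.000  0.60  0.00           C",
    "ATOM      2  CA BGLU A   2       1.500   2.000   3.000  0.40  0.00           C")
  m <- parse_structure(two)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$occ, 0.6)
  expect_equal(m$atoms$x, 1.0)

  tie <- c(
    "ATOM      1  CA BGLU A   2       9.000   2.000   3.000  0.50  0.00           C",
    "ATOM      2  CA AGLU A   2       1.000   2.000   3.000  0.50  0.00           C")
  m2 <- parse_structure(tie)
  expect_equal(nrow(m2$atoms), 1L)
  expect_equal(m2$atoms$alt, "A")
  expect_equal(m2$atoms$x, 1.0)
})

test_that("write/parse round trip preserves residues and coordinates to 3 decimals", {
  g <- generate_planted_structure(plant_spec(
    planted = data.frame(kind = c("salt_bridge", "pi_pi", "disulfide"),
                         distance = c(3.8, 6.5, 2.1)),
    metal_sites = data.frame(n_inner = 3L, inner_distance = 2.4,
                             n_outer = 1L, outer_distance = 3.5),
    n_filler = 2L, seed = 11L))
  m <- g$model
  m2 <- parse_structure(write_structure(m), structure_id = m$structure_id)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_equal(paste(m2$atoms$chain, m2$atoms$resno, m2$atoms$resname,
                     m2$atoms$name),
               paste(m$atoms$chain, m$atoms$resno, m$atoms$resname,
                     m$atoms$name))
  # PDB fixed columns carry 3 decimals
  expect_lt(max(abs(as.matrix(m2$atoms[, c("x", "y", "z")]) -
                      as.matrix(m$atoms[, c("x", "y", "z")]))), 5.1e-4)
  expect_equal(m2$atoms$hetero, m$atoms$hetero)
})

test_that("HELIX records survive the round trip", {
  p <- build_peptide(12L)
  p$helix <- data.frame(chain = "A", start = 2L, end = 9L,
                        stringsAsFactors = FALSE)
  p2 <- parse_structure(write_structure(p))
  expect_equal(p2$helix$start, 2L)
  expect_equal(p2$helix$end, 9L)
  expect_equal(p2$helix$chain, "A")
})

test_that("select_polymer restricts to a chain and separates hetero groups", {
  a <- build_peptide(4L)$atoms
  b <- a
  b$chain <- "B"
  b$x <- b$x + 30
  ca <- res_atoms("CA", 200L, atom_spec("CA", "CA", 5, 5, 5), hetero = TRUE)
  wat <- res_atoms("HOH", 201L, atom_spec("O", "O", 6.5, 5, 5), hetero = TRUE)
  m <- mk_model(a[, names(ca)], b[, names(ca)], ca, wat)
  onlyA <- select_polymer(m, "A")
  expect_setequal(unique(onlyA$atoms$chain), "A")
  expect_true(all(onlyA$atoms$polymer[!onlyA$atoms$hetero]))
  expect_equal(sum(!onlyA$atoms$polymer), 2L)  # ion + water retained
  expect_error(select_polymer(m, "Z"), "available chains.*A.*B")
  # default chain is the first in file order
  expect_setequal(unique(select_polymer(m)$atoms$chain), "A")
})

test_that("malformed and empty inputs raise informative parse errors", {
  good <- "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C"
  bad <- "ATOM      2  CA  ALA A   2       0.000   bad"
  expect_error(parse_structure(c(good, bad)), "line 2")
  expect_error(parse_structure("REMARK nothing here"), "no ATOM or HETATM")
  expect_error(parse_structure(character()), "empty")
})

test_that("multi-model files use the first model only, with a warning", {
  txt <- c(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      1  CA  ALA A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL")
  expect_warning(m <- parse_structure(txt), "first model")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 1.0)
})

test_that("write_structure rejects empty models and over-long atom names", {
  m <- build_peptide(2L)
  empty <- m
  empty$atoms <- empty$atoms[0L, ]
  expect_error(write_structure(empty), "empty")
  badname <- m
  badname$atoms$name[1L] <- "ABCDE"
  expect_error(write_structure(badname), "4 characters")
})
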