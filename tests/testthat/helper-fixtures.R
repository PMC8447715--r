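# hand-built minimal models for boundary-case detector tests

res_atoms <- function(resname, resno, spec, chain = "A", hetero = FALSE) {
  data.frame(
    name = spec$name, element = spec$element, resname = resname,
    chain = chain, resno = resno, insert = "", alt = "",
    x = spec$x, y = spec$y, z = spec$z, occ = 1, b = 0,
    hetero = hetero, polymer = !hetero & resname %in% standard_aa(),
    stringsAsFactors = FALSE
  )
}

mk_model <- function(..., id = "fixture") {
  atoms <- do.call(rbind, list(...))
  atoms$serial <- seq_len(nrow(atoms))
  structure(list(structure_id = id, atoms = atoms,
                 helix = data.frame(chain = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)),
            class = "structure_model")
}

atom_spec <- function(name, element, x, y, z) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

# flat aromatic ring in the z = 0 plane, centered at (cx, cy, 0)
flat_phe <- function(resno, cx = 0, cy = 0, cz = 0) {
  th <- 2 * pi * (0:5) / 6
  r <- 1.39 / (2 * sin(pi / 6))
  res_atoms("PHE", resno, atom_spec(
    c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), rep("C", 6),
    cx + r * cos(th), cy + r * sin(th), rep(cz, 6)))
}

# apply a rigid motion to every atom of a model
rigid_move <- function(model, axis = c(1, 2, 3), angle = 37,
                       shift = c(5, -3, 11)) {
  R <- thermogal:::.rotation_matrix(axis, angle)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2L, shift, "+")
  model$atoms$x <- xyz[, 1L]
  model$atoms$y <- xyz[, 2L]
  model$atoms$z <- xyz[, 3L]
  model
}

# random planted-structure spec over all interaction kinds, inside the
# single-kind distance windows
random_plant_spec <- function(seed) {
  set.seed(seed * 1000L)
  ranges <- list(
    salt_bridge = c(3.60, 3.95), hbond = c(2.70, 3.45),
    pi_pi = c(4.50, 7.15), cation_pi = c(3.20, 5.80),
    disulfide = c(2.00, 2.45))
  decoy_ranges <- list(
    salt_bridge = c(4.25, 5.50), hbond = c(3.75, 4.50),
    pi_pi = c(7.45, 8.50), cation_pi = c(6.45, 7.50),
    disulfide = c(2.75, 3.20))
  planted <- do.call(rbind, lapply(names(ranges), function(k) {
    n <- sample(0:3, 1L)
    if (n == 0L) return(NULL)
    data.frame(kind = k,
               distance = runif(n, ranges[[k]][1L], ranges[[k]][2L]),
               angle = if (k == "cation_pi") runif(n, 0, 50) else 0)
  }))
  decoys <- do.call(rbind, lapply(names(decoy_ranges), function(k) {
    n <- sample(0:2, 1L)
    if (n == 0L) return(NULL)
    data.frame(kind = k,
               distance = runif(n, decoy_ranges[[k]][1L],
                                decoy_ranges[[k]][2L]),
               angle = 0)
  }))
  # an in-plane cation decoy: below the distance cutoff but off-angle
  if (runif(1) < 0.5) {
    decoys <- rbind(decoys, data.frame(kind = "cation_pi",
                                       distance = runif(1, 4.0, 5.5),
                                       angle = runif(1, 66, 85)))
  }
  plant_spec(planted = planted, decoys = decoys,
             n_filler = sample(2:4, 1L), seed = seed)
}

# normalized pair-set for comparing detector output, oracle and manifest
pair_set <- function(res_a, res_b) {
  if (length(res_a) == 0L) return(character())
  sort(paste(pmin(res_a, res_b), pmax(res_a, res_b)))
}
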