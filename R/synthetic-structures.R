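# Generator for planted-interaction structures: residue pairs with idealized
# side-chain geometry are placed on a widely spaced lattice (one interaction
# per site, sites >= 17 A apart) so that each planted interaction has exactly
# its target distance and nothing else comes near any detector cutoff.
# Decoys use the same geometry at distances safely outside the cutoffs.
# Every generated model carries an exact ground-truth manifest, which is what
# makes detector sensitivity/specificity measurable.

.kind_cutoffs <- c(salt_bridge = 4.0, hbond = 3.5, pi_pi = 7.2,
                   cation_pi = 6.0, disulfide = 2.5)
# lower bounds keeping planted ground truth single-kind (e.g. a salt bridge
# planted below 3.5 A would legitimately also be a hydrogen bond)
.kind_floors <- c(salt_bridge = 3.55, hbond = 2.4, pi_pi = 4.2,
                  cation_pi = 3.0, disulfide = 1.9)

# residue templates: anchor atom (or ring centroid) at the origin, all other
# atoms at x <= 0, so that two mirrored templates anchored d apart along x
# have exactly one close contact -- the planted one
.bb_from_ca <- function(ca) {
  rbind(
    data.frame(name = "N", element = "N", x = ca[1] - 0.75,
               y = ca[2] + 1.15, z = ca[3] + 0.30),
    data.frame(name = "C", element = "C", x = ca[1] + 0.65,
               y = ca[2] + 1.05, z = ca[3] + 0.35),
    data.frame(name = "O", element = "O", x = ca[1] + 1.00,
               y = ca[2] + 2.10, z = ca[3] + 0.70)
  )
}

.tpl_row <- function(name, element, x, y, z) {
  data.frame(name = name, element = element, x = x, y = y, z = z,
             stringsAsFactors = FALSE)
}

.ring_tpl <- function(resname) {
  if (resname %in% c("PHE", "TYR")) {
    v <- .regular_ring(6L, 1.39)
    nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    atoms <- .tpl_row(nm, "C", v[, 1], v[, 2], v[, 3])
    if (resname == "TYR") {
      cz <- v[4L, ]
      r <- sqrt(sum(cz^2))
      oh <- cz * (r + 1.37) / r
      atoms <- rbind(atoms, .tpl_row("OH", "O", oh[1], oh[2], oh[3]))
    }
    cg <- v[1L, ]
  } else if (resname == "HIS") {
    v <- .regular_ring(5L, 1.37)
    nm <- c("CG", "ND1", "CE1", "NE2", "CD2")
    atoms <- .tpl_row(nm, c("C", "N", "C", "N", "C"),
                      v[, 1], v[, 2], v[, 3])
    cg <- v[1L, ]
  } else if (resname == "TRP") {
    v6 <- .regular_ring(6L, 1.39)
    nm6 <- c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
    cd2 <- v6[1L, ]; ce2 <- v6[2L, ]
    mid <- (cd2 + ce2) / 2
    u <- mid / sqrt(sum(mid^2))
    a5 <- 1.39 / (2 * tan(pi / 5))
    c5 <- mid + a5 * u
    r5 <- 1.39 / (2 * sin(pi / 5))
    ang_of <- function(p) atan2(p[3] - c5[3], p[2] - c5[2])
    phi2 <- ang_of(ce2)
    for (sgn in c(1, -1)) {
      phis <- phi2 + sgn * (2 * pi / 5) * (0:4)
      vv <- cbind(0, c5[2] + r5 * cos(phis), c5[3] + r5 * sin(phis))
      if (sqrt(sum((vv[5L, ] - cd2)^2)) < 1e-6) break
    }
    nm5 <- c("CE2", "NE1", "CD1", "CG", "CD2")
    pent <- .tpl_row(nm5[2:4], c("N", "C", "C"),
                     vv[2:4, 1], vv[2:4, 2], vv[2:4, 3])
    atoms <- rbind(.tpl_row(nm6, "C", v6[, 1], v6[, 2], v6[, 3]), pent)
    cg <- vv[4L, ]
  } else {
    stop("not an aromatic residue template")
  }
  cb <- cg + c(-1.05, 0.85, 0)
  ca <- cb + c(-1.40, 0.30, 0)
  rbind(atoms, .tpl_row("CB", "C", cb[1], cb[2], cb[3]),
        .tpl_row("CA", "C", ca[1], ca[2], ca[3]), .bb_from_ca(ca))
}

.residue_template <- function(resname) {
  switch(resname,
    LYS = {
      ca <- c(-5.9, 2.4, 0)
      rbind(.tpl_row(c("NZ", "CE", "CD", "CG", "CB", "CA"),
                     c("N", "C", "C", "C", "C", "C"),
                     c(0, -1.49, -2.20, -3.70, -4.40, ca[1]),
                     c(0, 0, 1.25, 1.20, 2.45, ca[2]),
                     c(0, 0, 0, 0, 0, ca[3])),
            .bb_from_ca(ca))
    },
    GLU = {
      ca <- c(-4.35, 2.3, 0)
      rbind(.tpl_row(c("OE1", "CD", "OE2", "CG", "CB", "CA"),
                     c("O", "C", "O", "C", "C", "C"),
                     c(0, -0.65, -0.35, -2.15, -2.85, ca[1]),
                     c(0, 1.05, 2.25, 1.00, 2.30, ca[2]),
                     c(0, 0, 0.20, 0, 0, ca[3])),
            .bb_from_ca(ca))
    },
    SER = {
      ca <- c(-2.10, 1.30, 0)
      rbind(.tpl_row(c("OG", "CB", "CA"), c("O", "C", "C"),
                     c(0, -1.42, ca[1]), c(0, 0, ca[2]), c(0, 0, ca[3])),
            .bb_from_ca(ca))
    },
    CYS = {
      ca <- c(-2.50, 1.35, 0)
      rbind(.tpl_row(c("SG", "CB", "CA"), c("S", "C", "C"),
                     c(0, -1.80, ca[1]), c(0, 0, ca[2]), c(0, 0, ca[3])),
            .bb_from_ca(ca))
    },
    ALA = {
      # anchored at backbone O (hydrogen-bond acceptor)
      .tpl_row(c("O", "C", "CA", "CB", "N"),
               c("O", "C", "C", "C", "N"),
               c(0, -1.23, -2.00, -1.30, -3.45),
               c(0, 0, 1.30, 2.55, 1.30),
               c(0, 0, 0, 0.60, 0.20))
    },
    PHE = .ring_tpl("PHE"),
    TYR = .ring_tpl("TYR"),
    HIS = .ring_tpl("HIS"),
    TRP = .ring_tpl("TRP"),
    stop(sprintf("no template for residue %s", resname))
  )
}

#' Specification for a planted-interaction structure
#'
#' @param planted Data frame with columns `kind` (one of salt_bridge, hbond,
#'   pi_pi, cation_pi, disulfide), `distance` (angstrom, strictly inside the
#'   kind's cutoff and above a kind-specific floor that keeps the ground
#'   truth single-kind) and optionally `angle` (degrees off the ring normal,
#'   cation_pi only, default 0).
#' @param decoys Same columns; distances must clear the cutoff by at least
#'   0.2 angstrom, or (cation_pi only) the angle must exceed 65 degrees at a
#'   sub-cutoff distance.
#' @param n_filler Number of isolated alanine filler residues.
#' @param metal_sites Data frame with columns `n_inner`, `inner_distance`,
#'   `n_outer`, `outer_distance`: calcium sites with water shells planted
#'   inside/outside the coordination cutoff.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return List of class `plant_spec`.
#' @export
plant_spec <- function(planted = NULL, decoys = NULL, n_filler = 4L,
                       metal_sites = NULL, seed = 1L) {
  empty <- data.frame(kind = character(), distance = numeric(),
                      angle = numeric(), stringsAsFactors = FALSE)
  norm <- function(x) {
    if (is.null(x) || nrow(x) == 0L) return(empty)
    if (is.null(x$angle)) x$angle <- 0
    x$angle[is.na(x$angle)] <- 0
    x
  }
  planted <- norm(planted)
  decoys <- norm(decoys)
  bad <- !planted$kind %in% names(.kind_cutoffs)
  if (any(bad)) stop(sprintf("unknown interaction kind(s): %s",
                             paste(unique(planted$kind[bad]), collapse = ", ")))
  hi <- .kind_cutoffs[planted$kind]
  lo <- .kind_floors[planted$kind]
  if (any(planted$distance >= hi | planted$distance <= lo)) {
    stop("planted distances must lie strictly inside the kind cutoff and above the single-kind floor")
  }
  if (any(planted$kind == "cation_pi" & planted$angle > 55)) {
    stop("planted cation_pi angles must be at most 55 degrees")
  }
  ang_decoy <- decoys$kind == "cation_pi" & decoys$angle >= 65
  if (any(!ang_decoy & decoys$distance < .kind_cutoffs[decoys$kind] + 0.2)) {
    stop("decoy distances must clear the cutoff by at least 0.2 angstrom")
  }
  if (!is.null(metal_sites) && nrow(metal_sites) > 0L) {
    stopifnot(all(metal_sites$inner_distance <= 2.8),
              all(metal_sites$outer_distance >= 3.2))
  }
  structure(list(planted = planted, decoys = decoys,
                 n_filler = as.integer(n_filler),
                 metal_sites = metal_sites, seed = as.integer(seed)),
            class = "plant_spec")
}

# partner residue names per kind; aromatic pi-pi partners drawn from the
# full aromatic set, cation-pi partners restricted to all-carbon PHE rings
# so no ring nitrogen or hydroxyl can form a shorter qualifying contact
.site_residues <- function(kind) {
  switch(kind,
         salt_bridge = c("LYS", "GLU"),
         hbond = c("SER", "ALA"),
         pi_pi = sample(c("PHE", "TYR", "TRP", "HIS"), 2L, replace = TRUE),
         cation_pi = c("LYS", "PHE"),
         disulfide = c("CYS", "CYS"))
}

#' Generate a structure with planted interactions
#'
#' Builds a single-chain model in which every requested interaction is
#' realized at exactly its target distance (to 1e-6 angstrom) and every
#' decoy sits outside its cutoff, plus isolated filler residues and optional
#' calcium-water coordination sites.  Each site receives a random rigid
#' rotation, so detector rotation-invariance is exercised by construction.
#' Deterministic for a given spec seed.
#'
#' @param spec A [plant_spec()].
#' @return List with `model` (a `structure_model`), `truth` (data frame of
#'   planted interaction records: `kind`, `res_a`, `res_b`, `distance`) and
#'   `metal_truth` (data frame `res`, `n` per calcium site).
#' @export
generate_planted_structure <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  set.seed(spec$seed)
  items <- rbind(
    if (nrow(spec$planted)) cbind(spec$planted, role = "planted"),
    if (nrow(spec$decoys)) cbind(spec$decoys, role = "decoy")
  )
  n_metal <- if (is.null(spec$metal_sites)) 0L else nrow(spec$metal_sites)
  n_items <- if (is.null(items)) 0L else nrow(items)
  n_sites <- n_items + n_metal + spec$n_filler
  if (n_sites == 0L) stop("empty spec: nothing to generate")
  m <- ceiling(n_sites^(1 / 3))
  lattice <- as.matrix(expand.grid(x = 0:(m - 1), y = 0:(m - 1),
                                   z = 0:(m - 1)))[seq_len(n_sites), ,
                                                   drop = FALSE] * 25
  atoms_list <- list()
  truth <- list()
  metal_truth <- list()
  serial <- 0L
  water_no <- 9000L
  add_res <- function(tpl, resname, resno, site_pos, rot, hetero = FALSE) {
    xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(rot)
    xyz <- sweep(xyz, 2L, site_pos, "+")
    n <- nrow(tpl)
    df <- data.frame(
      serial = serial + seq_len(n), name = tpl$name, alt = "",
      resname = resname, chain = "A", resno = resno, insert = "",
      x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], occ = 1, b = 0,
      element = tpl$element, hetero = hetero,
      polymer = !hetero & resname %in% standard_aa(),
      stringsAsFactors = FALSE)
    serial <<- serial + n
    atoms_list[[length(atoms_list) + 1L]] <<- df
    df
  }
  site <- 0L
  for (i in seq_len(n_items)) {
    site <- site + 1L
    kind <- items$kind[i]
    d <- items$distance[i]
    ang <- items$angle[i]
    resnames <- .site_residues(kind)
    rot <- .random_rotation()
    pos <- lattice[site, ]
    tpl_a <- .residue_template(resnames[1L])
    tpl_b <- .residue_template(resnames[2L])
    if (kind %in% c("cation_pi")) {
      # aromatic ring at the anchor; cation offset at `ang` off the normal,
      # lateral component on -y (away from the template bodies)
      offset <- d * c(cos(ang * pi / 180), -sin(ang * pi / 180), 0)
      tpl_cat <- tpl_a
      tpl_cat[, c("x")] <- -tpl_cat$x  # mirror so the body extends outward
      tpl_cat$x <- tpl_cat$x + offset[1L]
      tpl_cat$y <- tpl_cat$y + offset[2L]
      tpl_cat$z <- tpl_cat$z + offset[3L]
      ra <- add_res(tpl_b, resnames[2L], 10L * site + 1L, pos, rot)
      rb <- add_res(tpl_cat, resnames[1L], 10L * site + 5L, pos, rot)
      lab_arom <- .res_label("A", 10L * site + 1L, "")
      lab_cat <- .res_label("A", 10L * site + 5L, "")
      if (items$role[i] == "planted") {
        truth[[length(truth) + 1L]] <- data.frame(
          kind = kind, res_a = lab_cat, res_b = lab_arom, distance = d,
          stringsAsFactors = FALSE)
      }
    } else {
      tpl_bm <- tpl_b
      tpl_bm$x <- -tpl_bm$x + d
      ra <- add_res(tpl_a, resnames[1L], 10L * site + 1L, pos, rot)
      rb <- add_res(tpl_bm, resnames[2L], 10L * site + 5L, pos, rot)
      if (items$role[i] == "planted") {
        truth[[length(truth) + 1L]] <- data.frame(
          kind = kind,
          res_a = .res_label("A", 10L * site + 1L, ""),
          res_b = .res_label("A", 10L * site + 5L, ""),
          distance = d, stringsAsFactors = FALSE)
      }
    }
  }
  if (n_metal > 0L) {
    for (i in seq_len(n_metal)) {
      site <- site + 1L
      ms <- spec$metal_sites[i, ]
      rot <- .random_rotation()
      pos <- lattice[site, ]
      ca_tpl <- .tpl_row("CA", "CA", 0, 0, 0)
      add_res(ca_tpl, "CA", 10L * site + 1L, pos, rot, hetero = TRUE)
      lab <- .res_label("A", 10L * site + 1L, "")
      shells <- c(rep(ms$inner_distance, ms$n_inner),
                  rep(ms$outer_distance, ms$n_outer))
      dirs <- .sphere_points(max(1L, length(shells)))
      for (k in seq_along(shells)) {
        water_no <- water_no + 1L
        w <- dirs[k, ] * shells[k]
        add_res(.tpl_row("O", "O", w[1L], w[2L], w[3L]), "HOH",
                water_no, pos, rot, hetero = TRUE)
      }
      metal_truth[[length(metal_truth) + 1L]] <-
        data.frame(res = lab, n = ms$n_inner, stringsAsFactors = FALSE)
    }
  }
  if (spec$n_filler > 0L) {
    for (i in seq_len(spec$n_filler)) {
      site <- site + 1L
      add_res(.residue_template("ALA"), "ALA", 10L * site + 1L,
              lattice[site, ], .random_rotation())
    }
  }
  atoms <- do.call(rbind, atoms_list)
  rownames(atoms) <- NULL
  model <- structure(
    list(structure_id = sprintf("planted_seed%d", spec$seed), atoms = atoms,
         helix = data.frame(chain = character(), start = integer(),
                            end = integer(), stringsAsFactors = FALSE)),
    class = "structure_model")
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), res_a = character(),
               res_b = character(), distance = numeric(),
               stringsAsFactors = FALSE)
  metal_truth <- if (length(metal_truth)) do.call(rbind, metal_truth) else
    data.frame(res = character(), n = integer(), stringsAsFactors = FALSE)
  list(model = model, truth = truth, metal_truth = metal_truth)
}
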