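# internal geometry helpers shared by detectors, builders and trajectory code

.vnorm <- function(v) sqrt(sum(v * v))

# pairwise Euclidean distances between rows of two n x 3 matrices
.cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# dihedral angle (degrees, in (-180, 180]) defined by points p1-p2-p3-p4
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / .vnorm(b2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# place a new point at distance `bond` from c, with angle `ang` (deg) at c
# relative to b, and torsion `tor` (deg) about the b-c axis relative to a
# (natural extension reference frame)
.nerf_place <- function(a, b, c, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- -tor * pi / 180  # frame below is left-handed w.r.t. the IUPAC torsion sign
  bc <- c - b
  bc <- bc / .vnorm(bc)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / .vnorm(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# rotation matrix from axis (unit not required) and angle in degrees
.rotation_matrix <- function(axis, angle_deg) {
  u <- axis / .vnorm(axis)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    ct + ux^2 * (1 - ct),      ux * uy * (1 - ct) - uz * st, ux * uz * (1 - ct) + uy * st,
    uy * ux * (1 - ct) + uz * st, ct + uy^2 * (1 - ct),      uy * uz * (1 - ct) - ux * st,
    uz * ux * (1 - ct) - uy * st, uz * uy * (1 - ct) + ux * st, ct + uz^2 * (1 - ct)
  ), nrow = 3L, byrow = TRUE)
}

# random rotation matrix from a seeded RNG stream (uniform quaternion)
.random_rotation <- function() {
  q <- rnorm(4)
  q <- q / .vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

# vertices of a regular n-gon with given side length, centered at the origin
# in the yz-plane (normal along +x), first vertex on +y
.regular_ring <- function(n, side) {
  r <- side / (2 * sin(pi / n))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = 0, y = r * cos(th), z = r * sin(th))
}

#' Build an idealized peptide backbone
#'
#' Constructs N, CA, C, O and CB coordinates for a polypeptide with uniform
#' backbone dihedrals, using standard bond lengths and angles (N-CA 1.458,
#' CA-C 1.525, C-N 1.329 angstrom; omega fixed at 180 degrees).  Used by the
#' synthetic generators (ideal alpha-helix: phi = -57, psi = -47) and by the
#' dihedral-mode helix-assignment tests.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone dihedrals in degrees, recycled over residues.
#' @param resnames Residue names, recycled (default "ALA").
#' @param chain Chain identifier.
#' @return A `structure_model`.
#' @export
build_peptide <- function(n_res, phi = -57, psi = -47, resnames = "ALA",
                          chain = "A") {
  stopifnot(n_res >= 1)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  resnames <- rep_len(resnames, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- list()
  # seed first residue
  n1 <- c(0, 0, 0)
  ca1 <- c(b_nca, 0, 0)
  c1 <- .nerf_place(c(-1, 1, 0), n1, ca1, b_cac, a_ncac, phi[1])
  prev <- list(N = n1, CA = ca1, C = c1)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      ni <- .nerf_place(prev$N, prev$CA, prev$C, b_cn, a_cacn, psi[i - 1L])
      cai <- .nerf_place(prev$CA, prev$C, ni, b_nca, a_cnca, 180)
      ci <- .nerf_place(prev$C, ni, cai, b_cac, a_ncac, phi[i])
      prev <- list(N = ni, CA = cai, C = ci)
    }
    oi <- .nerf_place(prev$N, prev$CA, prev$C, 1.231, 120.8, psi[i] + 180)
    cbi <- .nerf_place(prev$C, prev$N, prev$CA, 1.53, 110.6, -122)
    at <- if (resnames[i] == "GLY") {
      list(N = prev$N, CA = prev$CA, C = prev$C, O = oi)
    } else {
      list(N = prev$N, CA = prev$CA, C = prev$C, O = oi, CB = cbi)
    }
    coords[[i]] <- at
  }
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    at <- coords[[i]]
    data.frame(name = names(at), resno = i, resname = resnames[i],
               t(vapply(at, identity, numeric(3L))),
               stringsAsFactors = FALSE)
  }))
  names(rows)[4:6] <- c("x", "y", "z")
  atoms <- data.frame(
    serial = seq_len(nrow(rows)), name = rows$name, alt = "",
    resname = rows$resname, chain = chain, resno = rows$resno, insert = "",
    x = rows$x, y = rows$y, z = rows$z, occ = 1, b = 0,
    element = substr(rows$name, 1L, 1L), hetero = FALSE,
    polymer = TRUE, stringsAsFactors = FALSE
  )
  structure(list(structure_id = "peptide", atoms = atoms,
                 helix = data.frame(chain = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)),
            class = "structure_model")
}
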