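# Independent brute-force oracles: plain nested loops over qualifying atoms
# with their own copies of the chemical dictionaries, sharing no geometry
# code with the package detectors.

.olab <- function(a, i) paste0(a$chain[i], ":", a$resno[i])

.opoly <- function(model) {
  a <- model$atoms
  a[a$polymer & a$element != "H", , drop = FALSE]
}

.odist <- function(a, i, j) {
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

.opairs_min <- function(a, ii, jj, cutoff, exclude_same_res = TRUE,
                        extra_skip = NULL) {
  best <- list()
  for (i in ii) {
    for (j in jj) {
      if (exclude_same_res &&
          a$chain[i] == a$chain[j] && a$resno[i] == a$resno[j]) next
      if (!is.null(extra_skip) && extra_skip(i, j)) next
      d <- .odist(a, i, j)
      if (d > cutoff) next
      key <- paste(sort(c(.olab(a, i), .olab(a, j))), collapse = " ")
      if (is.null(best[[key]]) || d < best[[key]]) best[[key]] <- d
    }
  }
  if (length(best) == 0L) {
    return(data.frame(pair = character(), distance = numeric()))
  }
  data.frame(pair = names(best), distance = unlist(best),
             row.names = NULL, stringsAsFactors = FALSE)
}

oracle_salt_bridges <- function(model, cutoff = 4.0) {
  a <- .opoly(model)
  bas <- which((a$resname == "ARG" & a$name %in% c("NH1", "NH2", "NE")) |
                 (a$resname == "LYS" & a$name == "NZ") |
                 (a$resname == "HIS" & a$name %in% c("ND1", "NE2")))
  aci <- which((a$resname == "GLU" & a$name %in% c("OE1", "OE2")) |
                 (a$resname == "ASP" & a$name %in% c("OD1", "OD2")))
  .opairs_min(a, bas, aci, cutoff)
}

oracle_hbonds <- function(model, cutoff = 3.5) {
  a <- .opoly(model)
  don_sc <- list(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
                 ASN = "ND2", GLN = "NE2", TRP = "NE1",
                 HIS = c("ND1", "NE2"), LYS = "NZ",
                 ARG = c("NE", "NH1", "NH2"))
  acc_sc <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
                 GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
                 HIS = c("ND1", "NE2"), MET = "SD")
  in_dict <- function(i, dict) {
    !is.null(dict[[a$resname[i]]]) && a$name[i] %in% dict[[a$resname[i]]]
  }
  don <- which(a$name == "N" | vapply(seq_len(nrow(a)), in_dict,
                                      logical(1L), dict = don_sc))
  acc <- which(a$name == "O" | vapply(seq_len(nrow(a)), in_dict,
                                      logical(1L), dict = acc_sc))
  skip_bb <- function(i, j) {
    a$name[i] == "N" && a$name[j] == "O" &&
      a$chain[i] == a$chain[j] && abs(a$resno[i] - a$resno[j]) < 2
  }
  .opairs_min(a, don, acc, cutoff, extra_skip = skip_bb)
}

# ring centroids/normals computed independently: normal from the cross
# product of two ring-edge vectors
.oracle_rings <- function(model) {
  a <- .opoly(model)
  defs <- list(
    PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
    HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
    TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
               c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))
  out <- list()
  for (key in unique(paste(a$chain, a$resno))) {
    ra <- a[paste(a$chain, a$resno) == key, , drop = FALSE]
    dd <- defs[[ra$resname[1L]]]
    if (is.null(dd)) next
    for (nm in dd) {
      idx <- match(nm, ra$name)
      if (anyNA(idx)) next
      xyz <- as.matrix(ra[idx, c("x", "y", "z")])
      cen <- colMeans(xyz)
      v1 <- xyz[2L, ] - xyz[1L, ]
      v2 <- xyz[3L, ] - xyz[1L, ]
      nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      out[[length(out) + 1L]] <- list(
        res = paste0(ra$chain[1L], ":", ra$resno[1L]),
        chain = ra$chain[1L], resno = ra$resno[1L],
        centroid = cen, normal = nrm)
    }
  }
  out
}

oracle_pi_pi <- function(model, cutoff = 7.2) {
  rings <- .oracle_rings(model)
  best <- list()
  n <- length(rings)
  if (n >= 2L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        ri <- rings[[i]]; rj <- rings[[j]]
        if (ri$res == rj$res) next
        if (ri$chain == rj$chain && abs(ri$resno - rj$resno) == 1L) next
        d <- sqrt(sum((ri$centroid - rj$centroid)^2))
        if (d > cutoff) next
        key <- paste(sort(c(ri$res, rj$res)), collapse = " ")
        if (is.null(best[[key]]) || d < best[[key]]) best[[key]] <- d
      }
    }
  }
  if (length(best) == 0L) {
    return(data.frame(pair = character(), distance = numeric()))
  }
  data.frame(pair = names(best), distance = unlist(best),
             row.names = NULL, stringsAsFactors = FALSE)
}

oracle_cation_pi <- function(model, dist_cutoff = 6.0, angle_cutoff = 60) {
  a <- .opoly(model)
  rings <- .oracle_rings(model)
  cat_idx <- which((a$resname == "LYS" & a$name == "NZ") |
                     (a$resname == "ARG" & a$name == "CZ"))
  best <- list()
  for (i in cat_idx) {
    for (r in rings) {
      if (r$res == .olab(a, i)) next
      v <- c(a$x[i], a$y[i], a$z[i]) - r$centroid
      d <- sqrt(sum(v^2))
      if (d > dist_cutoff || d == 0) next
      cosang <- abs(sum(v / d * r$normal))
      ang <- acos(min(1, cosang)) * 180 / pi
      if (ang > angle_cutoff) next
      key <- paste(sort(c(.olab(a, i), r$res)), collapse = " ")
      if (is.null(best[[key]]) || d < best[[key]]) best[[key]] <- d
    }
  }
  if (length(best) == 0L) {
    return(data.frame(pair = character(), distance = numeric()))
  }
  data.frame(pair = names(best), distance = unlist(best),
             row.names = NULL, stringsAsFactors = FALSE)
}

oracle_disulfides <- function(model, cutoff = 2.5) {
  a <- .opoly(model)
  sg <- which(a$resname == "CYS" & a$name == "SG")
  .opairs_min(a, sg, sg, cutoff)
}

# rigid superposition RMSD by direct minimization over quaternions,
# independent of the closed-form solution under test
oracle_superpose_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2L, colMeans(mobile))
  Q <- sweep(reference, 2L, colMeans(reference))
  rot_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           nrow = 3L, byrow = TRUE)
  }
  f <- function(q) sqrt(mean(rowSums((P %*% rot_q(q) - Q)^2)))
  set.seed(4242)
  best_q <- NULL
  best_v <- Inf
  for (k in 1:500) {
    q <- rnorm(4L)
    v <- f(q)
    if (v < best_v) {
      best_v <- v
      best_q <- q
    }
  }
  o <- optim(best_q, f, control = list(maxit = 5000, reltol = 1e-14))
  o$value
}
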