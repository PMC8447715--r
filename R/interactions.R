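# Geometric detectors for the intramolecular interaction classes counted per
# structure: salt bridges, hydrogen bonds, pi-pi stacks, cation-pi contacts,
# disulfides and metal coordination.  All criteria are heavy-atom,
# distance-based (the crystal structures carry no hydrogens); cutoffs are
# arguments with field-standard defaults (salt bridges 4.0 A, H-bonds 3.5 A,
# ring-centroid pi-pi 7.2 A).

.sb_basic <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                  HIS = c("ND1", "NE2"))
.sb_acidic <- list(GLU = c("OE1", "OE2"), ASP = c("OD1", "OD2"))

#' Hydrogen-bond donor/acceptor dictionary
#'
#' Heavy-atom donor and acceptor sets used by [detect_hydrogen_bonds()].
#' Backbone N is a donor and backbone O an acceptor for every residue;
#' side-chain membership follows standard chemistry.  The dictionary is
#' returned as a list so it can be modified and passed back in.
#'
#' @return List with elements `donors` and `acceptors`, each a named list
#'   mapping residue name to side-chain atom names, plus `backbone_donor`
#'   ("N") and `backbone_acceptor` ("O").
#' @export
hbond_dictionary <- function() {
  list(
    donors = list(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
                  ASN = "ND2", GLN = "NE2", TRP = "NE1",
                  HIS = c("ND1", "NE2"), LYS = "NZ",
                  ARG = c("NE", "NH1", "NH2")),
    acceptors = list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                     ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                     TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"),
    backbone_donor = "N",
    backbone_acceptor = "O"
  )
}

.ring_defs <- list(
  PHE = list(PHE6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(TYR6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(HIS5 = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(TRP5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             TRP6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

.empty_records <- function() {
  data.frame(kind = character(), res_a = character(), resname_a = character(),
             res_b = character(), resname_b = character(),
             atom_a = character(), atom_b = character(),
             distance = numeric(), angle = numeric(),
             stringsAsFactors = FALSE)
}

.res_label <- function(chain, resno, insert) {
  paste0(chain, ":", resno, ifelse(is.na(insert) | insert == "", "", insert))
}

# polymer heavy atoms with residue bookkeeping columns attached
.poly_atoms <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a <- a[a$polymer & a$element != "H", , drop = FALSE]
  a$res <- .res_label(a$chain, a$resno, a$insert)
  a
}

# assemble records from candidate atom-pair hits, one per residue pair,
# keeping the minimum distance; res_a/res_b ordered unless `directed`
.pair_records <- function(kind, a_rows, b_rows, dist, cutoff,
                          angle = NULL, directed = FALSE) {
  hit <- which(dist <= cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(.empty_records())
  recs <- data.frame(
    kind = kind,
    res_a = a_rows$res[hit[, 1L]], resname_a = a_rows$resname[hit[, 1L]],
    res_b = b_rows$res[hit[, 2L]], resname_b = b_rows$resname[hit[, 2L]],
    atom_a = a_rows$name[hit[, 1L]], atom_b = b_rows$name[hit[, 2L]],
    distance = dist[hit],
    angle = if (is.null(angle)) NA_real_ else angle[hit],
    stringsAsFactors = FALSE
  )
  recs <- recs[recs$res_a != recs$res_b, , drop = FALSE]
  if (nrow(recs) == 0L) return(.empty_records())
  if (!directed) {
    swap <- recs$res_a > recs$res_b
    recs[swap, c("res_a", "res_b", "resname_a", "resname_b",
                 "atom_a", "atom_b")] <-
      recs[swap, c("res_b", "res_a", "resname_b", "resname_a",
                   "atom_b", "atom_a")]
  }
  key <- paste(recs$res_a, recs$res_b)
  recs <- recs[order(key, recs$distance), , drop = FALSE]
  recs <- recs[!duplicated(paste(recs$res_a, recs$res_b)), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

# select atoms listed in a resname -> atom-names dictionary
.dict_atoms <- function(atoms, dict, warn_missing = FALSE, role = "side-chain") {
  keep <- rep(FALSE, nrow(atoms))
  for (rn in names(dict)) {
    keep <- keep | (atoms$resname == rn & atoms$name %in% dict[[rn]])
  }
  sel <- atoms[keep, , drop = FALSE]
  if (warn_missing) {
    cand <- unique(atoms$res[atoms$resname %in% names(dict)])
    found <- unique(sel$res)
    missing <- setdiff(cand, found)
    if (length(missing) > 0L) {
      warning(sprintf("skipping %d residue(s) with missing %s atoms: %s",
                      length(missing), role,
                      paste(missing, collapse = ", ")))
    }
  }
  sel
}

#' Detect salt bridges
#'
#' A salt bridge is recorded for every (basic, acidic) residue pair whose
#' minimum nitrogen-oxygen distance is at or below the cutoff.  Basic atoms:
#' Arg NH1/NH2/NE, Lys NZ, His ND1/NE2; acidic atoms: Glu OE1/OE2,
#' Asp OD1/OD2.  One record per residue pair, carrying the minimum distance.
#'
#' @param model A `structure_model` (polymer flags set, see
#'   [select_polymer()]).
#' @param cutoff Distance cutoff in angstrom (default 4.0).
#' @return Data frame of interaction records (columns `kind`, `res_a`,
#'   `resname_a`, `res_b`, `resname_b`, `atom_a`, `atom_b`, `distance`,
#'   `angle`); zero rows when nothing is found.
#' @export
detect_salt_bridges <- function(model, cutoff = 4.0) {
  a <- .poly_atoms(model)
  bas <- .dict_atoms(a, .sb_basic, warn_missing = TRUE, role = "basic side-chain")
  aci <- .dict_atoms(a, .sb_acidic, warn_missing = TRUE, role = "acidic side-chain")
  if (nrow(bas) == 0L || nrow(aci) == 0L) return(.empty_records())
  d <- .cross_dist(as.matrix(bas[, c("x", "y", "z")]),
                   as.matrix(aci[, c("x", "y", "z")]))
  .pair_records("salt_bridge", bas, aci, d, cutoff, directed = TRUE)
}

#' Detect hydrogen bonds
#'
#' Heavy-atom donor-acceptor pairs within the cutoff, using the dictionary
#' from [hbond_dictionary()].  Intra-residue pairs are excluded, as are
#' backbone-backbone pairs between residues fewer than 2 apart in sequence
#' along the same chain.  One record per residue pair (minimum distance,
#' donor reported as `atom_a`).
#'
#' @inheritParams detect_salt_bridges
#' @param cutoff Distance cutoff in angstrom (default 3.5).
#' @param dictionary Donor/acceptor dictionary, see [hbond_dictionary()].
#' @export
detect_hydrogen_bonds <- function(model, cutoff = 3.5,
                                  dictionary = hbond_dictionary()) {
  a <- .poly_atoms(model)
  don <- rbind(a[a$name %in% dictionary$backbone_donor, , drop = FALSE],
               .dict_atoms(a, dictionary$donors))
  acc <- rbind(a[a$name %in% dictionary$backbone_acceptor, , drop = FALSE],
               .dict_atoms(a, dictionary$acceptors))
  if (nrow(don) == 0L || nrow(acc) == 0L) return(.empty_records())
  d <- .cross_dist(as.matrix(don[, c("x", "y", "z")]),
                   as.matrix(acc[, c("x", "y", "z")]))
  # mask excluded pairs by inflating their distance
  same_res <- outer(don$res, acc$res, "==")
  bb <- outer(don$name == dictionary$backbone_donor,
              acc$name == dictionary$backbone_acceptor, "&") &
    outer(don$chain, acc$chain, "==") &
    abs(outer(don$resno, acc$resno, "-")) < 2
  d[same_res | bb] <- Inf
  .pair_records("hbond", don, acc, d, cutoff, directed = FALSE)
}

#' Aromatic ring descriptors for one residue
#'
#' Returns centroid and least-squares plane normal for each aromatic ring of
#' a Phe/Tyr/His/Trp residue (Trp contributes its 5- and 6-ring separately).
#' The centroid is the arithmetic mean of the ring-atom coordinates; the
#' normal is the unit eigenvector of smallest variance of the centered ring
#' coordinates.
#'
#' @param residue_atoms Data frame of one residue's atoms (rows of
#'   `model$atoms`).
#' @return List of descriptors, each a list with `label`, `atoms`,
#'   `centroid` (length-3 numeric) and `normal` (unit length-3 numeric).
#'   Empty list (with a warning) when ring atoms are incomplete, or
#'   (silently) for non-aromatic residues.
#' @export
compute_ring_descriptors <- function(residue_atoms) {
  resname <- residue_atoms$resname[1L]
  defs <- .ring_defs[[resname]]
  if (is.null(defs)) return(list())
  out <- list()
  for (lab in names(defs)) {
    nm <- defs[[lab]]
    idx <- match(nm, residue_atoms$name)
    if (anyNA(idx)) {
      warning(sprintf("incomplete %s ring in %s %s; skipping",
                      lab, resname,
                      .res_label(residue_atoms$chain[1L],
                                 residue_atoms$resno[1L],
                                 residue_atoms$insert[1L])))
      next
    }
    xyz <- as.matrix(residue_atoms[idx, c("x", "y", "z")])
    centroid <- colMeans(xyz)
    sv <- svd(sweep(xyz, 2L, centroid))
    normal <- sv$v[, 3L]
    normal <- normal / .vnorm(normal)
    out[[lab]] <- list(label = lab, atoms = nm, centroid = centroid,
                       normal = normal)
  }
  out
}

# all ring descriptors of a model, flattened with residue bookkeeping
.all_rings <- function(a) {
  arom <- a[a$resname %in% names(.ring_defs), , drop = FALSE]
  if (nrow(arom) == 0L) return(NULL)
  rings <- list()
  for (res in unique(arom$res)) {
    ra <- arom[arom$res == res, , drop = FALSE]
    for (d in compute_ring_descriptors(ra)) {
      rings[[length(rings) + 1L]] <- list(
        res = res, resname = ra$resname[1L], chain = ra$chain[1L],
        resno = ra$resno[1L], label = d$label, centroid = d$centroid,
        normal = d$normal)
    }
  }
  if (length(rings) == 0L) return(NULL)
  rings
}

#' Detect pi-pi interactions
#'
#' For every pair of aromatic residues (Phe, Tyr, Trp, His) all
#' ring-centroid to ring-centroid distances are computed (Trp contributes
#' both rings); if any is at or below the cutoff one record is emitted for
#' the residue pair, carrying the minimum centroid distance and the acute
#' angle between the two ring normals.  Sequence-adjacent aromatic pairs
#' (|i - j| = 1 on the same chain) are excluded.
#'
#' @inheritParams detect_salt_bridges
#' @param cutoff Centroid-centroid cutoff in angstrom (default 7.2).
#' @export
detect_pi_pi <- function(model, cutoff = 7.2) {
  a <- .poly_atoms(model)
  rings <- .all_rings(a)
  if (is.null(rings)) return(.empty_records())
  n <- length(rings)
  best <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ri <- rings[[i]]; rj <- rings[[j]]
      if (ri$res == rj$res) next
      if (ri$chain == rj$chain && abs(ri$resno - rj$resno) == 1L) next
      d <- .vnorm(ri$centroid - rj$centroid)
      if (d > cutoff) next
      key <- paste(sort(c(ri$res, rj$res)), collapse = "~")
      if (is.null(best[[key]]) || d < best[[key]]$distance) {
        cosang <- abs(sum(ri$normal * rj$normal))
        best[[key]] <- list(a = ri, b = rj, distance = d,
                            angle = acos(pmin(1, cosang)) * 180 / pi)
      }
    }
  }
  if (length(best) == 0L) return(.empty_records())
  recs <- do.call(rbind, lapply(best, function(h) {
    first_a <- h$a$res <= h$b$res
    aa <- if (first_a) h$a else h$b
    bb <- if (first_a) h$b else h$a
    data.frame(kind = "pi_pi", res_a = aa$res, resname_a = aa$resname,
               res_b = bb$res, resname_b = bb$resname,
               atom_a = aa$label, atom_b = bb$label,
               distance = h$distance, angle = h$angle,
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs[order(recs$res_a, recs$res_b), , drop = FALSE]
}

#' Detect cation-pi interactions
#'
#' Geometric criterion: a side-chain cation point (Lys NZ or Arg CZ) within
#' `dist_cutoff` of an aromatic ring centroid, with the acute angle between
#' the ring normal and the centroid-to-cation vector at most `angle_cutoff`
#' (i.e. the cation sits over the ring face rather than in its plane).
#' His rings participate as aromatic partners only.  One record per
#' (cation residue, aromatic residue) pair at the minimum qualifying
#' distance.
#'
#' @inheritParams detect_salt_bridges
#' @param dist_cutoff Centroid-cation cutoff in angstrom (default 6.0).
#' @param angle_cutoff Maximum angle from the ring normal in degrees
#'   (default 60).
#' @export
detect_cation_pi <- function(model, dist_cutoff = 6.0, angle_cutoff = 60) {
  a <- .poly_atoms(model)
  rings <- .all_rings(a)
  cat_dict <- list(LYS = "NZ", ARG = "CZ")
  cats <- .dict_atoms(a, cat_dict)
  if (is.null(rings) || nrow(cats) == 0L) return(.empty_records())
  best <- list()
  for (ci in seq_len(nrow(cats))) {
    cxyz <- as.numeric(cats[ci, c("x", "y", "z")])
    for (r in rings) {
      if (r$res == cats$res[ci]) next
      v <- cxyz - r$centroid
      d <- .vnorm(v)
      if (d > dist_cutoff || d == 0) next
      ang <- acos(pmin(1, abs(sum(v / d * r$normal)))) * 180 / pi
      if (ang > angle_cutoff) next
      key <- paste(cats$res[ci], r$res)
      if (is.null(best[[key]]) || d < best[[key]]$distance) {
        best[[key]] <- list(cat = cats[ci, ], ring = r, distance = d,
                            angle = ang)
      }
    }
  }
  if (length(best) == 0L) return(.empty_records())
  recs <- do.call(rbind, lapply(best, function(h) {
    data.frame(kind = "cation_pi", res_a = h$cat$res,
               resname_a = h$cat$resname, res_b = h$ring$res,
               resname_b = h$ring$resname, atom_a = h$cat$name,
               atom_b = h$ring$label, distance = h$distance,
               angle = h$angle, stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  recs[order(recs$res_a, recs$res_b), , drop = FALSE]
}

#' Detect disulfide bridges
#'
#' Cys SG-SG pairs within the cutoff (default 2.5 angstrom), one record per
#' pair.
#'
#' @inheritParams detect_salt_bridges
#' @param cutoff Distance cutoff in angstrom (default 2.5).
#' @export
detect_disulfides <- function(model, cutoff = 2.5) {
  a <- .poly_atoms(model)
  sg <- a[a$resname == "CYS" & a$name == "SG", , drop = FALSE]
  if (nrow(sg) < 2L) return(.empty_records())
  d <- .cross_dist(as.matrix(sg[, c("x", "y", "z")]),
                   as.matrix(sg[, c("x", "y", "z")]))
  d[lower.tri(d, diag = TRUE)] <- Inf
  .pair_records("disulfide", sg, sg, d, cutoff, directed = FALSE)
}

#' Metal coordination report
#'
#' For each hetero atom of the requested element, lists all oxygen and
#' nitrogen atoms (protein backbone/side-chain and water) within the cutoff;
#' the coordination number is the length of that list.  Bidentate
#' carboxylates therefore contribute each coordinating oxygen separately.
#'
#' @param model A `structure_model` retaining hetero atoms and waters.
#' @param metal_element Element symbol of the metal (default `"CA"`,
#'   calcium).
#' @param cutoff Metal-ligand distance cutoff in angstrom (default 3.0).
#' @return A list of class `metal_report`, one element per metal site, each
#'   with `metal` (one-row data frame) and `ligands` (data frame of
#'   coordinating atoms with distances) and `n` (coordination number).
#'   Empty list when no metal of that element is present.
#' @export
metal_coordination <- function(model, metal_element = "CA", cutoff = 3.0) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  a$res <- .res_label(a$chain, a$resno, a$insert)
  metals <- a[a$hetero & a$element == toupper(metal_element), , drop = FALSE]
  sites <- list()
  if (nrow(metals) > 0L) {
    lig_pool <- a[a$element %in% c("O", "N"), , drop = FALSE]
    for (i in seq_len(nrow(metals))) {
      m <- metals[i, , drop = FALSE]
      d <- .cross_dist(as.matrix(m[, c("x", "y", "z")]),
                       as.matrix(lig_pool[, c("x", "y", "z")]))[1L, ]
      keep <- d <= cutoff
      lig <- lig_pool[keep, c("res", "resname", "name", "element"),
                      drop = FALSE]
      lig$distance <- d[keep]
      lig <- lig[order(lig$distance), , drop = FALSE]
      rownames(lig) <- NULL
      sites[[length(sites) + 1L]] <-
        list(metal = m[, c("res", "resname", "name", "element")],
             ligands = lig, n = nrow(lig))
    }
  }
  structure(sites, class = "metal_report")
}

#' @export
print.metal_report <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<metal_report> no metal sites\n")
    return(invisible(x))
  }
  for (s in x) {
    cat(sprintf("%s (%s) coordination number %d\n",
                s$metal$res, s$metal$resname, s$n))
    if (s$n > 0L) {
      cat(paste0("  ", s$ligands$resname, " ", s$ligands$res, " ",
                 s$ligands$name, "  ",
                 sprintf("%.2f", s$ligands$distance), " A",
                 collapse = "\n"), "\n")
    }
  }
  invisible(x)
}

#' Run all pairwise interaction detectors
#'
#' Convenience wrapper returning the combined record table of
#' [detect_salt_bridges()], [detect_hydrogen_bonds()], [detect_pi_pi()],
#' [detect_cation_pi()] and [detect_disulfides()] with configured cutoffs.
#'
#' @inheritParams detect_salt_bridges
#' @param config Cutoff configuration, see [feature_config()].
#' @export
detect_interactions <- function(model, config = feature_config()) {
  rbind(
    detect_salt_bridges(model, config$salt_bridge_cutoff),
    detect_hydrogen_bonds(model, config$hbond_cutoff, config$hbond_dictionary),
    detect_pi_pi(model, config$pi_pi_cutoff),
    detect_cation_pi(model, config$cation_pi_dist, config$cation_pi_angle),
    detect_disulfides(model, config$disulfide_cutoff)
  )
}

#' Write interaction records as TSV
#'
#' @param records Record data frame from a detector.
#' @param file Output path or connection.
#' @param structure_id Identifier written in the first column.
#' @return The augmented data frame, invisibly.
#' @export
write_interactions <- function(records, file, structure_id = "structure") {
  out <- cbind(structure_id = structure_id, records)
  names(out)[names(out) == "distance"] <- "distance_A"
  names(out)[names(out) == "angle"] <- "angle_deg"
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
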