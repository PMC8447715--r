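# Per-structure feature table and correlation of each feature with the
# temperature optimum, with and without an exclusion set.

#' Analysis configuration
#'
#' Bundles every cutoff and numerical parameter used when building a feature
#' table, so a whole analysis is reproducible from one object.
#'
#' @param salt_bridge_cutoff,hbond_cutoff,pi_pi_cutoff,disulfide_cutoff
#'   Distance cutoffs in angstrom.
#' @param cation_pi_dist,cation_pi_angle Cation-pi distance (angstrom) and
#'   maximum angle from the ring normal (degrees).
#' @param metal_cutoff Metal-ligand cutoff in angstrom.
#' @param probe Probe radius for SASA/volumes.
#' @param sasa_points Sphere-sample points per atom.
#' @param grid_spacing Volume grid spacing in angstrom.
#' @param radii Per-element van der Waals radius table.
#' @param hbond_dictionary Donor/acceptor dictionary, see
#'   [hbond_dictionary()].
#' @param compactness Logical; compute SASA/volume features in
#'   [build_feature_table()] (the slowest step; switch off for
#'   interaction-only tables).
#' @return Named list of class `feature_config`.
#' @export
feature_config <- function(salt_bridge_cutoff = 4.0, hbond_cutoff = 3.5,
                           pi_pi_cutoff = 7.2, cation_pi_dist = 6.0,
                           cation_pi_angle = 60, disulfide_cutoff = 2.5,
                           metal_cutoff = 3.0, probe = 1.4,
                           sasa_points = 960, grid_spacing = 0.5,
                           radii = default_vdw_radii(),
                           hbond_dictionary = thermogal::hbond_dictionary(),
                           compactness = TRUE) {
  structure(list(
    salt_bridge_cutoff = salt_bridge_cutoff, hbond_cutoff = hbond_cutoff,
    pi_pi_cutoff = pi_pi_cutoff, cation_pi_dist = cation_pi_dist,
    cation_pi_angle = cation_pi_angle, disulfide_cutoff = disulfide_cutoff,
    metal_cutoff = metal_cutoff, probe = probe, sasa_points = sasa_points,
    grid_spacing = grid_spacing, radii = radii,
    hbond_dictionary = hbond_dictionary, compactness = compactness
  ), class = "feature_config")
}

#' Default temperature optima for the structurally characterized GH53 set
#'
#' Activity temperature optima (degrees C) for the seven structures used in
#' the family-wide feature correlation, keyed by PDB ID: IaGal 7OSK (95,
#' reported as "at least 95"), BlGal 1R8L (40), BtGal 6GP5 (37, a nominal
#' value for a human gut organism with no measured optimum), AaGal 1FOB
#' (50), EnGal 4BF7 (49), HiGal 1HJQ (65), MtGal 1HJS (65).
#'
#' @return Named numeric vector of temperatures.
#' @export
gh53_temperature_optima <- function() {
  c(`7OSK` = 95, `1R8L` = 40, `6GP5` = 37, `1FOB` = 50,
    `4BF7` = 49, `1HJQ` = 65, `1HJS` = 65)
}

#' Build the per-structure feature table
#'
#' Runs every detector with the configured cutoffs on each model and
#' assembles one row per structure: interaction counts, helix-dipole
#' aggregates, Pro/Gly ratio, compactness metrics and the phenotype column
#' `t_opt`.  Helices come from HELIX records when present, otherwise from
#' dihedral assignment.
#'
#' @param models List of `structure_model` objects (each already reduced to
#'   the chain of interest, e.g. via [select_polymer()]).
#' @param phenotypes Named numeric vector mapping `structure_id` to
#'   temperature optimum in degrees C.
#' @param config A [feature_config()].
#' @return Data frame with one row per structure (rownames = structure ids),
#'   feature columns `salt_bridges`, `hbonds`, `pi_pi`, `cation_pi`,
#'   `disulfides`, `stabilized_helices`, `dipole_net`, `pro_gly_ratio`
#'   (plus `sasa`, `total_volume`, `packing_density`, `surface_to_volume`
#'   when `config$compactness`), and `t_opt`.
#' @export
build_feature_table <- function(models, phenotypes,
                                config = feature_config()) {
  if (length(models) == 0L) stop("empty model list")
  ids <- vapply(models, function(m) m$structure_id, character(1L))
  missing <- setdiff(ids, names(phenotypes))
  if (length(missing) > 0L) {
    stop(sprintf("no phenotype entry for structure(s): %s",
                 paste(missing, collapse = ", ")))
  }
  rows <- lapply(models, function(m) {
    helices <- tryCatch(assign_helices(m, "records"),
                        error = function(e) assign_helices(m, "dihedral"))
    dip <- score_helix_dipoles(m, helices)
    row <- data.frame(
      salt_bridges = nrow(detect_salt_bridges(m, config$salt_bridge_cutoff)),
      hbonds = nrow(detect_hydrogen_bonds(m, config$hbond_cutoff,
                                          config$hbond_dictionary)),
      pi_pi = nrow(detect_pi_pi(m, config$pi_pi_cutoff)),
      cation_pi = nrow(detect_cation_pi(m, config$cation_pi_dist,
                                        config$cation_pi_angle)),
      disulfides = nrow(detect_disulfides(m, config$disulfide_cutoff)),
      stabilized_helices = dip$totals$n_stabilized,
      dipole_net = dip$totals$net,
      pro_gly_ratio = pro_gly_ratio(m)
    )
    if (isTRUE(config$compactness)) {
      cm <- compactness_metrics(m, probe = config$probe,
                                n_points = config$sasa_points,
                                grid_spacing = config$grid_spacing,
                                radii = config$radii)
      row <- cbind(row, cm[, c("sasa", "total_volume", "packing_density",
                               "surface_to_volume")])
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out$t_opt <- unname(phenotypes[ids])
  out
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with the argument checks needed for
#' small structure sets: equal lengths, at least three pairs, finite values.
#' Zero variance in either variable yields `NA` with a warning rather than
#' an error.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in \[-1, 1\], or `NA` when undefined.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations for a correlation")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite and free of missing values")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance: correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = "pearson")
}

#' Correlate features with the temperature optimum
#'
#' For each feature column of the table, computes the Pearson correlation
#' with `t_opt` over all rows (`r_with`) and over the rows remaining after
#' removing the exclusion set (`r_without`).  The family analysis excludes
#' the structure whose optimum is only a nominal assignment.
#'
#' @param table Feature table from [build_feature_table()] (or any data
#'   frame with numeric feature columns plus `t_opt`, rownames = structure
#'   ids).
#' @param exclude Character vector of structure ids to drop for the
#'   `r_without` column.
#' @return Data frame with columns `feature`, `r_with`, `r_without`,
#'   `n_with`, `n_without`, sorted by decreasing |r_with|.
#' @export
correlate_features <- function(table, exclude = character()) {
  stopifnot(is.data.frame(table), "t_opt" %in% names(table))
  bad <- setdiff(exclude, rownames(table))
  if (length(bad) > 0L) {
    stop(sprintf("exclusion id(s) not in table: %s", paste(bad, collapse = ", ")))
  }
  keep <- !(rownames(table) %in% exclude)
  if (nrow(table) < 3L) stop("need at least 3 structures")
  if (sum(keep) < 3L) stop("exclusion leaves fewer than 3 structures")
  feats <- setdiff(names(table)[vapply(table, is.numeric, logical(1L))],
                   "t_opt")
  res <- lapply(feats, function(f) {
    rw <- tryCatch(suppressWarnings(pearson_r(table[[f]], table$t_opt)),
                   error = function(e) NA_real_)
    ro <- tryCatch(suppressWarnings(pearson_r(table[[f]][keep],
                                              table$t_opt[keep])),
                   error = function(e) NA_real_)
    data.frame(feature = f, r_with = rw, r_without = ro,
               n_with = nrow(table), n_without = sum(keep),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-abs(out$r_with)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
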