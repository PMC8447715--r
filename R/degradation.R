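# Galactan degradation-profile quantification: degree of hydrolysis from
# reducing-end measurements, estimation of oligosaccharides longer than
# galactopentaose by mass balance, endpoint molar ratios, and
# Michaelis-Menten kinetics.
#
# Concentration conventions: analyte and reducing-end concentrations in mM;
# substrate load in mg/ml.  The theoretical maximum of reducing ends assumes
# full degradation to galactose and uses the anhydrogalactose polymer-residue
# mass (162.14 g/mol) by default, configurable via `unit_mass`.

.anhydro_mass <- 162.14

#' Construct a digest sample
#'
#' @param sample_id,enzyme_id Identifiers.
#' @param substrate_load Substrate load in mg/ml (> 0).
#' @param analytes Named numeric vector of quantified oligosaccharide
#'   concentrations in mM; names among G1..G5 (missing species count as 0).
#' @param reducing_ends Reducing-end concentration in mM.
#' @return One-row data frame with columns `sample_id`, `enzyme_id`,
#'   `substrate_load`, `G1`..`G5`, `reducing_ends`.
#' @export
digest_sample <- function(sample_id, enzyme_id, substrate_load, analytes,
                          reducing_ends) {
  stopifnot(substrate_load > 0, reducing_ends >= 0, all(analytes >= 0))
  species <- paste0("G", 1:5)
  g <- setNames(numeric(5L), species)
  g[intersect(names(analytes), species)] <-
    analytes[intersect(names(analytes), species)]
  out <- data.frame(sample_id = sample_id, enzyme_id = enzyme_id,
                    substrate_load = substrate_load, t(g),
                    reducing_ends = reducing_ends,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Theoretical maximum reducing-end concentration
#'
#' The reducing-end concentration reached at full degradation to galactose:
#' substrate load divided by the monomer unit mass.  The default unit mass
#' is the anhydrogalactose polymer residue (162.14 g/mol), i.e. the mass per
#' monomer actually present in the polysaccharide.
#'
#' @param substrate_load Substrate load in mg/ml (> 0).
#' @param unit_mass Monomer unit mass in g/mol.
#' @return Concentration in mM.
#' @examples
#' theoretical_max_reducing_ends(2.0)  # 12.335 mM
#' @export
theoretical_max_reducing_ends <- function(substrate_load,
                                          unit_mass = .anhydro_mass) {
  if (any(substrate_load <= 0)) stop("substrate_load must be positive")
  substrate_load / unit_mass * 1000
}

#' Degree of hydrolysis
#'
#' Reducing ends divided by the theoretical maximum amount of reducing ends
#' (full degradation to galactose), in percent.  Measurements up to 5% above
#' the theoretical maximum are tolerated as assay slack and clipped to 100%
#' with a warning; larger excesses are an assay inconsistency and raise an
#' error.
#'
#' @param sample A digest sample (see [digest_sample()]) or data frame of
#'   samples with columns `substrate_load` and `reducing_ends`.
#' @param unit_mass Monomer unit mass in g/mol.
#' @return Numeric vector of DoH percentages in \[0, 100\].
#' @export
compute_doh <- function(sample, unit_mass = .anhydro_mass) {
  tmax <- theoretical_max_reducing_ends(sample$substrate_load, unit_mass)
  re <- sample$reducing_ends
  if (any(re > 1.05 * tmax)) {
    stop("reducing ends exceed the theoretical maximum by more than 5%: assay inconsistency")
  }
  if (any(re > tmax)) {
    warning("reducing ends slightly above the theoretical maximum; clipping DoH to 100%")
  }
  pmin(100, pmax(0, 100 * re / tmax))
}

#' Estimate oligosaccharides larger than G5
#'
#' Mass-balance estimate: every chain contributes one reducing end, and
#' HPAEC-PAD quantifies G1..G5 individually, so reducing ends minus the
#' summed G1..G5 concentrations estimates the chain-molar concentration of
#' oligosaccharides longer than five units.  Small negative balances
#' (quantification noise) are clipped to zero with a warning.
#'
#' @inheritParams compute_doh
#' @return G>5 estimate in mM (chain-molar, i.e. reducing-end equivalents).
#' @export
estimate_g_gt5 <- function(sample) {
  species <- paste0("G", 1:5)
  est <- sample$reducing_ends - rowSums(sample[, species, drop = FALSE])
  if (any(est < 0)) {
    warning("summed G1..G5 exceed reducing ends; clipping G>5 estimate to 0")
  }
  pmax(0, est)
}

#' Per-sample degradation profile
#'
#' Convenience wrapper adding `doh_percent` and `g_gt5_mM` columns to a
#' table of digest samples.
#'
#' @inheritParams compute_doh
#' @export
degradation_profile <- function(sample, unit_mass = .anhydro_mass) {
  sample$doh_percent <- compute_doh(sample, unit_mass)
  sample$g_gt5_mM <- estimate_g_gt5(sample)
  sample
}

#' Endpoint molar ratio of degradation products
#'
#' Reduces the final-sample concentrations of the requested species to a
#' small-integer ratio (e.g. "3:2:6"): candidate integer vectors are
#' generated by scaling the concentrations so the smallest maps to each
#' denominator 1..`max_denominator`, rounding, and dividing by the greatest
#' common divisor; the candidate minimizing the maximum relative error wins,
#' ties going to the smallest integer sum.
#'
#' Candidates whose maximum relative error falls below `tolerance` (default
#' 3%, about the precision of chromatographic quantification) are treated as
#' equivalent, so that measurement noise selects the simplest ratio rather
#' than a large-integer overfit.
#'
#' @param samples Data frame of time-ordered digest samples (last row =
#'   endpoint).
#' @param species Character vector of species columns, subset of G1..G5.
#' @param max_denominator Largest scaling denominator searched (default 10).
#' @param tolerance Relative error below which candidates tie (default
#'   0.03).
#' @return Ratio string "a:b:c" with attributes `integers` and
#'   `relative_error`.
#' @export
endpoint_ratio <- function(samples, species = c("G1", "G2", "G3"),
                           max_denominator = 10L, tolerance = 0.03) {
  stopifnot(all(species %in% names(samples)), nrow(samples) >= 1L)
  conc <- as.numeric(samples[nrow(samples), species])
  if (sum(conc > 0) < 2L) {
    stop("endpoint ratio needs at least two nonzero species")
  }
  if (any(conc <= 0)) stop("all requested species must be nonzero at the endpoint")
  rel <- conc / min(conc)
  gcd2 <- function(a, b) if (b == 0L) a else gcd2(b, a %% b)
  cand <- list()
  for (q in seq_len(max_denominator)) {
    ints <- as.integer(round(rel * q))
    if (any(ints == 0L)) next
    g <- Reduce(gcd2, ints)
    ints <- ints %/% g
    scale_fit <- sum(ints * conc) / sum(ints^2)  # least-squares unit size
    err <- max(abs(ints * scale_fit - conc) / conc)
    cand[[length(cand) + 1L]] <- list(ints = ints, err = err)
  }
  errs <- vapply(cand, `[[`, numeric(1L), "err")
  tied <- errs <= max(min(errs), tolerance)
  sums <- vapply(cand, function(c) sum(c$ints), numeric(1L))
  pick <- which(tied)[order(sums[tied], errs[tied])][1L]
  best <- cand[[pick]]
  structure(paste(best$ints, collapse = ":"),
            integers = best$ints, relative_error = best$err)
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least-squares fit of v = Vmax * s / (Km + s) (via
#' \pkg{minpack.lm}), with kcat derived from the molar enzyme concentration
#' (load / molecular weight) and 95% confidence intervals from the
#' linearized covariance with t-quantiles on n - 2 degrees of freedom.
#' Profile-likelihood intervals are available with
#' `ci_method = "profile"`.
#'
#' @param s Substrate concentrations in mg/ml (>= 5 levels spanning the Km).
#' @param v Initial rates in molar units per second (M/s), same length.
#' @param enzyme_conc Enzyme load in mg/ml.
#' @param enzyme_mw Enzyme molecular weight in g/mol.
#' @param conf_level Confidence level (default 0.95).
#' @param ci_method `"linearized"` (default) or `"profile"`.
#' @return Object of class `mm_fit`: list with `km` (mg/ml), `kcat` (1/s),
#'   `efficiency` (ml mg^-1 s^-1 = kcat/Km), `vmax` (M/s), `ci95` (matrix
#'   with rows km/kcat/efficiency), and the underlying `fit`.
#' @export
fit_michaelis_menten <- function(s, v, enzyme_conc, enzyme_mw,
                                 conf_level = 0.95,
                                 ci_method = c("linearized", "profile")) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(s) == length(v), enzyme_conc > 0, enzyme_mw > 0)
  if (length(unique(s[s > 0])) < 5L) {
    stop("need at least 5 distinct positive substrate levels")
  }
  if (any(v[s > 0] <= 0)) stop("rates must be positive at positive substrate")
  dat <- data.frame(s = s, v = v)
  start <- list(vmax = max(v) * 1.2, km = median(s[s > 0]))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "Michaelis-Menten fit failed, parameters not identifiable: %s",
      conditionMessage(e))))
  est <- coef(fit)
  vmax <- est[["vmax"]]
  km <- est[["km"]]
  if (!is.finite(km) || !is.finite(vmax) || km <= 0 || vmax <= 0) {
    stop("non-positive parameter estimate: kinetics not identifiable from these data")
  }
  se <- sqrt(diag(vcov(fit)))
  if (!all(is.finite(se)) || km < 1e-8 * max(s) ||
      se[["km"]] / km > 10) {
    stop("Km not identifiable (rates do not resolve the saturation curve)")
  }
  e_molar <- enzyme_conc / enzyme_mw          # g/L over g/mol -> mol/L
  kcat <- vmax / e_molar
  efficiency <- kcat / km
  n <- length(v)
  tq <- qt(1 - (1 - conf_level) / 2, df = n - 2L)
  if (ci_method == "linearized") {
    ci_vmax <- vmax + c(-1, 1) * tq * se[["vmax"]]
    ci_km <- km + c(-1, 1) * tq * se[["km"]]
  } else {
    pr <- suppressMessages(stats::confint(fit, level = conf_level))
    ci_vmax <- pr["vmax", ]
    ci_km <- pr["km", ]
  }
  # delta-method CI for the efficiency ratio kcat/Km
  V <- vcov(fit)
  grad <- c(1 / (e_molar * km), -vmax / (e_molar * km^2))
  se_eff <- sqrt(drop(t(grad) %*% V %*% grad))
  ci <- rbind(km = ci_km,
              kcat = ci_vmax / e_molar,
              efficiency = efficiency + c(-1, 1) * tq * se_eff)
  colnames(ci) <- c("lower", "upper")
  structure(list(km = km, kcat = kcat, efficiency = efficiency,
                 vmax = vmax, ci95 = ci, conf_level = conf_level,
                 fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> Km %.3g mg/ml [%.3g, %.3g], kcat %.3g 1/s [%.3g, %.3g], kcat/Km %.3g ml mg^-1 s^-1\n",
    x$km, x$ci95["km", 1L], x$ci95["km", 2L],
    x$kcat, x$ci95["kcat", 1L], x$ci95["kcat", 2L], x$efficiency))
  invisible(x)
}
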