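# Synthetic trajectories with known per-residue fluctuation, and synthetic
# Michaelis-Menten rate tables with controlled noise.

#' Generate a synthetic trajectory
#'
#' Builds an ideal alpha-helical backbone (N, CA, C, O, CB per residue) and
#' emits `n_frames` frames: the first frame is the ideal reference; every
#' later frame adds independent isotropic Gaussian jitter of standard
#' deviation `jitter_sigma` per coordinate axis, so the expected RMSF of
#' every atom is `jitter_sigma * sqrt(3)`.  An optional two-state side-chain
#' flip displaces one residue's CB by a fixed vector from `switch_frame`
#' onward, emulating a subsite tryptophan conformational flip.
#'
#' @param n_res Number of residues.
#' @param n_frames Number of frames (>= 2).
#' @param jitter_sigma Per-axis jitter standard deviation in angstrom.
#' @param flip Optional list `list(resno =, displacement =, switch_frame =)`.
#' @param seed Integer seed.
#' @return A [trajectory()].
#' @export
generate_trajectory <- function(n_res = 30L, n_frames = 100L,
                                jitter_sigma = 0.5, flip = NULL,
                                seed = 1L) {
  stopifnot(n_frames >= 2L, n_res >= 3L, jitter_sigma >= 0)
  set.seed(seed)
  base_model <- build_peptide(n_res)
  at <- base_model$atoms[, c("resno", "resname", "name", "element")]
  base <- as.matrix(base_model$atoms[, c("x", "y", "z")])
  n_atoms <- nrow(base)
  co <- array(0, dim = c(n_frames, n_atoms, 3L))
  co[1L, , ] <- base
  if (n_frames > 1L) {
    noise <- array(rnorm((n_frames - 1L) * n_atoms * 3L, sd = jitter_sigma),
                   dim = c(n_frames - 1L, n_atoms, 3L))
    for (ax in 1:3) {
      co[2:n_frames, , ax] <- matrix(base[, ax], nrow = n_frames - 1L,
                                     ncol = n_atoms, byrow = TRUE) +
        noise[, , ax]
    }
  }
  if (!is.null(flip)) {
    stopifnot(all(c("resno", "displacement", "switch_frame") %in% names(flip)))
    idx <- which(at$resno == flip$resno & at$name == "CB")
    if (length(idx) != 1L) stop("flip residue has no CB atom")
    dvec <- c(0, 0, flip$displacement)
    frames <- seq.int(max(2L, flip$switch_frame), n_frames)
    for (ax in 1:3) {
      co[frames, idx, ax] <- co[frames, idx, ax] + dvec[ax]
    }
  }
  trajectory(co, at)
}

#' Generate a synthetic Michaelis-Menten rate table
#'
#' v = Vmax s / (Km + s) with multiplicative Gaussian noise
#' (coefficient of variation `noise_cv`), Vmax = kcat times the molar
#' enzyme concentration (load / molecular weight).  Default parameters are
#' in the range measured for a hyperthermostable galactanase on lupin
#' galactan (Km 0.47 mg/ml, kcat 34.3 1/s).
#'
#' @param km Michaelis constant in mg/ml.
#' @param kcat Turnover number in 1/s.
#' @param enzyme_conc Enzyme load in mg/ml.
#' @param enzyme_mw Enzyme molecular weight in g/mol.
#' @param s_levels Substrate concentrations in mg/ml (should span Km).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @return Data frame with columns `s` (mg/ml) and `v` (M/s); the true
#'   parameters are attached as attribute `truth`.
#' @export
generate_kinetics <- function(km = 0.47, kcat = 34.3, enzyme_conc = 1e-3,
                              enzyme_mw = 45000,
                              s_levels = c(0.05, 0.1, 0.2, 0.4, 0.8,
                                           1.2, 1.75),
                              noise_cv = 0.05, seed = 1L) {
  stopifnot(km > 0, kcat > 0, enzyme_conc > 0, enzyme_mw > 0,
            noise_cv >= 0, length(s_levels) >= 1L, all(s_levels > 0))
  set.seed(seed)
  e_molar <- enzyme_conc / enzyme_mw
  vmax <- kcat * e_molar
  v <- vmax * s_levels / (km + s_levels)
  if (noise_cv > 0) {
    v <- v * (1 + rnorm(length(v), sd = noise_cv))
  }
  out <- data.frame(s = s_levels, v = v)
  attr(out, "truth") <- list(km = km, kcat = kcat, vmax = vmax,
                             enzyme_conc = enzyme_conc,
                             enzyme_mw = enzyme_mw)
  out
}
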