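Package: thermogal
Title: Thermostability Feature Profiling and Degradation Analysis for
    GH53 Galactanases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural thermostability-feature profiling for glycoside
    hydrolase family 53 (GH53) endo-beta-1,4-galactanases and related
    enzymes: detection of salt bridges, hydrogen bonds, pi-pi, cation-pi,
    disulfide and metal-coordination interactions from PDB coordinates;
    helix-dipole stabilization scoring and residue-composition metrics;
    solvent-accessible surface area, van der Waals and envelope volumes
    and packing density; correlation of per-structure features with
    temperature optima. Also quantifies galactan degradation profiles
    (degree of hydrolysis, estimation of oligosaccharides longer than
    galactopentaose from reducing-end mass balance, endpoint molar
    ratios, Michaelis-Menten kinetics), computes per-residue RMSF from
    coordinate trajectories after Kabsch superposition, and provides a
    stochastic subsite-model endo-hydrolysis simulator plus synthetic
    generators for planted-interaction structures, trajectories and
    kinetics data so that every analysis stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
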