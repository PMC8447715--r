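# thermogal

Thermostability-feature profiling and degradation-profile analysis for
GH53 endo-β-1,4-galactanases (and protein structures generally), in R.

Family GH53 spans mesophilic fungal and bacterial galactanases up to a
hyperthermophilic archaeal enzyme with a temperature activity optimum near
95 °C. Two questions drive the analyses this package implements, for
structural biologists and enzyme engineers working on thermal adaptation
and product-profile engineering:

1. **Which structural features track thermophilicity across the family?**
   For each structure the package counts salt bridges (min N–O ≤ 4.0 Å over
   Arg/Lys/His vs Glu/Asp side chains), hydrogen bonds (heavy-atom
   donor–acceptor dictionary, ≤ 3.5 Å), π–π stacks (aromatic ring-centroid
   distance ≤ 7.2 Å, Trp contributing both rings), cation–π contacts
   (Lys NZ / Arg CZ within 6.0 Å of a ring centroid and ≤ 60° off the ring
   normal), disulfides and metal coordination; scores helix-dipole
   stabilization (charged residues in the first/last three helix
   residues); and computes Pro/Gly ratio, Shrake–Rupley SASA, grid-based
   van der Waals and solvent-excluded volumes, packing density
   *P = V_vdW / V_env* and surface-to-volume ratio. Each feature *x* is
   then correlated with the temperature optimum *T_opt* by Pearson's

   *r = Σ(xᵢ−x̄)(Tᵢ−T̄) / √(Σ(xᵢ−x̄)² Σ(Tᵢ−T̄)²)*,

   reported with and without an exclusion set (one family member's optimum
   is a nominal assignment, not a measurement).

2. **How does subsite architecture shape the degradation profile?** From
   reducing-end (*RE*) and oligosaccharide measurements the package
   computes the degree of hydrolysis *DoH = RE / (load/162.14 g mol⁻¹)*,
   the mass-balance estimate *G>5 = RE − Σ(G1..G5)* of oligosaccharides
   longer than galactopentaose, endpoint molar ratios, and
   Michaelis–Menten fits *v = V_max s/(K_m+s)* with *k_cat = V_max/[E]*
   and 95% confidence intervals. A Gillespie simulator models endo-
   hydrolysis over a chain population with bond rate weights
   *w(k, L) = min(k, n₋)·min(L−k, n₊)* and an enzyme-specific inert length
   (the longest chain bound only non-productively), reproducing the
   characteristic product floors of fungal-like (inert 2) versus
   archaeal/bacterial-like (inert 3) enzymes. Per-residue RMSF after
   Kabsch superposition onto the first trajectory frame covers the
   simulation arm.

Seeded generators (planted-interaction structures with exact ground truth,
digests, trajectories, kinetics tables) make every stage testable offline.

## Worked example

Plant interactions at exact distances, detect them, and run a simulated
digest:

```r
library(thermogal)

sp <- plant_spec(
  planted = data.frame(kind = c("salt_bridge", "pi_pi", "pi_pi", "cation_pi"),
                       distance = c(3.8, 5.6, 6.9, 4.2),
                       angle = c(0, 0, 0, 25)),
  decoys = data.frame(kind = "pi_pi", distance = 7.6),
  metal_sites = data.frame(n_inner = 7L, inner_distance = 2.4,
                           n_outer = 2L, outer_distance = 3.4),
  seed = 42)
g <- generate_planted_structure(sp)
detect_pi_pi(select_polymer(g$model))
#>    kind res_a resname_a res_b resname_b atom_a atom_b distance angle
#> 1 pi_pi  A:21       PHE  A:25       HIS   PHE6   HIS5      5.6     0
#> 2 pi_pi  A:31       TYR  A:35       TYR   TYR6   TYR6      6.9     0
metal_coordination(g$model)[[1]]$n
#> [1] 7
```

Both planted stacks are recovered at their exact centroid distances, the
7.6 Å decoy is rejected, and the calcium site reports its seven inner-shell
waters (the ninth and tenth, planted at 3.4 Å, fall outside the 3.0 Å
coordination cutoff).

```r
ds <- simulate_endo_hydrolysis(digest_spec(n_chains = 120, lengths = 15,
                                           archetype = "iagal_like",
                                           times = c(0.05, 0.3, 2, Inf), seed = 42))
degradation_profile(ds$samples)
#>   sample_id   G1   G2   G3   G4   G5 reducing_ends doh_percent g_gt5_mM
#> 1       t01 0.32 0.50 0.54 0.47 0.33          2.86       23.22     0.71
#> 2       t02 1.32 2.23 1.86 0.20 0.03          5.65       45.78     0.00
#> 3       t03 1.42 2.51 1.97 0.00 0.00          5.89       47.78     0.00
#> 4       t04 1.42 2.51 1.97 0.00 0.00          5.89       47.78     0.00
```

Early in the digest most material is still longer than G5 (0.71 mM of
chains); at the endpoint only G1–G3 remain — an inert-length-3 enzyme
cannot cleave galactotriose, so DoH plateaus at 48% rather than 100%.

```r
k <- generate_kinetics(km = 0.47, kcat = 34.3, noise_cv = 0.05, seed = 42)
fit_michaelis_menten(k$s, k$v, enzyme_conc = 1e-3, enzyme_mw = 45000)
#> <mm_fit> Km 0.512 mg/ml [0.395, 0.63], kcat 36.5 1/s [33.3, 39.7],
#>          kcat/Km 71.2 ml mg^-1 s^-1
```

The 95% intervals bracket the generating parameters (Km 0.47 mg/ml,
kcat 34.3 s⁻¹).

To analyse real structures, read them with `parse_structure()` /
`select_polymer()` and feed them to `build_feature_table()` +
`correlate_features()` with `gh53_temperature_optima()` as phenotypes.

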