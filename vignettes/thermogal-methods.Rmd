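---
title: "Methods: thermostability features and degradation profiles in thermogal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermostability features and degradation profiles in thermogal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogal)
```

## Scope and scientific setting

Family GH53 endo-β-1,4-galactanases hydrolyse the galactan side chains of
pectic rhamnogalacturonan I.  The family spans mesophilic fungal and
bacterial enzymes up to a hyperthermophilic archaeal member with an activity
optimum near 95&nbsp;°C, which makes it a natural system for asking *which
structural features track thermal adaptation*, and — because members differ
in the number of negative substrate-binding subsites — *how the subsite
architecture shapes the oligosaccharide product profile*.

`thermogal` implements both analysis arms as reusable, testable components:

1. **Structure side** — geometric detection of stabilizing interactions from
   PDB coordinates, helix-dipole scoring, compactness metrics, and Pearson
   correlation of each per-structure feature with the temperature optimum.
2. **Biochemistry side** — quantification of galactan digests (degree of
   hydrolysis, mass-balance estimation of long oligosaccharides, endpoint
   molar ratios, Michaelis–Menten kinetics), per-residue RMSF from
   trajectories, and a stochastic subsite-model hydrolysis simulator.

Every stage has a synthetic-data generator so the whole pipeline is testable
without downloading structures or instrument data.

## Interaction detectors

All detectors are heavy-atom and distance-based: crystal structures at
typical resolution carry no hydrogens, so donor–hydrogen geometry is not
available and distance criteria are the reproducible choice.  Records are
deduplicated to one per residue pair per interaction kind, carrying the
minimum qualifying distance, and are invariant under rigid motion of the
structure.

| kind | criterion | default cutoff |
|---|---|---|
| salt bridge | min N–O distance, Arg NH1/NH2/NE, Lys NZ, His ND1/NE2 vs Glu OE1/OE2, Asp OD1/OD2 | 4.0 Å |
| hydrogen bond | heavy-atom donor–acceptor dictionary | 3.5 Å |
| π–π | aromatic ring-centroid to ring-centroid | 7.2 Å |
| cation–π | Lys NZ / Arg CZ to ring centroid, ≤ 60° off the ring normal | 6.0 Å |
| disulfide | Cys SG–SG | 2.5 Å |
| metal coordination | metal to any O/N (protein or water) | 3.0 Å |

Design notes, in decreasing order of consequence:

* **Hydrogen bonds.** The donor/acceptor dictionary
  (`hbond_dictionary()`) is an explicit, configurable stand-in for
  external H-bond assignment programs: backbone N donates, backbone O
  accepts, side chains follow standard chemistry (Ser/Thr/Tyr hydroxyls are
  listed both ways).  Backbone–backbone pairs closer than two positions in
  sequence are excluded (they are covalent-geometry artifacts), as are
  intra-residue pairs.
* **π–π.** Trp contributes its five- and six-membered rings separately;
  His counts as aromatic.  A residue pair is reported once even if several
  ring pairs qualify.  Manual, visual pruning of spurious stacks — common in
  published interaction counts — is *not* reproducible and is replaced by
  two deterministic rules: one record per residue pair, and exclusion of
  sequence-adjacent aromatic pairs, whose rings are constrained by covalent
  geometry rather than attraction.
* **Cation–π.** Energy-based tools exist for this interaction class; the
  package instead applies a documented geometric criterion (distance ≤ 6 Å
  *and* ≤ 60° off the ring normal, so the cation must sit over the ring
  face).  Both thresholds are arguments.  His is aromatic only — its
  protonation state is unknown from coordinates, so it is never treated as
  the cation.
* **Metal coordination.** Each oxygen counts separately, so a bidentate
  carboxylate contributes two — required for the characteristic 7-fold
  calcium coordination seen when a glutamate chelates with both Oε atoms.
* Occupancies and B-factors are ignored throughout; alternate locations are
  resolved at parse time (highest occupancy, ties to altloc "A").

## Helix dipoles and composition

The α-helix macrodipole places a partial positive charge at the N-terminus
and a partial negative charge at the C-terminus.  `score_helix_dipoles()`
inspects the first three and last three helix residues: positives
(Lys/Arg/His) stabilize at the C-terminus and destabilize at the N-terminus,
negatives (Glu/Asp) the reverse.  A helix is *stabilized* when stabilizing
counts exceed destabilizing ones.  Both per-structure aggregates — the
number of net-stabilized helices and the summed net count — are exposed,
because family-level analyses have used either convention.  His is counted
positive, consistent with the salt-bridge basic set.

Helices come from HELIX records when the file has them; otherwise
`assign_helices(..., "dihedral")` takes maximal runs of ≥ 4 residues with
φ ∈ [−100°, −30°] and ψ ∈ [−80°, −5°].  Chain-terminal residues, which have
only one defined dihedral, join a run when that dihedral qualifies.  3₁₀
helices are not classified separately.

`pro_gly_ratio()` is the classic rigidity indicator count(Pro)/count(Gly);
it is undefined (flagged `NA`) without glycines.

## Compactness numerics

`compute_sasa()` is Shrake–Rupley with a deterministic golden-section
spiral (default 960 points per atom, probe 1.4 Å, Bondi radii) — no RNG, so
SASA is exactly reproducible.  Sample points are weighted by a soft
indicator one sample-spacing wide around the buried/exposed boundary; this
suppresses the orientation-dependent quantization of buried arcs, making
SASA rigid-motion stable to better than 0.05%.

`compute_volumes()` integrates on a grid (default 0.5 Å).  It first
evaluates the signed clearance field $M(p) = \min_i(\lVert p - x_i\rVert -
r_i)$.  The van der Waals volume counts cells with $M \le 0$, refining
boundary cells on a 3×3×3 subgrid with a soft indicator; the measured error
against analytic single-sphere and two-sphere-lens volumes is below 0.2% at
the default spacing.  The envelope (solvent-excluded) volume erodes the
probe-inflated union by the probe: a boundary cell is solvent-side when a
probe center at distance 1.4 Å from it clears every inflated atom sphere.
Because $M$ is 1-Lipschitz its maximum over the probe ball lies on the ball
surface, so the test samples 240 spherical directions and evaluates $M$
analytically there — avoiding the O(h) bias of lattice-ball morphology.
Halving the grid spacing moves both volumes by well under 1% on peptide
fixtures, and all metrics are rigid-motion invariant to better than 0.5%.

Packing density is vdW/envelope volume; surface-to-volume is
SASA/envelope volume.  The probe-series convergence protocol used by some
published volume tools is replaced by this fixed-grid scheme; only
relative/property validation is possible for these quantities since
reference values for the family are not published per structure.

## Feature table and correlation

`build_feature_table()` runs every detector at configured cutoffs
(`feature_config()`) and produces one row per structure with the phenotype
column `t_opt`.  The bundled optima (`gh53_temperature_optima()`) are 95,
40, 37, 50, 49, 65, 65&nbsp;°C for the archaeal, *B. licheniformis*,
*B. thetaiotaomicron*, two *Aspergillus*, *H. insolens* and
*T. thermophila* enzymes (by PDB ID).  The 37&nbsp;°C entry is a nominal
assignment from the organism's gut niche, not a measurement, which is why
`correlate_features()` reports every coefficient both with and without an
exclusion set.  Coefficients are raw Pearson r (via `stats::cor`), with no
p-values or multiple-testing correction: with n = 6–7 structures the
coefficients are descriptive, not inferential.  `pearson_r()` flags
zero-variance inputs as undefined rather than erroring, so constant feature
columns survive a table-wide sweep.

## Degradation profiles

Concentration conventions: analytes (G1..G5) and reducing ends in mM,
substrate load in mg/ml.

* **Theoretical maximum of reducing ends** = load / 162.14 g mol⁻¹ × 1000.
  162.14 is the anhydrogalactose *polymer residue* mass — the mass per
  monomer actually present in the chain.  Using free galactose (180.16)
  would overcount the water of hydrolysis; the choice is configurable
  (`unit_mass`) since reducing-end assays are calibrated against free
  sugar standards and either convention appears in practice.
* **DoH** = reducing ends / theoretical maximum × 100, clipped to
  [0, 100] with 5% assay slack; beyond that the sample is internally
  inconsistent and rejected.
* **G>5** = reducing ends − Σ(G1..G5): every chain carries one reducing
  end, chromatography quantifies the five smallest species, so the balance
  counts chains longer than five units.  The estimate is reported
  chain-molar (reducing-end equivalents); multiplying by a mean length
  would require information the assay does not provide.  Negative balances
  (quantification noise) clip to zero with a warning.
* **Endpoint ratios** reduce final concentrations to small integers by
  scanning scaling denominators 1..10 and dividing by the gcd; candidates
  within 3% relative error (about chromatographic precision) are treated as
  tied and the smallest integer sum wins, so noise selects "3:2:6" rather
  than a large-integer overfit.
* **Kinetics.** `fit_michaelis_menten()` fits v = Vmax·s/(Km+s) by
  Levenberg–Marquardt least squares (`minpack.lm::nlsLM`, which also
  handles the zero-residual case exactly), converts Vmax to kcat through
  the molar enzyme concentration (load/MW), and reports 95% confidence
  intervals from the linearized covariance with t-quantiles on n − 2
  degrees of freedom; profile-likelihood intervals are available via
  `ci_method = "profile"`, and the efficiency interval uses the delta
  method.  Data in the zero-order regime only (flat rates) are rejected as
  unidentifiable.  At 5% multiplicative noise over 100 seeded replicates
  the Km interval covers the truth in well over 90 runs.  kcat recovery is
  validated on synthetic data only: converting published kcat values
  requires exact construct masses that are not generally available.

## The subsite hydrolysis simulator

`simulate_endo_hydrolysis()` is an exact Gillespie simulation over
glycosidic bonds.  A chain of length L has cleavable bonds k = 1..L−1 only
when L exceeds the enzyme's *inert length* — the longest oligosaccharide it
can only bind non-productively.  The bond rate weight is

  w(k, L) = min(k, n₋) · min(L−k, n₊),

a minimal subsite-occupancy model: the rate grows with how many of the n₋
negative and n₊ positive subsites the flanking chain segments can fill and
saturates beyond them.  No rate law for this family is published; any law
monotone in subsite occupancy preserves the invariants the package tests
(monomer conservation, monotone chain count and DoH, archetype endpoints).

Archetype presets encode the observed product floors as interpretive model
choices: `fungal` (n₋ 2, n₊ 2, inert 2 — degrades galactotriose, floor at
galactose/galactobiose), `iagal_like` (3, 2, 3 — binds galactotriose
non-productively across −1..−3), `blgal_like` (4, 2, 3 — an extra −4
subsite, but still able to degrade galactotetraose and not galactotriose).
A configurable −5-subsite blocking term (suggested by a lysine occluding
that position in some structures) was considered and left out: it changes
only transient length preferences, not any tested invariant, and its
magnitude would be pure conjecture.  Trans-glycosylation (the β-1,3-linked
disaccharide by-product of some members) is out of scope.

Census snapshots are rendered as digest samples by the monomer-to-mM scale
implied by the substrate load, so DoH, G>5 and endpoint ratios computed
from simulated samples are exactly consistent with the generator's ground
truth — this closes the loop that makes the degradation arithmetic testable.

## Trajectories and RMSF

`compute_rmsf()` aligns every frame onto the **first frame** with the
Kabsch closed-form fit (proper rotation enforced, degenerate point sets
rejected) on Cα atoms by default, then reports per-atom root-mean-square
deviation from the first-frame positions, aggregated per residue.  Using
frame 1 rather than the mean structure as reference is a deliberate match
to how simulation analyses in this family report RMSF; it is the less
common convention, and profiles computed either way differ slightly.  The
default profile selection is all heavy atoms, because the scientifically
interesting signal here — subsite tryptophan side-chain flips — lives in
side chains; `"calpha"` and `"sidechain"` selections are flags.

`generate_trajectory()` emits an ideal α-helical backbone (frame 1,
unjittered — it *is* the reference) plus per-coordinate Gaussian jitter of
σ per axis in later frames, so the expected per-atom RMSF is σ√3 — the
closed form used in tests (0.866 Å at σ = 0.5, matched within 3% over 5000
frames).  An optional two-state flip displaces one residue's CB from a
switch frame onward, emulating a side-chain conformational transition; a
half-run flip of amplitude d gives RMSF ≈ √(d²/2 + 3σ²) on that atom.

## The planted-structure generator

`generate_planted_structure()` places idealized residue templates on a
25 Å lattice, one interaction per site, each site randomly rotated
(seeded), so each planted interaction is realized at *exactly* its target
distance and nothing else approaches any cutoff — sites are ≥ 17 Å apart
and each template extends away from its interaction anchor.  Decoys use the
same geometry at least 0.2 Å outside their cutoff.  Two constraints keep
the ground truth single-kind, and are enforced by `plant_spec()`:

* planted distances respect kind-specific floors (e.g. salt bridges are
  planted above 3.55 Å, because a closer N–O pair would legitimately also
  be a hydrogen bond under the dictionary);
* cation–π plants pair Lys with Phe only, whose all-carbon ring offers no
  shorter hydrogen-bond or ring-nitrogen contact to the cation (Trp's
  second ring and Tyr's hydroxyl would).

These are constraints on the *test fixtures*, not on the detectors, which
handle all residue types; the brute-force oracle comparison in the test
suite runs over all kinds and all aromatic types.

What the generator does **not** emulate about real structures: missing
side-chain atoms, alternate conformations interacting across sites, crystal
contacts, solvent networks, or realistic packing density.  Detector
agreement with the oracle on planted fixtures therefore demonstrates the
geometry and bookkeeping are right, not that any particular published count
is reproduced — published counts additionally depend on manual pruning
choices that are explicitly not reproduced here.

## Problem sizes and numerical defaults

The shipped tests use: 100 fuzzed planted structures (≤ 500 atoms each) for
the detector/oracle equivalence; 10–50-residue peptides for compactness
checks; 100-seed replication for CI calibration; 5000-frame, 100-residue
trajectories for the RMSF closed form; digests of 40–150 chains of length
4–15.  These sizes make every check sharp (Monte-Carlo error well below the
asserted tolerances) while keeping the default suite fast.  Numerical
defaults — grid 0.5 Å, 960 SASA points, 240 erosion directions, 3×3×3
subcell refinement — were fixed once against the analytic references above
and are all exposed as arguments.

## Known limitations

* PDB fixed-column format only (first MODEL, no mmCIF, no symmetry
  expansion); one chain analysed at a time, defaulting to the first chain,
  since per-chain analysis is the family convention.
* Interaction counts depend on the stated geometric criteria; no
  force-field energies, no angular sub-classification of stacks, no
  water-mediated hydrogen-bond networks.
* The subsite simulator's rate law is a minimal occupancy model — suitable
  for invariants and archetype endpoints, not for fitting real time
  courses quantitatively.
* Correlation with 6–7 structures is descriptive; the package deliberately
  reports no significance measures.
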