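---
title: "Methods: quaternary-state analysis from shifts, relaxation and coordinates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quaternary-state analysis from shifts, relaxation and coordinates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerlens)
```

dimerlens answers one question three independent ways: *does this small
protein form a dimer in solution, and if so, how is the interface
organized?* This vignette is the package's own account of the models it
implements, the conventions it had to choose where the field's practice
is under-specified, and what its synthetic validation does and does not
demonstrate.

## Secondary-shift secondary-structure prediction

Backbone ¹³Cα and ¹³Cβ shifts deviate from their random-coil values in
opposite directions in helices and strands, so the index
ΔδCα − ΔδCβ (with Δδ = δ_obs − δ_random-coil) is a robust per-residue
reporter: positive in α-helix, negative in β-strand. The index is
smoothed with the three-residue running mean
Δδᵢ = (Δδᵢ₋₁ + Δδᵢ + Δδᵢ₊₁)/3 before classification.

Three conventions were genuinely open:

* **Random-coil reference.** No single reference set is canonical. The
  shipped default is the Wishart et al. (1995) DSS-referenced set
  (reduced cysteine); its provenance string is attached to every
  profile and echoed in output headers so results remain auditable, and
  a user-supplied table (same columns plus a `provenance` attribute) is
  accepted everywhere. Because the synthetic generator adds designed
  deltas *to the same table*, round-trip validation is insensitive to
  this choice; real-data interpretation is not, which is exactly why the
  provenance travels with the numbers.
* **Termini and assignment gaps.** Real assignment sets have holes
  (prolines, exchange-broadened stretches). The smoothing window
  averages over the members that exist rather than dropping the
  residue, so coverage is preserved at chain ends and next to gaps; a
  residue with no index of its own stays undefined. Users comparing
  against tools that drop window-incomplete residues should expect
  differences in exactly those positions.
* **Coil deadband.** The sign rule alone over-calls structure on noisy
  data. Labels use a symmetric deadband (default 0.7 ppm, configurable;
  `deadband = 0` recovers the pure sign rule). The default is roughly
  a quarter of a typical full secondary-shift effect (±3 ppm), small
  enough to keep genuine runs of structure and large enough to absorb
  referencing jitter.

Glycine has no Cβ; its ΔδCβ is defined as 0 so the index degrades
gracefully to ΔδCα. The same fallback applies to residues whose CB was
simply never assigned. Residues missing CA are reported undefined, not
guessed.

## Chemical-shift perturbation

Amide perturbations between two states combine the proton and nitrogen
differences as Δδ_NH = √[(Δδ_H² + (Δδ_N/5)²)/2]; the 1/5 factor maps
the ¹⁵N dispersion onto the ¹H scale. Signed components are retained
for diagnostics (the combined value uses only squares, making it
symmetric in the two states). Residues present in only one state are
reported in an `unmatched` attribute — an assignment lost on titration
is itself information and must never vanish silently.

Significance tiers count thresholds *strictly* exceeded, matching the
usual "> x ppm" reporting convention; typical sets are
`c(0.25, 0.5, 1.0)` ppm for variant-vs-wild-type comparison and
`c(0.05, 0.1)` ppm for a weak-ligand titration, and the set is fully
configurable.

## Relaxation analysis

Decays are fit to I(t) = I₀e^(−Rt) by Levenberg–Marquardt least squares
(log-linear regression provides the initializer, so noiseless input is
recovered to machine precision). Peak-intensity uncertainty in
relaxation series is dominated by a constant *fractional* component, so
the default weighting is relative (1/I²); this is also what keeps the
curvature-based standard errors calibrated over a decay's dynamic range
— with unweighted least squares on multiplicative noise the reported
errors are mis-scaled and 2-sigma intervals undercover. Monte-Carlo
validation (500 decays per grid at 2% noise, fixed seed, run in the
test suite) checks bias below 1% and 2-se coverage of at least 90%.
Failed or negative-rate fits are flagged per residue rather than
aborting a batch.

Protein-level averages use a trimmed mean (default 10% per tail) after
excluding flagged fits and residues with NOE < 0.6 — flexible termini
tumble faster than the molecular frame and drag rigid-body averages
down. The exclusion rule is this package's convention, stated in the
output, and configurable.

The tumbling time uses the standard single-field approximation
τ_c ≈ √(6·R₂/R₁ − 7)/(4π·ν_N), valid for slow, nearly isotropic
tumbling dominated by dipolar/CSA relaxation; the formula name is
recorded in every estimate and a user-supplied estimator can be plugged
in. The oligomer call is a deterministic interval lookup with default
windows τ_c ∈ [3, 6.5) ns → monomer, [6.5, 10.5] ns → dimer, anything
else → higher-order/indeterminate. These windows bracket the observed
anchors for an ~8 kDa chemokine at 298 K (monomer near 4 ns, dimer near
8–9 ns); they are calibration defaults, not physics, and should be
overridden for other sizes, temperatures or viscosities. No model-free
analysis, anisotropic diffusion or exchange decomposition is attempted.

## Coordinate-based interface analysis

**Symmetry expansion.** When a dimer is generated by crystal symmetry
from a one-molecule asymmetric unit, all mates under the space-group
operators within the 3×3×3 block of neighbouring cells are generated
(contacts across one cell edge are possible; farther is not) and the
mate with the most heavy-atom contacts under 5 Å is the partner; zero
contacts is reported as monomeric packing. The operator table ships
with the package for the common protein space groups and is validated
by operator count and properness in the tests.

**Hydrogen bonds without hydrogens.** Moderate-resolution crystal
structures carry no amide protons, so the backbone N–H···O=C criterion
degrades to: N···O ≤ 3.5 Å plus a C–O···N angle in [90°, 180°], which
rejects approaches from behind the carbonyl. When hydrogens exist the
direct ∠N–H···O ≥ 120° criterion is used. All cutoffs are configurable;
prolines are never donors; each donor reports only its closest
qualifying acceptor.

**Register comparison.** An antiparallel pairing (i, j) has centre
(i + j)/2, a quantity invariant to swapping the two chains — which is
what makes two dimers comparable even when their chain labelling
differs. The register shift is the difference of median pairing centres
inside a residue window (default residues 5–15, the chemokine
N-terminal interface), rounded to the nearest integer; the median makes
the statistic robust to flanking bonds. Sign convention: positive means
the pairing centre of the second interface sits closer to the
C-terminus.

**Buried area.** Shrake–Rupley quadrature with a deterministic
golden-spiral point lattice (default 960 points/atom, probe 1.4 Å,
Bondi radii; provenance in output headers). Interface area is
(SASA_A + SASA_B − SASA_AB)/2 — the PISA convention — with waters
excluded. Against closed forms the quadrature lands within 1% on an
isolated sphere and 2% on a two-sphere cap (verified in the tests);
against PISA itself, differences of up to ~15% are expected because
point counts, radius sets and probe handling differ between
implementations.

**Superposition.** Kabsch SVD with reflection correction; default
selection Cα over residues 6–68 because chemokine models typically omit
the first few disordered N-terminal residues. The selection actually
used is recorded in the result. A mismatched selection is an error
listing the unpaired atoms unless the caller opts into the
intersection. The implementation is checked against a brute-force
Euler-angle grid oracle in the tests.

**Crystal content.** V_M = V_cell/(Z·mass) with Z = operators × chains
per ASU, chain mass from average isotopic residue masses (plus one
water; an expression-artifact initiator Met is included when present in
the sequence), and solvent fraction 1 − 1.230/V_M (1.230 Å³/Da ≙ the
conventional 0.74 cm³/g protein partial specific volume). For the
trigonal chemokine cell this gives V_M = 2.60 Å³/Da and 52.7% solvent;
published solvent contents computed with slightly different partial
volumes can sit a point or so higher, which is why the tests accept a
±2-point band.

## What the synthetic generators emulate — and what they don't

* `gen_shift_table()` draws the secondary-shift index around ±3 ppm
  class centres (typical full-effect magnitudes; a synthetic
  convention, not a measured value) over a chemokine-like topology
  (strands 24–28, 39–43, 46–51; helix 56–66), splits it symmetrically
  between CA and CB, and adds Gaussian noise. It does *not* emulate
  referencing offsets, nearest-neighbour sequence corrections, or the
  correlated errors of real assignment pipelines — so recovery rates on
  synthetic tables bound what the classifier can do when the
  random-coil reference is exactly right, not more.
* `gen_decays()` produces mono-exponential decays on the standard R₁
  (5–1000 ms) and R₂ (0–237.44 ms) delay grids with multiplicative
  Gaussian noise. Real decays add exchange contributions, offset
  miscalibration and correlated spectral noise; none are simulated, so
  the Monte-Carlo calibration validates the estimator, not the
  spectrometer.
* `gen_beta_dimer()` builds idealized antiparallel strands whose
  designed pairs sit at N···O = 2.9 Å with linear carbonyl geometry,
  carbonyls of unpaired residues pointing away; geometry constants live
  in one place (`beta_geometry()`) so structural tests reproduce
  bit-for-bit. It is a register fixture, not a protein: no side chains,
  no pleat, no twist. Chain B is an exact two-fold image of chain A for
  symmetric pair sets, which is what makes the symmetry-expansion
  round-trip test exact.
* `gen_sphere_fixture()` provides pseudo-atoms with explicit radii for
  analytic surface-area oracles.

All generators are pure functions of their seed: identical inputs give
byte-identical outputs, and truth objects are returned alongside every
dataset so tests never re-derive ground truth from generator internals.

## Numerical choices and degenerate inputs

* Shifts outside [0, 250] ppm are rejected as probable column mix-ups.
* Strict inequalities at tier thresholds; ties at a threshold fall to
  the lower tier.
* `fit_rate()` requires ≥ 3 points with ≥ 2 distinct delays; growing
  intensities yield a flagged negative-rate result, not an exception.
* τ_c is undefined for 6·R₂/R₁ − 7 ≤ 0 (sub-nanosecond regime) — an
  error for the estimator, a fall-through to "indeterminate" for the
  classifier.
* Symmetry-operator matrices are rounded to integer entries (and
  translations to twelfths) after parsing, removing floating-point
  residue from expression evaluation.
* Altlocs resolve to the highest-occupancy copy; waters are flagged on
  read and excluded from interfaces; V_M ≤ 1.230 Å³/Da is rejected as
  impossible packing.
* Problem sizes in the default suite are chosen for exactness of the
  check, not realism of scale: 500-replicate Monte-Carlo per relaxation
  grid, 960-point quadrature (480 where only monotonicity is probed),
  68-residue synthetic profiles.

## Known limitations

* The published interface areas and monomer RMSDs for the deposited
  chemokine structures can only be recomputed from the deposited
  coordinates; the default suite validates the same code paths on
  generated fixtures with exact ground truth instead, and the
  structure-file readers accept whatever PDB/mmCIF files the user
  supplies.
* The space-group table covers the common protein groups shipped with
  the package, not all 230; unsupported symbols fail loudly with the
  supported list.
* τ_c from R₂/R₁ assumes isotropic tumbling and no significant
  exchange broadening; for elongated oligomers or exchange-broadened
  residues the protein-average call should be treated as a screen, not
  a measurement.
* The hydrogen-bond fallback criterion (no explicit H) cannot
  distinguish bifurcated geometries; at the 3.5 Å default this is a
  deliberate over-inclusion kept honest by the one-bond-per-donor rule.
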