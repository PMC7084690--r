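# dimerlens

Deciding how a small protein oligomerizes — and how its dimer interface
is organized — from three independent lines of evidence: backbone
chemical shifts, ¹⁵N relaxation, and crystallographic coordinates.

The package grew out of the analysis of an oligomerization-deficient
CC-chemokine (CCL5) variant whose crystal packs a *novel* dimer: the
N-terminal antiparallel β-pairing slides by exactly one residue relative
to the wild-type interface (C10–C10′ pairing instead of the canonical
⁸TPC¹⁰–⁸′TPC¹⁰′ sheet). It is aimed at structural biologists who have
assigned shifts, relaxation series and/or coordinates in hand and want
the downstream quaternary-state arithmetic done reproducibly.

## What it computes

**Chemical shifts.** Secondary shifts Δδ = δ_obs − δ_random-coil for
¹³Cα/¹³Cβ; the secondary-structure index (ΔδCα − ΔδCβ) smoothed as
Δδᵢ = (Δδᵢ₋₁ + Δδᵢ + Δδᵢ₊₁)/3 (negative ⇒ β-strand, positive ⇒ α-helix,
with a configurable coil deadband); and amide perturbation mapping

Δδ_NH = √[(Δδ_H² + (Δδ_N/5)²)/2]

with configurable significance tiers (e.g. 0.25/0.5/1.0 ppm between
variants, 0.05/0.1 ppm along a titration).

**Relaxation.** Mono-exponential I(t) = I₀e^(−Rt) fits (Levenberg–
Marquardt, relative-error weighting, curvature standard errors),
steady-state hetNOE ratios, the rotational correlation time

τ_c ≈ √(6·R₂/R₁ − 7) / (4π·ν_N)

and a calibrated monomer / dimer / indeterminate call from τ_c.

**Coordinates.** Crystallographic dimer reconstruction from a one-chain
asymmetric unit (built-in space-group operator table, 3×3×3 neighbour
cells, contact-maximizing mate), interchain backbone hydrogen bonds
(with or without explicit amide hydrogens), Shrake–Rupley buried
interface area ((SASA_A + SASA_B − SASA_AB)/2, the PISA convention),
Kabsch SVD superposition RMSD, β-pairing register maps and the integer
register shift between two interfaces, and Matthews coefficient /
solvent-content arithmetic.

**Synthetic data.** Generators with exact ground truth for every stage:
shift tables with a designed topology, mono-exponential decays on the
standard delay grids, ideal antiparallel β-dimers with a controllable
pairing register, and sphere fixtures for analytic SASA checks.

## Worked example

```r
library(dimerlens)

# crystal content of the trigonal cell with one Met-CCL5-12AAA14 chain
# per asymmetric unit
crystal_content(c(48.3, 48.3, 60.4, 90, 90, 120), "P 31 2 1",
                ccl5_sequence(c("12" = "A", "14" = "A")))
#> crystal content: V_M = 2.60 A^3/Da, solvent 52.7%, Z = 6, chain 7814 Da

# tumbling time from protein-averaged rates at 60.81 MHz (15N on a
# 600 MHz spectrometer), and the oligomer call
est <- tau_c_from_ratio(1.26, 11.47, 60.81)
sprintf("tau_c = %.2f ns (R2/R1 = %.2f)", est$tau_c_ns, est$r2_over_r1)
#> "tau_c = 9.03 ns (R2/R1 = 9.10)"
classify_oligomer(est)$state
#> "dimer"

# register shift between a native-like and a C10-centred beta pairing
native <- gen_beta_dimer(list(c(8, 10), c(10, 8)))
mutant <- gen_beta_dimer(list(c(10, 10)))
register_map(native$model)
#>   res_a res_b
#> 1     8    10
#> 2    10     8
register_shift(register_map(native$model), register_map(mutant$model))
#> 1
```

A V_M of 2.60 Å³/Da with ~53% solvent is ordinary protein packing and
confirms one chain per asymmetric unit; a 9 ns tumbling time is far too
slow for an 8 kDa monomer (~4 ns) and pins the solution state as a
dimer; and the register maps show the pairing centre moving from
residue 9 to residue 10 — a one-residue slide of the N-terminal
interface.

The pipeline wrappers `run_nmr_pipeline()` and
`run_structure_pipeline()` chain these stages over whole datasets and
write self-describing TSV/summary bundles.

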