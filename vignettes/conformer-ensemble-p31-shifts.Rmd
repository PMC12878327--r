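---
title: "Conformer-ensemble ³¹P shift prediction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformer-ensemble ³¹P shift prediction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p31shift)
```

## Scope and assumptions

`p31shift` turns per-conformer isotropic phosphorus shieldings into
referenced, Boltzmann-weighted chemical shifts and evaluates them against
experiment with stratified error statistics. It assumes:

* conformer ensembles arrive with **relative Gibbs energies** in kcal/mol
  (the package renormalizes so the minimum is exactly 0) and a consistent
  atom ordering across conformers;
* shieldings are **isotropic values at phosphorus** produced elsewhere — a
  quantum-chemistry backend, a precomputed table, or the package's
  deterministic surrogate. Nothing here computes electronic structure;
* solvent enters only as a **condition label** (which implicit-solvent
  variant of the backend produced the shieldings) and as experimental
  metadata for cohort building. The dielectric model itself is a backend
  concern.

## The pipeline, step by step

**Energy window (6 kcal/mol, inclusive).** Conformers above the window are
discarded as thermally inaccessible at 298.15 K. The boundary is treated
as *inclusive*: "within 6 kcal/mol" is ambiguous at exactly 6.0, and an
inclusive rule keeps the decision deterministic under exact-value inputs.
The minimum-energy conformer always survives, so the result is nonempty.

**Greedy RMSD pruning (threshold 0.5 Å, cap 20).** Ensembles larger than
the cap are pruned: candidates are visited in ascending energy (ties
broken by conformer id so traversal is reproducible), the lowest-energy
conformer is always selected first, and a candidate joins the selection
only if its minimum RMSD against every already-selected conformer is
strictly greater than the threshold. Selection stops at the cap or when
candidates are exhausted; if fewer than the cap survive, **no threshold
relaxation is attempted** — the procedure's description specifies no
fallback, and relaxing would trade reproducibility for an unstated goal.
Ensembles already at or below the cap pass through unchanged.

RMSD design choices: all atoms of the stored geometry are used (hydrogens
included when present); no symmetry-equivalent-atom permutation is
attempted (a permutation-aware RMSD would change selections and costs
combinatorially more); mirror-image superpositions are excluded by forcing
the rotation determinant to +1, since an improper "superposition" would
let an enantiomeric geometry alias a distinct conformer.

**Boltzmann averaging.** Weights are `exp(-ΔG/RT)` normalized to 1, with
`R = 1.987204259e-3` kcal mol⁻¹ K⁻¹ fixed so energies stay in the same
unit as the window. The implementation is safe in both temperature limits
(T → ∞ gives the arithmetic mean, T → 0 the ground-state value), which the
tests assert at 10⁹ K and 10⁻³ K. Molecules with several
symmetry-equivalent phosphorus atoms average their per-atom shieldings
within each conformer *before* weighting; with equivalent nuclei any
per-atom weighting would be arbitrary, and the mean is the only symmetric
choice.

**Referencing.** Computed shieldings reach the 85 % phosphoric acid scale
through trimethylphosphine: `delta = (sigma_ref - sigma) + delta_ref_exp`
with `delta_ref_exp = -62.0` ppm. This "physical" convention maps the
reference compound onto its own experimental shift — the property the
secondary-reference construction exists to deliver. The frequently quoted
sign layout `delta = sigma_ref - sigma - delta_ref_exp` is also available
(`convention = "as_printed"`); taken literally it assigns PMe₃ a shift of
+62 ppm, so it cannot be the physically intended map, but it is retained
because the two conventions differ only by the constant
`2 * |delta_ref_exp|` = 124 ppm and users comparing against published
pipelines may need either. `sigma_ref` is deliberately a *configuration
input*, not a constant: its value depends on functional, basis set and
solvent model, so each backend (the surrogate included) must supply its
own.

**Single-point vs ensemble shift.** The "single-point" shift of a
condition is the shift of the minimum-energy conformer, mirroring a
workflow that optimizes one geometry before any conformer search; the
ensemble shift is the Boltzmann average. Both, plus the shifts of the
lowest- and highest-shielding conformers, are reported per molecule and
condition.

## Evaluation

Errors are `delta_exp - delta_calc`, so a negative mean signed error means
overestimated shifts. Relative MAE divides by the data set's shift range,
default 698 ppm. Cohorts:

* **all** molecules with an experimental shift;
* **solvent**: one cohort per canonical solvent label; records with
  unknown solvent form their own `unknown` cohort rather than being
  distributed or dropped;
* **size / rotatable-bond quantiles**: records sorted by the key with
  `mol_id` as tie-breaker (many molecules share an atom count, so the
  exact boundary assignment is otherwise unstable), cut into k contiguous
  cohorts whose sizes differ by at most one, larger cohorts first — 10,007
  records in 5 cohorts give 2002/2002/2001/2001/2001;
* **class**: substitution-pattern classes at phosphorus (phosphonate,
  dialkyl phosphinate, monoalkyl phosphinate, phosphonite, other), matched
  in that fixed priority order with exact connectivity (ester oxygens must
  bind carbon, no extra substituents on P). Class cohorts also report mean
  experimental and calculated shifts per condition.

Relative improvement between two conditions is
`100 * (rmse_ref - rmse_alt) / rmse_ref` at full precision, rounded to one
decimal only for display (round half away from zero, matching how printed
tables round). When a cohort's reference RMSE is exactly 0 the ratio is
undefined; the report returns 0 if the alternative is also perfect and
`NA` otherwise.

## The synthetic world

The generator exists so the pipeline's algebra and statistics are testable
without downloads or electronic-structure codes. Its defaults state the
emulated world once:

* **Scaffold grammar**: alkyl chains (length 2–8) on the four ester-class
  cores plus phosphines, phosphites and phosphine oxides as "other". The
  first five molecules of any run cycle deterministically through the five
  classes so class cohorts are never empty in moderate data sets. This is
  a device to exercise the classifier and class stratification, not a
  claim about real data-set composition.
* **True shifts**: class centres at the typical per-class experimental
  means (24.7, 115.2, 18.3, 34.3 ppm for the four ester classes; −40, 135,
  40 ppm for the "other" subtypes) with 15 ppm spread.
* **Solvent metadata**: assigned solvent frequencies 2955 : 43 : 11 : 205 : 4
  (CHCl₃ : DMSO : toluene : H₂O : CH₃CN) and a 32 % revelation
  probability, reproducing the structure of large shift collections where
  most records lack solvent metadata and chloroform dominates the known
  subset.
* **Observed shift**: `delta_exp = delta_true + solvent_offset +
  class_offset + N(0, noise_sd)`, defaults `noise_sd = 5` ppm, solvent
  offsets (3, −2, 4, −5, 2) ppm and class offsets (3, −8, 2, −4, 0) ppm —
  systematic biases on the scale such collections exhibit.
* **Conformer counts**: mean `0.1 * 0.0314 * n_atoms^2.515`, capped at 30.
  The power law is fitted to how mean ensemble size grows with atom count
  in large collections (≈ 24 conformers near 14 atoms to ≈ 933 near 60);
  the 0.1 scale and the cap keep the *retained* ensembles near the ~15
  conformers such workflows actually evaluate per molecule, and keep
  desk-scale runtime. Energies are truncated-exponential (mean 2 kcal/mol)
  inside the 6 kcal/mol window; geometries are a 1.5 Å-step random walk
  per molecule with 0.4 Å per-atom Gaussian jitter per conformer, which
  puts typical conformer RMSDs near the 0.5 Å pruning threshold so both
  pruning branches are exercised.
* **Surrogate shieldings**:
  `sigma_i = sigma_ref - (delta_true - delta_ref_exp) + g_i + s`, with
  `sigma_ref = 350` ppm, `g_i` a deterministic perturbation (±2 ppm)
  keyed on the conformer's geometry — so it survives pruning and
  reordering — and `s` cancelling the molecule's solvent offset exactly
  when the condition names its assigned solvent. Inverting the referencing
  equation on these shieldings recovers `delta_true` exactly when `g` and
  the offsets vanish; with them, vacuum predictions carry the planted
  biases and the matched-solvent condition removes precisely the solvent
  part.

All randomness flows from one master seed through a counter-based stream
per molecule, so any subset of molecules is bit-reproducible regardless of
how many molecules are generated.

**What the generator does *not* emulate** — and therefore what a green
test does not establish: real shielding physics (no dependence of σ on
conformation beyond the bounded hash perturbation, no ring currents, no
heavy-atom effects), real geometry (random-walk "molecules" have no
chemically meaningful shape, only controllable RMSD structure), outliers
and heavy-tailed errors, correlations between solvent and compound class,
and the full 698 ppm shift range. Tests on synthetic data validate the
pipeline's *statistics and algebra*, not quantum-chemical accuracy.

One experimental-design note: the offset-recovery acceptance check runs
with `solvent_known_fraction = 1`. Planted per-solvent biases are only
recoverable on records whose solvent is observable, and at the default
32 % revelation the smaller planted cohort holds only ~17 of 1000
records — small enough that ordinary cohort noise (mean error
≈ noise_sd/√17 ≈ 1.2 ppm against a 5 ppm bias) fails the sign check for
a few percent of seeds. Full revelation is the appropriate design for
that experiment; the zero-offset solvents must still show exactly zero
improvement there, which is the sharper half of the check.

## Numerical choices

* `kabsch_rmsd` applies the optimal rotation and measures the residual
  directly instead of using the closed-form trace expression
  `sqrt((|A|² + |B|² - 2Σd)/N)`: the trace form cancels catastrophically
  for congruent geometries (observed ~10⁻⁷ Å spurious RMSD), while the
  residual form is exact to ~10⁻¹⁵.
* Fewer than 3 atoms is a hard error (the optimal rotation is
  under-determined), as are shape mismatches and non-finite coordinates.
* ppm values are serialized to SDF at 2 decimals, the precision of
  reported shift tables; round-tripping is exact at that precision.
* Reported roundings use round-half-away-from-zero; all internal
  computation is full precision.
* The SMILES reader covers the organic subset plus bracket atoms, rings
  and explicit bonds, with implicit hydrogens from the standard valence
  model. Aromatic (lowercase) input is rejected with a pointer to
  kekulized form rather than mis-counted; the rotatable-bond count
  implements the strict definition (terminal atoms, triple-bond
  participants, amide/ester/thioester carbonyl bonds and symmetric
  terminal rotors such as CF₃ and *t*-Bu excluded), validated against an
  independent cheminformatics toolkit on frozen cases.

## Known limitations

* No conformer generation or geometry optimization: ensembles come from
  files or the generator.
* The classifier demands exact core connectivity; substituted variants
  (e.g. a phosphonate with an additional P-heteroatom bond) fall into
  "other" by design.
* Quantile cohort *boundaries* depend on the `mol_id` tie-break; only the
  cohort sizes are invariant.
* The CSV/XYZ/SDF dialects are fixed local conventions (documented in the
  readers); arbitrary third-party NMReData files may use tags this package
  preserves but does not interpret.
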