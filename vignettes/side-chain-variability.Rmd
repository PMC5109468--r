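---
title: "Measuring side-chain conformational variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring side-chain conformational variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scvar)
```

# The problem

A deposited crystal structure is a model, not an observation. Three facts
complicate any statement about "the" conformation of a side chain:

1. **Alternate locations.** Where the electron density supports several
   discrete positions, depositors record multiple coordinate sets per atom,
   each with a fractional occupancy. Some residues carry states labelled
   only `'C'`/`'D'`; pipelines that keep only state `'A'` silently drop
   them.
2. **Unsupported coordinates.** At any resolution some side chains have no
   interpretable density; their coordinates are effectively modelled by the
   crystallographer. Scoring a predictor against such coordinates measures
   nothing.
3. **Genuine polymorphism.** The same residue of the same protein can adopt
   clearly different, individually well-supported rotamers in two chains of
   one crystal, or in two crystals.

`scvar` implements the measurement machinery for all three, plus the
assessment scheme they motivate: score a predicted side chain against the
*closest* member of a multi-conformer native ensemble, optionally restricted
to density-reliable residues, optionally in pure map terms via a density
sum.

# Models and rules

## Dihedrals and the 30° change rule

χ angles follow the standard quadruple table (χ₁ = N–CA–CB–Xγ, numbering
outward; the table ships with the package, `chi_atom_table()`). The signed
torsion uses the convention `atan2((n₁×n₂)·b̂₂, n₁·n₂)`, which is invariant
under rigid motion. Two conformations of a residue differ when **any**
shared χ differs by strictly more than 30° — so Δχ = 30.0° exactly is
*unchanged*; 31° is changed. For the chemically 2-fold symmetric terminal
groups the difference is flip-aware:
`min(Δ(a,b), Δ(a, b+180°))` at Asp χ₂, Glu χ₃, Phe χ₂, Tyr χ₂. The source
analysis also lists Arg as symmetric; strictly, guanidinium symmetry swaps
NH1/NH2 without changing χ₄ (NE–CZ), but we follow the published protocol
and flip Arg's last measured χ, behind `scvar_config(flip_arg_terminal=)`,
so the discrepancy is visible and reversible. A χ measurable in only one
partner is excluded from the comparison; if χ₁ is unmeasurable in either,
the residue is *incomparable* and enters no percentage. Pro's χ₂ is
measured and reported, while type-level summaries treat Pro as one degree
of freedom.

The categories reported everywhere are cumulative: `same_chi1`
(Δχ₁ ≤ 30°), `same_chi12` (χ₁ and χ₂), `same_all` (every shared χ), and
`changed = !same_all`; monotonicity `same_all ⇒ same_chi12 ⇒ same_chi1` is
enforced by construction and re-checked property-style in the tests.

## Density reliability

Maps are consumed as CCP4/MRC files and σ-normalized over all voxels
(`(v − μ)/σ`, population σ; a constant map is a hard error). Point density
is **trilinear** interpolation in fractional coordinates — the published
method says only "interpolation", so trilinear is the contract and the test
oracle; it is exact at grid nodes and linear along axes. An atom is
reliable iff its point density is strictly above 1σ (1.0σ exactly is
unreliable — both published phrasings, ">1σ reliable" and "<1σ unreliable",
agree once the boundary goes to unreliable). A residue is reliable when all
heavy atoms are; its side-chain conformation when all heavy side-chain
atoms are. Hydrogens are excluded throughout (maps at survey resolutions do
not resolve them). Reliability is evaluated on the **first conformer** —
the state with the lexicographically smallest indicator, which is 'A' when
present but never drops a 'C'/'D'-only residue — matching the published
per-structure reliability percentages; a config switch allows any-conformer
evaluation. Atoms outside a cropped (non-periodic) map count unreliable
with a warning instead of aborting a survey run, because real
density-server maps are sometimes cropped to a margin around the model.

## Accessibility

Shrake–Rupley with 960 quasi-uniform sphere points and a 1.4 Å probe, over
the **whole structure** jointly with per-chain attribution afterwards —
computing a chain in isolation can only increase its area, and a dedicated
test pins that direction. Element-based van der Waals radii (C 1.70,
N 1.55, O 1.52, S 1.80 Å…) ship as plain-text data. A residue is *exposed*
at absolute ASA ≥ 1.0 Å². The source's main text once says "buried" for the
≥ 1.0 Å² class; its figure caption says "exposed", which is the
self-consistent reading and the one implemented. Relative ASA divides by a
Gly-X-Gly tripeptide reference; we ship the Miller scale because an
extended tripeptide built by our own generator reproduces it under our
radii to a few percent (the theoretical-maximum scales run ~15–25 %
higher). Absolute ASA, not relative, drives the exposure classifier, so
this choice does not move any survey number. Waters and ligands are
excluded from occlusion by default (NACCESS convention), switchable.

## Pair curation and the survey

Chain pairs enter the survey when: global sequence identity > 90 %
(Needleman–Wunsch via Biostrings, BLOSUM62, gap open 10 / extend 0.5 —
identity is insensitive to these constants at > 90 % identity; the
denominator is aligned columns excluding terminal gaps), TM-score > 0.8
normalized by the reference chain (d₀ = 1.24·(L−15)^⅓ − 1.8, floored at
0.5 Å; superposition refined iteratively on residues within
max(d₀, 3 Å) until the included set repeats, ≤ 20 iterations), Cα RMSD
< 3.0 Å, both resolutions ≤ 3.5 Å, length > 100 aa, and the PDB-id rule:
same-crystal pairs are two chains of one entry; cross-crystal pairs must
have ids differing at more than two of four positions (Hamming distance,
taken literally from the published Methods — note this excludes id pairs
like `2pa8`/`2pmz` that differ at exactly two).

Within an accepted pair, residues are matched through the alignment;
type-mismatched columns are kept but flagged (they feed the
mutation-effect grouping, not χ comparison); residues with alternate
locations in either partner, known-unreliable side chains, Gly/Ala, or
unmeasurable χ₁ are excluded — the published same-crystal protocol.
Backbone change is attributed when Δφ > 30° or Δψ > 30° (undefined at
termini and chain breaks, detected by a 2.5 Å C–N sanity distance).

Aggregation computes **per-structure percentages first**, then mean ± SD
across structures within each resolution bin (<1.0, 1.0–2.0, 2.0–3.0,
3.0–3.5 Å), residue type, or exposure class. This is not the same as
pooling residues — a regression test pins the difference on an unbalanced
cohort. SD is population SD (the convention behind error bars is ambiguous
in the source; `sd_type = "sample"` switches).

The flexibility estimate is plain arithmetic:
`pct_altloc + (100 − pct_certain) [+ pct_cross_structure_changed]`,
reproducing 12 + (100−95) = 17, 3 + (100−87) = 16 and 17 + 3 = 20. The
source's Discussion calls the 95 %/87 % figures "uncertain residues", but
its own parenthetical arithmetic only works if they are *certain*
percentages; the function takes certain-%.

## Assessment

`build_ensemble()` collects, per residue of a reference chain, **every**
altloc state of every supplied native source — never only 'A'. With maps
supplied, residues unreliable in all sources are excluded (reported as
`n_excluded`, separate from predicted-but-missing residues, which count as
incorrect). The *closest* conformer minimizes the **maximum** flip-aware
per-χ difference — chosen because it aligns with the all-χ correctness
criterion (a conformer within 30° on every χ, if one exists, always wins);
ties break by smaller Δχ₁, then provenance order; a χ₁-lexicographic
alternative sits behind `closest_metric`. Correctness uses the survey's own
30° (not the 40° used in some benchmarks) so that "accurate" means "within
the same-conformation band of the survey". The density-sum score adds the
interpolated σ-value at every predicted side-chain heavy atom
(first predicted conformer; backbone excluded by default because it
inflates scores without testing packing). It is additive over disjoint
residue sets and, on rendered fixtures, separates native from 2 Å-displaced
models in ≥ 95 of 100 seeds.

# The synthetic world

Every test runs on generated data; nothing is downloaded. The generator's
stated world is:

* **Backbone:** ideal α-helix, φ = −57°, ψ = −47°, ω = 180°, standard bond
  lengths/angles, built by natural-extension (NeRF) placement. Helices are
  the simplest valid chains; no test needs sheet geometry.
* **Side chains:** ideal internal-coordinate templates for seven types
  spanning the interesting cases — symmetric terminal χ (Asp, Phe, Arg),
  long flexible (Lys, Arg, Met), short polar (Ser), branched (Leu).
  Placement recovers requested χ to < 10⁻³ degrees (round-trip tested for
  all types × 100 random draws). Untemplated types raise a clear error.
* **Rotamer sampling:** χ drawn from {−60°, 60°, 180°} ± U(−10°, 10°) —
  the canonical gauche∓/trans wells with realistic scatter.
* **Variant pairs:** exactly `round(f · n)` eligible residues rebuilt with
  χ₁ rotated by U(90°, 135°), guaranteeing a > 30° flip-aware change;
  every other residue is copied bit-identically, so change labels are exact
  by construction, and the survey engine is required to recover them at
  100 %, not approximately.
* **Altloc injection:** extra states built at stated χ shifts and
  occupancies (e.g. the 0.45/0.55 two-state case, or twenty 0.05-occupancy
  states), emitted as valid fixed-column altloc records.
* **Maps:** Gaussian atoms, ρ(x) = Σ occ·exp(−|x−r|²/2σ²) with σ = 0.8 Å on
  a 0.5 Å grid, padding ≥ 3σ, optional noise, then σ-normalization. This is
  deliberately not scattering physics: the reliability rule only needs a
  density field correlated with atom positions and occupancies. Rendered
  this way, ≥ 99 % of true atom positions score above 1σ while points ≥ 3σ
  from every atom score below — the reliable/unreliable dichotomy holds by
  construction, and low-occupancy (0.1) deviant states lose reliability
  more often than 0.5-occupancy ones.

What a green test therefore establishes: the classifiers, filters and
aggregations implement their rules exactly, and the whole pipeline inverts
the generator. What it does not establish: agreement with any real-PDB
survey percentage — real maps have solvent, series-termination ripple and
model bias that Gaussian atoms do not emulate, and real cohorts are not
balanced across bins. The published headline numbers (94.8 ± 5.7 % reliable
atoms, ~91 %/~95 % retention, 56 % of structures with altlocs, …) need
thousands of entries plus experimental maps and are out of desk-scale
scope by design.

# Numerical choices and degenerate inputs

* Strict inequalities at both decision boundaries (Δχ > 30°; density
  > 1σ) — boundary cases are pinned in tests.
* "First conformer" with no 'A' state: lexicographically smallest
  indicator; a blank-altloc residue is its own single state with
  occupancy 1. Partial-occupancy blank-altloc atoms (occupancy < 1, no
  indicator — a case the source never discusses) are treated as
  single-state and logged.
* Occupancy sums per atom name above 1 + 10⁻⁶ are logged, never fatal;
  state occupancy disagreements resolve to the mode.
* Multi-MODEL files: first MODEL with a warning (the ensemble-style altloc
  entries are handled through altloc grouping, not MODEL records).
* TM-score on short targets: d₀ floored at 0.5 Å; pairings shorter than 3
  are errors; ties in the refinement iteration resolve by accepting the
  first repeated included set.
* Kabsch uses SVD with reflection correction (det = +1 enforced); < 3
  points is an error; degenerate rank is handled by the sign convention.
* Insertion codes are part of residue identity (`number + icode`);
  HETATM amino acids (MSE → MET etc.) map to parents and are flagged;
  nonstandard ATOM residues keep a sequence letter 'X'; waters/ligands are
  retained in the model but excluded from residue statistics.
* The 0.5σ secondary threshold mentioned once in the source is not a
  second hard-coded rule; `density_sigma_cutoff` is a parameter.

# Known limitations

* No mmCIF reader (the fixed-column dialect is the contract here).
* No structure validation or symmetry expansion; maps are consumed as
  given, with no structure-factor synthesis.
* TM-score correspondence always comes from sequence alignment — there is
  no TM-align-style alignment search, so the score is meaningful only for
  the > 90 %-identity pairs the survey curates.
* The Gaussian-map generator is not a physics model; conclusions about
  absolute σ-levels on real maps should not be drawn from fixture maps.
* Sequence-redundancy clustering across large chain sets (the 25 % cutoff
  between pairs) is honored as a configuration value applied to provided
  lists, not recomputed.
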