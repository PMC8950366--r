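---
title: "The Fe-heme distance discriminant: model, calibration and design notes"
author: "CypDiscriminant maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Fe-heme distance discriminant: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CypDiscriminant)
```

## The scientific problem

Cytochrome P450 2D6 (CYP2D6) is a highly polymorphic drug-metabolising
enzyme: star alleles such as \*14A, \*51, \*110 and \*122 carry missense
mutations that can change how well a ligand is metabolised. Direct
experimental activity data are scarce for rare alleles, so structural
trajectories of enzyme–ligand complexes are used as a proxy: for a
ligand to be transformed, the atom at which the reaction occurs (the
*reactive atom*) must sit close to the heme iron, where the oxidation
chemistry happens.

The package implements this reasoning as a reusable, testable pipeline.
The discriminant signal is the per-frame distance

$$d(t) \;=\; \lVert \mathbf{r}_{\mathrm{reactive}}(t) -
\mathbf{r}_{\mathrm{Fe}}(t) \rVert ,$$

summarised over a trajectory as mean ± SE and compared between a
variant and the reference allele with an independent two-sample t test.
Short, stable distances read as catalytically competent poses; long or
escaping distances as poor or absent metabolism. The calls are
deliberately *semi-quantitative*: labels, not rate constants.

## Pipeline components

1. **Structure/trajectory I/O** (`readPDB()`, `readModelTrajectory()`):
   multi-model PDB is the native trajectory dialect — one MODEL block
   per frame over a constant atom set. Coordinates stay in Ångström
   internally (the PDB's native precision); every reported distance is
   converted to nm. Author residue numbering is used everywhere; the
   mutation positions of the built-in alleles (e.g. 445) are interpreted
   in that numbering, and no renumbering ever happens.
2. **Geometry** (`kabsch()`, `rmsdSeries()`, `distanceSeries()`):
   Kabsch superposition with a determinant correction (reflections are
   not physical rigid motions and are excluded), mass-unweighted RMSD,
   and the Fe–reactive-atom distance series. The RMSD reference is
   frame 1 — inputs are assumed post-equilibration — and ligand RMSD is
   computed in the protein frame (superpose on C-alpha, measure the
   ligand), which is the mode that exposes detachment; ligand-self
   superposition would hide it.
3. **Discriminant statistics** (`summarizeSeries()`, `compareSeries()`,
   `detectDetachment()`, `callSubstrate()`, `callVariantEffect()`).
4. **Variant bookkeeping** (`builtinVariants()`, `applyMutations()`,
   `classifyStability()`, `mutationSiteDistances()`).
5. **Conservation** (`readMSA()`, `columnConservation()`,
   `scanHemeMotif()`).
6. **Synthetic data** (`simulateDistanceSeries()`, `scenarioPresets()`,
   `buildToyComplex()`, `embedSeriesIntoTrajectory()`, `simulateMSA()`).

## Statistical conventions

**SE treats frames as independent.** `summarizeSeries()` reports
SE = SD/√n over all frames. This is the field's reporting convention —
it is the only way SEs of ~0.001–0.003 nm arise from 5000 frames with
SDs of ~0.07–0.2 nm — but it understates uncertainty for autocorrelated
frames. `essCorrection = TRUE` replaces n with an effective sample size
from the integrated autocorrelation time; it is off by default so that
default output matches the convention, and honest uncertainty is one
flag away.

**Student's pooled-variance t is the default** (`mode = "student"`,
df = nA + nB − 2, two-sided p); Welch's form is available as
`mode = "welch"`. Frame-wise t tests on autocorrelated series
over-reject slightly; the test suite bounds this type-I inflation at
~0.10 for the shipped generator parameters, and the ESS option exists
for users who need calibrated tests. No multiple-testing correction is
applied across comparisons — the workflow reports a handful of planned
contrasts, and this is documented rather than silently corrected.

**Degenerate inputs.** Two constant, equal series compare with t = 0,
p = 1 (documented contract); constant unequal series are reported as an
infinite t with p = 0. Coincident atoms in a frame yield distance 0,
which is allowed and logged.

## Semi-quantitative call rules

* **Substrate likelihood** (`callSubstrate()`): the probe envelope is
  the largest mean distance among the probe-substrate complexes
  (dextromethorphan and bufuralol with the reference allele). A mean
  within +0.05 nm of the envelope is `probe_like`; within +0.15 nm,
  `minor_substrate`; beyond, `poor_or_non_substrate`. The margins are
  this package's operationalisation of a qualitative scale: they place
  the ochratoxin A (OTA) reference complex (~0.50 nm against probes at
  ~0.41–0.44 nm) in the minor band and clearly escaped complexes
  (>0.6 nm) outside it. Both margins are arguments.
* **Variant effect** (`callVariantEffect()`): significantly *lower*
  variant mean → `likely_enhanced`; significantly higher →
  `likely_reduced`; not significant → `unchanged`.
* **Detachment** (`detectDetachment()`): first run of frames strictly
  above 0.6 nm lasting at least 1 ns. The threshold sits between the
  stable complexes (means 0.41–0.54 nm) and the detached ones
  (0.63 nm and up); the 1 ns persistence window suppresses transient
  excursions. Both are arguments.
* **Stability** (`classifyStability()`): ΔΔG < 1 kcal/mol →
  `limited_effect`, else `potentially_destabilising`. The boundary
  value 1.0 is classed destabilising under the strict-inequality rule.
* **Proximity annotation** (`mutationSiteDistances()`): a mutated
  residue whose closest atom lies within 1.0 nm of the iron is
  `proximal` — the heme-pocket scale — else `distal`; configurable.

## The synthetic-data generator

No deposited trajectories exist for the complexes this package is
calibrated around, so the generator produces every input the pipeline
needs at desk scale. A distance trace is modelled as an
Ornstein–Uhlenbeck (OU) process with the exact discretisation

$$x_{t+\Delta t} = \mu + (x_t - \mu)\,e^{-\theta \Delta t} +
\sigma\sqrt{\tfrac{1 - e^{-2\theta \Delta t}}{2\theta}}\; z,
\qquad z \sim \mathcal{N}(0, 1),$$

optionally with a one-time switch of $\mu$ (detachment), floored at
0.15 nm (hard-sphere contact; flooring is logged and is rare by
construction). This captures what the discriminant analysis actually
consumes — a mean-reverting, autocorrelated, roughly Gaussian signal
with occasional regime changes — and nothing else.

**Preset calibration.** The shipped presets
(`scenarioPresets()`, one per ligand × allele complex) use:

* $\mu$ equal to the reported mean distance of each of the ten
  numerically characterised complexes (0.407–1.157 nm);
* $\sigma$ chosen per preset so that the stationary SD
  $\sigma/\sqrt{2\theta}$ equals the SD implied by each complex's
  reported SE over 5000 frames (SE·√5000, i.e. 0.071–0.21 nm), capped
  at $(\mu - 0.15)/3.72$ so the contact floor is hit with probability
  ≤ 1e-4 per frame — an uncapped 0.14 nm SD at a 0.41 nm mean would
  floor ~3% of frames, which is unphysical for a bound ligand;
* $\theta = 0.2\,\mathrm{ps}^{-1}$, a 5 ps decorrelation time. Bound
  ligand–iron distances decorrelate on picoseconds, and at the 10 ps
  frame spacing this leaves a lag-1 autocorrelation of
  $e^{-2} \approx 0.14$: visible autocorrelation (so the ESS machinery
  is exercised) without destroying the frame-wise SE convention;
* OTA-\*122, for which only a marked early detachment is described,
  carries a regime switch at 5 ns ("early" relative to a 50 ns run) to
  a detached mean of 1.2 nm instead of a calibrated $\mu$. It is
  excluded from numeric recovery checks by construction.

The default 5000 frames at 10 ps reproduce a 50 ns production run.

**What the generator does *not* emulate:** force-field physics,
solvent, periodic-boundary artefacts, docking poses, side-chain
rebuilding after mutation, or any coupling between protein RMSD and the
distance signal (toy trajectories jitter the protein independently).
Passing tests therefore demonstrate that the *analysis* is correct and
well-calibrated on signals with the right statistical structure — not
that MD trajectories of these complexes would reproduce the preset
means.

Toy complexes (`buildToyComplex()`) are self-avoiding random-walk
backbones with a single-iron HEM group and a ligand placed 4.39 Å from
the iron; `embedSeriesIntoTrajectory()` rigidly translates the ligand
per frame so the embedded distance is exact before any write/read
rounding (multi-model PDB stores 3 decimals in Å, so round trips are
good to ~1e-3 nm).

Synthetic MSAs (`simulateMSA()`) plant an exact number of substituted
records at one reference-mapped column (default substitution alphabet
Ala/Ser/Tyr/Phe/Asp/Leu, the residues observed at the G445-equivalent
position in homologs) over an i.i.d. background at 80% identity —
enough to make column bookkeeping non-trivial, with no attempt at
phylogenetic realism. Gap handling in `columnConservation()` excludes
gap rows from numerator and denominator by default (flagged via
`countGaps`), since real alignments rarely state their convention.

## Numerical choices and degenerate cases

* Kabsch uses base SVD; n < 3 points or mismatched dimensions are
  errors, and near-collinear sets fall back to whichever optimal
  rotation SVD selects (RMSD is still minimal; only the rotation is
  non-unique).
* `mapPosition()`/columns are 1-based throughout, matching residue
  numbering.
* Wild-type residues are verified before every substitution in
  `applyMutations()`, so numbering drift fails loudly instead of
  silently mutating the wrong site.
* Per-scenario seeds are derived as global seed + preset index, so a
  run is reproducible end-to-end from one integer and scenarios remain
  independent.

## Problem sizes

The shipped tests exercise the full study conditions where the
statistics demand it (5000-frame series for mean recovery, ordering,
detachment and type-I checks; a 1635-sequence alignment with 80
substituted records for conservation) and small fixtures everywhere the
check is structural (toy complexes of 20–30 residues, 40–200-frame
trajectories for round trips). These sizes are the package's test
design: large enough that every statistical claim is tested under the
conditions it is made for, small enough that the whole suite runs in
well under a minute.

## Known limitations

* The pipeline never builds variant structures; mutations are
  bookkeeping on sequences plus a proximity annotation. Structural
  effects of substitutions enter only through whatever trajectories the
  user supplies.
* Substrate calls depend on the probe envelope; with no probe complex
  in a run, no substrate call is possible (the pipeline refuses rather
  than guessing).
* The naive SE convention is reported because it is the field's; it is
  not a statistically honest uncertainty for autocorrelated frames.
  Use `essCorrection = TRUE` when the uncertainty itself matters.
* Exact reproduction of published conservation percentages would
  require the original dated sequence download; the synthetic MSA
  reproduces the counts' structure, not the database snapshot.
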