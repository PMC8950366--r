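# CypDiscriminant

Semi-quantitative assessment of CYP2D6 substrate metabolism from
structural trajectories, for structural bioinformaticians and
pharmacogenetics researchers who need a reproducible, tested version of
a common visual analysis: *is the ligand's reactive atom close enough to
the heme iron, for long enough, for metabolism to be plausible — and
does a missense variant change that?*

## The method

Cytochrome P450 2D6 (CYP2D6) oxidises its substrates at the heme iron,
so a catalytically competent pose keeps the ligand atom undergoing the
reaction near the Fe. For a trajectory of an enzyme–ligand complex the
package computes, per frame,

    d(t) = || r_reactive(t) − r_Fe(t) ||        (reported in nm)

and derives from it:

* **mean ± SE** over frames (`summarizeSeries()`; SD/√n over n frames,
  with an optional autocorrelation-corrected effective-sample-size SE);
* **variant vs reference comparisons** with independent two-sample
  t tests at α = 0.05 (`compareSeries()`; pooled-variance Student's
  form by default, Welch optional) and an effect call: a significantly
  *shorter* distance than the reference allele reads as
  `likely_enhanced` metabolism, longer as `likely_reduced`;
* **substrate-likelihood labels** against the envelope of the probe
  substrates dextromethorphan and bufuralol (`callSubstrate()`:
  `probe_like` / `minor_substrate` / `poor_or_non_substrate`);
* **detachment events** — the first ≥1 ns run of frames above 0.6 nm
  (`detectDetachment()`), i.e. loss of a catalytically competent pose;
* **stability RMSD series** after Kabsch superposition
  (`rmsdSeries()`: protein C-alpha, and ligand-in-protein-frame).

Around the discriminant sit the supporting analyses: CYP2D6 star-allele
bookkeeping (`builtinVariants()` ships \*1, \*14A, \*51, \*110, \*122;
`applyMutations()` verifies wild-type residues before substituting), the
ΔΔG stability rule (`classifyStability()`: < 1 kcal/mol ⇒ limited
effect), heme-binding-motif scanning (`scanHemeMotif()`:
`G-X-[HR]-X-C-[PLAV]-G`, with a relaxed variant for the tolerant "+2"
position), and MSA column conservation mapped through the reference
sequence (`columnConservation()`).

Because no trajectories are deposited for the calibrated complexes, a
first-class synthetic-data module generates every input at desk scale:
Ornstein–Uhlenbeck distance traces with per-complex calibrated means
and volatilities (`scenarioPresets()`), toy complexes and multi-model
PDB trajectories that embed a chosen trace exactly
(`embedSeriesIntoTrajectory()`), and alignments with exact planted
conservation (`simulateMSA()`). See the vignette
(`vignettes/fe-heme-discriminant.Rmd`) for the model, its assumptions
and the calibration.

## Worked example

A full synthetic run over all shipped scenarios at the study scale
(5000 frames, 10 ps spacing — a 50 ns trajectory):

```r
library(CypDiscriminant)
res <- runPipeline(runConfig(nFrames = 5000L, seed = 1L))
res$complexes[, c("label", "mean_nm", "se_nm", "substrate_call",
                  "detachment_onset_ps")]
```

```
                   label mean_nm    se_nm        substrate_call detachment_onset_ps
1    dextromethorphan:*1   0.443 0.001096            probe_like                  NA
2  dextromethorphan:*14A   0.516 0.001411       minor_substrate                  NA
3   dextromethorphan:*51   1.157 0.000984 poor_or_non_substrate                   0
4           bufuralol:*1   0.409 0.000984            probe_like                  NA
5         bufuralol:*14A   0.659 0.001941 poor_or_non_substrate                  NA
6          bufuralol:*51   0.535 0.000999       minor_substrate                  NA
7                 OTA:*1   0.501 0.001012       minor_substrate                  NA
8               OTA:*14A   0.629 0.000985 poor_or_non_substrate                  NA
9                OTA:*51   0.720 0.001023 poor_or_non_substrate                8020
10              OTA:*110   0.450 0.000989            probe_like                  NA
11              OTA:*122   1.131 0.003147 poor_or_non_substrate                5000
```

The two probe complexes sit lowest (~0.41–0.44 nm) and are labelled
`probe_like`; ochratoxin A (OTA) with the reference allele \*1 sits
slightly higher (0.501 nm, `minor_substrate`); complexes above the
0.6 nm threshold are `poor_or_non_substrate`, and OTA–\*122 detaches at
5 ns (its generating regime switch). The variant comparisons for OTA:

```r
res$effects[res$effects$ligand == "OTA",
            c("allele", "delta_nm", "t", "p", "effect_call")]
```

```
  allele delta_nm     t         p     effect_call
    *14A   0.1275  90.3  0.00e+00  likely_reduced
     *51   0.2184 151.8  0.00e+00  likely_reduced
    *110  -0.0516 -36.5 1.06e-273 likely_enhanced
    *122   0.6295 190.5  0.00e+00  likely_reduced
```

\*110 is the one variant whose reactive atom sits *closer* to the iron
than in the wild type (Δ = −0.052 nm, p ≪ 0.001): a candidate for
enhanced OTA turnover. Its single mutation G445R is compatible with a
folded, expressed protein:

```r
classifyStability(0.9)
#> StabilityCall: limited_effect (ddG = 0.90 kcal/mol)

# reference with the heme-binding motif placed so G445 is its +2 position
refSeq <- paste0(strrep("A", 438), "GAHACPG", strrep("V", 55))
msa <- simulateMSA(1635, 80, refSeq, 445, seed = 2)
runConservation(msa, refPosition = 445)$conservation
#> ConservationReport: column 445 (ref G @445): 95.1% conserved over 1635 sequences
```

G445 is the "+2" position of the heme-binding motif — conserved in 95%
of homologs but demonstrably substitutable, which is why a variant
there can remain functional.

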