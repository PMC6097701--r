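# erescape

Scoring, calibration and simulation tools for the **ER-ESCAPE motif** —
the amino-terminal tripeptide of a mature secreted protein (the first
three residues left after signal-peptide cleavage) that determines
binding affinity for the ER cargo receptor **Surf4** (Erv29p in yeast).

Aggregation-prone soluble cargo (DSPP, amelogenin, hormones stored in
granules) cannot rely on passive ER-to-Golgi bulk flow: their lumenal
concentrations would climb past the point where intralumenal aggregates
form. Surf4 binds the exposed tripeptide and loads such cargo into COPII
vesicles, so that each protein settles at a steady-state ER concentration
set by its motif's affinity, and the most problematic cargo is
prioritized when receptor becomes limiting.

The package is aimed at protein-trafficking and secretory-pathway
researchers who want to ask: *given a mature protein start, how strong an
ER-ESCAPE motif is it, and what does that predict for its ER steady
state?*

## What it implements

* **Additive motif model** — a 3 × 20 per-position contribution table
  (favorable/neutral/unfavorable, Φ = {A, I, L, M, F, V, Y} favorable at
  positions 1 and 3, proline favorable at 2 and unfavorable at 3, D/E
  unfavorable everywhere, ...), tripeptide score
  `S(t) = w(1,t1) + w(2,t2) + w(3,t3)`, classification into
  strong/modest/nonbinding with a ≥2-acidic hard rule and documented
  exceptions (FPV, KVH). `scoreTripeptide()`, `classifyTripeptides()`,
  `isPhiPPhi()`.
* **Sequence IO** — tripeptide extraction from FASTA plus 1-based
  mature-start annotations, survey tables and predicate tallies.
  `readMatureRecords()`, `tallySurvey()`, `surveyClassify()`.
* **Calibration** — within-experiment IPV-normalization of reporter
  steady-state levels and monotone (isotonic) regression of level on
  score with rank-concordance diagnostics. `normalizeToReference()`,
  `fitMonotone()`, `concordanceReport()`.
* **Binding** — single-site saturation fits
  `B(c) = b0 + Bmax·c/(Kd + c)` for microsome titrations at the
  0–800 nM design, dose-response plateau estimation, motif-ranked binding
  comparisons with Welch/Holm tests. `fitSaturation()`,
  `doseResponsePlateau()`, `compareMotifBinding()`.
* **Trafficking simulation** — deterministic mass-action steady states
  under synthesis + bulk flow + competitively shared receptor export
  (`dC_i/dt = s_i − k_bulk·C_i − V_r·(C_i/K_i)/(1 + Σ_j C_j/K_j)`),
  coexpression and receptor-knockdown experiments, aggregation-threshold
  flags. `solveSteadyState()`, `knockdownExperiment()`.
* **Alignment** — global Needleman–Wunsch/Gotoh with affine gaps,
  BLOSUM62, unpenalized end gaps and identity over the full alignment
  length, for receptor-ortholog comparisons. `globalAlign()`.
* **Synthetic data** — seeded generators for every input above.
  `genProteome()`, `genSteadyStateTable()`, `genBindingData()`,
  `genScenarios()`, `genDivergedPair()`.

A thin command-line wrapper (`inst/exec/erescape`) exposes
`score / scan / survey / calibrate / bindfit / simulate / align / gen`
subcommands over the same functions.

## Worked example

```r
library(erescape)

classifyTripeptides(c("IPV", "FSM", "KVH", "EET", "FPV"))
#> DataFrame with 5 rows and 5 columns
#>    tripeptide     score      klass exception_applied     rule_id
#>   <character> <numeric>   <factor>         <logical> <character>
#> 1         IPV       3.0 strong                 FALSE          NA
#> 2         FSM       2.0 modest                 FALSE          NA
#> 3         KVH       0.5 modest                  TRUE  KVH-modest
#> 4         EET      -2.0 nonbinding             FALSE          NA
#> 5         FPV       3.0 modest                  TRUE  FPV-modest
```

IPV (the wild-type DSPP start) scores +3 — favorable residues at all
three positions — and classifies *strong*. FSM, the conserved bone
sialoprotein Φ-S-Φ start, loses the position-2 proline contribution and
is *modest*. The diacidic EET is forced *nonbinding* by the ≥2-acidic
rule, and FPV/KVH show the documented exception overrides (a consensus
motif measured weaker than predicted; a non-consensus motif measured
positive).

Tally a tripeptide survey with the consensus predicate — here the bundled
survey of mating-factor alpha-1 starts across budding yeasts:

```r
svy <- readSurveyTable(system.file("extdata", "mfa1_tripeptide_survey.tsv",
                                   package = "erescape"))
tallySurvey(svy, isPhiPPhi)    # 35 of 44 starts are Φ-P-Φ (24 are APV)
```

Fit a noisy synthetic titration at the standard six-concentration design:

```r
fitSaturation(genBindingData(bmax = 100, kdTrue = 250, b0 = 5,
                             noiseSd = 0.05, seed = 1))
#> BindingFit (single-site, Hill = 1 )
#>   Bmax = 99.21 (SE 3.95)
#>   Kd   = 242.6 (SE 27.7)
#>   b0   = 5.327 (SE 1.63)
#>   converged: TRUE  saturable: TRUE
```

The recovered half-maximal concentration (243 nM here) falls in the
200–300 nM range characteristic of a strong motif binding its receptor.

Simulate receptor knockdown for a strong vs a modest binder:

```r
sc <- genScenarios()[["knockdown-grid"]]
knockdownExperiment(sc$strong, sc$modest, sc$kBulk, sc$vr, sc$factors)
#>   factor  vr conc_strong conc_modest ratio
#> 1   1.00 2.0       0.175        2.63 15.01
#> 2   0.50 1.0       1.934        8.27  4.28
#> 3   0.20 0.4       6.313        9.72  1.54
#> 4   0.10 0.2       8.126        9.89  1.22
#> 5   0.05 0.1       9.057        9.95  1.10
```

Both steady states rise as receptor capacity falls, with the strong
binder always lower in absolute terms; see the methods vignette
(`vignettes/erescape-methods.Rmd`) for why the concentration *ratio*
relaxes toward the bulk-flow limit even though the strong cargo keeps the
larger receptor flux share.

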