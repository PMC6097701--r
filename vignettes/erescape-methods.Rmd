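---
title: "ER-ESCAPE motifs: scoring model, calibration and receptor-limited export simulation"
author: "erescape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ER-ESCAPE motifs: scoring model, calibration and receptor-limited export simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erescape)
```

## The biological problem

Roughly half of all human proteins enter the endoplasmic reticulum (ER).
Soluble cargo destined for secretion can leave by passive diffusion into
forming COPII vesicles ("bulk flow"), but for proteins that polymerize or
aggregate at low concentration — dentin sialophosphoprotein (DSPP),
amelogenin, matrix proteins, hormones stored in granules — bulk flow is too
slow: their lumenal concentration would climb past the point where damaging
intralumenal aggregates form. The cargo receptor Surf4 (Erv29p in yeast)
solves this by binding the first three residues of the mature protein — the
tripeptide exposed after signal-peptide cleavage, called the **ER-ESCAPE
motif** — and loading cargo into COPII vesicles. Motif composition sets the
receptor affinity, the affinity sets the steady-state ER concentration,
and differential affinities prioritize export of the most
aggregation-prone proteins when receptor becomes limiting.

This package implements that conceptual model end to end as computable
pieces: a per-position contribution model for the tripeptide; extraction of
tripeptides from annotated protein sequences; calibration of the score
against reporter steady-state measurements; saturation-binding fits for
receptor titration data; a mass-action competition model of ER exit; and
global protein alignment for receptor-ortholog comparisons. A seeded
synthetic-data module generates every input the pipeline consumes so all
stages are testable offline.

## The additive motif model

Each position `p` in 1..3 and residue `a` carries an ordinal contribution
class (favorable / neutral / unfavorable) and a numeric weight `w(p, a)`.
The tripeptide score is the plain sum
`S(t) = w(1, t1) + w(2, t2) + w(3, t3)`.

The default table (`defaultWeightTable()`) encodes the experimental
picture:

* the hydrophobic set Φ = `r paste(phiSet(), collapse = ", ")` is favorable
  at positions 1 and 3 but **not** at position 2 (neutral there);
  tryptophan, though hydrophobic, is untested and deliberately excluded
  from Φ;
* proline is favorable at position 2 (the Φ-P-Φ consensus) and
  unfavorable at position 3;
* serine and threonine are favorable at position 1 (SPV and TPV traffic
  like IPV) but neutral at positions 2 and 3 (Φ-S-Φ motifs are modest,
  not strong);
* arginine is favorable at every position; lysine is weakly favorable
  (+0.5, strictly below arginine — "R better than K");
* aspartate and glutamate are unfavorable everywhere, and glutamine is
  unfavorable at positions 1 and 2 (glutamines mark deliberate
  nonbinders such as chaperones and fibrillar collagens);
* untested residues (C, G, H, W) default to neutral and are tagged
  `default-neutral` so users can see where the table is thin. Each entry
  carries a provenance tag (`paper-stated`, `paper-implied`,
  `default-neutral`).

The numeric scale is favorable = +1, neutral = 0, unfavorable = −1 (K
= +0.5). The experimental evidence is ordinal, so the scale is a modeling
choice and the whole table is serializable to TSV
(`writeWeightTable()` / `readWeightTable()`) for users who want a
different encoding.

### Classification thresholds

`classifyTripeptides()` partitions scores into `strong` /
`modest` / `nonbinding` with inclusive thresholds
(`defaultThresholds()`: strong at ≥ +2.5, nonbinding at ≤ −1; boundary
scores take the higher class). The strong cutoff sits between +2 and +3
deliberately: under the +1/0/−1 encoding, two-favorable motifs such as
FSM, ISV, ITV and FPT score exactly +2 and are experimentally *modest*,
while all-favorable motifs score +3 and their lysine variants (e.g. KPV)
score +2.5. A cutoff at +2 would misclassify the whole Φ-S-Φ family as
strong; +2.5 reproduces the observed partition on every tested
tripeptide. Both thresholds remain arguments, not constants.

Two overrides run after additive scoring:

1. **Hard acidic rule** — two or more D/E residues force `nonbinding`
   regardless of score. Diacidic reporters (EET, EEE) always sat at the
   highest steady-state levels.
2. **Documented exceptions** (`defaultExceptionRules()`) — FPV (a
   consensus motif that measured only modest) and KVH (no position-2
   proline/serine yet measurably positive) are forced to `modest`, each
   rule carrying a citation note. Removing the exception list reproduces
   pure additive behaviour, which the test suite checks as a regression.

## Sequence handling

`readMatureRecords()` pairs FASTA sequences with 1-based mature-start
annotations (from SignalP/Phobius or experiment — signal-peptide
prediction is consumed, never reimplemented) and extracts the tripeptide
at `[mature_start, mature_start + 2]`. Coordinates are 1-based inclusive
to match how biologists cite positions (a "P17L" mutation is position 17
of the precursor). Per-record problems (out-of-range starts, ambiguous
residues in the window) are collected in a report instead of aborting a
batch; duplicate ids are a hard error; `*` stop characters are stripped
with a warning. A deliberately crude A-X-A fallback
(`guessMatureStart()`) exists for unannotated input and is documented as
unvalidated.

Survey tables (gene, taxon, species, accession, tripeptide, count) support
predicate tallies (`tallySurvey()`), e.g. counting Φ-P-Φ starts of
mating-factor alpha-1 across budding yeasts with `isPhiPPhi`. The bundled
`mfa1_tripeptide_survey.tsv` fixture stores that survey as itemized
per-tripeptide counts (24 APV, 8 API, 1 IPV, 1 VPA, 1 APA, 4 APT, 4 AIA,
1 TAI — 44 records, 35 of them consensus starts); species and accession
columns are intentionally `NA` because only the counts are itemized in
the source.

## Calibration: score versus steady-state level

Reporter steady-state levels (ng cargo per mg protein) are comparable only
within an experiment, so `normalizeToReference()` divides each experiment
group by the mean of its reference rows (IPV), making the reference 1 by
construction. Replicates aggregate to mean ± SEM (at least three
replicates per construct in the emulated design).

`fitMonotone()` then fits a least-squares **monotone non-increasing**
step function of mean level on score — stronger motifs must not sit
higher — using pool-adjacent-violators. Score ties are pooled first into
weighted observations (weights = replicate counts), the standard
secondary tie handling. The weighted PAV is authored here because the
base isotonic routine is unweighted; the test suite compares it
pointwise against an independent naive merge-until-monotone oracle on
random instances (n ≤ 60). Spearman's rho between score and level is the
headline diagnostic (negative; `-1` only when scores are untied).
`concordanceReport()` flags residuals beyond a MAD-standardized threshold
(default 3) as exception-rule candidates — constructing a table with FPV
displaced upward flags exactly that motif.

## Saturation binding

`fitSaturation()` fits the single-site Langmuir isotherm with additive
background, `B(c) = b0 + Bmax·c/(Kd + c)`, by bounded Levenberg–Marquardt
least squares. The emulated design is the six-point titration 0, 100,
200, 300, 400, 800 nM. Choices:

* a Hill exponent is exposed but fixed (default 1), not fitted — four free
  parameters on six concentrations would be overparameterized;
* initialization: `b0` = min signal, `Bmax` = range, `Kd` = concentration
  nearest the half-range signal; all parameters bounded at 0;
* non-convergence and background-only ligands (a diacidic nonbinder gives
  a flat titration) return a *flagged* fit, never an exception: the fit is
  called non-saturable when the optimizer fails, `Bmax < 2·SE(Bmax)`, or
  `SE(Kd) > 10·Kd`;
* the identity `B(Kd) = b0 + Bmax/2` holds on every converged fit by
  construction and is asserted to 1e−12 in the tests.

`doseResponsePlateau()` estimates detergent-permeabilization plateaus as
the smallest dose whose isotonic-fitted response reaches within 5% of the
upper asymptote (flat data plateau at the minimum dose; curves still
rising at the top dose are right-censored and flagged).
`compareMotifBinding()` ranks per-motif signals and runs two-sided Welch
tests against reference motifs (APV and EET), Holm-corrected — the
published comparisons report per-pair significance without naming a
correction, so the conservative familywise choice is made explicit here.

## The trafficking model

`solveSteadyState()` finds the steady state of

$$\frac{dC_i}{dt} = s_i \;-\; k_{bulk}\,C_i \;-\;
V_r\,\frac{C_i/K_{d,i}}{1+\sum_j C_j/K_{d,j}}$$

— synthesis, first-order bulk flow, and saturable receptor export shared
competitively through a single pooled receptor under quasi-steady-state
binding. This is the simplest rate law consistent with the verbal model
(shared limiting receptor, per-cargo dissociation constant,
prioritization); whether the receptor binds cargo before or only during
COPII engagement is deliberately left open — the pooled law is agnostic.
`Kd = Inf` encodes a nonbinder, `Vr = 0` removes the receptor, and units
are abstract (nondimensionalized concentration and time).

The solver is a damped Newton iteration with analytic Jacobian, positivity
projection and halving line search, run from two independent starts
(bulk-only solution and near zero) with a built-in agreement check and a
relaxation fallback; residual tolerance is 1e−10 relative to synthesis.
The test suite checks it against independent long-time ODE integration at
relative tolerance 1e−6, the exact bulk-only closed form
`C* = s/k_bulk`, flux conservation per cargo, scale invariance, and the
priority ordering (equal synthesis, smaller Kd ⇒ strictly smaller
steady state).

Aggregation is a threshold *flag* (`C* ≥ C_agg`, inclusive at the
boundary), not a simulated sink — aggregates demonstrably form, but no
kinetics are available to parameterize a loss term, so
`aggregationFlags()` reports the flag and the margin instead of inventing
dynamics.

### What receptor depletion does to the modest:strong ratio

`knockdownExperiment()` scales `Vr` down a factor grid and reports the
concentration ratio of a modest to a strong binder. One direction claim
deserves care. Intuition (and the motivating siRNA experiment) suggests
the ratio should *rise* as receptor is depleted, because the strong cargo
is prioritized. Under the competitive rate law above, the opposite holds
for the solved concentrations, provably: the ratio is
$(s_m K_{d,m})/(s_s K_{d,s})$-bounded in the receptor-rich limit and
relaxes monotonically to the bulk-only limit $s_m/s_s$ (= 1 at equal
synthesis) as $V_r \to 0$. The strong binder is held *lowest* while
receptor is abundant, so it has the most ground to lose; a random scan of
300 parameter sets over several decades of every rate never produced a
single increase. Prioritization is still real in the model — the strong
cargo keeps the larger receptor flux share at every depletion level, and
both absolute concentrations rise monotonically — but it shows in the
flux partition, not in a rising concentration ratio. The observed rise of
the measured intracellular ratio in cells must involve features this
minimal law omits (aggregated pools, non-steady harvest times, or
cooperative engagement thresholds); the package reports what the law
actually predicts rather than forcing the expected sign.

## Alignment

`globalAlign()` is a full Needleman–Wunsch/Gotoh dynamic program with
affine gaps (gap of length L costs `open + L·extend`; defaults BLOSUM62,
10, 0.5) written here rather than delegated, because the installed
aligner's ends-free mode clips unaligned ends from its traceback, which
changes both the displayed alignment and the identity denominator.
Conventions, each of which changes the reported number and is therefore
explicit:

* end gaps are **unpenalized by default** (toggleable) but still appear
  in the alignment;
* percent identity = identical columns / **total alignment length
  including gap columns** × 100;
* traceback ties break deterministically: diagonal over gap-in-second
  ("up") over gap-in-first ("left").

Tests compare scores against exhaustive enumeration of *all* global
alignments on short pairs (both end-gap policies) and against the
installed aligner for the end-gap-penalized mode on longer pairs. The
cross-kingdom receptor comparison (human Surf4 vs yeast Erv29p, about 30%
identity) runs through `alignReceptorOrthologs()` on user-supplied FASTA
files; the package performs no remote fetching, and the bundled
stand-in for pipeline demonstrations is an explicitly synthetic diverged
pair (`genDivergedPair()`).

## Synthetic data: what it does and does not show

Every generator takes a mandatory seed (no silent global RNG; the global
seed state is restored afterwards) and emits a ground-truth sidecar.

* `genProteome()` — signal peptide (M + random core + A-X-A cassette) plus
  a mature region whose tripeptide is drawn from a spectrum. It emulates
  annotated secreted proteins structurally, **not** real signal-peptide
  statistics: passing tests show the extraction and bookkeeping are
  correct, not that the heuristic would find real cleavage sites.
* `genSteadyStateTable()` — the 60-motif reporter panel split across
  experiment groups with per-group scales, reference rows in every group,
  and levels `link(score) × lognormal noise`. The default link
  `exp(0.45·(3 − score))` places diacidic nonbinders ≈ 9.5-fold above the
  reference, matching the dynamic range such reporters show; noise is
  multiplicative lognormal because abundances are positive. Real data
  would add construct-specific deviations (that is exactly what the
  exception machinery is for).
* `genBindingData()` — the six-concentration titration with ~5%
  multiplicative noise plus a small additive floor; `bmax = 0` produces
  the flat nonbinder curve.
* `genScenarios()` — three named receptor scenarios (coexpression
  invariance under excess, the knockdown grid, a receptor-null
  aggregation case) with their expected qualitative outcomes attached.

## Problem sizes and runtime choices

The shipped tests run the full 8,000-tripeptide enumeration, 60-motif
calibration tables, 200-replicate Kd-recovery simulations at the
six-point design, exhaustive alignment enumeration up to length 6, and
two-cargo ODE cross-checks — sizes chosen so the whole suite completes in
a few minutes while still exercising every code path at the scale of the
emulated experiments.

## Known limitations

* The contribution table is ordinal evidence forced onto a numeric scale;
  modest-affinity calls are correspondingly soft (the original
  interpretation is itself described as subjective for mid-range motifs).
* Exception rules are enumerative, not predictive; they encode measured
  departures (FPV, KVH) and nothing else.
* The trafficking model is well-mixed and deterministic: no ER exit-site
  geometry, COPII budding mechanics, chaperone competition, UPR/ERAD
  feedback, or stochasticity; aggregation is a flag, not a sink (an
  irreversible-loss mode would need kinetics nobody has measured).
* The binding model assumes one independent site and fixed Hill
  coefficient; titrations with six concentrations cannot distinguish
  richer schemes.
* Percent identity depends on alignment conventions; numbers from tools
  with other end-gap policies or denominators are not directly
  comparable.
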