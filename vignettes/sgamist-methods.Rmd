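---
title: "Models and methods: scoring genetic interactions of a mistranslating tRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: scoring genetic interactions of a mistranslating tRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgamist)
library(dplyr)
```

## The biological problem

tRNA-Ser variants carrying a proline anticodon (tRNA-Ser(UGG)) charge serine
but read proline codons, so a few percent of proline positions across the
proteome end up as serine. Cells buffer this proteotoxic load through
redundant tRNA isodecoders and protein quality control, but hypomorphic
mutations elsewhere in the genome can make an otherwise tolerated
mistranslation level costly. `sgamist` packages the quantitative workflow for
studying that genotype-by-mistranslation interaction in budding yeast:

1. score a synthetic genetic array (SGA) screen of a mistranslating query
   strain against a temperature-sensitive (ts) allele collection;
2. validate hits by spot assays against the multiplicative expectation;
3. estimate doubling times from OD600 growth curves;
4. measure the proline-to-serine substitution frequency from
   peptide-spectrum-match (PSM) tables;
5. classify how the strength of a synthetic interaction responds to graded
   mistranslation levels.

Every stage has a synthetic-data generator with planted ground truth, so the
whole pipeline is testable end to end without any external data.

## The multiplicative interaction model

For a ts allele A and the mistranslating query B, the interaction score is

$$\varepsilon = W_{AB} - W_A\, W_B$$

with fitness measured from colony sizes (wild type = 1). Under the
multiplicative null, a double mutant grows as the product of its single
mutants; negative deviations mark synthetic sickness. An allele is called a
negative interaction when the mean replicate score falls below −0.2 with a
Benjamini–Hochberg adjusted p-value below 0.05; positive calls mirror the
rule at +0.2. The magnitude gate matters: with quadruplicate replicates a
tiny but consistent deviation can be statistically significant while being
biologically trivial, so both gates must pass.

The positive threshold deserves a note: only the negative rule is anchored in
the screen design, and symmetric mirroring at +0.2 is the least arbitrary
default. Positive calls should be treated as candidates for mechanistic
follow-up (e.g. anticodon suppression of the ts lesion) rather than as a
calibrated class.

### Normalization and the fitness reference

Colony arrays carry systematic spatial artifacts: nutrient and incubation
gradients across a plate and pinning differences between plates. The default
correction (`normalize_plates(mode = "medpolish")`) median-polishes log
colony sizes per plate and removes the row and column effects, keeping the
overall plate level and the residuals. The effects are centred to mean zero
over informative rows/columns, so the correction reshapes the plate without
moving its size scale — important because the double-mutant and control
plates are polished independently and their levels must stay comparable. A
`"scale"` mode additionally maps each plate median onto a common reference
median for multi-plate screens with pinning drift. Corrections are
multiplicative throughout: a dead colony (size 0) stays dead, and missing
colonies (contamination, pinning failures) are first-class `NA`s excluded
from every statistic, never imputed.

Absolute fitness needs a reference: the colony size a no-defect strain
reaches under the same pinning conditions. On arrays where most strains grow
near wild type, the plate median is a workable proxy; a ts collection at
semi-permissive conditions violates that assumption badly (its median
fitness is well below 1), and using the plate median would shrink every
$\varepsilon$ by the inverse median fitness. `fitness_table()` therefore
takes an explicit `reference` colony size — calibrated from control
positions in a real screen, and supplied by the scenario in simulations.
This is a deliberate design choice: a wrong but explicit reference is
auditable, a silent plate-median assumption is not.

### Replicates, the query fitness and the test

Each allele sits in a technical quadruplicate 2×2 block (the standard
384-to-1,536 condensation; the geometry is verified when a key is read).
Per-replicate double-mutant fitness is retained — premature averaging would
hide replicate dispersion, which is exactly what the test uses. The query
single-mutant fitness $W_B$ is shared by all alleles. When it is not
supplied, it is estimated as the median over scorable alleles of
$\overline{W_{AB}}/W_A$: with interactions sparse, $W_{AB} = W_A W_B$ for
the large majority of alleles, and the median is robust to the interacting
minority. (The median of single-mutant fitness on the control array is *not*
a valid estimate here, for the same reason the plate median is not a valid
reference.)

Per-allele p-values come from a one-sample two-sided t-test of the
replicate scores against zero — the minimal defensible choice for
quadruplicates; with only 3 degrees of freedom it is underpowered for small
effects, which the −0.2 magnitude gate compensates. Replicates with zero
variance (noise-free simulations) are handled explicitly: p = 1 when the
mean is zero, p = 0 otherwise, rather than a spurious error. The
published-screen convention of scoring across plates rather than within
quadruplicates is not documented anywhere we could verify; the
within-quadruplicate test is the package's stated choice.

Alleles with fewer than 2 usable replicates in either cross are reported as
unscorable (`call = "none"`, no p-value) rather than imputed.

## Spot-assay validation

Validation remakes each double mutant and spots it alongside both single
mutants and a control. Fitness is mean spot intensity relative to the mean
control intensity; the expected double-mutant fitness is the product of the
single-mutant fitnesses, and a hit validates when observed/expected falls
below `theta`. The strict multiplicative rule is `theta = 1`; the default
0.9 leaves a 10% margin against intensity noise, since the point-estimate
rule uses no replicate-level test (matching how such validations are read by
eye). `theta` is exposed; with `theta = 1` on noise-free data the call
equals the sign of $\varepsilon$ exactly, which is tested.

## Logistic growth and doubling time

OD600 series (15-min sampling over 24 h) are fitted with the three-parameter
logistic

$$N(t) = \frac{K}{1 + \frac{K - N_0}{N_0} e^{-rt}},$$

by Levenberg–Marquardt least squares; the doubling time is $\ln 2 / r$ in
the input's time units. Starting values are $K \leftarrow \max(\mathrm{OD})$,
$N_0 \leftarrow \mathrm{OD}(0)$ and $r$ from the slope of log-OD over the
steepest 5-point window; parameters are bounded positive, the relative
tolerance is $10^{-8}$ and at most 500 iterations are allowed. There is no
lag-phase term: cultures diluted from saturated growth resume quickly, and
the carrying-capacity and exponential phases dominate the fit; doubling
times of strongly lagged curves will absorb part of the lag into $r$ and
should be read accordingly. Non-growing series return `converged = FALSE`
with the reason, never a fabricated rate. Against noiseless curves the
recovered doubling time is accurate to well under 0.1%; with 0.01 OD
Gaussian noise, to about 2% — both are asserted in the test suite at the
84 min (control) and 98 min (mistranslating) regimes.

## Mistranslation frequency from PSM tables

The substitution frequency is estimated from post-search PSM tables (the
package deliberately consumes search output: database search and rescoring
are out of scope). Records are filtered to a 1% FDR at the PSM level, then
mistranslated peptides (≥1 serine-for-proline site, −10.0207 Da on a
proline) are qualified by the **sibling rule**: the identical reference
sequence must also be observed unmodified among the retained records.
Without a sibling, a mistranslated identification is weaker evidence (the
unmodified form is almost always more abundant and more detectable), so
unqualified peptides leave both the numerator and the denominator — the
conservative reading. The frequency is then

$$f = 100 \times
  \frac{\text{counts of qualified mistranslated peptides}}
       {\text{counts of all retained peptides whose reference sequence contains Pro}}.$$

Two counting conventions are implemented because the field mixes them:
spectral counts (default; every spectrum votes) and unique peptide forms
(every distinct form votes once). A peptide with two substitution sites
counts once — the counting unit is the mistranslated peptide observation —
with a per-site mode behind a flag. Mass shifts are matched to a
modification catalogue within ±0.01 Da, generous for the monoisotopic
deltas in play yet far below the spacing between catalogued shifts; a shift
placed on the wrong residue is a hard error, and more than two occurrences
of one variable modification rejects the record with a warning (mirroring
the search-engine constraint), with rejected rows reported so that no input
row ever disappears silently.

## Dose-response classification

With the tRNA gene under regulatable expression, each strain is assayed at
three mistranslation levels (low/medium/high, nominally 0.9%, 3.5% and 5.6%
substitution, against a 0.3% background with the wild-type tRNA). Growth is
first normalized within strain (percent of the same strain carrying the
wild-type tRNA), then expressed relative to the wild-type strain at the
same level; 100% means no synthetic interaction beyond the general cost of
mistranslation. Uncertainty is propagated by a seeded bootstrap over
replicates (1,000 draws by default) rather than the delta method, matching
the mean ± sd style in which such assays are reported.

The response patterns form a continuum; the four categories are an
operationalization with all constants exposed
(`dose_response_constants()`):

* **uniform** — spread ≤ 10 points across levels;
* **proportional** — low ≥ 90 and strictly decreasing;
* **threshold** — 75 ≤ low < 90 with medium and high both < 75 and within
  10 points of each other (a plateau);
* **low_sensitive** — deficit at low ≥ 0.6 × deficit at high;
* remaining profiles fall back by the `low` band (≥ 90 → proportional,
  else threshold).

Two structural properties drove the design. First, the rule set is total
and single-valued: every admissible triple maps to exactly one category
(verified exhaustively on a 1-point grid over [0, 120]³). Second, the
`low < 90` band on `threshold` makes classification stable under a
worsening high-level effect: lowering the high-level value can never
relabel a threshold profile as proportional, because proportional is
reserved for profiles with essentially no low-level interaction. Without
the band, a profile like (95, 70, 72) would sit in `threshold` and jump to
`proportional` as the high-level effect deepens — an artifact, not a
biological statement. The constants are decisions, not measured
quantities, and are deliberately configurable.

Group comparisons (substitution frequency, doubling time, reporter
induction between strains) use Welch's unequal-variance t-test with
Bonferroni correction, `min(1, m · p)`, with `m` overridable for
externally defined comparison families.

## What the generators emulate — and what they do not

* `simulate_screen()`: colony size = reference × fitness × linear row/col
  gradient × lognormal noise, in quadruplicate 2×2 blocks with blank corner
  blocks (380 alleles + 4 blanks = 384 blocks per 1,536 plate). Defaults:
  1,000 alleles, single-mutant fitness uniform on [0.5, 1], query fitness
  0.86 (the ratio of control to mistranslating doubling times, 84/98),
  noise sd(log) 0.05, gradient amplitude ±10%, reference 500 area units.
  Lognormal noise reflects positive, right-skewed colony sizes. Planted
  scores are validated for feasibility ($\varepsilon \ge -W_A W_B$).
* `simulate_psms()`: per-observation substitution with probability `f` at a
  uniformly chosen proline site, q-values split cleanly around the 1%
  cutoff, optional sibling dropout. Default depth 20,000 spectral counts
  keeps the binomial error of the recovered percentage near 0.15 points.
* `simulate_growth()`: logistic curves on the 15-min/24-h schedule with
  additive Gaussian OD noise (sd 0.01).
* `simulate_spots()`: the wild-type strain follows the near-linear dose
  profile 71%/55%/37% of its wild-type-tRNA growth; other strains multiply
  that by their planted interaction factor, so the planted relative
  synthetic effect is 100 × factor.

All generators are pure functions of scenario + seed (asserted by identity
of repeated runs, including byte-identical written files).

What they do **not** emulate: competition between neighbouring colonies,
non-separable (non-row/column) spatial artifacts, batch effects between
plates pinned on different days, chimeric or co-eluting spectra and
FDR-estimation error in the PSM tables, lag phases and diauxic shifts in
growth curves, and saturation of spot intensities. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated noise
model, not robustness to every artifact of real bench data.

## Numerical choices and degenerate inputs

* Missing colony ≠ dead colony: `NA` is excluded from statistics, 0 is a
  fitness observation.
* Plates with < 50% usable positions are rejected for normalization;
  all-missing plates are an error.
* BH adjustment is the standard step-up via `stats::p.adjust`; `NA`
  p-values (unscorable alleles) pass through untouched.
* Constant-replicate t-tests and constant-group Welch tests degrade to
  p ∈ {0, 1} by the sign of the effect instead of erroring.
* The bootstrap, every generator, and the pipeline are seeded; the
  pipeline manifest records a configuration hash so reruns are verifiable.

## Problem sizes used in the checks

The automated checks run 200 all-null screens of 1,000 alleles ×
4 replicates for false-call behaviour, one 1,000-allele screen with 20
planted interactions at $\varepsilon = -0.4$ for recall and accuracy,
~20,000-count PSM tables for frequency recovery, 4 replicate growth curves
per strain at the 84/98 min regimes, and the exhaustive 121³ classification
grid. These sizes were chosen so the complete suite exercises every claim
at full statistical scale while remaining comfortable on a single CPU.

## Known limitations

* The fitness reference must be supplied or calibrated; there is no magic
  recovery of absolute fitness from a ts-biased array.
* The within-quadruplicate t-test treats technical replicates as the unit
  of replication; biological replication across independent crosses would
  require a hierarchical extension.
* Spatial correction is limited to separable row/column effects.
* The dose-response categories are descriptive bins over a continuum;
  boundary profiles are sensitive to the configured constants by design.
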