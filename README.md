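# sgamist

Quantitative analysis of genetic interactions with mistranslating tRNAs in
*Saccharomyces cerevisiae*.

tRNA-Ser variants carrying a proline anticodon insert serine at proline
codons across the proteome. Whether a cell tolerates that depends on its
genetic background: hypomorphic alleles in protein quality control, RNA
processing and related pathways turn a tolerated mistranslation load into a
growth defect. `sgamist` implements the analysis workflow for mapping and
dissecting those interactions:

* **SGA interaction scoring.** Colony arrays of a mistranslating query strain
  crossed to a temperature-sensitive allele collection are normalized
  (median-polish gradient correction, optional plate rescaling) and scored
  under the multiplicative model,

  ε = W<sub>AB</sub> − W<sub>A</sub> · W<sub>B</sub>,

  with per-replicate scores from technical quadruplicates, one-sample
  t-tests, Benjamini–Hochberg correction, and the joint call rule
  ε < −0.2 and q < 0.05 (positives mirrored at +0.2).
* **Spot-assay validation** of hits against the multiplicative expectation
  W<sub>AB</sub><sup>exp</sup> = W<sub>A</sub>·W<sub>B</sub>.
* **Growth kinetics.** Logistic fits of OD600 curves
  (N(t) = K / (1 + ((K−N0)/N0)·e<sup>−rt</sup>)) with doubling time ln 2 / r,
  broom-style `tidy()`/`glance()`/`autoplot()` methods.
* **Mistranslation frequency** from peptide-spectrum-match tables: 1% PSM-level
  FDR filter, sibling-peptide qualification, and frequency = counts of
  Pro→Ser peptides / counts of all Pro-containing peptides, as a percentage.
* **Dose–response classification** of synthetic-interaction strength across
  low/medium/high regulated mistranslation levels into four categories
  (proportional, threshold, uniform, low-sensitive), plus Welch/Bonferroni
  group comparisons.
* **Synthetic data generators** for every input kind with planted ground
  truth (interaction scores, substitution rates, doubling times, dose
  profiles), making the full pipeline testable offline.

All user-facing functions take data frames and return tibbles, so stages
compose with the pipe; plain TSV/CSV readers and writers cover every input
format (`read_plate_table()`, `read_array_key()`, `read_psm_table()`,
`read_spot_table()`, `read_od_table()`).

## Worked example

Simulate a 1,000-allele screen with 20 planted interactions (ε = −0.4),
score it, and look at the strongest calls:

```r
library(sgamist)
library(dplyr)

set.seed(1)
planted <- tibble(allele = sample(1000, 20), eps = -0.4)
sim <- simulate_screen(screen_scenario(n_alleles = 1000, interactions = planted, seed = 1))

hits <- score_screen(sim$doubles, sim$controls, sim$key, reference = 500)
hits |> filter(call == "negative") |> select(allele, w_a, eps_mean, p_raw, q_bh, call) |> head(5)
#> # A tibble: 5 × 6
#>   allele   w_a eps_mean       p_raw     q_bh call
#>   <chr>  <dbl>    <dbl>       <dbl>    <dbl> <chr>
#> 1 ts0270 0.780   -0.534 0.000000666 0.000138 negative
#> 2 ts0874 0.764   -0.486 0.00000170  0.000243 negative
#> 3 ts0277 0.690   -0.430 0.00000538  0.000598 negative
#> 4 ts0299 0.565   -0.426 0.000000810 0.000138 negative
#> 5 ts0679 0.696   -0.418 0.00000278  0.000347 negative
sum(hits$call == "negative")
#> [1] 20
```

All 20 planted interactions are recalled, none of the 980 null alleles is
called. Doubling times from simulated growth curves at the control and
mistranslating regimes:

```r
g <- simulate_growth(
  tibble(strain = c("control", "tS(UGG)"), doubling_time = c(84, 98)),
  replicates = 4, seed = 2
)
fit_growth_curves(g$od) |> group_by(strain) |> summarise(doubling_min = mean(doubling_time))
#> # A tibble: 2 × 2
#>   strain  doubling_min
#>   <chr>          <dbl>
#> 1 control         83.9
#> 2 tS(UGG)         97.4
```

Substitution frequency from a simulated PSM table with a planted 4.9%
per-observation Pro→Ser rate:

```r
ps <- simulate_psms(proteome_scenario(f = 0.049, seed = 3))
mistranslation_frequency(validate_psm_tbl(ps$psms))
#> # A tibble: 1 × 5
#>   n_mistranslated n_pro_total frequency_pct n_qualified_unique_peptides excluded_no_sibling
#>             <int>       <int>         <dbl>                       <int>               <int>
#> 1             846       17953          4.71                         293                   0
```

Dose–response classification of a strain whose planted relative synthetic
effect is (95, 70, 40)% at low/medium/high mistranslation:

```r
fac <- tibble(strain = "ctf8-like", level = c("low", "medium", "high"),
              factor = c(0.95, 0.70, 0.40))
sp   <- simulate_spots(fac, seed = 4)
prof <- normalized_growth(sp$spots, seed = 4)
classify_profiles(relative_synthetic_effect(prof))
#> # A tibble: 1 × 5
#>   strain    rel_low rel_medium rel_high category
#>   <chr>       <dbl>      <dbl>    <dbl> <chr>
#> 1 ctf8-like    91.8       69.4     38.0 proportional
```

`rel_*` are percentages of the wild-type strain's normalized growth at the
same mistranslation level — 100 means no synthetic interaction beyond the
general cost of mistranslation. The whole flow is also available as a single
configured run (`run_config()` / `run_pipeline()`), which persists every
stage's TSV outputs and a provenance manifest.

See `vignettes/sgamist-methods.Rmd` for the models, assumptions, parameter
choices and known limitations.

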