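# tpprank

Prioritising candidate medicines in an R&D pipeline against target product
profiles (TPPs).

Conditions with a crowded but unfocused drug pipeline — the package ships
worked data for pre-eclampsia, a hypertensive disorder of pregnancy and a
leading cause of maternal mortality — need a systematic, drug-agnostic way
to decide which candidates merit further investment. `tpprank` implements
a TPP-matching triage for exactly that audience: pipeline analysts, funders
and product-development groups working from a curated candidate registry.

The pipeline:

1. **Screen** the registry with six exclusion rules (approved/marketed,
   recommended/routine use, subgroup-only use, negative-outcome inactive,
   symptom-only target, inferior to current care), reporting a reason code
   per excluded candidate.
2. **Reconcile** dual-reviewer TPP assessments per candidate-indication
   pair: agreement stands, disagreements go to a third reviewer, anything
   unresolved stops the run with the conflict named.
3. **Score** each candidate on nine critical TPP criteria (setting,
   efficacy, companion diagnostic, clinical monitoring, safety, mode of
   administration, adherence, stability, WHO EML status) using

   total = Σ_c w_c · s(ℓ_c)

   with level scores s = 0/1/2/3 for not met / partially met / met
   minimum / met preferred (`unknown` scores 0 but is tracked through a
   completeness fraction) and efficacy and safety double-weighted.
4. **Rank** by the normalised score r = total / max attainable against
   per-phase thresholds (defaults: high ≥ 0.60, medium ≥ 0.40), giving
   high / medium / low potential. Score coding, weights and thresholds are
   a replaceable configuration (`read_scheme()`), so an external coding
   table drives the identical engine.
5. **Report**: traffic-light matrices (CSV/HTML/SVG/ggplot2), landscape
   summaries by activity, phase, product type and archetype, and a
   preclinical taxonomy.

A seeded generator (`simulate_registry()`) produces registries with
planted exclusion flags, match profiles and ranks for end-to-end
validation, and `run_cli()` (wrapper script in `inst/cli/tpprank.R`)
exposes the stages as `validate` / `screen` / `rank` / `summarize` /
`report` / `simulate` subcommands.

## Worked example

The bundled clinical registry holds the 32 unique pre-eclampsia candidates
retained for TPP matching (prevention: 10 phase III, 5 phase II, 2 phase I;
treatment: 4 phase III, 9 phase II, 6 phase I; four candidates appear for
both indications). With illustrative reviewer assessments:

```r
library(tpprank)
library(dplyr)

reg <- example_clinical_registry()
pairs <- reg |>
  select(candidate_id, indications) |>
  tidyr::unnest_longer(indications, values_to = "indication")
grid <- tidyr::crossing(pairs, criterion_id = tpp_criteria()$criterion_id)
set.seed(2021)
grid$level <- sample(c(informative_levels(), "unknown"), nrow(grid),
                     replace = TRUE, prob = c(.15, .2, .3, .25, .1))
asmt <- bind_rows(mutate(grid, reviewer_id = "A"),
                  mutate(grid, reviewer_id = "B"))

rk <- rank_registry(reg, asmt, reference_year = 2021)
glance(rk)
#> # A tibble: 1 × 9
#>   n_input n_excluded n_retained n_ranked n_unique_ranked n_high n_medium n_low
#>     <int>      <int>      <int>    <int>           <int>  <int>    <int> <int>
#> 1      32          0         32       36              32     15       17     4
head(tidy(rk), 3)
#> # A tibble: 3 × 9
#>   candidate_id name         indication phase activity total_score max_attainable
#>   <chr>        <chr>        <chr>      <chr> <chr>          <dbl>          <dbl>
#> 1 cl-19        Resveratrol  treatment  III   active            23             33
#> 2 cl-07        Esomeprazole prevention III   active            21             33
#> 3 cl-08        Pravastatin  prevention III   active            21             33
```

32 unique candidates yield 36 ranked rows because dual-indication
candidates are ranked once per indication. `autoplot(rk)` draws the
traffic-light matrix; `write_ranked()` / `render_matrix()` export it.

The preclinical registry reproduces the published taxonomy of the 40
retained preclinical candidates:

```r
tx <- categorize_preclinical(example_preclinical_registry())
tx$indication
#> # A tibble: 3 × 3
#>   membership      count percent
#>   <chr>           <int>   <dbl>
#> 1 prevention_only    11    27.5
#> 2 treatment_only     24    60
#> 3 both                5    12.5
unique_candidate_count(clinical_phase_lists())
#> [1] 32
```

## Package structure

| Surface | Purpose |
| --- | --- |
| `as_registry()`, `read_registry()`, `read_assessments()`, `validate_assessments()`, `classify_activity()` | schema, validation, CSV/JSON I/O |
| `apply_exclusions()`, `screening_flowchart()` | six-rule eligibility screen |
| `reconcile_assessments()`, `derive_categorical_levels()`, `score_profiles()`, `assign_rank()`, `rank_registry()` | TPP matching engine |
| `summarize_pipeline()`, `categorize_preclinical()`, `unique_candidate_count()` | landscape summaries |
| `build_matrix()`, `render_matrix()`, `autoplot()` | traffic-light reporting |
| `synthetic_config()`, `simulate_registry()`, `empirical_mix_check()` | seeded generator with planted truth |
| `run_cli()` | command-line entry point |

See `vignettes/tpp-ranking-methods.Rmd` for the full account of the model,
defaults and design choices.
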