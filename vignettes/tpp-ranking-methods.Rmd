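---
title: "Ranking pipeline candidates against target product profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking pipeline candidates against target product profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpprank)
library(dplyr)
```

## The problem

Many conditions — obstetric conditions such as pre-eclampsia prominently
among them — have a research and development pipeline full of candidate
medicines but no systematic way to decide which candidates deserve
investment. A target product profile (TPP) states, parameter by parameter,
what a usable product must achieve ("minimum") and what it should ideally
achieve ("preferred"). `tpprank` implements a drug-agnostic triage built on
that idea: screen the candidate registry with explicit exclusion rules,
grade each clinical-phase candidate against a small set of critical TPP
criteria, combine the grades into a weighted score, and classify each
candidate's potential as high, medium or low relative to phase-specific
thresholds.

The package ships a worked registry for the pre-eclampsia pipeline (40
preclinical candidates and the 32 unique clinical candidates retained for
TPP matching), but every stage is driven by plain tabular inputs, so any
registry following the same schema can be analysed.

## The procedure

**Screening.** Six exclusion rules remove candidates for which TPP matching
is uninformative: (1) already approved and marketed for the indication,
(2) recommended or in routine use, (3) recommended for a subgroup only,
(4) inactive after negative trial outcomes, (5) targeting a single symptom
rather than the underlying pathology, (6) inferior to current treatment.
These are curator judgments carried as boolean registry columns — the
package deliberately does not attempt to infer them from literature. A
candidate triggering several rules is excluded once, under the
lowest-numbered rule, with all triggered rules retained in a secondary
list; this keeps flowchart accounting single-counted while losing no
information. The rules do not state a precedence among themselves, so the
fixed 1→6 order is a design choice made for deterministic reporting.

**Dual review and adjudication.** Each retained clinical candidate is
assessed per indication by two independent reviewers on each criterion,
using five match levels: `met_preferred`, `met_minimum`, `partially_met`,
`not_met`, and `unknown` when evidence is insufficient. Agreement stands;
disagreement is settled by a third reviewer. A disagreement with no
adjudicator level, or a criterion assessed by only one reviewer, is an
unresolved conflict and stops the pipeline with the candidate and criterion
named — silent tie-breaking between two equally authoritative reviewers
would be arbitrary.

**Derived criteria.** Three criteria are mechanical functions of registry
attributes and are filled in automatically where reviewers left no record:
trial setting (both high-income and low/middle-income country trials →
`met_preferred`; exactly one → `partially_met`; none stated → `unknown`),
stability (no cold chain → `met_preferred`; cold chain → `not_met`; unsure
→ `unknown`) and WHO Essential Medicines List status (listed →
`met_preferred`; not listed → `not_met`). When a reviewer level and a
derived level both exist, the reviewer wins — including a reviewer's
explicit `unknown`, which is a judgment that the evidence is insufficient,
not an absence of data. Criteria with neither a reviewer record nor a
derived value become `unknown` with provenance `unassessed`.

**Scoring.** The nine default criteria are trial setting, efficacy,
companion diagnostic, clinical monitoring, safety, mode of administration,
treatment adherence, stability and WHO EML status. The total score is
$\sum_c w_c\, s(\ell_c)$ over criteria $c$, where $s$ maps levels to
numbers and $w_c$ is the criterion weight. Defaults: $s$ = 0/1/2/3 for
not met / partially met / met minimum / met preferred, `unknown` = 0;
efficacy and safety weighted 2 against 1 for the rest, reflecting their
greater importance for wide-scale implementation. An `unknown` level earns
the same score as `not_met` but the two are kept distinct everywhere else:
the completeness fraction (share of informative levels) travels with every
score, and traffic-light output renders `unknown` grey, never red.

**Ranking.** The normalised score $r = \text{total}/\text{maximum
attainable}$ is compared with per-phase thresholds: high when
$r \ge 0.60$, medium when $r \ge 0.40$, low otherwise (defaults, identical
across phases I–IV). Both cutoffs are inclusive, so a score landing exactly
on a threshold takes the better rank — a deterministic, documented
tie-break. Ranking uses the ratio rather than the raw score so the
thresholds stay meaningful if a criterion is configured out. Preclinical
candidates are described, never ranked: there is no clinical evidence to
grade.

All three pieces — score coding, weights, thresholds — are a configuration
(`tpp_scheme()`, YAML/JSON via `read_scheme()`/`write_scheme()`). The
defaults above are this package's documented choice; an externally
specified coding and per-phase threshold table can be replayed through the
identical engine, and the rank output then follows that configuration
exactly.

```{r scheme}
default_scheme()
```

## A worked example

```{r example}
reg <- example_clinical_registry()

# uniform illustrative assessments: both reviewers grade every criterion
# met_minimum for every candidate-indication pair
pairs <- reg |>
  select(candidate_id, indications) |>
  tidyr::unnest_longer(indications, values_to = "indication")
asmt <- tidyr::crossing(pairs, reviewer_id = c("A", "B"),
                        criterion_id = tpp_criteria()$criterion_id) |>
  mutate(level = "met_minimum")

rk <- rank_registry(reg, asmt, reference_year = 2021)
glance(rk)
tidy(rk) |> head(5)
```

Dual-indication candidates (four in the bundled clinical registry) are
ranked once per indication, which is why 32 unique candidates produce 36
ranked rows. The traffic-light matrix mirrors the published visual style:

```{r plot, fig.width = 8, fig.height = 6}
autoplot(rk)
```

## Landscape summaries

`summarize_pipeline()` reports counts and percentages by activity, phase,
product type and archetype; `categorize_preclinical()` gives the
preclinical taxonomy with dual-indication candidates counted once in the
denominator. Percentages are rounded half-up to one decimal, matching the
printed style of pipeline reviews. A candidate is *active* when its last
recorded activity is at most three calendar years before the reference
year, boundary inclusive (reference 2021 → active means 2018 or later);
candidates with no recorded activity are inactive.

```{r taxonomy}
tx <- categorize_preclinical(example_preclinical_registry())
tx$indication
tx$subclass |> head(3)
```

The bundled preclinical registry transcribes the published candidate
tables verbatim. Its archetype column yields 21 unique repurposed
candidates while the accompanying summary text prints 20 (50%); the
fixture keeps the table values and carries the discrepancy as a
`source_notes` attribute that `categorize_preclinical()` propagates into
its `notes` field, rather than silently resolving it either way. The
fixture's product types, activity years, trial settings, cold-chain and
EML flags are illustrative editorial annotations — the published tables do
not print them — with activity years chosen so the 80%/20% active/inactive
split holds at a 2021 reference.

## The synthetic-data generator

`simulate_registry()` draws a registry whose margins emulate the
pre-eclampsia pipeline: phase mix 66/11/32/43/1 over
preclinical/I/II/III/IV, product types 90/38/25 drug/dietary/biological,
archetypes 38/115 new/repurposed (all out of 153), and a planted rank mix
of 7 high / 8 medium / 21 low out of 36. Each of the six exclusion flags
is planted independently at rate 0.15, which makes roughly 63% of clinical
candidates excluded — the rate observed in the real screen (55 of 87). A
candidate is proposed for both indications with probability 0.12 (4 of 32
clinically, 5 of 40 preclinically in the real data).

For every retained clinical candidate-indication pair the generator plants
a rank, then rejection-samples per-criterion levels (i.i.d. uniform over
the four informative levels, `unknown` injected at rate 0.1) until the
normalised score lands in the planted rank's threshold band; 10,000
rejections raise an infeasible-configuration error rather than looping
forever, which catches threshold bands too narrow for the discrete score
lattice. Reviewer A reports the truth; reviewer B deviates per criterion
with the configured disagreement probability, drawing uniformly from the
other four levels (the simplest symmetric noise model — no empirical
disagreement statistics exist to calibrate anything richer); the
adjudicator reports the truth. Because adjudication restores the truth
wherever B deviates, planted ranks are recovered exactly at any
disagreement rate — the recovery tests exercise the reconciliation
machinery, not a statistical margin. All randomness flows from one integer
seed through R's Mersenne-Twister generator with fixed normal and sampling
kinds, so runs are byte-reproducible across platforms.

What the generator does *not* emulate: correlated criteria (real efficacy
and safety evidence often move together), reviewer biases that adjudication
cannot fix (e.g. both reviewers misreading the same trial), informative
missingness (unknowns concentrate in early phases in real data), and real
candidate names or literature metadata. Passing recovery tests therefore
demonstrate that the pipeline machinery is faithful, not that real
reviewer panels would reach the published ranks.

## Numerical and design notes

* Score arithmetic is exact on the default integer codings; no tolerances
  are involved anywhere in scoring or ranking.
* Problem sizes in the test-suite: 1,000 random profiles for the
  scoring-oracle and monotonicity checks, 200-candidate registries for
  rank-recovery and reproducibility, 50–60-candidate registries for the
  screening partition properties. These sizes give exact (non-statistical)
  checks wherever the property is deterministic.
* Matrix row order is fixed (phase descending, then total score
  descending, then name) so reports are reproducible; ties in score are
  broken alphabetically.
* The level→colour map is bijective and hard-wired
  (`met_preferred`→dark green, `met_minimum`→light green,
  `partially_met`→yellow, `not_met`→red, `unknown`→grey); hex values are
  overridable for rendering, tokens are not.
* CSV is the canonical machine-readable render of the traffic-light
  matrix; HTML and SVG are presentation-only emitters.
* The published headline ranks (7 high / 8 medium / 21 low) depend on the
  full external registry and the original supplementary score codings,
  which are not machine-readable inputs; the engine reproduces them only
  when fed those tables via scheme config replay. The bundled fixtures
  cover the quantities that are printed in machine-usable form: the
  preclinical taxonomy and the clinical phase lists.

## Limitations

Match levels are curated inputs: the package validates, reconciles, scores
and reports them, but contains no evidence-extraction machinery, by
design. Preclinical evidence quality is carried only as free-text
annotation. Name-based deduplication across indications is exact
(case-folded, trimmed) with no fuzzy matching, so spelling variants of one
candidate count twice — the conservative failure mode for a triage tool.
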