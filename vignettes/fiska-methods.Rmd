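---
title: "Methods: fuzzy inference ranking for kidney allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy inference ranking for kidney allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiska)
```

## The allocation problem

Given one deceased donor and a waiting list, each candidate is described by
eight factors: medical urgency (binary), PRA sensitisation (0–100%),
recipient age (pediatric bins matter below 18), waiting time (years),
HLA-A/B/DR mismatch count (0–6), ABO relation to the donor
(identical/compatible; incompatible candidates are excluded outright),
donor–recipient age difference, and predicted post-transplant survival.
`fiska` ranks the list three ways — point scoring, ABO/urgency filtering,
and a Mamdani fuzzy inference system — and provides the metrics to compare
the rankings.

## Point scoring

`total_score()` is `100 × Σ` of the applicable global weights. The packaged
weight table is a three-level product: criterion (equity 0.33 / utility
0.67) × sub-criterion × bin. The loader enforces three invariants:
criterion weights sum to 1 ± 0.01, every relative-weight group sums to
1 ± 0.02 (published weights are rounded to two decimals; the pediatric age
bins sum to 0.99), and each global weight equals its product within
± 2×10⁻⁴. One published cell (4 HLA mismatches, 0.00947 vs the product
0.00938) is internally inconsistent at the 10⁻⁴ level; we keep the
published value and the tolerance absorbs it. Scoring conventions worth
stating:

* waiting-time points accrue linearly per year, pro rata and uncapped;
* recipients aged 18+ earn nothing from the pediatric age factor;
* an HLA mismatch count of 6 (possible with two fully mismatched antigens
  per locus) uses the 5-mismatch weight — the table stops at 5;
* ABO-incompatible pairs are a domain error, not a zero score.

`quantize_priority()` turns scores into the five ordered classes. The
expert-chosen cut points behind the original five-way split are not
published, so the default is quintiles of the training scores; explicit
thresholds can be supplied. Intervals are closed on the left, open on the
right, and a degenerate distribution (all scores equal) maps everything to
the highest class rather than erroring.

## The fuzzy system

Membership functions are trapezoids μ(x; a,b,c,d) — 0 outside [a,d],
linear ramps on [a,b] and [c,d], 1 on [b,c] — with b = c giving triangles
and a = b (or c = d) giving crisp edges; at a degenerate edge the plateau
value applies, which is how the binary inputs (urgency, ABO) are encoded as
crisp sets inside the same machinery. Inference is classical max–min
Mamdani: firing strength = min over antecedent term memberships (an
antecedent-free rule fires at 1), aggregation = max over rules of
min(strength, consequent membership), defuzzification = centre of gravity
by rectangle rule on a sampled output grid.

Tunable parameters:

| parameter | default | meaning |
|---|---|---|
| `resolution` | 0.1 | output sample step on the 0–100 universe; halving it moves results by < 10⁻² |
| `fallback` | off | when no rule fires, substitute the centroid of `medium` (50) instead of raising |
| `max_depth` | 6 | tree depth for rule induction |
| `min_leaf` | 20 | minimum rows per leaf |
| `k`, `seed` | 10, 42 | cross-validation folds and fold-shuffle seed |

Out-of-universe inputs are clamped to the nearest universe edge (signalled
as a `fiska_clamp` condition, never an error): an allocation run must not
crash on a PRA of 100 or a waiting time beyond the modelled decade.

### The default variable definition

The original system's membership breakpoints were never published; only the
set counts are (2, 4, 3, 3, 6, 4, 4, 2 across the eight inputs, whose full
rule grid is 13,824). The packaged definition
(`inst/extdata/variables_default.json`) is therefore this package's own
design, built on two principles:

1. **Plateaus and crossovers sit at the scoring-system bin boundaries**
   (PRA 80, age difference 5/15, survival 1/5, the pediatric limits,
   integer HLA counts). The induced tree splits overwhelmingly at these
   same points, so the fuzzy cells track the tree's regions.
2. **The broad sets carry long inner ramps** so that every point of every
   universe has positive membership in at least one set of each variable.
   Without this, a rule whose antecedent set only partially covers its
   leaf's interval leaves part of the cohort firing no rule at all.

The output variable uses five *separated symmetric* plateaus centred at
10/30/50/70/90. A clipped symmetric set's centroid is its centre at any
clip height, so a single dominant rule always defuzzifies into its
consequent's maximal-membership region, and blending two classes crosses
the class boundary only when the weaker class contributes the larger area.
Overlapping triangle outputs (the other common textbook choice) were tried
first and systematically leaked edge classes (very_low inferences surfacing
as low) because the edge centroids sit close to the class boundaries.

Everything lives in config; none of these numbers appear in code.

## Rule induction

The training table pairs each patient with a donor, computes the eight
crisp predictors, scores, and quantises. A deterministic Gini CART
(`fit_tree()`) is grown with axis-aligned binary splits; ties break to the
earlier predictor and the lower threshold, so a fixed table always yields
the same tree. The two binary predictors enter as 0/1 indicators, for which
a threshold split and a category-subset split coincide.

`tree_to_fuzzy_rules()` is the bespoke step: each leaf's path constraints
are intersected into one interval per variable, and the fuzzy set with the
maximal membership integral over that interval becomes the antecedent term
(ties: plateau centre nearest the interval midpoint, then set order; an
interval entirely outside the universe falls back to membership at the
nearest edge). Unconstrained variables are omitted. Duplicate rules merge;
contradictory duplicates keep the more populous leaf and report the
conflict. This mapping is lossy by construction — a leaf interval spanning
two sets keeps only one — which is why the package carries an explicit
fidelity property: on a 5,000-patient synthetic cohort, classifying by
`infer()` + maximal-membership read-out agrees with the tree's own
predictions on ≥ 70% of rows (observed 0.73–0.83 across development seeds),
and fuzzy scores correlate with point scores at Spearman ρ ≈ 0.9 on
held-out cohorts.

`cross_validate()` reports stratified k-fold one-vs-rest sensitivity,
specificity and precision per class plus overall accuracy, averaged over
folds, in percent — the layout of the original study's performance table.
Metrics undefined in a fold (empty class) are excluded from that average.

## Ranking policies and metrics

All three policies first exclude ABO-incompatible candidates — by design
they exclude *exactly* the same set. Fuzzy and scoring ranks sort
descending by crisp score with ties to the longer-waiting patient, then
patient id; filtering ranks urgency tiers by waiting time and truncates to
six (two recipients, four reserves, mirroring two-kidney donors).

The overlapping rate is 100·|top-6 ∩ top-6|/6 *truncated* (not rounded) to
one decimal — the published convention under which 4/6 prints as 66.6 —
and two first choices is the unordered top-2 comparison (100/50/0). Raw
EPTS is the UNOS linear predictor with natural logarithms and the
years-on-dialysis = 0 indicator; the package reports the raw score and does
not ship the UNOS raw-to-percentile table.

## Synthetic cohorts

`generate_patients()`/`generate_donors()` state one fixed world: ABO
frequencies O/A/B/AB = .37/.34/.22/.07; PRA as a 0.6 point mass at zero
plus a uniform sensitised tail; ages Normal(45, 15) truncated to [1, 80];
10% urgent; 30% diabetic; 8% prior transplant; dialysis years gamma with
15% pre-emptive zeros; waiting times exponential with mean 2.5 years; HLA
antigens drawn independently from pools of 20/30/15 labels at A/B/DR;
predicted survival 20 − 0.16·age − 0.6·dialysis + N(0, 2.5), clamped to
[0, 20], so survival carries the negative age/dialysis dependence the
monotonicity and recovery tests need. A master seed fans out to per-field
substreams, so adding a field never perturbs earlier draws.

What the generator does **not** emulate: HLA linkage disequilibrium and
haplotype structure, the correlation between sensitisation and prior
transplant, registry-specific age/waiting distributions, and longitudinal
relisting. A green test therefore establishes that the pipeline is
internally coherent on a plausible cohort — not that any number matches a
national registry. In particular, the original study's cross-validated
accuracy (86.9% on a 430k-record registry extract), its 69-rule base and
its Fig-6 output of 76.5, and its outcome-table values are not reproducible
from synthetic data and are deliberately not asserted anywhere.

## Numerical choices and degenerate inputs

* Dates are ISO-8601; waiting time uses 365.25-day years; a
  `waiting_time_years` column overrides date arithmetic.
* COG uses the rectangle rule; on a 0–100 universe at step 0.1 the
  refinement error is below 10⁻².
* An all-zero aggregate raises a classed domain error naming the patient;
  the CLI surfaces it per patient unless `--fallback-rule` is given.
* Rule-base and variable files round-trip through JSON loss-free
  (`digits = NA`); the CLI writes plain CSV reports.
* Exit codes: 0 success, 2 config/schema error, 3 domain error.

## Known limitations

The interval-to-set mapping can still drop a minority of a leaf's
population into a neighbouring rule when tree thresholds fall far from any
set boundary; the fidelity property bounds, but does not eliminate, this
loss. HLA "compatibility" is treated at antigen level (the convention when
typing is reported as two antigens per locus); allele-level typing would
need a different mismatch rule. The filtering policy resolves the published
ambiguity ("filtered by blood type and urgency") as urgency-tier-then-wait;
an urgent-only variant is available via `urgent_only = TRUE`.
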