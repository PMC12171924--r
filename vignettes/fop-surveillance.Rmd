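---
title: "Methods: front-of-pack 'high in' symbol surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: front-of-pack 'high in' symbol surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopscan)
```

## The problem

Canada's front-of-pack (FoP) regulation requires a "high in" symbol on
packaged foods whose sodium, saturated fat or total sugar content meets
category-dependent thresholds. Monitoring how a food supply sits relative
to those thresholds — and how far modest reformulation would move it —
requires joining a label database to sales data, applying the threshold
rules faithfully, and weighting descriptive statistics by what people
actually buy. `fopscan` implements that pipeline as small, composable
pieces, each testable on synthetic data.

## The classification model

For every product the classifier resolves, in order:

1. **Exemptions.** Declarative rules (attribute, comparator, cutoff) per
   category; any match exempts the product and empties its flagged set.
   Reformulation can never create an exemption in this model, so exempt
   products stay exempt under every scenario.
2. **Tier fraction** τ: 0.30 for mixed-dish categories; else 0.10 when the
   category's reference amount (RA) is less than or equal to the small-RA
   cutoff (30 g/30 mL — the boundary is inclusive, so RA = 30 g takes the
   10 % tier); else 0.15. The branches are evaluated in that order and are
   exhaustive and mutually exclusive: exactly one tier per product.
3. **Basis amount** b = max(serving size, RA). Both quantities must be in
   the RA's unit family; a serving declared in the other family converts
   only through an explicit per-category density (g/mL) in the scheme —
   without one the product errors rather than being guessed at.
4. **Per-nutrient test.** The per-serving amount is rescaled linearly to
   the basis (`x · b / s`; returned unchanged, with no floating-point round
   trip, when b = s) and flagged when it meets or exceeds τ · DV.

Three choices here were genuinely open and are pinned by tests:

* **Comparator at the threshold is ≥** ("meets or exceeds"). A product
  exactly at τ · DV carries the symbol; one representable step below does
  not.
* **No rounding before comparison.** Label-rounding rules are out of scope;
  comparisons use exact stored values.
* **Missing nutrient values** follow a policy: `strict` stops with the
  product code; `lenient` (default) records an `NA` flag that never counts
  toward `n_flagged`, so one missing value cannot flip a product's
  symbol count.

### Tunable parameters

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `daily_values` | Na 2300, sat fat 20, sugars 100 | mg / g / g | Canadian labelling DVs; editable config because regulation constants change |
| `tier_fractions` | 0.15 / 0.10 / 0.30 | fraction of DV | the regulation's three-tier structure |
| `small_ra_cutoff` | 30 | g or mL | inclusive boundary for the 10 % tier |
| `reference_amounts` | per category | g or mL | illustrative placeholders in the style of the regulatory reference-amount table; swap in the official values for real analyses |
| `densities` | soups 1.0, pasta sauces 1.05, beverages 1.03 | g/mL | required for any cross-unit serving/RA comparison |
| exemption rule | yoghurt calcium ≥ 15 % DV | %DV | illustrative: the regulation's exemption list is richer; rules are data, add as needed |

## Merging and coverage

The label table must be unique per (trimmed, upper-cased) product code;
codes are otherwise opaque — no UPC checksum semantics are imposed.
Duplicate sales rows per code are summed before the join, treating them as
period slices of a flow quantity. Unmatched label products are retained for
unweighted analyses but excluded from every sales-weighted statistic.

"Market coverage" is not a uniquely defined quantity. The default basis is
the product count: per-category coverage is matched/total products, and the
overall figure is the unweighted mean of per-category coverages. A
`sales_kg` basis is also offered — the share of total sales-table kilograms
captured by matched codes — but since unmatched sales rows carry no
category, it is only defined overall and per-category values are reported
as missing. A registered category with zero products has undefined (`NA`)
coverage, never 0.

## Weighted statistics

Category nutrient portraits are weighted by sales volume in kilograms:
mean `Σwx/Σw`, and SD in the frequency-weight population form
`sqrt(Σw(x − x̄)²/Σw)` with no reliability correction — the weighted SD
formula was an open choice; the population form is invariant to rescaling
all weights and reduces to the population SD under equal weights, and is
pinned by test. Portrait values are per label serving (the label-facing
"portion"), with a `per_100` flag for per-100 g/mL comparisons.

Symbol prevalences and the 0/1/2/3 flagged-nutrient distribution are
unweighted product fractions by default — the regulatory burden is per
product — with a weighted variant available via per-product weights.
Zero-total-weight groups are reported as missing, never as 0.

## Reformulation scenarios

A scenario multiplies one nutrient's per-serving amount by (1 − r) for
in-scope products and re-classifies. Because the basis rescaling is linear,
reducing per serving and reducing at basis are equivalent; this is asserted
by test. The grid engine always includes the r = 0 baseline, and reports
prevalence and percentage-point change (baseline − scenario) per category
and overall, at full precision — pp values are rounded only in rendered
reports.

`minimum_deflag_reduction()` reports both the closed form
`r* = 1 − threshold/amount_at_basis` and the smallest grid multiple that
strictly unflags. The two differ by construction: at exactly r* the amount
sits on the threshold and — with the inclusive comparator — still flags, so
the grid answer is the first step past r*. Products with
`amount ≥ threshold/(1 − 0.15)` cannot shed the symbol within the 15 %
study grid and are reported as not achievable.

## What the synthetic supply emulates — and what it does not

The generator draws, per category: serving sizes from a discrete set or
uniform range; the seven per-serving nutrients from lognormal marginals
parameterised by method of moments from target mean/SD (non-negative and
right-skewed, like real nutrient contents; SD 0 degenerates to a constant;
a positive SD with a non-positive mean is rejected by name); optional
exchangeable inter-nutrient correlation through a Gaussian copula; sales
kilograms from a heavy-tailed lognormal (meanlog 6.5, sdlog 1.4 by
default); and an independent Bernoulli(0.79) label-to-sales match,
emulating the roughly four-fifths market coverage typical of commercial
sales extracts. Everything is reproducible from one seed, which is applied
locally and does not disturb the session RNG.

The default 15-category specification (5132 products) uses nutrient-target
magnitudes the authors consider realistic for a Canadian packaged-food
supply — sodium-dense soups, deli meats, processed cheeses and pizzas;
sugar-dense cookies, sweetened beverages and cereals; saturated-fat-dense
sausages, pizzas and frozen meals — and lands the pipeline in a plausible
overall regime (around two-thirds of matched products flagged for at least
one nutrient, sodium the most common). These targets are assumptions, not
measurements: passing tests demonstrate the machinery is correct and the
regime is sensible, not that any real supply has these values.

Deliberately not emulated: brand and private-label structure, temporal
sales dynamics, correlation between sales and nutrient content (a
configurable dependence knob exists for sensitivity probes, default off),
satfat ≤ total-fat coherence (marginals are drawn independently so moment
targets stay exact), and label-rounding artefacts.

`generate_boundary_fixture()` is the sharp tool for exact tests: it places
product *i* at exactly `threshold × (1 + fᵢ)` at basis (serving = RA, so no
rescaling error), making every flag — at baseline and under any uniform
reduction — analytically known. The worked percentage-point examples
(70 → 48 = 22 pp, 71 → 59 = 12 pp, 77 → 49 = 28 pp) are reproduced this way
with fixtures of 50–100 products constructed to those prevalences.

## Numerical choices and degenerate inputs

* Threshold comparisons and prevalence identities are exact; the only
  tolerance in the test suite is 1e-9 on distribution sums.
* `amount_at_basis` short-circuits `b == s` to avoid a `x·b/b ≠ x`
  floating-point round trip, so boundary fixtures are exact.
* Single-product SDs are 0 with a `single` flag; zero total weight yields
  `NA`; empty classification input yields an empty, correctly typed
  verdict table.
* Pipeline outputs are computed fully before any file is written, so a
  failing stage (named in the error) leaves no partial reports. Reports are
  CSV-first; the chart carries a sidecar CSV of exactly the plotted
  numbers.

## Problem sizes

The test suite works at sizes chosen to make sampling checks sharp while
keeping the whole suite comfortably under a minute of compute: oracle
equivalence on 1200 randomised products, monotonicity over 500 random
supplies × 4 reductions, closed-form-vs-grid agreement on 1000 flagged
products at step 0.001, moment recovery at n = 1000–2000, and end-to-end
determinism on a two-category supply. The acceptance script runs the full
5132-product default supply.

## Known limitations

* The shipped reference amounts and the single exemption rule are
  illustrative; real surveillance must load the official tables into the
  scheme.
* Serving-size/RA comparisons for beverages are done in mL; products
  labelled in g convert only through the configured density.
* Sales-weighted prevalences, nutrient substitution (sweeteners, potassium
  salts) and health-impact modelling are out of scope.
* Inferential statistics are deliberately absent: the pipeline is
  descriptive.
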