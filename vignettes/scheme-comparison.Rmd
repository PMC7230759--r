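---
title: "Methods: comparing front-of-package nutrient-profiling schemes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing front-of-package nutrient-profiling schemes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fopcompare)
```

## The problem

Front-of-package (FOP) nutrition labelling schemes rank the same
product differently: an interpretive rating system such as Nutri-Score
grades on a continuous score, while health symbols such as the Keyhole
or the Slovenian Protective Food symbol are binary endorsements with
category-specific limits. `fopcompare` puts ten such schemes on a
common footing for five categories of prepacked foods — breakfast
cereals, pasta, cheese, yoghurt products (plain, flavoured,
flavoured drinks) and cooking oils — and measures how far their
verdicts agree.

Every scheme's verdict is harmonised to one binary *healthier* flag:
Nutri-Score grade A or B; Health Star Rating (HSR) of at least 3.5
stars; no red traffic light; eligibility to carry the symbol (Keyhole,
Choices, Finnish Heart, Protective Food); permission for marketing to
children (Ofcom, WHO-Europe); permission to carry health claims
(FSANZ). Agreement is then a comparison of binary raters.

## Point-scoring models

Nutri-Score, HSR, Ofcom and FSANZ share a skeleton: negative (baseline)
points for energy, saturated fat, total sugars and sodium, minus
positive (modifying) points for fruit/vegetable/nut content, fibre and
protein, each component read off an increasing threshold ladder. The
package implements only this skeleton in code; every ladder, cap, class
boundary and cut-off lives in a versioned YAML file under
`inst/extdata/config/` and is validated (strict monotonicity) at load
time. This keeps the transcriptions auditable and swappable: a 2022/23
Nutri-Score update, for instance, is a new config file, not a code
change.

Details that matter:

* **Protein suppression.** Protein points are excluded when the
  negative total reaches the model's cut-off (11 for Nutri-Score and
  Ofcom, 13 for FSANZ and HSR) and FVN points are below the maximum —
  except in Nutri-Score's cheese category, where protein always counts.
* **Category routing.** Each model groups the seven leaf categories
  its own way (configured in `category-mapping.yaml`): Ofcom
  distinguishes only foods from drinks, and is the only model here that
  routes flavoured yoghurt drinks as drinks; Nutri-Score adds cheese
  and added fats; HSR adds dairy foods, cheese and oils; FSANZ routes
  oils — and cheese with at least 320 mg calcium/100 g — to its
  category 3 (claim cut-off 28), with a logged fallback to category 2
  when calcium is undeclared. Yoghurt drinks default to HSR dairy
  foods; a config override can treat them as a separate class.
* **Saturated-fat handling.** Added fats under Nutri-Score score the
  percentage of fat that is saturated (a `>=` ladder); FSANZ category 3
  and HSR oils/cheese use the extended saturated-fat ladder (up to 30
  points).
* **Salt vs sodium.** Labels declare salt; all sodium ladders consume
  the derived sodium at 400 mg per g of salt, the EU labelling
  convention.
* **Fibre basis.** Fibre ladders use the AOAC thresholds for both
  Nutri-Score and Ofcom, since EU labels declare AOAC fibre; the NSP
  ladder is kept in the Ofcom config as a comment for a manual switch.
* **No pre-rounding.** Declared values are compared to thresholds
  as-is; any rounding belongs to the label, upstream of this package.

The configuration values are transcriptions of the publicly available
protocol documents for each scheme. The Nutri-Score 2017 and Ofcom
ladders are standard and exact. For the HSR score-to-star breakpoint
maps and the per-category numeric limits of the four symbol schemes,
the shipped files are this package's transcription — monotone,
version-tagged and realistic, but users applying the package to real
regulatory questions should verify them against the current official
documents and replace the config where needed. Regression fixtures in
the test suite pin hand-computed scores against the shipped tables, so
any later re-transcription that changes results is caught explicitly.

One known substantive tension: under the standard 2017 added-fats
tables, any near-pure fat receives at least 10 energy points, so
virtually no cooking oil can reach Nutri-Score A/B. Published
market surveys sometimes report high A/B shares for oils, which cannot
be produced by these tables; the package ships the standard tables
rather than reverse-engineering a variant.

## Threshold schemes

The traffic-light classifier bands total fat, saturated fat, sugars
and salt per 100 g (green ≤ 3.0 / 1.5 / 5.0 / 0.3 g; red > 17.5 / 5.0
/ 22.5 / 1.5 g; amber between) and is applied to every category,
single-ingredient oils included — which is why oils are structurally
0% healthier under it. The per-portion red overrides of the newer UK
guidance are out of scope (no portion data in supply tables).

The Protective Food symbol uses the traffic light as its first step
except for dairy (total fat < 3 g and saturated fat < 1.5 g per 100 g,
both strict, matching the printed "<" of the scheme's criteria) and
cooking oils, where eligibility requires an authorised
nutrition/health claim. Which claim a given oil would carry is not
fixed by the scheme's public documentation; the package
operationalises it as a high-unsaturated-fat claim — unsaturated fat
at least 70% of total fat *and* supplying more than 20% of energy at
37 kJ/g — and exposes the predicate's parameters in
`protective-food-1992.yaml` for replacement.

Keyhole, Choices, Finnish Heart and WHO-Europe are conjunctive rule
sets per (scheme, category): each rule compares one nutrient or derived
quantity (e.g. saturated share of fat) to a limit; boolean
requirements (no sweeteners; Keyhole bans them in every category)
join the conjunction. Transcribed limits default to non-strict `<=`
unless the source document demands otherwise. A category a scheme does
not cover is marked `never_eligible` rather than borrowing a
neighbour's limits. Flavoured yoghurts are assessed on added sugars
where the scheme's dairy criteria target added sugar (Keyhole,
Choices) and on total sugars where they target total (Finnish Heart,
WHO-Europe); the choice is visible per scheme in the config. A rule
referencing a nutrient that is absent and not defaultable (calcium) is
a configuration error, never a silent pass.

## Comparison statistics

For each (category, scheme) the package reports the healthier
proportion and, when sales are recorded, the sales-weighted proportion
Σ sales(healthier)/Σ sales. Sales are unitless relative weights;
products without sales are excluded from both sums and logged — a
package choice, as is reporting an error rather than 0 for an empty
category or zero total sales. No parent-category aggregation is
performed: the five categories are a selected, not representative,
slice of a market.

Agreement between two schemes' flags is Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$ with $p_e$ from the marginal positive
rates, labelled on the conventional bands (0.01–0.20 slight, 0.21–0.40
fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–0.99 near
perfect). Two edge conventions: values at or below 0 fold into
"none-to-slight" and 1.0 into "near perfect" (the printed ranges leave
both unnamed, and the raw value is always reported alongside); and
when both raters are constant, $p_e = 1$ makes the statistic 0/0 — the
package returns 0 with a `degenerate` flag, since agreement under zero
variation is indistinguishable from chance. That convention also makes
the kappa between two schemes that each reject every cooking oil an
exact 0 rather than an error.

The scenario cross-tab addresses the conflicting-information question
directly: for a symbol scheme and a rating scheme used together,
products split into A (green rating, symbol), B (green, no symbol),
C (non-green rating *but* symbol-eligible — the conflict) and D
(neither). A + B + C + D always equals the sample size; the C
percentage is the headline conflict rate.

## The synthetic supply generator

Branded-food composition databases with retail sales are rarely
deposited, so the package ships a seeded generator
(`supply-default.yaml`) whose defaults are fixed study conditions, not
tuning dials:

* 1,370 products: 320 breakfast cereals, 250 pasta, 370 cheese, 80
  plain / 180 flavoured / 70 drinkable yoghurts, 100 cooking oils.
* Nutrients drawn from truncated normal/log-normal distributions with
  hard bounds chosen to be label-realistic per category: oils are
  91–100 g fat/100 g with energy derived at 37 kJ/g and a wide
  saturated-fat spread (7–92 g, capped at total fat); cheese is fat-
  and salt-rich with calcium recorded; plain yoghurts are less sugary
  than flavoured ones (added sugars derived as total minus a lactose
  allowance); pasta is low fat/salt with a 30% wholegrain, high-fibre
  subpopulation; cereals carry wide sugar and fibre spreads with
  occasional fruit/nut content.
* Sales are log-normal (meanlog 7.6, sdlog 1.2 — heavy-tailed, as
  retail sales are), with a per-category bias coefficient *b* tilting
  expected sales along a continuous quality index. The index is the
  negative Ofcom score: continuous and category-agnostic, so no single
  binary scheme under test defines its own weighting. Defaults encode
  the directional market patterns the comparison is designed to
  surface: *b* = −0.6 for cereals (market leaders less healthy),
  +0.6 for cheese (leaders healthier), +0.3 elsewhere.

The generator emulates marginal nutrient distributions and a
sales-quality link. It does not emulate brands, portion sizes,
reformulation over time, correlations between nutrients beyond those
implied by the draws, or any real market's category shares. Tests
passing on synthetic data therefore demonstrate correctness of the
classification and comparison machinery and qualitative
reproducibility of structural results (oils under the traffic light,
directional sales-weighting effects); they do not certify quantitative
agreement with any real market.

## Verification

The test suite exercises, among others: monotonicity for all ten
schemes (increasing energy, saturated fat, sugars or salt never makes
a verdict better; increasing fibre, FVN or wholegrain never makes it
worse) over 1,000 random panels; component points against an
independently coded reverse-scan ladder oracle; kappa symmetry and
equality with an independent 2×2 closed form to 1e−12 over 500 random
rater pairs plus a hand-worked 20/5/10/65 table (κ = 0.625); scenario
conservation; equal-sales invariance of the weighted proportion; seed
determinism of the generator; and the class-boundary and
protein-suppression behaviour of Nutri-Score. The sales-bias mechanism
is checked by parameter recovery: across 200 seeded replicates of
100-product cereal markets, the sales-weighted healthier share falls
below the unweighted share in at least 95% of replicates. These
problem sizes keep the full suite under a minute on one CPU while
leaving the statistical checks well-powered.

## Known limitations

* The symbol-scheme limits and HSR star maps are transcriptions (see
  above); treat them as defaults, not authority.
* Per-100 g basis throughout, including drinks; density differences
  and per-portion rules are ignored.
* Undeclared optional nutrients (fibre, FVN, trans fat, added sugars,
  wholegrain) default to zero with a warning — conservative for
  positive components, and the package's own choice.
* No confidence intervals or significance tests for kappa are
  computed; with category sizes of a few hundred, band labels near
  boundaries should be read with that in mind.
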