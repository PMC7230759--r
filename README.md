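# fopcompare

Comparison of front-of-package (FOP) nutrient-profiling schemes on a
food-supply table.

When several FOP labelling schemes coexist on one market, the same
product can be rated "healthier" by one scheme and not by another — a
real risk wherever an interpretive rating system (such as Nutri-Score)
is introduced alongside an established health symbol. `fopcompare`
quantifies that alignment. It classifies prepacked products — breakfast
cereals, pasta, cheese, yoghurt products and cooking oils — under ten
schemes, harmonises every verdict to a binary *healthier* flag, and
compares schemes by per-category proportions, sales-weighted
proportions, Cohen's kappa agreement and symbol-versus-rating conflict
scenarios. It is intended for public-health nutrition researchers and
food-policy analysts working with branded-food composition data.

## The schemes and their harmonisation

Four point-scoring models compute a score from negative (N) and
positive (P) nutrient components per 100 g,

    score = N(energy, saturated fat, total sugars, sodium)
          − P(fruit/veg/nuts, fibre, protein)

with model-specific threshold ladders, component caps and a
protein-suppression rule (protein only counts below an N cut-off unless
FVN points are maximal):

| scheme | verdict | *healthier* means |
|---|---|---|
| Nutri-Score (2017) | letter A–E | grade A or B |
| Health Star Rating (2016) | 0.5–5.0 stars | ≥ 3.5 stars |
| Ofcom NPM (2004/5) | integer score | score < 4 (foods) / < 1 (drinks) |
| FSANZ NPSC (2016) | integer score | score < 1 / 4 / 28 by category |

Six threshold schemes check per-100 g limits: the UK FSA traffic light
(*healthier* = no red light), the Slovenian Protective Food symbol
(traffic light with dairy and cooking-oil overrides), and the Keyhole,
Choices, Finnish Heart and WHO-Europe rule sets (*healthier* = eligible
to carry the symbol / permitted for marketing to children). All point
tables, class boundaries and limits ship as versioned YAML under
`inst/extdata/config/` — the code fixes only the scoring skeletons.

Agreement between two schemes' binary flags is Cohen's kappa,
κ = (p_o − p_e)/(1 − p_e), interpreted on the conventional bands
(0.01–0.20 slight … 0.81–0.99 near perfect). Because the real
branded-food database behind these questions is not publicly
deposited, the package includes a seeded synthetic supply generator
with category-typical nutrient distributions, heavy-tailed sales and a
tunable sales-quality bias.

## Worked example

```r
library(fopcompare)

# one product: a plain yoghurt per 100 g
yog <- nutrient_panel(energy_kj = 260, total_fat_g = 3.5, sat_fat_g = 2.4,
                      total_sugars_g = 4.7, salt_g = 0.1, protein_g = 4)
score_nutriscore(yog, "general_food")
#> <nutriscore 2017> category=general_food N=3 P=2 score=1 grade=B healthier=TRUE
```

Three negative points (2 for saturated fat, 1 for sugars) minus two
protein points give score 1 → grade B → healthier.

```r
# a full synthetic market and three schemes
spec <- default_supply_spec(seed = 2026)
supply <- generate_supply(spec)
matrix <- classify_all(supply, models = c("nutriscore", "traffic_light",
                                          "protective_food"))
#> nutriscore       (2017): 526/1370 healthier
#> traffic_light    (FSA-2007-per100g): 732/1370 healthier
#> protective_food  (1992): 554/1370 healthier

proportion_report(matrix, supply) |>
  dplyr::filter(model == "nutriscore") |>
  dplyr::select(category, n, proportion, sw_proportion)
#>   category                    n proportion sw_proportion
#> 1 breakfast_cereals         320      0.2          0.0590
#> 2 pasta                     250      1            1
#> 3 cheese                    370      0            0
#> 4 yoghurt_plain              80      0.95         0.989
#> 5 yoghurt_flavoured         180      0.461        0.642
#> 6 yoghurt_drink_flavoured    70      0.757        0.820
#> 7 cooking_oil               100      0            0
```

`proportion` is the share of products rated A/B by Nutri-Score in each
category; `sw_proportion` weights each product by its 12-month sales.
The drop for breakfast cereals (0.20 → 0.06) reflects the generator's
negative sales-quality bias for that category: the market leaders are
the less healthy products.

```r
scenario_table(matrix, "protective_food", "nutriscore")$scenario_c_pct
#> [1] 10.51095
```

Scenario C — eligible for the health symbol yet rated non-green by
Nutri-Score — is the conflicting-information case; here it affects
10.5% of the synthetic sample.

A thin command-line wrapper is available at `inst/cli/fopcompare.R`
(subcommands `simulate`, `profile`, `compare`, `validate`).

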