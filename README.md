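# difnet

Differential item functioning (DIF) detection for ordinal questionnaire
items with proportional-odds regression — plain maximum likelihood or
elastic net penalized likelihood with BIC-selected regularization — plus a
graded response model simulator and a Monte Carlo engine for power and
type-I-error studies in small samples.

## Who this is for

Psychometric and health-related quality-of-life researchers screening
Likert-type scales for measurement invariance between two groups (e.g.
patients vs proxies, gender, language versions), especially when one or
both groups are small (tens, not hundreds, of respondents), where the
asymptotics behind the usual likelihood-ratio screen are shaky.

## The method

For each studied item with ordered response `Y ∈ {1..J}`, three nested
cumulative logit (proportional-odds) models are fitted:

```
model 1:  logit P(Y ≤ j) = γ0j + β1 θ
model 2:  logit P(Y ≤ j) = γ0j + β1 θ + β2 G
model 3:  logit P(Y ≤ j) = γ0j + β1 θ + β2 G + β3 (θ × G)
```

where `θ` is the observed total test score (the matching criterion) and
`G` the group indicator. Uniform DIF is tested by the 1-df likelihood-ratio
comparison of models 1 and 2, nonuniform DIF by models 2 and 3.

In the regularized variant each model minimizes the elastic net penalized
objective

```
-(1/N) log L + λ [ w Σ|βj| + (1−w)/2 Σ βj² ]
```

(`w = 1` LASSO, `w = 0` ridge; intercepts never penalized) over an
automatically generated descending 20-point λ path, selecting λ per model
by `BIC = −2 log Lλ + log(N) · N_nonzero` with intercepts counted in
`N_nonzero`. The LR comparison then uses the unpenalized log-likelihoods
evaluated at each model's BIC-selected estimates. The solver is a proximal
Newton iteration with soft-thresholded coordinate descent on the quadratic
model (Rcpp), verified in the test suite against `MASS::polr` (ML limit)
and a brute-force minimizer of the same objective.

The simulator generates responses from Samejima's graded response model
(`P(Y ≥ j | θ) = logistic(a(θ − b_j))`) with `a ~ U(1,2)`, sorted `N(0,1)`
thresholds and `θ ~ N(0,1)`, injecting uniform DIF by shifting the studied
item's focal-group thresholds.

## Worked example

```r
library(difnet)
bank  <- sample_item_bank(n_items = 5, n_categories = 5, seed = 7)
focal <- apply_uniform_dif(bank, target_item = 1, magnitude = 0.8)
ds    <- simulate_responses(bank, focal, n_ref = 100, n_focal = 100, seed = 8)
analyze_scale(ds, dif_config("elastic_net", w = 0.1))
```

```
Per-item DIF tests (elastic_net, w = 0.1, alpha = 0.05): 1 of 5 items flagged for uniform DIF
 item uniform_stat uniform_p nonuniform_stat nonuniform_p flagged_uniform ...
    1      15.1903 0.0000972        0.000000       1.0000            TRUE
    2       0.0803 0.7768893        0.365893       0.5453           FALSE
    3       0.4784 0.4891501        0.007608       0.9305           FALSE
    4       0.4815 0.4877306        1.295499       0.2550           FALSE
    5       0.1910 0.6620821        0.023672       0.8777           FALSE
```

Item 1 — the item whose focal-group thresholds were shifted by 0.8 — is the
only one flagged for uniform DIF (LR statistic 15.19 on 1 df,
p ≈ 1e-4); the DIF-free items sit comfortably above α = 0.05, and no item
shows nonuniform DIF. The `lambda_model*` columns record each nested
model's BIC-selected regularization strength.

A power study over a condition grid:

```r
cond <- sim_condition(100, ratio = 1, n_items = 5, dif = 0.8,
                      w_grid = c(0, 0.05, 1), n_reps = 500)
run_condition(cond, base_seed = 1)   # power + type-I per method, with MC SEs
```

## Command line

```sh
Rscript inst/cli/difnet.R simulate --n 100 --ratio 1 --items 5 --dif 0.4 --seed 7 -o d.csv
Rscript inst/cli/difnet.R dif d.csv --method elastic_net --w 0.1 -o results.tsv
Rscript inst/cli/difnet.R power-study grid.yaml -o summary.tsv
```

Input CSVs need `item_*` columns (integers; `--zero-based` accepts 0-coded
Likert items) and a `group` column (0 = reference, 1 = focal). Outputs are
TSVs with `#` header lines carrying the seed and config hash needed to
regenerate them.

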