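# cardiopredict

Cardiovascular-disease risk prediction on tabular clinical records, end to
end: seeded synthetic cohorts with a known logistic ground truth, cleaning
with auditable bookkeeping, the derived clinical features BMI / MAP / PP,
random-forest Gini feature importance, and a from-scratch LSTM classifier
(standard tanh or Softsign candidate activation) trained by
backpropagation through time under a family of optimizers — including
**R-Lookahead**, Lookahead slow/fast weight averaging whose fast-weight
inner optimizer is Rectified Adam.

The package is for biostatisticians and ML practitioners who want every
stage of such a pipeline inspectable and testable without any external
download: the synthetic generator reproduces the cardio schema (age in
days, gender 1/2, height/weight, `ap_hi`/`ap_lo` blood pressures, ordinal
cholesterol/glucose, binary habits, binary `cardio` outcome), plants known
duplicates and out-of-range records, and labels records by

    Pr(cardio = 1) = sigmoid(b0 + Σ_j beta_j z_j)

over standardised derived features (MAP-dominated by default), so
recovery of the planted signal is a checkable fact rather than an
anecdote.

The core pieces, in the field's standard notation:

* **Gini importance** — node impurity `Gini(p) = Σ_k p_k (1 − p_k)`;
  per-split score `GI_m − GI_l − GI_r` (literal mode, honouring the
  method's printed definition) or the standard weighted decrease
  `GI_m − (n_l/n_m) GI_l − (n_r/n_m) GI_r`; summed per feature over a
  seeded bootstrap CART forest and normalised to sum to 1; the top 12 of
  the 14 features feed the classifier.
* **LSTM cell** — `f, i, o = σ(W·[h_{t−1}, x_t] + b)`,
  `C̃ = tanh(·)` or `softsign(·) = x/(1+|x|)`,
  `C_t = f ⊙ C_{t−1} + i ⊙ C̃`, `h_t = o ⊙ tanh(C_t)`, sigmoid head on
  `h_T`; exact BPTT gradients, verified against central finite
  differences.
* **R-Lookahead** — k = 5 inner RAdam steps
  (`ρ_t = ρ_∞ − 2tβ₂ᵗ/(1−β₂ᵗ)`; momentum update while `ρ_t ≤ 4`,
  variance-rectified adaptive update with
  `r_t = √(((ρ_t−4)(ρ_t−2)ρ_∞)/((ρ_∞−4)(ρ_∞−2)ρ_t))` after), then the
  slow weights move `φ ← (1−α)φ + αθ` with α = 0.5.
* **Metrics** — accuracy, precision, recall, specificity, F1 and
  `MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.

Everything is data frame in, tibble out, with broom-style `tidy()` /
`glance()` and ggplot2 `autoplot()` methods.

## Worked example

```r
library(cardiopredict)
library(dplyr)

spec <- cohort_spec(n = 2000, seed = 42, dup_count = 10,
                    outliers = list(negative_bp = 3, ap_hi_over_200 = 4))
cohort  <- generate_cohort(spec) %>% plant_anomalies(spec)
cleaned <- clean_cohort(cohort)
cleaning_report(cleaned)
#> # A tibble: 5 × 2
#>   rule                   removed
#>   <chr>                    <int>
#> 1 duplicate                   10
#> 2 negative_bp                  3
#> 3 ap_hi_over_200               4
#> 4 ap_lo_under_50               0
#> 5 height_weight_quantile     324
```

All 17 planted anomalies are removed under their own rules; the
height/weight trim additionally drops the 5% distribution tails, as the
cleaning procedure prescribes. Ranking the cleaned, feature-engineered
records:

```r
imp <- cleaned %>% add_derived_features() %>% rank_features(seed = 42)
head(tidy(imp), 5)
#> # A tibble: 5 × 3
#>   feature importance  rank
#>   <chr>        <dbl> <int>
#> 1 BMI          0.148     1
#> 2 age          0.142     2
#> 3 weight       0.119     3
#> 4 MAP          0.112     4
#> 5 height       0.101     5
```

The planted risk drivers (BMI, age, MAP and the blood-pressure block)
dominate the normalised importances, which sum to 1. The whole protocol —
clean, derive, rank, keep the top 12, min-max normalise, one-hot encode
gender, stratified 80/20 split, train the Softsign LSTM under R-Lookahead,
evaluate held-out — is one call:

```r
run <- run_pipeline(run_config(n = 2000, seed = 42, epochs = 50))
run
#> Cardio risk prediction run
#>   rows: raw 2000 -> cleaned 1676 (train 1341 / test 335)
#>   selected features: age, BMI, MAP, weight, height, ap_hi, PP, ap_lo, cholesterol, active, gender, gluc
#>   optimizer r-lookahead, variant softsign
#>   held-out metrics:
#>   accuracy precision recall     f1 specificity   mcc
#> 1    0.797    0.7964 0.7964 0.7964      0.7976 0.594
```

Held-out accuracy of 0.797 against the generator's Bayes ceiling of about
0.91 (see the methods vignette): the model has learned most of the planted
signal within the 50-epoch budget, with balanced precision/recall and an
MCC of 0.59. `autoplot(run$model)` draws the loss trajectory,
`autoplot(run$importance)` the ranking, and
`compare_optimizers(config, c("rmsprop", "adam", "radam", "lookahead",
"r-lookahead"))` reproduces the optimizer comparison tables at steps
500–2000.

A thin command-line wrapper over the same functions ships at
`inst/cli/cardiopredict.R` (`simulate`, `clean`, `features`, `corr`,
`rank`, `run`, `compare` subcommands).

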