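# tiiclnc

Discovery of **tumor-infiltrating immune cell-associated lncRNA (TIIClnc)
prognostic signatures** from bulk transcriptomes.

Long noncoding RNAs that are highly and *uniformly* expressed across purified
immune cell types, yet depleted in tumor cell lines, behave as transcriptional
proxies for immune infiltration when measured in bulk tumor tissue. This
package implements the full discovery pipeline that turns that observation
into a validated prognostic score: candidate screening on purified-cell
panels, survival-based feature selection, an exhaustive benchmark of
selector→predictor machine-learning combinations, and risk stratification —
together with a synthetic-data generator that plants a known ground truth so
every stage can be checked end to end.

## The method

**Four-stage screen.** Starting from a lncRNA-by-sample panel of purified
immune cell lines (by default 19 cell types with replicate lines):

1. **Top expression** — the top 15% expressed lncRNAs of each immune cell
   line are pooled as candidates.
2. **Generality** — per candidate, replicate lines are averaged within each
   cell type (linear scale) and the cell-type specificity index

   TSI = Σᵢ₌₁..N (1 − xᵢ) / (N − 1),   xᵢ = profileᵢ / maxᵢ(profile)

   is computed over the N cell types; TSI = 0 means uniform ("general")
   expression, TSI = 1 single-type expression. Candidates with TSI < 0.2 are
   kept as immune-intrinsic lncRNAs.
3. **Tumor depletion** — Welch's t-test (Benjamini–Hochberg, FDR 0.05) keeps
   lncRNAs significantly higher in immune cell lines than in tumor cell lines.
4. **Prognosis** — a univariate Cox screen on the training cohort keeps
   lncRNAs with Wald p < 0.05 (z-scored expression).

**Combination harness.** Survival learners are held in a registry (Cox,
lasso/ridge/elastic net, stepwise Cox, componentwise CoxBoost, random
survival forest); every single predictor and every cross-family
selector→predictor composition is trained with 10-fold cross-validated
hyperparameters and ranked by mean validation-cohort concordance (C-index).
The flagship composition is **CoxBoost → RSF**: componentwise likelihood
boosting picks the sparse lncRNA set, and a random survival forest split by
the standardized log-rank score statistic

S(x, c) = ( Σ_{xⱼ ≤ c} aⱼ − n₁·ā ) / √( n₁ (1 − n₁/n) s²ₐ )

(with aⱼ the Savage/log-rank scores of the node's subjects) predicts
ensemble-mortality risk. Cohorts are stratified at the maximally selected
log-rank cutpoint; evaluation covers Kaplan–Meier/log-rank tests, IPCW
time-dependent AUC, and calibration curves. All survival machinery (Cox
partial likelihood with Efron ties, boosting, forests, C-index, KM,
log-rank scores and tests, time-dependent AUC) is implemented from first
principles in this package.

## Worked example

```r
library(tiiclnc)

cfg   <- sim_config(seed = 7)          # 19 cell types x 5 lines, 2000 lncRNAs,
study <- simulate_study(cfg)           # 10 tumor lines, 3 bulk cohorts (n = 400)

trace <- run_screen(study$panel, study$annotation, study$tumor,
                    study$cohorts[[1]])
print(trace)
#> Four-stage TIIClncRNA screen:
#>   top_expressed    2000 ->  1990
#>   tsi_general      1990 ->    30
#>   differential       30 ->    30
#>   univariate_cox     30 ->    13

cohorts  <- lapply(study$cohorts, function(co) {
  co$expr <- co$expr[trace$selected, , drop = FALSE]; co })
registry <- default_registry(rsf_trees = 300)
sig <- build_signature(cohorts[[1]], selector = "coxboost",
                       predictor = "rsf", registry, k = 10, seed = 8)
print(sig)
#> TIIClnc signature: 12 lncRNA(s), coxboost selector + rsf predictor, cutpoint 138.3

for (co in cohorts[2:3]) {
  scores <- score_cohort(sig, co, restandardize = TRUE)
  sd_    <- surv_data(co$time, co$event)
  strat  <- stratify_and_test(scores, optimal_cutpoint(scores, sd_)$cutpoint, sd_)
  cat(sprintf("%s: C-index %.3f, log-rank p = %.2g\n", co$name,
              concordance_index(scores, sd_), strat$test$p_value))
}
#> cohort2: C-index 0.756, log-rank p = 1.1e-33
#> cohort3: C-index 0.775, log-rank p = 9e-48
```

The screen funnels 2000 lncRNAs down to 13, recovering all 12 planted
prognostic immune-general lncRNAs (one false positive); the CoxBoost→RSF
signature transfers to the two held-out cohorts with C ≈ 0.76 and cleanly
separated Kaplan–Meier strata. `benchmark_combos()` runs the same exercise
over the whole registry and returns a leaderboard; a YAML-driven front end
(`pipeline_simulate`/`pipeline_screen`/`pipeline_benchmark`/`pipeline_fit`,
also callable via `inst/cli/tiiclnc.R`) orchestrates everything from a
single config.

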