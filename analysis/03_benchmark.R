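#!/usr/bin/env Rscript
# Benchmark O-PLS against LASSO, random forest and SVR (linear/quadratic)
# on the stratified train/test split, then compare per-sample LOOCV errors
# with an exact binomial win-count test against O-PLS.

library(oplsense)

seed <- 1
sim <- generate_rppa_like(synthetic_preset("default", seed = seed))
al <- intersect_datasets(sim$x, sim$y)
sc <- autoscale(impute_missing(filter_by_detection(al$x)))
split <- stratified_split(sc$x, al$y, test_n = 6, seed = seed)

rep <- run_baselines(
  train = list(x = sc$x[split$train_ids, ], y = al$y$auc[split$train_ids]),
  test = list(x = sc$x[split$test_ids, ], y = al$y$auc[split$test_ids]),
  model_specs = c("opls", "lasso_cv", "random_forest",
                  "svr_linear", "svr_quadratic"),
  reference = "opls", seed = seed)
print(rep)
dir.create("results", showWarnings = FALSE)
write_comparison_report(rep, "results/benchmark_split.tsv",
                        "results/benchmark_split.json")

cat("\nLeave-one-out comparison on the confounded regime (binomial test vs O-PLS):\n")
simc <- generate_rppa_like(synthetic_preset("confounded", seed = seed))
alc <- intersect_datasets(simc$x, simc$y)
scc <- autoscale(impute_missing(filter_by_detection(alc$x)))
loo <- loocv_compare(scc$x, alc$y, model_specs = c("opls", "svr_linear"),
                     reference = "opls", seed = seed)
vs <- loo$vs_reference$svr_linear
cat(sprintf("O-PLS wins %g of %d cell lines vs linear SVR (ties: %d), two-sided binomial p = %.3g\n",
            vs$wins, vs$n, vs$ties, vs$p_value))
write_comparison_report(loo, "results/benchmark_loocv.tsv",
                        "results/benchmark_loocv.json")
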