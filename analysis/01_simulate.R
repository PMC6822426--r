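#!/usr/bin/env Rscript
# Generate the synthetic study datasets: an RPPA-like 30 x 200 matrix with a
# planted sensitivity-predictive direction and a tumor-type-driven
# orthogonal factor, under the default and the confounded (3x) regime.

library(oplsense)

seed <- 1
dir.create("results", showWarnings = FALSE)

for (preset in c("default", "confounded")) {
  out <- file.path("results", paste0("data_", preset))
  simulate_to_dir(preset, seed = seed, out_dir = out)
  sim <- generate_rppa_like(synthetic_preset(preset, seed = seed))
  cat(sprintf(
    "[%s] wrote %s: %d samples x %d features, %.1f%% missing, %d planted predictive features, orthogonal strength %gx\n",
    preset, out, nrow(sim$x$values), ncol(sim$x$values),
    100 * mean(is.na(sim$x$values)),
    length(sim$truth$planted_features), sim$truth$spec$orth_strength))
}
cat("Ground truth (planted/orthogonal/receptor feature ids) is in truth.json per directory.\n")
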