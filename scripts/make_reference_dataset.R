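#!/usr/bin/env Rscript
## Regenerates the packaged synthetic reference measurements
## (inst/extdata/measurements_synthetic.tsv): chloroplast metabolite totals
## emitted from Rubisco-only ground truths under both conditions, with
## 4-replicate lognormal noise.  Run from the repository root.

library(pyrenoidCBC)

scens <- standard_scenarios()
rows <- list()
for (spec in list(list(cond = "HC", seed = 101L),
                  list(cond = "LC*", seed = 202L))) {
  truth <- generate_ground_truth(scens$rubisco, spec$cond, seed = spec$seed)
  ds <- emit_measurements(truth, noise_cv = 0.15, n_replicates = 4,
                          seed = spec$seed + 1L)
  rows[[spec$cond]] <- ds$measurements
}
out <- do.call(rbind, rows)
write_measurements(out, "inst/extdata/measurements_synthetic.tsv")
cat("wrote", nrow(out), "rows\n")
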