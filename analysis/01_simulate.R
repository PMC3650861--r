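#!/usr/bin/env Rscript
# Stage 1: generate the study-mimic synthetic cohort (master seed 17).
#
# The cohort reproduces the study design: 12 normal donor livers, 30
# HCV-cirrhosis, 31 early (T1/T2) and 18 late (T3/T4) HCC samples, over
# the 179-slot liver-development registry and the 1,399-slot silent
# registry, with probe-level technical bias in GC / Tm / position.

library(livdevscreen)

dir.create("results", showWarnings = FALSE)

registry <- default_registry()
config <- study_mimic_config(master_seed = 17, registry = registry)
sim <- generate_cohort(config)

write_expression_tsv(sim$expr, "results/expression_true.tsv",
                     "results/groups.tsv")
biased <- inject_technical_bias(sim$probes, sim$truth)
write_probe_tsv(biased, "results/probes_raw.tsv")
write_truth(sim$truth, "results/truth.json")
write_registry(registry, "results/registry.yaml")

cat(sprintf("cohort: %d genes x %d samples (%s)\n",
            nrow(sim$expr$exprs), ncol(sim$expr$exprs),
            paste(table(sim$expr$groups), collapse = "/")))
cat(sprintf("probe table: %d probes, planted bias amplitudes gc=%.1f tm=%.1f pos=%.1f\n",
            nrow(biased$intensities), config$bias_amplitudes[["gc"]],
            config$bias_amplitudes[["tm"]], config$bias_amplitudes[["position"]]))
cat("wrote results/expression_true.tsv, probes_raw.tsv, truth.json, registry.yaml\n")
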