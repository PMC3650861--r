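#!/usr/bin/env Rscript
# Stage 5: BMP-inhibitor marker panel.
#
# Coverage of tumor samples under the rule "at least one of GPC3, GREM1,
# FSTL3, FST with per-sample fold-change > 1.5 vs the normal mean", plus
# a greedy set-cover search over the BMP gene set as candidates.

library(livdevscreen)

expr <- read_expression_tsv("results/expression_true.tsv", "results/groups.tsv")
registry <- default_registry()

pr <- panel_coverage(expr, registry$panel, "HCC", threshold = 1.5)
write.table(pr$per_sample, "results/panel.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(pr)
for (g in registry$panel) {
  cat(sprintf("  %s alone: %.0f%%; panel without it: %.0f%%\n", g,
              100 * panel_coverage(expr, g, "HCC")$coverage,
              100 * panel_coverage(expr, setdiff(registry$panel, g),
                                   "HCC")$coverage))
}

found <- greedy_panel_search(expr, registry$bmp, "HCC", max_size = 4)
cat("greedy search over the BMP set picks:", paste(found, collapse = ", "),
    sprintf("(coverage %.0f%%)\n",
            100 * panel_coverage(expr, found, "HCC")$coverage))
cat("wrote results/panel.tsv\n")
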