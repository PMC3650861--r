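#!/usr/bin/env Rscript
# Stage 3: combined mean-variance differential-expression screen over the
# 179-slot liver-development registry, with expression-pattern
# classification (cirrhosis peak, tumor-only, late-only, ...).

library(livdevscreen)

expr <- read_expression_tsv("results/expression_true.tsv", "results/groups.tsv")
registry <- default_registry()

de <- screen_gene_set(expr, registry$liver_dev$gene_id, alpha = 0.001)
write_de_tsv(de, "results/de_screen.tsv")

flagged <- de$NOR_CIR_sig | de$NOR_EARLY_sig | de$NOR_LATE_sig
cat(sprintf("flagged in >= 1 normal-vs-disease contrast: %d/%d (%.0f%%)\n",
            sum(flagged), nrow(de), 100 * mean(flagged)))
cat("pattern counts:\n")
print(table(de$pattern))

late_only <- de$gene_id[de$pattern == "LATE_ONLY"]
cat("late-only genes:", paste(late_only, collapse = ", "), "\n")
ep <- de[de$gene_id == "EPCAM", ]
cat(sprintf("EPCAM fold-changes vs normal: CIR %.1f, early %.1f, late %.1f (%s)\n",
            ep$NOR_CIR_fc, ep$NOR_EARLY_fc, ep$NOR_LATE_fc, ep$pattern))
cat("wrote results/de_screen.tsv\n")
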