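#!/usr/bin/env Rscript
# Stage 3: single-sample gene-set variation scores by the rank-based random
# walk, and the two-group comparison of pathway scores.

library(mdmnet)

counts <- read_counts("results/study/counts.tsv")
meta <- read_panel("results/study/metadata.tsv", "metadata")
sets <- read_gmt("results/study/gene_sets.gmt")

nm <- log_cpm(counts, tmm_factors(counts))
scores <- gsva_scores(nm, sets)
df <- data.frame(set_id = rownames(scores), signif(unclass(scores), 6),
                 check.names = FALSE)
write.table(df, "results/pathway_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

res <- pathway_group_test(scores, meta)
write.table(format(res, digits = 6), "results/pathway_dge.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("%d sets scored on %d samples; score range [%.3f, %.3f]\n",
            nrow(scores), ncol(scores), min(scores), max(scores)))
cat("pathways ranked by group difference:\n")
print(head(res[, c("set_id", "effect", "t_mod", "p", "adj_p")], 5),
      row.names = FALSE, digits = 4)
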