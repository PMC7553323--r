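#!/usr/bin/env Rscript
# Stage 2: TMM-normalized log2-CPM differential expression between groups
# with the empirical-Bayes moderated t, BH adjustment, and the gene
# selections used downstream.

library(mdmnet)

counts <- read_counts("results/study/counts.tsv")
meta <- read_panel("results/study/metadata.tsv", "metadata")
truth <- jsonlite::read_json("results/study/truth.json",
                             simplifyVector = TRUE)

deg <- run_dge(counts, meta)
write.table(format(as.data.frame(deg), digits = 6), "results/dge.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

n_nom <- sum(deg$p < 0.05, na.rm = TRUE)
n_adj <- sum(deg$adj_p < 0.05, na.rm = TRUE)
cat(sprintf("DEGs: %d at nominal p < 0.05; %d at BH-adjusted p < 0.05\n",
            n_nom, n_adj))

hits <- select_genes(deg, "adj_p_threshold", 0.05)
sens <- mean(truth$de_gene_ids %in% hits)
cat(sprintf("sensitivity for planted DE genes at adjusted p < 0.05: %.2f\n",
            sens))
cat(sprintf("genes at p < 0.01 entering the integrative model: %d\n",
            length(select_genes(deg, "p_threshold", 0.01))))
cat("top genes by p:\n")
print(head(as.data.frame(deg)[, c("gene_id", "logFC", "t_mod", "p", "adj_p")],
           5), row.names = FALSE, digits = 4)
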