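#!/usr/bin/env Rscript
# Stage 5: the integrative model — rank lipid species by their average
# Pearson correlation to the p < 0.01 DEGs, take the top 50, correlate all
# allowed gene/lipid/biomarker pairs, and keep edges with |r| > 0.5 and
# p < 0.01.

library(mdmnet)

counts <- read_counts("results/study/counts.tsv")
meta <- read_panel("results/study/metadata.tsv", "metadata")
lipids <- read_panel("results/study/lipids.tsv", "lipid")
bio <- read_panel("results/study/biomarkers.tsv", "biomarker")
truth <- jsonlite::read_json("results/study/truth.json",
                             simplifyVector = TRUE)

deg <- run_dge(counts, meta)
nm <- attr(deg, "normalized")
cfg <- network_config()  # p < 0.01 genes, top 50 lipids, |r| > 0.5, p < 0.01

ranking <- rank_lipids(nm, lipids, deg, cfg)
write.table(format(ranking, digits = 6), "results/lipid_ranking.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
top50 <- head(ranking$lipid_id, 50)
cat(sprintf("lipid ranking: %d species; %d of %d planted block lipids in the top 50\n",
            nrow(ranking), sum(top50 %in% truth$block_lipid_ids),
            length(truth$block_lipid_ids)))

net <- build_network(nm, lipids, bio, deg, ranking, cfg)
write_network(net, "results/network", "tsv_pair")
write_network(net, "results/network.graphml", "graphml")

summ <- network_summary(net)
write.table(summ$degrees, "results/network_degrees.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("network: %d nodes, %d edges\n", nrow(net$nodes),
            nrow(net$edges)))
print(summ$edge_counts, row.names = FALSE)
cat("hub nodes by degree:\n")
print(head(summ$degrees, 8), row.names = FALSE)
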