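#!/usr/bin/env Rscript
# Stage 4: associate gene expression with serum covariates — the
# biomarker-to-pathway cascade for sCD14, per-biomarker gene association
# tables, and the age confounder scan.

library(mdmnet)

counts <- read_counts("results/study/counts.tsv")
meta <- read_panel("results/study/metadata.tsv", "metadata")
bio <- read_panel("results/study/biomarkers.tsv", "biomarker")
sets <- read_gmt("results/study/gene_sets.gmt")

nm <- log_cpm(counts, tmm_factors(counts))

for (marker in c("sCD14", "sCD163", "TNFR2")) {
  assoc <- feature_covariate_association(nm, bio$values[marker, ],
                                         covariate_id = marker)
  write.table(format(assoc, digits = 6),
              sprintf("results/assoc_%s.tsv", marker),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d genes at p < 0.05 (strongest r = %.2f)\n", marker,
              sum(assoc$p < 0.05), assoc$r[which.min(assoc$p)]))
}

casc <- biomarker_pathway_cascade(nm, sets, bio$values["sCD14", ],
                                  covariate_id = "sCD14")
cat(sprintf("sCD14 cascade: %d genes at p <= 0.05 -> %d sets scored -> %d sets at p <= 0.05\n",
            sum(casc$genes$p <= 0.05),
            if (is.null(casc$scores)) 0 else nrow(casc$scores),
            if (is.null(casc$pathways)) 0 else nrow(casc$pathways)))
if (!is.null(casc$pathways)) {
  write.table(format(casc$pathways, digits = 6),
              "results/cascade_sCD14_pathways.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("pathways tracking sCD14 (by PCC):\n")
  print(head(casc$pathways[, c("feature_id", "r", "p", "adj_p")], 5),
        row.names = FALSE, digits = 3)
}

age <- setNames(meta$age, meta$sample_id)
scan <- confounder_scan(nm, age)
cat(sprintf("age confounder scan: %d of %d genes at nominal p < 0.05\n",
            scan$n_below, nrow(scan$table)))
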