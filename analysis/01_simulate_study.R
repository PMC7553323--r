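#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-group study that stands in for the
# cohort (13 control / 15 condition donors): NB counts for 2,000 genes with
# 10% planted DE, a 200-species 13-class lipidome with ceramide/SaFA
# elevation and PUFA depletion in the condition group, a 12-marker
# inflammation panel, and the planted truth for later evaluation.

library(mdmnet)

out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(seed = 20260928)
study <- generate_study(cfg)

write_counts(study$counts, file.path(out, "counts.tsv"))
write_panel(study$lipids, file.path(out, "lipids.tsv"))
write_panel(study$biomarkers, file.path(out, "biomarkers.tsv"))
write_panel(study$metadata, file.path(out, "metadata.tsv"))
jsonlite::write_json(study$truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

# gene sets for the pathway stages: the planted module plus random sets
set.seed(cfg$seed + 1)
gene_ids <- rownames(study$counts$counts)
sets <- gene_set_collection(c(
  list(MODULE = study$truth$module_gene_ids),
  stats::setNames(lapply(1:20, function(i) sample(gene_ids, 30)),
                  sprintf("RANDOM%02d", 1:20))))
write_gmt(sets, file.path(out, "gene_sets.gmt"))

cat(sprintf("study: %d genes x %d samples; %d lipid species in %d classes; %d biomarkers\n",
            nrow(study$counts$counts), ncol(study$counts$counts),
            nrow(study$lipids$concentrations),
            length(unique(study$lipids$class)),
            nrow(study$biomarkers$values)))
cat(sprintf("planted: %d DE genes, %d module genes, %d block lipids\n",
            length(study$truth$de_gene_ids),
            length(study$truth$module_gene_ids),
            length(study$truth$block_lipid_ids)))
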