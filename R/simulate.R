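#' @title Synthetic multi-omic study generator
#' @description A seeded generator for a complete two-group study: negative
#'   binomial RNA-seq counts with planted differentially expressed genes, a
#'   13-class serum lipidome with saturated-fatty-acid and ceramide elevation
#'   and polyunsaturated-fatty-acid depletion in the condition group, a
#'   12-marker inflammation biomarker panel, and sample metadata. A single
#'   latent inflammation factor, mean-shifted in group B, couples a gene
#'   module, a lipid block and the biomarkers into one interactive system,
#'   so that the downstream correlation network has planted structure to
#'   recover.
#' @name simulate
NULL

# FFA species with their saturation annotation; the four SaFA species mirror
# the serum fatty acids elevated in the condition group (14:0, 16:0, 17:0,
# 18:0).
ffa_species <- function() {
  c("FFA(14:0)" = "SaFA", "FFA(16:0)" = "SaFA", "FFA(17:0)" = "SaFA",
    "FFA(18:0)" = "SaFA", "FFA(16:1)" = "MUFA", "FFA(18:1)" = "MUFA",
    "FFA(18:2)" = "PUFA", "FFA(18:3)" = "PUFA", "FFA(20:4)" = "PUFA",
    "FFA(22:6)" = "PUFA")
}

#' Simulation configuration
#'
#' Defaults emulate the motivating study's design: 13 control (A) and 15
#' condition (B) donors, a desk-scale expressed transcriptome of 2,000
#' genes, a 200-species lipidome spanning all 13 classes, and a latent
#' inflammation factor shifted by one standard deviation in group B that
#' loads on a 100-gene module, a 30-lipid block and all 12 biomarkers.
#'
#' @param n_A,n_B Samples per group (defaults 13 and 15).
#' @param n_genes Number of genes (default 2000).
#' @param n_lipids Number of lipid species, >= 36 so every class is
#'   populated (default 200).
#' @param frac_de Fraction of genes planted as differentially expressed
#'   (default 0.1).
#' @param logfc_values Planted log2 fold changes sampled uniformly for DE
#'   genes (default \code{c(-2, -1, 1, 2)}).
#' @param nb_dispersion_meanlog,nb_dispersion_sdlog Log-normal
#'   hyperparameters of the per-gene negative-binomial dispersion
#'   (defaults log(0.1) and 0.3).
#' @param libsize_meanlog,libsize_sdlog Log-normal hyperparameters of the
#'   per-sample library size (defaults log(1e6) and 0.2).
#' @param factor_shift Mean shift (in SD units) of the latent factor in
#'   group B (default 1).
#' @param gene_module_size Genes loading on the latent factor (default 100;
#'   disjoint from the planted DE genes).
#' @param lipid_block_size Lipid species loading on the latent factor
#'   (default 30).
#' @param loading Correlation strength in [0, 1) between loaded features and
#'   the latent factor (default 0.8). For module genes it enters the count
#'   mean as \eqn{2^{loading \cdot u_j}}; for lipids and biomarkers the
#'   log-scale coefficient is chosen so the latent-factor correlation of the
#'   noise-free log level equals \code{loading}.
#' @param class_effects Named multiplicative group-B effects on lipid
#'   concentrations; names are class labels or the pseudo-classes
#'   \code{FFA_SaFA}, \code{FFA_MUFA}, \code{FFA_PUFA} for
#'   saturation-resolved free fatty acids. Default: ceramides and saturated
#'   FFAs up 1.5-fold, polyunsaturated FFAs down to 2/3.
#' @param seed Integer seed; same config + seed gives bit-identical output.
#' @return List of class \code{simulation_config}.
#' @export
simulation_config <- function(n_A = 13, n_B = 15,
                              n_genes = 2000, n_lipids = 200,
                              frac_de = 0.1,
                              logfc_values = c(-2, -1, 1, 2),
                              nb_dispersion_meanlog = log(0.1),
                              nb_dispersion_sdlog = 0.3,
                              libsize_meanlog = log(1e6),
                              libsize_sdlog = 0.2,
                              factor_shift = 1,
                              gene_module_size = 100,
                              lipid_block_size = 30,
                              loading = 0.8,
                              class_effects = c(CER = 1.5, FFA_SaFA = 1.5,
                                                FFA_PUFA = 2 / 3),
                              seed = 1L) {
  cfg <- list(n_A = n_A, n_B = n_B, n_genes = n_genes, n_lipids = n_lipids,
              frac_de = frac_de, logfc_values = logfc_values,
              nb_dispersion_meanlog = nb_dispersion_meanlog,
              nb_dispersion_sdlog = nb_dispersion_sdlog,
              libsize_meanlog = libsize_meanlog,
              libsize_sdlog = libsize_sdlog,
              factor_shift = factor_shift,
              gene_module_size = gene_module_size,
              lipid_block_size = lipid_block_size,
              loading = loading, class_effects = class_effects,
              seed = as.integer(seed))
  ok_counts <- c("n_A", "n_B", "n_genes", "n_lipids")
  if (any(vapply(cfg[ok_counts], function(x) x < 1, logical(1))))
    stop("sample and feature counts must be positive", call. = FALSE)
  if (cfg$n_lipids < 36)
    stop("n_lipids must be >= 36 to populate all 13 classes", call. = FALSE)
  if (cfg$frac_de < 0 || cfg$frac_de >= 1)
    stop("frac_de must lie in [0, 1)", call. = FALSE)
  if (cfg$loading < 0 || cfg$loading >= 1)
    stop("loading must lie in [0, 1)", call. = FALSE)
  if (cfg$gene_module_size + round(cfg$frac_de * cfg$n_genes) > cfg$n_genes)
    stop("gene module and DE genes cannot exceed n_genes", call. = FALSE)
  if (cfg$lipid_block_size > cfg$n_lipids)
    stop("lipid_block_size cannot exceed n_lipids", call. = FALSE)
  extra <- setdiff(names(cfg$class_effects),
                   c(lipid_classes(), "FFA_SaFA", "FFA_MUFA", "FFA_PUFA"))
  if (length(extra) > 0)
    stop("unknown class_effects name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  structure(cfg, class = "simulation_config")
}

#' Draw negative binomial counts with a mean/dispersion parameterization
#'
#' Variance is \eqn{mean + dispersion \cdot mean^2}; the Poisson limit is
#' approached as dispersion tends to 0.
#'
#' @param n Number of draws.
#' @param mean Positive mean (scalar or length n).
#' @param dispersion Positive dispersion (scalar or length n).
#' @return Integer vector of n non-negative counts.
#' @export
sample_nb <- function(n, mean, dispersion) {
  if (any(mean <= 0)) stop("mean must be > 0", call. = FALSE)
  if (any(dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  stats::rnbinom(n, mu = mean, size = 1 / dispersion)
}

#' Generate a complete synthetic two-group multi-omic study
#'
#' Draw order (fixed, so outputs are reproducible across versions): sample
#' ages; latent factor u; gene relative abundances; DE gene assignment and
#' fold changes; module gene assignment; per-gene dispersions; library
#' sizes; the count matrix (sample-major, genes fastest); lipid base
#' concentrations; lipid block assignment; lipid noise; biomarker base
#' levels; biomarker noise.
#'
#' Counts are \eqn{c_{gj} \sim NB(L_j q_g 2^{x_j \beta_g + \lambda_g u_j},
#' \phi_g)} with \eqn{x_j} the group indicator; lipid species are log-normal
#' around a species base level times the class group effect, with the block
#' species loading on u; the 12 biomarkers (sCD14, sCD163, TNFR1, TNFR2,
#' IL-6, CRP, ICAM-1, VCAM-1, CX3CL1, LBP, MPO, D-dimer) are log-normal with
#' positive loading on u, so group B inherits elevated inflammation via the
#' factor shift.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{counts} (\code{\link{expression_matrix}}),
#'   \code{lipids} (\code{\link{lipid_panel}}), \code{biomarkers}
#'   (\code{\link{biomarker_panel}}), \code{metadata}
#'   (\code{\link{sample_metadata}} with an \code{age} covariate) and
#'   \code{truth} (planted DE genes and log2FC, module genes, block lipids,
#'   per-feature loadings, latent factor per sample).
#' @export
generate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_A + config$n_B
  sample_ids <- sprintf("S%02d", seq_len(n))
  group <- rep(c("A", "B"), c(config$n_A, config$n_B))
  x <- as.numeric(group == "B")

  age <- round(stats::rnorm(n, 45, 10))
  u <- stats::rnorm(n, mean = config$factor_shift * x, sd = 1)
  names(u) <- sample_ids

  # --- transcriptome ---
  gene_ids <- sprintf("G%04d", seq_len(config$n_genes))
  q <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1.2)
  q <- q / sum(q)
  n_de <- round(config$frac_de * config$n_genes)
  de_idx <- sort(sample.int(config$n_genes, n_de))
  beta <- numeric(config$n_genes)
  beta[de_idx] <- sample(config$logfc_values, n_de, replace = TRUE)
  # the inflammation module sits among the up-regulated DE genes (as in the
  # motivating biology, where factor-tracking genes are themselves top DEGs);
  # topped up from non-DE genes if the sign draw leaves too few
  up_idx <- de_idx[beta[de_idx] > 0]
  module_idx <- if (length(up_idx) >= config$gene_module_size) {
    sort(sample(up_idx, config$gene_module_size))
  } else {
    sort(c(up_idx, sample(setdiff(seq_len(config$n_genes), de_idx),
                          config$gene_module_size - length(up_idx))))
  }
  lambda <- numeric(config$n_genes)
  lambda[module_idx] <- config$loading
  phi <- stats::rlnorm(config$n_genes, config$nb_dispersion_meanlog,
                       config$nb_dispersion_sdlog)
  lib <- stats::rlnorm(n, config$libsize_meanlog, config$libsize_sdlog)
  mu <- outer(q, lib) * 2^(outer(beta, x) + outer(lambda, u))
  counts <- matrix(sample_nb(length(mu), as.vector(mu), rep(phi, n)),
                   nrow = config$n_genes,
                   dimnames = list(gene_ids, sample_ids))

  # --- lipidome: 10 named FFA species plus the other 12 classes ---
  ffa <- ffa_species()
  other <- setdiff(lipid_classes(), "FFA")
  remaining <- config$n_lipids - length(ffa)
  weights <- c(TAG = 0.38, PC = 0.12, CE = 0.10, SM = 0.08, DAG = 0.06,
               PE = 0.06, CER = 0.06, LPC = 0.04, LPE = 0.02, DCER = 0.03,
               HCER = 0.025, LCER = 0.025)[other]
  n_per <- stats::setNames(pmax(1, round(remaining * weights / sum(weights))),
                           other)
  while (sum(n_per) != remaining) {  # nudge largest classes to hit the total
    k <- if (sum(n_per) > remaining) which.max(n_per) else which.max(weights)
    n_per[k] <- n_per[k] + sign(remaining - sum(n_per))
  }
  lipid_class <- c(rep("FFA", length(ffa)), rep(other, n_per))
  lipid_ids <- c(names(ffa),
                 unlist(lapply(other, function(cl)
                   sprintf("%s(%02d)", cl, seq_len(n_per[cl])))))
  names(lipid_class) <- lipid_ids

  mult <- rep(1, config$n_lipids)
  names(mult) <- lipid_ids
  ce <- config$class_effects
  for (nm in names(ce)) {
    if (nm %in% c("FFA_SaFA", "FFA_MUFA", "FFA_PUFA")) {
      sat <- sub("FFA_", "", nm)
      mult[names(ffa)[ffa == sat]] <- ce[[nm]]
    } else {
      mult[lipid_class == nm] <- ce[[nm]]
    }
  }

  sigma_l <- 0.4  # log-scale species noise SD
  base_l <- stats::rlnorm(config$n_lipids, meanlog = log(5), sdlog = 1)
  block_idx <- sort(sample.int(config$n_lipids, config$lipid_block_size))
  lambda_l <- numeric(config$n_lipids)
  lambda_l[block_idx] <- config$loading / sqrt(1 - config$loading^2) * sigma_l
  eps_l <- matrix(stats::rnorm(config$n_lipids * n, 0, sigma_l),
                  config$n_lipids, n)
  conc <- base_l * exp(outer(lambda_l, u) + eps_l) * outer(mult, x, "^")
  dimnames(conc) <- list(lipid_ids, sample_ids)

  # --- biomarker panel ---
  marker_ids <- c("sCD14", "sCD163", "TNFR1", "TNFR2", "IL-6", "CRP",
                  "ICAM-1", "VCAM-1", "CX3CL1", "LBP", "MPO", "D-dimer")
  sigma_m <- 0.4
  base_m <- stats::rlnorm(length(marker_ids), meanlog = log(1000), sdlog = 1)
  lambda_m <- rep(config$loading / sqrt(1 - config$loading^2) * sigma_m,
                  length(marker_ids))
  eps_m <- matrix(stats::rnorm(length(marker_ids) * n, 0, sigma_m),
                  length(marker_ids), n)
  bio <- base_m * exp(outer(lambda_m, u) + eps_m)
  dimnames(bio) <- list(marker_ids, sample_ids)

  meta <- sample_metadata(sample_ids, group, data.frame(age = age))
  truth <- list(de_gene_ids = gene_ids[de_idx],
                de_logfc = stats::setNames(beta[de_idx], gene_ids[de_idx]),
                module_gene_ids = gene_ids[module_idx],
                block_lipid_ids = lipid_ids[block_idx],
                gene_loadings = stats::setNames(lambda, gene_ids),
                lipid_loadings = stats::setNames(lambda_l, lipid_ids),
                factor = u)

  list(counts = expression_matrix(counts),
       lipids = lipid_panel(conc, lipid_class),
       biomarkers = biomarker_panel(bio),
       metadata = meta,
       truth = truth)
}
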