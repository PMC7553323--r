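#' @title End-to-end pipeline
#' @description One call that runs the whole analysis from a config: obtain
#'   inputs (simulate or read), differential expression, gene-set scoring,
#'   covariate associations, lipid ranking and the integrative network, with
#'   every intermediate persisted as a file and a checksum manifest written
#'   at the end. Reruns with identical config and inputs are byte-identical.
#' @name pipeline
NULL

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory (created if absent).
#' @param simulate NULL, or a \code{\link{simulation_config}} (or a list of
#'   overrides for one) to generate the study inputs.
#' @param paths When not simulating: named list with \code{counts},
#'   \code{lipids}, \code{biomarkers}, \code{metadata} file paths.
#' @param gene_sets Optional GMT path; when simulating and absent, a small
#'   collection (the planted module plus random sets) is generated.
#' @param covariates Covariate ids for the association stage: biomarker row
#'   ids and/or metadata covariate columns (default \code{c("sCD14", "age")}).
#' @param network A \code{\link{network_config}} or list of overrides.
#' @param gsva List of \code{tau}/\code{min_size} overrides.
#' @param seed Seed for any randomness in input generation.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            simulate = list(),
                            paths = NULL,
                            gene_sets = NULL,
                            covariates = c("sCD14", "age"),
                            network = list(),
                            gsva = list(),
                            seed = 1L) {
  if (!is.null(simulate) && !inherits(simulate, "simulation_config"))
    simulate <- do.call(simulation_config,
                        c(simulate, if (!"seed" %in% names(simulate))
                          list(seed = seed)))
  if (!inherits(network, "network_config"))
    network <- do.call(network_config, network)
  if (is.null(simulate)) {
    need <- c("counts", "lipids", "biomarkers", "metadata")
    if (is.null(paths) || !all(need %in% names(paths)))
      stop("paths must name counts, lipids, biomarkers, metadata",
           call. = FALSE)
    missing <- !vapply(paths[need], file.exists, logical(1))
    if (any(missing))
      stop("input file(s) not found: ",
           paste(unlist(paths[need])[missing], collapse = ", "),
           call. = FALSE)
  }
  structure(list(out_dir = out_dir, simulate = simulate, paths = paths,
                 gene_sets = gene_sets, covariates = covariates,
                 network = network,
                 gsva = utils::modifyList(list(tau = 1, min_size = 5), gsva),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of \code{\link{pipeline_config}}.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain inputs (simulate or read), write input copies,
#' DGE, gene-set scores and two-group pathway test, one association table
#' per configured covariate, lipid ranking, network construction and
#' persistence, then a manifest of every artifact with its MD5 checksum and
#' row count. A failing stage removes all files written so far and aborts
#' with the stage name.
#'
#' @param config A \code{\link{pipeline_config}} or a YAML path.
#' @return Invisibly, the manifest data.frame (\code{file}, \code{md5},
#'   \code{rows}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  note <- function(path) written <<- c(written, path)
  stage <- "setup"
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("pipeline failed in stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  out <- function(name) file.path(config$out_dir, name)

  manifest <- tryCatch({
    stage <- "inputs"
    if (!is.null(config$simulate)) {
      study <- generate_study(config$simulate)
      sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
        else default_gene_sets(study, config$seed)
      jsonlite::write_json(study$truth, out("truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      note(out("truth.json"))
    } else {
      study <- list(counts = read_counts(config$paths$counts),
                    lipids = read_panel(config$paths$lipids, "lipid"),
                    biomarkers = read_panel(config$paths$biomarkers,
                                            "biomarker"),
                    metadata = read_panel(config$paths$metadata, "metadata"))
      sets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
        else NULL
    }
    note(write_counts(study$counts, out("counts.tsv")))
    note(write_panel(study$lipids, out("lipids.tsv")))
    note(write_panel(study$biomarkers, out("biomarkers.tsv")))
    note(write_panel(study$metadata, out("metadata.tsv")))
    if (!is.null(sets)) note(write_gmt(sets, out("gene_sets.gmt")))

    stage <- "dge"
    deg <- run_dge(study$counts, study$metadata)
    nm <- attr(deg, "normalized")
    write_result_table(deg, out("dge.tsv"))
    note(out("dge.tsv"))

    stage <- "gsva"
    if (!is.null(sets) && length(sets) > 0) {
      scores <- gsva_scores(nm, sets, tau = config$gsva$tau,
                            min_size = config$gsva$min_size)
      write_scores(scores, out("pathway_scores.tsv"))
      note(out("pathway_scores.tsv"))
      write_result_table(pathway_group_test(scores, study$metadata),
                         out("pathway_dge.tsv"))
      note(out("pathway_dge.tsv"))
    }

    stage <- "covariates"
    for (cov_id in config$covariates) {
      covariate <- resolve_covariate(cov_id, study)
      assoc <- feature_covariate_association(nm, covariate,
                                             covariate_id = cov_id)
      fname <- out(sprintf("assoc_%s.tsv", gsub("[^A-Za-z0-9]", "_", cov_id)))
      write_result_table(assoc, fname)
      note(fname)
    }

    stage <- "lipid_ranking"
    ranking <- rank_lipids(nm, study$lipids, deg, config$network)
    write_result_table(ranking, out("lipid_ranking.tsv"))
    note(out("lipid_ranking.tsv"))

    stage <- "network"
    net <- build_network(nm, study$lipids, study$biomarkers, deg,
                         ranking, config$network)
    note(write_network(net, out("network"), "tsv_pair"))
    note(write_network(net, out("network.graphml"), "graphml"))
    summ <- network_summary(net)
    write_result_table(summ$degrees, out("network.summary.tsv"))
    note(out("network.summary.tsv"))

    stage <- "manifest"
    yaml::write_yaml(config_echo(config), out("config.yaml"))
    note(out("config.yaml"))
    files <- sort(unique(written))
    manifest <- data.frame(
      file = basename(files),
      md5 = unname(tools::md5sum(files)),
      rows = vapply(files, function(f)
        length(readLines(f, warn = FALSE)), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    utils::write.table(manifest, out("manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest
  }, error = on_fail)
  invisible(manifest)
}

# A desk-scale gene-set collection for simulated runs: the planted module
# plus seeded random sets of comparable size.
default_gene_sets <- function(study, seed, n_random = 20, size = 30) {
  set.seed(seed + 1)
  gene_ids <- rownames(study$counts$counts)
  sets <- c(list(MODULE = study$truth$module_gene_ids),
            stats::setNames(
              lapply(seq_len(n_random), function(i) sample(gene_ids, size)),
              sprintf("RANDOM%02d", seq_len(n_random))))
  gene_set_collection(sets)
}

resolve_covariate <- function(cov_id, study) {
  if (cov_id %in% rownames(study$biomarkers$values))
    return(study$biomarkers$values[cov_id, ])
  meta <- as.data.frame(study$metadata)
  if (cov_id %in% names(meta))
    return(stats::setNames(meta[[cov_id]], meta$sample_id))
  if (cov_id %in% rownames(study$lipids$class_totals))
    return(study$lipids$class_totals[cov_id, ])
  stop("covariate id not found in biomarkers, metadata or lipid classes: ",
       cov_id, call. = FALSE)
}

write_result_table <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

write_scores <- function(scores, path) {
  params <- attr(scores, "params")
  hdr <- sprintf("# %s = %s", names(params),
                 vapply(params, as.character, character(1)))
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(hdr, con)
  close(con)
  df <- data.frame(set_id = rownames(scores), signif(unclass(scores), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  suppressWarnings(
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE,
                       fileEncoding = "UTF-8"))
  invisible(path)
}

config_echo <- function(config) {
  list(out_dir = config$out_dir,
       simulate = if (!is.null(config$simulate))
         unclass(config$simulate) else NULL,
       paths = config$paths,
       gene_sets = config$gene_sets,
       covariates = as.list(config$covariates),
       network = unclass(config$network),
       gsva = config$gsva,
       seed = config$seed)
}
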