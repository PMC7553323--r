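#' @title Serum covariate association
#' @description Per-feature Pearson association of genes or pathway scores
#'   with a continuous per-sample covariate (serum biomarker, lipid class
#'   total, monocyte-subset proportion, age), the biomarker-to-pathway
#'   cascade, and the transcriptome-wide confounder scan.
#' @name covariate
NULL

align_covariate <- function(covariate, sample_ids) {
  if (!is.null(names(covariate))) {
    missing <- setdiff(sample_ids, names(covariate))
    if (length(missing) > 0)
      stop("covariate missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    covariate <- covariate[sample_ids]
  } else if (length(covariate) != length(sample_ids)) {
    stop("unnamed covariate must have one value per sample", call. = FALSE)
  }
  as.numeric(covariate)
}

#' Associate each feature with a continuous covariate
#'
#' Each matrix row is correlated with the covariate using
#' \code{\link{pearson_with_p}} (complete pairs only); features with fewer
#' than \code{min_n} complete pairs or an undefined correlation are skipped
#' with a message. BH adjustment is applied across the tested features.
#'
#' @param values Feature x sample numeric matrix (genes or pathway scores);
#'   a \code{normalized_matrix} or \code{pathway_score_matrix} is accepted.
#' @param covariate Per-sample numeric vector, named by sample id or aligned
#'   with the matrix columns; must not be constant.
#' @param rank_by \code{"p"} (ascending p) or \code{"r"} (descending r);
#'   ties broken by feature id.
#' @param covariate_id Label recorded in the output (default "covariate").
#' @param min_n Minimum complete pairs per feature (default 3).
#' @return data.frame of class \code{association_table}: \code{feature_id},
#'   \code{r}, \code{n}, \code{p}, \code{adj_p}, \code{covariate_id}.
#' @export
feature_covariate_association <- function(values, covariate,
                                          rank_by = c("p", "r"),
                                          covariate_id = "covariate",
                                          min_n = 3) {
  rank_by <- match.arg(rank_by)
  if (inherits(values, "normalized_matrix")) values <- values$logcpm
  values <- as.matrix(values)
  covariate <- align_covariate(covariate, colnames(values))
  if (stats::sd(covariate, na.rm = TRUE) == 0 || all(is.na(covariate)))
    stop("covariate is constant", call. = FALSE)

  recs <- lapply(seq_len(nrow(values)), function(i) {
    tryCatch(pearson_with_p(values[i, ], covariate, min_n = min_n),
             error = function(e) NULL)
  })
  ok <- !vapply(recs, is.null, logical(1))
  if (!all(ok))
    message(sum(!ok), " feature(s) skipped (constant or too few pairs)")
  if (!any(ok)) stop("no feature could be tested", call. = FALSE)

  out <- data.frame(
    feature_id = rownames(values)[ok],
    r = vapply(recs[ok], `[[`, numeric(1), "r"),
    n = vapply(recs[ok], `[[`, numeric(1), "n"),
    p = vapply(recs[ok], `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE, row.names = NULL)
  out$adj_p <- bh_adjust(out$p)
  out$covariate_id <- covariate_id
  ord <- if (rank_by == "p") order(out$p, out$feature_id) else
    order(-out$r, out$feature_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

#' Biomarker-to-pathway association cascade
#'
#' Stage 1 correlates every gene with the covariate; stage 2 computes
#' gene-set variation scores on the sub-matrix of genes associated at
#' \code{p <= gene_p_threshold}; stage 3 correlates the pathway scores with
#' the same covariate, keeps sets at p <= 0.05, and ranks them by PCC.
#'
#' @param nm A \code{normalized_matrix} (or gene x sample matrix).
#' @param sets A \code{\link{gene_set_collection}}.
#' @param covariate Per-sample covariate as in
#'   \code{\link{feature_covariate_association}}.
#' @param gene_p_threshold Stage-1 inclusion threshold (default 0.05).
#' @param covariate_id Label for the output tables.
#' @param tau,min_size Passed to \code{\link{gsva_scores}}.
#' @return List with \code{genes} (stage-1 association table), \code{scores}
#'   (stage-2 \code{pathway_score_matrix} or NULL), \code{pathways}
#'   (stage-3 association table, filtered and ranked by r, or NULL). If
#'   fewer than \code{min_size} genes pass stage 1, stages 2-3 are NULL
#'   with a warning.
#' @export
biomarker_pathway_cascade <- function(nm, sets, covariate,
                                      gene_p_threshold = 0.05,
                                      covariate_id = "covariate",
                                      tau = 1, min_size = 5) {
  expr <- if (inherits(nm, "normalized_matrix")) nm$logcpm else as.matrix(nm)
  genes <- feature_covariate_association(expr, covariate, rank_by = "p",
                                         covariate_id = covariate_id)
  selected <- genes$feature_id[genes$p <= gene_p_threshold]
  if (length(selected) < min_size) {
    warning(sprintf(
      "only %d gene(s) at p <= %g: pathway stages skipped",
      length(selected), gene_p_threshold), call. = FALSE)
    return(list(genes = genes, scores = NULL, pathways = NULL))
  }
  scores <- tryCatch(
    gsva_scores(expr[selected, , drop = FALSE], sets,
                tau = tau, min_size = min_size),
    error = function(e) NULL)
  if (is.null(scores)) {
    warning("no gene set retained on the selected genes: pathway stages ",
            "skipped", call. = FALSE)
    return(list(genes = genes, scores = NULL, pathways = NULL))
  }
  pathways <- feature_covariate_association(scores, covariate,
                                            rank_by = "r",
                                            covariate_id = covariate_id)
  pathways <- pathways[pathways$p <= 0.05, , drop = FALSE]
  rownames(pathways) <- NULL
  list(genes = genes, scores = scores, pathways = pathways)
}

#' Transcriptome-wide confounder scan
#'
#' Correlates every gene with a putative confounding covariate (e.g. donor
#' age) and reports how many genes pass a nominal p-value threshold.
#'
#' @param nm A \code{normalized_matrix} or gene x sample matrix.
#' @param covariate Per-sample covariate (e.g. age in years).
#' @param p_threshold Nominal threshold (default 0.05).
#' @param covariate_id Label for the output table.
#' @return List with \code{table} (association table ranked by p) and
#'   \code{n_below} (count of genes with p < \code{p_threshold}).
#' @export
confounder_scan <- function(nm, covariate, p_threshold = 0.05,
                            covariate_id = "age") {
  tab <- feature_covariate_association(nm, covariate, rank_by = "p",
                                       covariate_id = covariate_id)
  list(table = tab, n_below = sum(tab$p < p_threshold))
}
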