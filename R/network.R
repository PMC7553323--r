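#' @title Integrative gene-lipid-biomarker network
#' @description The systems model: lipid species are ranked by the absolute
#'   average Pearson correlation to the top differentially expressed genes,
#'   the top 50 enter the model together with the biomarker panel, the
#'   selected genes and a fixed set of anchor genes, and all allowed pairwise
#'   correlations are filtered (default p < 0.01 and |r| > 0.5) into a typed
#'   correlation network.
#' @name network
NULL

#' Anchor genes of the integrative model
#'
#' Genes added to the network node set by hand, selected from differential
#' gene expression and/or protein analyses of the motivating study.
#'
#' @return Character vector of eight gene symbols.
#' @export
anchor_gene_panel <- function() {
  c("PPARD", "IL1B", "CD300E", "MMP14", "SREBF1", "SPON2", "SNX13", "CDC20")
}

#' Network construction configuration
#'
#' @param gene_p_threshold Strict nominal p cut selecting DEG nodes
#'   (default 0.01).
#' @param n_top_lipids Number of top-ranked lipid species entering the model
#'   (default 50).
#' @param edge_r_threshold Edges require correlation magnitude strictly above
#'   this (default 0.5).
#' @param edge_p_threshold Edges require p strictly below this (default 0.01).
#' @param anchor_genes Gene ids appended to the gene node set regardless of
#'   their differential-expression p (default empty; see
#'   \code{\link{anchor_gene_panel}} for the motivating study's panel).
#' @param allowed_pair_classes Which pair classes are correlated (default
#'   gene-lipid, gene-biomarker and gene-gene; lipid-lipid, lipid-biomarker
#'   and biomarker-biomarker pairs are never computed).
#' @param signed_edge_filter If TRUE the edge filter reads r >
#'   \code{edge_r_threshold} literally (discarding inverse relationships);
#'   default FALSE, i.e. |r| > threshold.
#' @param lipid_rank_stat \code{"signed_mean"} (average the signed r, then
#'   rank on its absolute value; default) or \code{"mean_abs"} (average
#'   |r|).
#' @param adjust_edge_p If TRUE, BH-adjust the pairwise p-values before edge
#'   filtering (default FALSE: the filter is nominal).
#' @return List of class \code{network_config}.
#' @export
network_config <- function(gene_p_threshold = 0.01,
                           n_top_lipids = 50,
                           edge_r_threshold = 0.5,
                           edge_p_threshold = 0.01,
                           anchor_genes = character(),
                           allowed_pair_classes = c("gene-lipid",
                                                    "gene-biomarker",
                                                    "gene-gene"),
                           signed_edge_filter = FALSE,
                           lipid_rank_stat = c("signed_mean", "mean_abs"),
                           adjust_edge_p = FALSE) {
  lipid_rank_stat <- match.arg(lipid_rank_stat)
  stopifnot(gene_p_threshold > 0, gene_p_threshold <= 1,
            edge_p_threshold > 0, edge_p_threshold <= 1,
            edge_r_threshold >= 0, edge_r_threshold <= 1,
            n_top_lipids >= 1)
  if (!all(allowed_pair_classes %in% valid_pair_classes))
    stop("allowed_pair_classes must be among: ",
         paste(valid_pair_classes, collapse = ", "), call. = FALSE)
  structure(list(gene_p_threshold = gene_p_threshold,
                 n_top_lipids = n_top_lipids,
                 edge_r_threshold = edge_r_threshold,
                 edge_p_threshold = edge_p_threshold,
                 anchor_genes = as.character(anchor_genes),
                 allowed_pair_classes = allowed_pair_classes,
                 signed_edge_filter = isTRUE(signed_edge_filter),
                 lipid_rank_stat = lipid_rank_stat,
                 adjust_edge_p = isTRUE(adjust_edge_p)),
            class = "network_config")
}

# Edge retention rule; tol loosens the comparison for re-validating tables
# whose r/p were rounded on write.
edge_filter_keep <- function(r, p, config, tol = 1e-6) {
  rv <- if (config$signed_edge_filter) r else abs(r)
  rv > config$edge_r_threshold - tol & p < config$edge_p_threshold + tol
}

selected_gene_ids <- function(deg, config) {
  ids <- select_genes(deg, "p_threshold", config$gene_p_threshold)
  if (length(ids) == 0)
    stop("no gene passes gene_p_threshold = ", config$gene_p_threshold,
         "; raise the threshold", call. = FALSE)
  ids
}

#' Rank lipid species by average correlation to the top DEGs
#'
#' For each lipid species, the Pearson correlation to every gene passing the
#' DGE p threshold is computed over the shared samples and averaged
#' (signed); species are ranked by the absolute average correlation,
#' descending, ties broken by lipid id. Correlations undefined for a given
#' gene (constant vector) are omitted from that species' average; species
#' undefined against every selected gene are excluded with a message.
#'
#' @param nm A \code{normalized_matrix} (genes x samples).
#' @param lipids A \code{\link{lipid_panel}}.
#' @param deg A \code{dge_result} from \code{\link{run_dge}}.
#' @param config A \code{\link{network_config}}.
#' @return data.frame of class \code{lipid_ranking}: \code{lipid_id},
#'   \code{mean_r}, \code{abs_mean_r}, \code{n_genes_used}, \code{rank},
#'   ordered by rank.
#' @export
rank_lipids <- function(nm, lipids, deg, config = network_config()) {
  stopifnot(inherits(lipids, "lipid_panel"))
  expr <- if (inherits(nm, "normalized_matrix")) nm$logcpm else as.matrix(nm)
  genes <- selected_gene_ids(deg, config)
  shared <- intersect(colnames(expr), colnames(lipids$concentrations))
  if (length(shared) < 3)
    stop("need >= 3 shared samples between expression and lipid panels",
         call. = FALSE)
  g_mat <- expr[genes, shared, drop = FALSE]
  l_mat <- lipids$concentrations[, shared, drop = FALSE]

  r_mat <- suppressWarnings(
    stats::cor(t(l_mat), t(g_mat), use = "pairwise.complete.obs"))
  n_used <- rowSums(!is.na(r_mat))
  undefined <- n_used == 0
  if (any(undefined))
    message(sum(undefined),
            " lipid(s) excluded: correlation undefined vs every gene")
  r_mat <- r_mat[!undefined, , drop = FALSE]
  n_used <- n_used[!undefined]

  mean_r <- if (config$lipid_rank_stat == "signed_mean")
    rowMeans(r_mat, na.rm = TRUE) else rowMeans(abs(r_mat), na.rm = TRUE)
  out <- data.frame(lipid_id = rownames(r_mat),
                    mean_r = mean_r,
                    abs_mean_r = abs(mean_r),
                    n_genes_used = n_used,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$abs_mean_r, out$lipid_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("lipid_ranking", "data.frame")
  out
}

# Pairwise Pearson r, n and two-sided t-based p for the rows of X
# (pairwise-complete). Pairs with n < min_n or undefined r are NA.
cor_matrix_with_p <- function(X, min_n = 3) {
  obs <- !is.na(X)
  n <- obs %*% t(obs)
  r <- suppressWarnings(stats::cor(t(X), use = "pairwise.complete.obs"))
  r[n < min_n] <- NA
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  list(r = r, n = n, p = p)
}

#' Build the thresholded gene-lipid-biomarker correlation network
#'
#' Node candidates are the top \code{n_top_lipids} species of the ranking,
#' every biomarker, and the genes passing the DGE p threshold plus the
#' configured anchor genes (anchors absent from the expression matrix are
#' skipped with a message). Every unordered pair whose class is allowed is
#' correlated over the shared samples; edges with
#' p < \code{edge_p_threshold} and |r| > \code{edge_r_threshold} are
#' retained. Non-anchor candidates without any retained edge are dropped.
#'
#' @param nm A \code{normalized_matrix}.
#' @param lipids A \code{\link{lipid_panel}}.
#' @param biomarkers A \code{\link{biomarker_panel}}.
#' @param deg A \code{dge_result}.
#' @param ranking A \code{lipid_ranking} from \code{\link{rank_lipids}},
#'   computed from the same inputs; defaults to computing it here.
#' @param config A \code{\link{network_config}}.
#' @return An \code{\link{integrative_network}} with deterministically
#'   ordered node and edge tables.
#' @export
build_network <- function(nm, lipids, biomarkers, deg,
                          ranking = NULL, config = network_config()) {
  stopifnot(inherits(lipids, "lipid_panel"),
            inherits(biomarkers, "biomarker_panel"))
  expr <- if (inherits(nm, "normalized_matrix")) nm$logcpm else as.matrix(nm)
  if (is.null(ranking)) ranking <- rank_lipids(nm, lipids, deg, config)

  genes <- selected_gene_ids(deg, config)
  anchors <- config$anchor_genes
  missing_anchor <- setdiff(anchors, rownames(expr))
  if (length(missing_anchor) > 0)
    message("anchor gene(s) absent from expression matrix, skipped: ",
            paste(missing_anchor, collapse = ", "))
  anchors <- setdiff(intersect(anchors, rownames(expr)), genes)
  gene_nodes <- c(genes, anchors)

  if (nrow(ranking) < config$n_top_lipids)
    warning(sprintf("only %d rankable lipids (< n_top_lipids = %d): using all",
                    nrow(ranking), config$n_top_lipids), call. = FALSE)
  lipid_nodes <- utils::head(ranking$lipid_id, config$n_top_lipids)
  marker_nodes <- rownames(biomarkers$values)

  shared <- Reduce(intersect, list(colnames(expr),
                                   colnames(lipids$concentrations),
                                   colnames(biomarkers$values)))
  if (length(shared) < 3)
    stop("need >= 3 shared samples across all three panels", call. = FALSE)

  X <- rbind(expr[gene_nodes, shared, drop = FALSE],
             lipids$concentrations[lipid_nodes, shared, drop = FALSE],
             biomarkers$values[marker_nodes, shared, drop = FALSE])
  role <- c(rep("gene", length(gene_nodes)),
            rep("lipid", length(lipid_nodes)),
            rep("biomarker", length(marker_nodes)))
  names(role) <- c(gene_nodes, lipid_nodes, marker_nodes)
  if (anyDuplicated(names(role)))
    stop("node ids collide across roles", call. = FALSE)

  cm <- cor_matrix_with_p(X)
  idx <- which(upper.tri(cm$r), arr.ind = TRUE)
  id1 <- rownames(X)[idx[, 1]]
  id2 <- rownames(X)[idx[, 2]]
  pc <- pair_class_of(role[id1], role[id2])
  r <- cm$r[idx]
  p <- cm$p[idx]
  n <- cm$n[idx]
  ok <- !is.na(pc) & pc %in% config$allowed_pair_classes & !is.na(r)
  if (config$adjust_edge_p) p[ok] <- bh_adjust(p[ok])
  keep <- ok & edge_filter_keep(r, p, config, tol = 0)

  # canonical unordered pair: smaller id first, then sort
  a <- pmin(id1[keep], id2[keep])
  b <- pmax(id1[keep], id2[keep])
  edges <- data.frame(id1 = a, id2 = b, r = r[keep], p = p[keep],
                      n = as.integer(n[keep]), pair_class = pc[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$id1, edges$id2), , drop = FALSE]
  rownames(edges) <- NULL

  incident <- unique(c(edges$id1, edges$id2))
  keep_node <- names(role) %in% incident | names(role) %in% config$anchor_genes
  dropped <- sum(!keep_node)
  if (dropped > 0)
    message(dropped, " isolated candidate node(s) dropped")
  nodes <- data.frame(id = names(role)[keep_node],
                      role = unname(role[keep_node]),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$role, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (nrow(edges) == 0)
    warning("empty edge set under the configured filter", call. = FALSE)

  integrative_network(nodes, edges, config)
}

#' Degree and edge-count summary of a network
#'
#' @param net An \code{\link{integrative_network}}.
#' @return List with \code{degrees} (node_id, role, degree; degree
#'   descending, id ascending) and \code{edge_counts} (pair_class, count).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "integrative_network"))
  if (nrow(net$nodes) == 0) {
    return(list(degrees = data.frame(node_id = character(),
                                     role = character(),
                                     degree = integer()),
                edge_counts = data.frame(pair_class = character(),
                                         count = integer())))
  }
  deg <- vapply(net$nodes$id, function(id)
    sum(net$edges$id1 == id | net$edges$id2 == id), integer(1))
  degrees <- data.frame(node_id = net$nodes$id, role = net$nodes$role,
                        degree = unname(deg), stringsAsFactors = FALSE)
  degrees <- degrees[order(-degrees$degree, degrees$node_id), , drop = FALSE]
  rownames(degrees) <- NULL
  counts <- as.data.frame(table(factor(net$edges$pair_class,
                                       levels = valid_pair_classes)),
                          stringsAsFactors = FALSE)
  names(counts) <- c("pair_class", "count")
  list(degrees = degrees, edge_counts = counts)
}
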