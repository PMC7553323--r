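#' @title Shared data model
#' @description Constructors and validators for the containers passed between
#'   pipeline stages: count matrices, sample metadata, lipid and biomarker
#'   panels, gene-set collections, and the integrative correlation network.
#' @name data-model
NULL

#' The 13 lipid classes of a Lipidyzer-style serum lipidome
#'
#' Free fatty acids (FFA), ceramides (CER), dihydroceramides (DCER),
#' hexosylceramides (HCER), lactosylceramides (LCER), sphingomyelins (SM),
#' phosphatidylcholines (PC), phosphatidylethanolamines (PE),
#' lysophosphatidylcholines (LPC), lysophosphatidylethanolamines (LPE),
#' cholesteryl esters (CE), diacylglycerols (DAG) and triacylglycerols (TAG).
#'
#' @return Character vector of the 13 recognized class labels.
#' @export
lipid_classes <- function() {
  c("FFA", "CER", "DCER", "HCER", "LCER", "SM", "PC", "PE",
    "LPC", "LPE", "CE", "DAG", "TAG")
}

#' Construct a validated expression count matrix
#'
#' @param counts Integer matrix, genes in rows and samples in columns, with
#'   unique row and column names. All entries must be non-negative integers
#'   and every sample must have a positive total count.
#'
#' @return An object of class \code{expression_matrix} wrapping the matrix.
#' @export
expression_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in count matrix", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in count matrix", call. = FALSE)
  if (anyNA(counts))
    stop("missing values are not permitted in counts", call. = FALSE)
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "counts must be non-negative integers; first offender gene '%s', sample '%s' (value %g)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      counts[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("samples with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "), call. = FALSE)
  storage.mode(counts) <- "double"  # keeps large libraries exact, avoids int overflow in sums
  structure(list(counts = counts), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (total %.3g reads)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$counts)

#' Construct sample metadata for a two-group study
#'
#' @param sample_id Character vector of unique sample ids.
#' @param group Group label per sample; coerced to a factor with levels
#'   \code{c("A", "B")} (A maps to the reference/control group, B to the
#'   condition group; in the motivating study A = HIV-negative, B = HIV-positive).
#' @param covariates Optional data.frame of numeric per-sample covariates
#'   (e.g. age in years), rows aligned with \code{sample_id}.
#'
#' @return A data.frame of class \code{sample_metadata} with columns
#'   \code{sample_id}, \code{group}, then one column per covariate.
#' @export
sample_metadata <- function(sample_id, group, covariates = NULL) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in metadata", call. = FALSE)
  group <- as.character(group)
  if (!all(group %in% c("A", "B")))
    stop("group labels must be 'A' or 'B'", call. = FALSE)
  meta <- data.frame(sample_id = sample_id,
                     group = factor(group, levels = c("A", "B")),
                     stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_id))
      stop("covariates must have one row per sample", call. = FALSE)
    if (any(c("sample_id", "group") %in% names(covariates)))
      stop("covariate names 'sample_id'/'group' are reserved", call. = FALSE)
    if (!all(vapply(covariates, is.numeric, logical(1))))
      stop("covariates must be numeric", call. = FALSE)
    meta <- cbind(meta, covariates)
  }
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' Check that metadata covers the samples of a matrix, both groups non-empty
#'
#' @param meta A \code{sample_metadata} object.
#' @param sample_ids Character vector of sample ids that must each appear
#'   exactly once in the metadata.
#' @return Invisibly, the metadata subset to \code{sample_ids}, in that order.
#' @export
check_metadata <- function(meta, sample_ids) {
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing) > 0)
    stop("samples absent from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  if (any(table(factor(sub$group, levels = c("A", "B"))) == 0))
    stop("both groups must be non-empty", call. = FALSE)
  invisible(sub)
}

#' Construct a validated lipid panel
#'
#' Holds species-level concentrations with their class annotation, plus the
#' derived class totals and within-class mol\% composition.
#'
#' @param concentrations Numeric matrix of concentrations in uM, lipid species
#'   in rows (unique names), samples in columns. \code{NA} encodes values
#'   below the limit of quantification.
#' @param class Named character vector mapping every lipid id to one of the
#'   13 recognized class labels (see \code{\link{lipid_classes}}).
#'
#' @return An object of class \code{lipid_panel} with elements
#'   \code{concentrations}, \code{class}, \code{class_totals} (class x sample,
#'   uM, \code{NA} treated as absent) and \code{composition} (mol\% within
#'   class, summing to 100 per class per sample).
#' @export
lipid_panel <- function(concentrations, class) {
  concentrations <- as.matrix(concentrations)
  if (is.null(rownames(concentrations)) || is.null(colnames(concentrations)))
    stop("concentrations must carry lipid row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(concentrations)))
    stop("duplicate lipid ids", call. = FALSE)
  ids <- rownames(concentrations)
  if (!all(ids %in% names(class)))
    stop("every lipid id needs a class annotation", call. = FALSE)
  class <- class[ids]
  bad <- setdiff(unique(class), lipid_classes())
  if (length(bad) > 0)
    stop("unknown lipid class label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(lipid_classes(), collapse = ", "), call. = FALSE)
  if (any(concentrations < 0, na.rm = TRUE))
    stop("lipid concentrations must be non-negative", call. = FALSE)

  present <- intersect(lipid_classes(), unique(class))
  totals <- do.call(rbind, lapply(present, function(cl) {
    colSums(concentrations[class == cl, , drop = FALSE], na.rm = TRUE)
  }))
  rownames(totals) <- present
  comp <- do.call(rbind, lapply(present, function(cl) {
    m <- concentrations[class == cl, , drop = FALSE]
    tot <- colSums(m, na.rm = TRUE)
    sweep(m, 2, ifelse(tot > 0, tot, NA_real_), "/") * 100
  }))
  comp <- comp[ids[ids %in% rownames(comp)], , drop = FALSE]

  structure(list(concentrations = concentrations,
                 class = class,
                 class_totals = totals,
                 composition = comp),
            class = "lipid_panel")
}

#' @export
print.lipid_panel <- function(x, ...) {
  cat(sprintf("lipid_panel: %d species in %d classes x %d samples\n",
              nrow(x$concentrations), length(unique(x$class)),
              ncol(x$concentrations)))
  invisible(x)
}

#' Construct a validated biomarker panel
#'
#' @param values Numeric matrix of soluble-marker concentrations, markers in
#'   rows, samples in columns; entries must be positive (assay units vary by
#'   marker); \code{NA} permitted for below-LOQ.
#' @return An object of class \code{biomarker_panel}.
#' @export
biomarker_panel <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry marker row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate marker ids", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values)) ||
      any(values <= 0, na.rm = TRUE))
    stop("biomarker values must be finite and > 0 (NA for below-LOQ)",
         call. = FALSE)
  structure(list(values = values), class = "biomarker_panel")
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of set descriptions.
#' @return An object of class \code{gene_set_collection}: a named list of
#'   unique, non-empty member vectors with a \code{descriptions} attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets))))
    stop("sets must have unique names", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- lengths(sets) == 0
  if (any(empty))
    stop("empty gene sets: ", paste(names(sets)[empty], collapse = ", "),
         call. = FALSE)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions[names(sets)],
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, member counts %s\n",
              length(x),
              if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

valid_pair_classes <- c("gene-lipid", "gene-biomarker", "gene-gene")

#' Construct a validated integrative correlation network
#'
#' The network object of the integrative model: typed nodes (gene, lipid or
#' biomarker) joined by Pearson-correlation edges that passed the configured
#' r/p filter.
#'
#' @param nodes data.frame with columns \code{id} (unique) and \code{role}
#'   (one of gene, lipid, biomarker).
#' @param edges data.frame with columns \code{id1}, \code{id2}, \code{r},
#'   \code{p}, \code{n}, \code{pair_class}. No self-edges or duplicate
#'   unordered pairs; \code{pair_class} must match endpoint roles.
#' @param config The \code{\link{network_config}} the edges were filtered
#'   with; used to re-assert the edge filter on construction.
#' @return An object of class \code{integrative_network}.
#' @export
integrative_network <- function(nodes, edges, config = network_config()) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "role") %in% names(nodes)),
            all(c("id1", "id2", "r", "p", "n", "pair_class") %in% names(edges)))
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$role %in% c("gene", "lipid", "biomarker")))
    stop("node roles must be gene, lipid or biomarker", call. = FALSE)
  if (nrow(edges) > 0) {
    if (!all(edges$id1 %in% nodes$id) || !all(edges$id2 %in% nodes$id))
      stop("edge endpoints must exist in node table", call. = FALSE)
    if (any(edges$id1 == edges$id2))
      stop("self-edges are not allowed", call. = FALSE)
    key <- paste(pmin(edges$id1, edges$id2), pmax(edges$id1, edges$id2))
    if (anyDuplicated(key))
      stop("duplicate unordered edge pairs", call. = FALSE)
    role <- stats::setNames(nodes$role, nodes$id)
    expect <- pair_class_of(role[edges$id1], role[edges$id2])
    if (any(is.na(expect)) || !all(edges$pair_class == expect))
      stop("pair_class inconsistent with endpoint roles", call. = FALSE)
    if (any(abs(edges$r) > 1) || any(edges$p < 0 | edges$p > 1))
      stop("edge r must lie in [-1,1] and p in [0,1]", call. = FALSE)
    keep <- edge_filter_keep(edges$r, edges$p, config)
    if (!all(keep))
      stop("an edge violates the configured r/p filter", call. = FALSE)
  }
  structure(list(nodes = nodes[, c("id", "role")],
                 edges = edges[, c("id1", "id2", "r", "p", "n", "pair_class")],
                 config = config),
            class = "integrative_network")
}

# Canonical pair class of two roles; NA for disallowed role combinations
# (lipid-lipid, lipid-biomarker, biomarker-biomarker).
pair_class_of <- function(role1, role2) {
  a <- pmin(role1, role2)  # alphabetical: biomarker < gene < lipid
  b <- pmax(role1, role2)
  out <- rep(NA_character_, length(a))
  out[a == "gene" & b == "gene"] <- "gene-gene"
  out[a == "gene" & b == "lipid"] <- "gene-lipid"
  out[a == "biomarker" & b == "gene"] <- "gene-biomarker"
  out
}

#' @export
print.integrative_network <- function(x, ...) {
  cat(sprintf("integrative_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0)
    print(table(x$edges$pair_class))
  invisible(x)
}
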