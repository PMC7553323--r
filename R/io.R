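#' @title File readers and writers
#' @description TSV and MatrixMarket count I/O, lipid/biomarker/metadata panel
#'   TSVs, GMT gene-set files, and network persistence (pair tables, GraphML).
#'   TSV dialect everywhere: UTF-8, tab separated, header row, first column is
#'   the feature id, "NA" for missing, decimal point.
#' @name io
NULL

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          fileEncoding = "UTF-8")
  if (ncol(df) < 2)
    stop("malformed table (need feature id column plus >= 1 sample): ", path,
         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read a gene-level count matrix
#'
#' @param path Path to the counts file. For \code{format = "tsv"} a
#'   tab-separated table with a header of sample ids and a first column of
#'   gene ids. For \code{format = "mtx"} a MatrixMarket file accompanied by
#'   \code{<path>.rownames} and \code{<path>.colnames} sidecars (one id per
#'   line).
#' @param format Either \code{"tsv"} or \code{"mtx"}.
#' @return A validated \code{\link{expression_matrix}}.
#' @export
read_counts <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    m <- read_tsv_matrix(path)
    if (!is.numeric(m))
      stop("non-numeric entries in count matrix: ", path, call. = FALSE)
  } else {
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn))
      stop("mtx requires sidecar files ", rn, " and ", cn, call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(rn)
    colnames(m) <- readLines(cn)
  }
  expression_matrix(m)
}

#' Write a count matrix
#'
#' Inverse of \code{\link{read_counts}}; integer-lossless round trip.
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"mtx"} (with id sidecar files).
#' @return Invisibly, \code{path}.
#' @export
write_counts <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "expression_matrix"))
  if (format == "tsv") {
    write_feature_table(m$counts, path, id_col = "gene_id")
  } else {
    Matrix::writeMM(Matrix::Matrix(m$counts, sparse = TRUE), path)
    writeLines(rownames(m$counts), paste0(path, ".rownames"))
    writeLines(colnames(m$counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

write_feature_table <- function(mat, path, id_col = "id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a lipid, biomarker or metadata panel
#'
#' @param path TSV path. Lipid files need columns \code{lipid_id} and
#'   \code{class} (one of the 13 recognized labels) followed by sample
#'   columns; biomarker files a \code{marker_id} column then samples;
#'   metadata files columns \code{sample_id}, \code{group} and optional
#'   numeric covariates.
#' @param kind One of \code{"lipid"}, \code{"biomarker"}, \code{"metadata"}.
#' @return A \code{\link{lipid_panel}}, \code{\link{biomarker_panel}} or
#'   \code{\link{sample_metadata}} object; lipid class totals and mol\% are
#'   recomputed from the species table.
#' @export
read_panel <- function(path, kind = c("lipid", "biomarker", "metadata")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          fileEncoding = "UTF-8")
  if (kind == "metadata") {
    if (!all(c("sample_id", "group") %in% names(df)))
      stop("metadata needs sample_id and group columns: ", path, call. = FALSE)
    cov <- df[, setdiff(names(df), c("sample_id", "group")), drop = FALSE]
    return(sample_metadata(df$sample_id, df$group,
                           if (ncol(cov) > 0) cov else NULL))
  }
  if (kind == "lipid") {
    if (!all(c("lipid_id", "class") %in% names(df)))
      stop("lipid panel needs lipid_id and class columns: ", path,
           call. = FALSE)
    m <- as.matrix(df[, setdiff(names(df), c("lipid_id", "class")),
                      drop = FALSE])
    rownames(m) <- df$lipid_id
    return(lipid_panel(m, stats::setNames(df$class, df$lipid_id)))
  }
  if (!"marker_id" %in% names(df))
    stop("biomarker panel needs a marker_id column: ", path, call. = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "marker_id"), drop = FALSE])
  rownames(m) <- df$marker_id
  biomarker_panel(m)
}

#' Write a lipid panel, biomarker panel or metadata table as TSV
#'
#' @param x The panel object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_panel <- function(x, path) {
  if (inherits(x, "lipid_panel")) {
    df <- data.frame(lipid_id = rownames(x$concentrations),
                     class = unname(x$class),
                     x$concentrations, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8")
  } else if (inherits(x, "biomarker_panel")) {
    write_feature_table(x$values, path, id_col = "marker_id")
  } else if (inherits(x, "sample_metadata")) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  } else stop("unsupported panel object", call. = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set id, description, then member gene symbols.
#' Duplicate members within a set are collapsed with a warning.
#'
#' @param path GMT path.
#' @return A \code{\link{gene_set_collection}}; empty file gives an empty
#'   collection.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(gene_set_collection(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0)
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]),
         call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  members <- lapply(fields, function(f) f[-(1:2)])
  dup <- vapply(members, anyDuplicated, integer(1)) > 0
  if (any(dup))
    warning("duplicate members collapsed in set(s): ",
            paste(ids[dup], collapse = ", "), call. = FALSE)
  gene_set_collection(stats::setNames(members, ids),
                      stats::setNames(desc, ids))
}

#' Write a gene-set collection as GMT
#'
#' @param sets A \code{\link{gene_set_collection}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Persist an integrative network
#'
#' \code{tsv_pair} writes \code{<path>.nodes.tsv} (id, role) and
#' \code{<path>.edges.tsv} (id1, id2, r, p, n, pair_class; r and p at 6
#' significant digits). \code{graphml} writes a single GraphML file with role
#' as a node attribute and r, p, n, pair_class as edge attributes.
#'
#' @param net An \code{\link{integrative_network}}.
#' @param path Output path (prefix for \code{tsv_pair}).
#' @param format \code{"tsv_pair"} or \code{"graphml"}.
#' @return Invisibly, the path(s) written.
#' @export
write_network <- function(net, path, format = c("tsv_pair", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "integrative_network"))
  if (format == "tsv_pair") {
    nodes_path <- paste0(path, ".nodes.tsv")
    edges_path <- paste0(path, ".edges.tsv")
    utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    e <- net$edges
    e$r <- signif(e$r, 6)
    e$p <- signif(e$p, 6)
    utils::write.table(e, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(c(nodes_path, edges_path)))
  }
  g <- igraph::graph_from_data_frame(
    d = if (nrow(net$edges) > 0) net$edges else
      data.frame(id1 = character(), id2 = character(), r = numeric(),
                 p = numeric(), n = integer(), pair_class = character()),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$id, role = net$nodes$role))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read an integrative network written by \code{\link{write_network}}
#'
#' @param path The path (prefix for \code{tsv_pair}) used when writing.
#' @param format \code{"tsv_pair"} or \code{"graphml"}.
#' @param config Network filter configuration to re-validate against;
#'   defaults to \code{\link{network_config}()}.
#' @return An \code{\link{integrative_network}}.
#' @export
read_network <- function(path, format = c("tsv_pair", "graphml"),
                         config = network_config()) {
  format <- match.arg(format)
  if (format == "tsv_pair") {
    nodes <- utils::read.delim(paste0(path, ".nodes.tsv"), sep = "\t",
                               stringsAsFactors = FALSE,
                               colClasses = "character")
    edges <- utils::read.delim(paste0(path, ".edges.tsv"), sep = "\t",
                               stringsAsFactors = FALSE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(id = igraph::V(g)$name, role = igraph::V(g)$role,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(id1 = el[, 1], id2 = el[, 2],
                        stringsAsFactors = FALSE)
    if (igraph::ecount(g) > 0) {
      edges$r <- igraph::E(g)$r
      edges$p <- igraph::E(g)$p
      edges$n <- igraph::E(g)$n
      edges$pair_class <- igraph::E(g)$pair_class
    } else {
      edges$r <- numeric(0); edges$p <- numeric(0)
      edges$n <- integer(0); edges$pair_class <- character(0)
    }
  }
  integrative_network(nodes, edges, config)
}
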