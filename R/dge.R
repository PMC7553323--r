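#' @title Normalization and differential expression
#' @description Trimmed-mean-of-M-values scaling factors, log2-CPM
#'   transformation, the two-group differential-expression table, and the
#'   gene selections consumed by the pathway, covariate and network stages.
#' @name dge
NULL

#' Trimmed mean of M-values normalization factors
#'
#' Computes one scaling factor per sample relative to a reference sample (the
#' one whose 75th-percentile count fraction is closest to the mean of those
#' quantiles). For sample j versus reference r, gene-wise log2 relative
#' expression ratios M and average log2 relative expression A are computed
#' over genes positive in both; 30\% of genes are trimmed from each M tail
#' and 5\% from each A tail; the factor is 2 to the precision-weighted mean
#' of the surviving M values, with asymptotic inverse-variance weights
#' \eqn{1/(1/c_{gj} - 1/N_j + 1/c_{gr} - 1/N_r)}. Factors are rescaled to
#' geometric mean 1.
#'
#' @param m An \code{\link{expression_matrix}} with >= 2 samples.
#' @return Named numeric vector of positive per-sample factors with geometric
#'   mean 1.
#' @export
tmm_factors <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  counts <- m$counts
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Trimmed weighted mean of M-values for one sample against the reference.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     trim_m = 0.3, trim_a = 0.05) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (length(obs) == 0) return(1)
  m_val <- log2((obs / n_obs) / (ref / n_ref))
  a_val <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- 1 / (1 / obs - 1 / n_obs + 1 / ref - 1 / n_ref)

  n <- length(m_val)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m_val) >= lo_m & rank(m_val) <= hi_m &
    rank(a_val) >= lo_a & rank(a_val) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(w[keep] * m_val[keep]) / sum(w[keep]))
}

#' Normalized log2 counts per million
#'
#' Entry-wise \eqn{\log_2((c + 0.5) / (N f + 1) \times 10^6)} where N is the
#' sample's total count and f its normalization factor; the 0.5 prior count
#' keeps zero counts finite.
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param factors Positive per-sample factors, e.g. from
#'   \code{\link{tmm_factors}}; default all 1.
#' @return An object of class \code{normalized_matrix}: list with
#'   \code{logcpm} (gene x sample) and \code{factors}.
#' @export
log_cpm <- function(m, factors = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  counts <- m$counts
  if (is.null(factors)) factors <- stats::setNames(rep(1, ncol(counts)),
                                                   colnames(counts))
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  factors <- factors[colnames(counts)]
  lib <- colSums(counts)
  logcpm <- log2(sweep(counts + 0.5, 2, lib * factors + 1, "/") * 1e6)
  structure(list(logcpm = logcpm, factors = factors),
            class = "normalized_matrix")
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix: %d genes x %d samples (log2-CPM)\n",
              nrow(x$logcpm), ncol(x$logcpm)))
  invisible(x)
}

#' Two-group differential expression
#'
#' The full DGE pipeline: genes with zero total count are dropped (reported
#' via a message), TMM factors and log2-CPM are computed, the moderated
#' two-group test is applied, and p-values are BH-adjusted. The log2 fold
#' change is the difference of group means of log2-CPM (group B minus A).
#'
#' @param m An \code{\link{expression_matrix}}.
#' @param meta A \code{\link{sample_metadata}} covering its samples.
#' @return A data.frame of class \code{dge_result}, one row per retained
#'   gene, ordered by p ascending (ties broken by gene id): \code{gene_id},
#'   \code{logFC}, \code{t_mod}, \code{p}, \code{adj_p}, \code{mean_expr},
#'   \code{tested}. The \code{normalized_matrix} used is attached as
#'   attribute \code{"normalized"}.
#' @export
run_dge <- function(m, meta) {
  stopifnot(inherits(m, "expression_matrix"))
  zero <- rowSums(m$counts) == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero total count dropped")
    m <- expression_matrix(m$counts[!zero, , drop = FALSE])
  }
  factors <- tmm_factors(m)
  nm <- log_cpm(m, factors)
  tt <- moderated_two_group_test(nm$logcpm, meta)
  res <- data.frame(gene_id = tt$feature_id,
                    logFC = tt$effect,
                    t_mod = tt$t_mod,
                    p = tt$p,
                    adj_p = bh_adjust(tt$p),
                    mean_expr = rowMeans(nm$logcpm),
                    tested = tt$tested,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  ord <- order(res$p, res$gene_id, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "normalized") <- nm
  attr(res, "s2_prior") <- attr(tt, "s2_prior")
  attr(res, "df_prior") <- attr(tt, "df_prior")
  class(res) <- c("dge_result", "data.frame")
  res
}

#' Select genes from a differential-expression table
#'
#' @param res A \code{dge_result} from \code{\link{run_dge}}.
#' @param mode \code{"top_n_by_p"} (value = number of genes),
#'   \code{"p_threshold"} or \code{"adj_p_threshold"} (value = strict upper
#'   bound on nominal/adjusted p).
#' @param value Positive selection parameter.
#' @return Character vector of gene ids ordered by ascending p (ties broken
#'   by gene id). Untested genes are never selected.
#' @export
select_genes <- function(res, mode = c("top_n_by_p", "p_threshold",
                                       "adj_p_threshold"), value) {
  mode <- match.arg(mode)
  if (!is.numeric(value) || length(value) != 1 || value <= 0)
    stop("value must be a positive number", call. = FALSE)
  res <- res[res$tested, , drop = FALSE]
  res <- res[order(res$p, res$gene_id), , drop = FALSE]
  switch(mode,
         top_n_by_p = utils::head(res$gene_id, value),
         p_threshold = res$gene_id[res$p < value],
         adj_p_threshold = res$gene_id[res$adj_p < value])
}
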