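#' @title Single-sample gene-set variation scores
#' @description A rank-based random-walk enrichment score per gene set and
#'   sample, computed from normalized expression: a Gaussian-kernel
#'   cumulative density statistic per gene across samples, a symmetric rank
#'   statistic within each sample, and a Kolmogorov-Smirnov-like walk over
#'   the ranked gene list.
#' @name gsva
NULL

#' Gene-set variation scores
#'
#' For gene i and sample j the expression statistic is
#' \eqn{\hat{z}_{ij} = \frac{1}{n}\sum_k \Phi((e_{ij} - e_{ik})/h_i)} with
#' Gaussian kernel bandwidth \eqn{h_i = sd_i/4}. Within each sample genes are
#' ranked by \eqn{\hat{z}} descending, and the symmetric rank statistic is
#' \eqn{z'_{ij} = |p/2 - rank_{ij}|} with p the number of genes. For each set
#' the score is the sum of the maximum positive and minimum negative
#' deviation of a random walk down the ranked list whose inside-set
#' increments are proportional to \eqn{(z')^\tau} and whose outside-set
#' increments are uniform; scores are bounded in [-1, 1].
#'
#' Genes that are constant across samples get statistic 0.5 uniformly
#' (reported via a message). Sets are intersected with the matrix's genes;
#' sets with fewer than \code{min_size} mapped members, or covering every
#' gene of the matrix (degenerate walk), are dropped with a message.
#'
#' @param nm A \code{normalized_matrix} (from \code{\link{log_cpm}}) or a
#'   plain numeric gene x sample matrix with >= 3 samples.
#' @param sets A \code{\link{gene_set_collection}}.
#' @param tau Weighting exponent on the rank statistic (default 1).
#' @param min_size Minimum mapped set size retained (default 5).
#' @return Set x sample numeric matrix of class \code{pathway_score_matrix}
#'   with the parameters attached as attribute \code{"params"}.
#' @export
gsva_scores <- function(nm, sets, tau = 1, min_size = 5) {
  expr <- if (inherits(nm, "normalized_matrix")) nm$logcpm else as.matrix(nm)
  if (ncol(expr) < 3) stop("need >= 3 samples", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expression matrix must carry gene row names", call. = FALSE)
  p <- nrow(expr)
  n <- ncol(expr)

  mapped <- lapply(sets, function(g) intersect(g, rownames(expr)))
  small <- lengths(mapped) < min_size
  full <- lengths(mapped) >= p
  drop <- small | full
  if (any(drop))
    message("dropping ", sum(drop), " set(s): below min_size or covering ",
            "the whole matrix (", paste(names(sets)[drop], collapse = ", "),
            ")")
  mapped <- mapped[!drop]
  if (length(mapped) == 0)
    stop("no gene set retained after size filtering", call. = FALSE)

  # density statistic: across-sample Gaussian-kernel CDF per gene
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0))
    message(sum(sds == 0), " constant gene(s): statistic set to 0.5")
  zhat <- matrix(0.5, p, n, dimnames = dimnames(expr))
  for (i in which(sds > 0)) {
    h <- sds[i] / 4
    d <- outer(expr[i, ], expr[i, ], "-") / h  # d[j, k] = (e_ij - e_ik)/h
    zhat[i, ] <- rowMeans(stats::pnorm(d))
  }

  # per-sample ranking (descending statistic, row order as tie-break)
  ord <- apply(zhat, 2, order, decreasing = TRUE)  # p x n, gene indices
  rk <- apply(zhat, 2, function(z) rank(-z, ties.method = "first"))
  zprime <- abs(p / 2 - rk)

  scores <- matrix(NA_real_, length(mapped), n,
                   dimnames = list(names(mapped), colnames(expr)))
  for (s in seq_along(mapped)) {
    inset <- rownames(expr) %in% mapped[[s]]
    m_size <- sum(inset)
    for (j in seq_len(n)) {
      o <- ord[, j]
      tags <- inset[o]
      w <- zprime[o, j]^tau * tags
      pos <- cumsum(w) / sum(w)
      neg <- cumsum(!tags) / (p - m_size)
      walk <- pos - neg
      scores[s, j] <- max(c(walk, 0)) + min(c(walk, 0))
    }
  }
  structure(scores,
            params = list(tau = tau, min_size = min_size,
                          kernel = "gaussian", bandwidth = "sd/4",
                          convention = "max.pos + min.neg"),
            class = c("pathway_score_matrix", "matrix", "array"))
}

#' Two-group comparison of pathway scores
#'
#' Applies the empirical-Bayes moderated two-group test to the rows of a
#' pathway score matrix, BH-adjusts, and ranks by p.
#'
#' @param ps A \code{pathway_score_matrix} from \code{\link{gsva_scores}}.
#' @param meta A \code{\link{sample_metadata}}; both groups >= 2 samples.
#' @return data.frame ordered by ascending p (ties by set id): \code{set_id},
#'   \code{effect}, \code{t_mod}, \code{p}, \code{adj_p}, \code{tested}.
#' @export
pathway_group_test <- function(ps, meta) {
  tt <- moderated_two_group_test(unclass(ps), meta)
  res <- data.frame(set_id = tt$feature_id,
                    effect = tt$effect,
                    t_mod = tt$t_mod,
                    p = tt$p,
                    adj_p = bh_adjust(tt$p),
                    tested = tt$tested,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  res <- res[order(res$p, res$set_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  res
}
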