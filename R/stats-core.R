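#' @title Core statistical primitives
#' @description Pearson correlation with a t-based p-value, Benjamini-Hochberg
#'   adjustment, and the empirical-Bayes moderated two-group t-test shared by
#'   the differential-expression, pathway and covariate-association stages.
#' @name stats-core
NULL

#' Pearson correlation with a two-sided p-value
#'
#' Pairs with a missing value in either vector are dropped. The p-value comes
#' from referring \eqn{t = r \sqrt{(n-2)/(1-r^2)}} to a Student t distribution
#' with \eqn{n-2} degrees of freedom (two-sided); \eqn{|r| = 1} gives
#' \eqn{p = 0}.
#'
#' @param x,y Numeric vectors of equal length.
#' @param min_n Minimum number of complete pairs required (default 3).
#' @return A list of class \code{correlation_record} with elements \code{r},
#'   \code{n} (complete pairs used) and \code{p}.
#' @export
pearson_with_p <- function(x, y, min_n = 3) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < min_n)
    stop(sprintf("insufficient data: %d complete pairs, need >= %d", n, min_n),
         call. = FALSE)
  dx <- x - mean(x)
  dy <- y - mean(y)
  sxx <- sum(dx * dx)
  syy <- sum(dy * dy)
  if (sxx == 0 || syy == 0)
    stop("undefined correlation: constant vector after pairing", call. = FALSE)
  r <- sum(dx * dy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))  # guard rounding just past +-1
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  structure(list(r = r, n = n, p = p), class = "correlation_record")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps \code{stats::p.adjust(method = "BH")}; missing entries are passed
#' through unchanged and excluded from the family size m.
#'
#' @param p Numeric vector of p-values in [0, 1]; \code{NA} allowed.
#' @return Adjusted p-values in the original order, \code{NA} where the input
#'   was \code{NA}.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Invert the trigamma function by Newton iteration on 1/trigamma
# (monotone, nearly linear), as in the published empirical-Bayes variance
# moment estimator.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group t-test
#'
#' For each feature (row), the difference of group means is tested against a
#' posterior variance that shrinks the per-feature pooled variance
#' \eqn{s_g^2} (with \eqn{d_g = n_A + n_B - 2} df) toward a common prior.
#' The prior hyperparameters \eqn{(d_0, s_0^2)} are fitted by matching the
#' first two moments of \eqn{\log s_g^2} to a scaled inverse-chi-square
#' distribution (trigamma inversion by Newton iteration); when the excess
#' variance of \eqn{\log s_g^2} is non-positive, \eqn{d_0 = \infty} and the
#' posterior variance equals \eqn{s_0^2}. Then
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),\quad
#'   t_g = (\bar{x}_{gB} - \bar{x}_{gA}) / (\tilde{s}_g \sqrt{1/n_A + 1/n_B})}
#' with a two-sided p-value on \eqn{d_0 + d_g} df (capped at the pooled
#' residual df of all tested features). With a single testable feature no
#' moment matching is possible: \eqn{d_0} is taken as 0 and the statistic is
#' the ordinary pooled t.
#'
#' Features whose residual variance is zero in both groups are flagged
#' (\code{tested = FALSE}) and carry \code{NA} statistics.
#'
#' @param values Numeric feature x sample matrix (e.g. log2-CPM).
#' @param meta A \code{\link{sample_metadata}} covering the matrix's samples;
#'   both groups need >= 2 samples.
#' @return A data.frame with one row per feature: \code{feature_id},
#'   \code{effect} (mean B - mean A), \code{t_mod}, \code{df_total}, \code{p},
#'   \code{tested}; hyperparameters \code{s2_prior} and \code{df_prior} are
#'   attached as attributes of the same name.
#' @export
moderated_two_group_test <- function(values, meta) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("values must carry feature row names", call. = FALSE)
  meta <- check_metadata(meta, colnames(values))
  a <- meta$group == "A"
  b <- meta$group == "B"
  n_a <- sum(a); n_b <- sum(b)
  if (n_a < 2 || n_b < 2)
    stop("each group needs >= 2 samples", call. = FALSE)

  mean_a <- rowMeans(values[, a, drop = FALSE])
  mean_b <- rowMeans(values[, b, drop = FALSE])
  ss_a <- rowSums((values[, a, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((values[, b, drop = FALSE] - mean_b)^2)
  df_res <- n_a + n_b - 2
  s2 <- (ss_a + ss_b) / df_res
  tested <- s2 > 0

  effect <- mean_b - mean_a
  se_unit <- sqrt(1 / n_a + 1 / n_b)

  n_tested <- sum(tested)
  if (n_tested == 0)
    stop("no feature has positive residual variance", call. = FALSE)

  if (n_tested < 2) {
    # no shrinkage possible: ordinary pooled t
    df_prior <- 0
    s2_prior <- NA_real_
    s2_post <- s2
    df_total <- rep(df_res, length(s2))
  } else {
    z <- log(s2[tested])
    e <- z - digamma(df_res / 2) + log(df_res / 2)
    emean <- mean(e)
    evar <- stats::var(e) - trigamma(df_res / 2)
    if (evar > 0) {
      df_prior <- 2 * trigamma_inverse(evar)
      s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
    } else {
      df_prior <- Inf
      s2_prior <- mean(s2[tested])  # the published estimator's infinite-d0 limit
    }
    if (is.finite(df_prior)) {
      s2_post <- (df_prior * s2_prior + df_res * s2) / (df_prior + df_res)
    } else {
      s2_post <- rep(s2_prior, length(s2))
    }
    df_total <- pmin(df_prior + df_res, n_tested * df_res)
  }

  t_mod <- effect / (sqrt(s2_post) * se_unit)
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  t_mod[!tested] <- NA_real_
  p[!tested] <- NA_real_

  out <- data.frame(feature_id = rownames(values),
                    effect = effect,
                    t_mod = t_mod,
                    df_total = ifelse(tested, df_total, NA_real_),
                    p = p,
                    tested = tested,
                    stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "s2_prior") <- s2_prior
  attr(out, "df_prior") <- df_prior
  out
}
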