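# Independent oracle implementations used to check the package's statistics.
# These are deliberately written as plain enumerations, separate from the
# package's vectorized code paths.

# Pearson r and two-sided p via the base cor.test machinery.
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# Hand-enumerated Benjamini-Hochberg step-up: sort ascending, take the
# running minimum of p * m / rank from the largest rank down, cap at 1,
# restore input order.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    q[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Step-by-step enumeration of the gene-set random-walk score for one set,
# with explicit loops over genes, samples and walk positions.
oracle_gsva <- function(E, set_genes, tau = 1) {
  p <- nrow(E); n <- ncol(E)
  zhat <- matrix(NA_real_, p, n)
  for (i in 1:p) {
    s <- stats::sd(E[i, ])
    if (s == 0) { zhat[i, ] <- 0.5; next }
    h <- s / 4
    for (j in 1:n) {
      acc <- 0
      for (k in 1:n) acc <- acc + stats::pnorm((E[i, j] - E[i, k]) / h)
      zhat[i, j] <- acc / n
    }
  }
  inset <- rownames(E) %in% set_genes
  m <- sum(inset)
  scores <- numeric(n)
  for (j in 1:n) {
    o <- order(-zhat[, j])  # stable: ties keep row order
    rk <- integer(p); rk[o] <- 1:p
    zp <- abs(p / 2 - rk)
    wsum <- sum(zp[inset]^tau)
    walk <- 0; mx <- 0; mn <- 0
    for (t in 1:p) {
      g <- o[t]
      if (inset[g]) walk <- walk + zp[g]^tau / wsum
      else walk <- walk - 1 / (p - m)
      if (walk > mx) mx <- walk
      if (walk < mn) mn <- walk
    }
    scores[j] <- mx + mn
  }
  scores
}

# Plain-loop TMM: reference selection by 75th-percentile count fraction,
# M/A trimming by rank (30% per M tail, 5% per A tail), weighted mean.
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  f75 <- sapply(seq_len(ncol(counts)),
                function(j) unname(stats::quantile(counts[, j], 0.75)) / lib[j])
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    pos <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[pos, j]; r <- counts[pos, ref]
    M <- log2((o / lib[j]) / (r / lib[ref]))
    A <- 0.5 * log2((o / lib[j]) * (r / lib[ref]))
    w <- 1 / (1 / o - 1 / lib[j] + 1 / r - 1 / lib[ref])
    n <- length(M)
    keepM <- rank(M) >= floor(n * 0.3) + 1 & rank(M) <= n - floor(n * 0.3)
    keepA <- rank(A) >= floor(n * 0.05) + 1 & rank(A) <= n - floor(n * 0.05)
    keep <- keepM & keepA
    f[j] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# Small labelled matrix builder for fixtures.
named_matrix <- function(values, nrow, prefix_row = "F", prefix_col = "S") {
  m <- matrix(values, nrow = nrow)
  dimnames(m) <- list(sprintf("%s%02d", prefix_row, seq_len(nrow(m))),
                      sprintf("%s%02d", prefix_col, seq_len(ncol(m))))
  m
}

two_group_meta <- function(n_a, n_b) {
  ids <- sprintf("S%02d", seq_len(n_a + n_b))
  sample_metadata(ids, rep(c("A", "B"), c(n_a, n_b)))
}
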