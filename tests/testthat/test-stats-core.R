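test_that("pearson_with_p handles perfect correlation and the textbook case", {
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$r, 1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(2, 4, 6))$p, 0)
  expect_equal(pearson_with_p(c(1, 2, 3), c(6, 4, 2))$r, -1)
  expect_equal(pearson_with_p(c(1, 2, 3), c(6, 4, 2))$p, 0)

  rec <- pearson_with_p(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(rec$r, 0.8)
  orc <- oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(rec$p, orc$p, tolerance = 1e-12)
  expect_equal(rec$p, 0.2, tolerance = 1e-12)
})

test_that("pearson_with_p drops incomplete pairs and rejects degenerate input", {
  rec <- pearson_with_p(c(1, 2, NA, 4, 5), c(2, 4, 6, NA, 10))
  expect_equal(rec$n, 3)
  expect_equal(rec$r, 1)
  expect_error(pearson_with_p(c(1, 2), c(3, 4)), "insufficient data")
  expect_error(pearson_with_p(c(1, 1, 1), c(1, 2, 3)), "undefined correlation")
  expect_error(pearson_with_p(1:3, 1:4), "equal length")
})

test_that("pearson_with_p matches the cor.test oracle on random vectors", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    rec <- pearson_with_p(x, y)
    orc <- oracle_pearson(x, y)
    expect_equal(rec$r, orc$r, tolerance = 1e-12)
    expect_equal(rec$p, orc$p, tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces the step-up procedure and its fixed points", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA passed through, excluded from the family size
  expect_equal(bh_adjust(c(0.01, NA, 0.04)), c(0.02, NA, 0.04))
})

test_that("bh_adjust agrees with hand enumeration and respects its bounds", {
  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-14)
    expect_true(all(q >= p & q <= 1))
    expect_equal(rank(q), rank(oracle_bh(p)))
  }
})

test_that("moderated test gives t = 0, p = 1 for identical group profiles", {
  set.seed(9)
  X <- rbind(rep(c(1, 2, 3, 4), 2),  # group B values equal group A values
             matrix(rnorm(3 * 8), 3))
  dimnames(X) <- list(sprintf("F%02d", 1:4), sprintf("S%02d", 1:8))
  tt <- moderated_two_group_test(X, two_group_meta(4, 4))
  expect_equal(tt$effect[1], 0)
  expect_equal(tt$t_mod[1], 0)
  expect_equal(tt$p[1], 1)
})

test_that("a single feature falls back to the ordinary pooled t", {
  set.seed(2)
  X <- named_matrix(rnorm(10), 1)
  meta <- two_group_meta(5, 5)
  tt <- moderated_two_group_test(X, meta)
  ordinary <- t.test(X[1, 6:10], X[1, 1:5], var.equal = TRUE)
  expect_equal(tt$t_mod, unname(ordinary$statistic), tolerance = 1e-12)
  expect_equal(tt$p, ordinary$p.value, tolerance = 1e-12)
  expect_equal(attr(tt, "df_prior"), 0)
})

test_that("moderated test matches the limma reference on both prior branches", {
  set.seed(42)
  meta <- two_group_meta(6, 6)
  design <- cbind(1, rep(0:1, each = 6))
  # homoscedastic rows: infinite prior df
  X1 <- named_matrix(rnorm(500 * 12), 500)
  tt1 <- moderated_two_group_test(X1, meta)
  fit1 <- limma::eBayes(limma::lmFit(X1, design))
  expect_equal(attr(tt1, "df_prior"), fit1$df.prior)
  expect_equal(attr(tt1, "s2_prior"), fit1$s2.prior, tolerance = 1e-10)
  expect_equal(tt1$t_mod, unname(fit1$t[, 2]), tolerance = 1e-10)
  expect_equal(tt1$p, unname(fit1$p.value[, 2]), tolerance = 1e-10)
  # heteroscedastic rows: finite prior df from the trigamma inversion
  sds <- sqrt(1 / rgamma(500, 4, 4))
  X2 <- named_matrix(rnorm(500 * 12, sd = rep(sds, 12)), 500)
  tt2 <- moderated_two_group_test(X2, meta)
  fit2 <- limma::eBayes(limma::lmFit(X2, design))
  expect_equal(attr(tt2, "df_prior"), fit2$df.prior, tolerance = 1e-8)
  expect_equal(tt2$t_mod, unname(fit2$t[, 2]), tolerance = 1e-8)
})

test_that("infinite prior df collapses the posterior variance to the prior", {
  # every feature has the same within-group spread, so log s^2 has zero
  # excess variance and the prior df estimate diverges
  set.seed(3)
  base <- rnorm(10)
  X <- t(sapply(1:50, function(i) base + i))
  dimnames(X) <- list(sprintf("F%02d", 1:50), sprintf("S%02d", 1:10))
  X[, 6:10] <- X[, 6:10] + rep(rnorm(50), 5)  # feature-specific group offsets
  meta <- two_group_meta(5, 5)
  tt <- moderated_two_group_test(X, meta)
  expect_identical(attr(tt, "df_prior"), Inf)
  s0 <- sqrt(attr(tt, "s2_prior"))
  expect_equal(tt$t_mod, tt$effect / (s0 * sqrt(1 / 5 + 1 / 5)),
               tolerance = 1e-12)
})

test_that("zero-variance features are flagged, not tested", {
  X <- rbind(rep(1, 8), rnorm(8))
  dimnames(X) <- list(c("F01", "F02"), sprintf("S%02d", 1:8))
  meta <- two_group_meta(4, 4)
  tt <- moderated_two_group_test(X, meta)
  expect_false(tt$tested[1])
  expect_true(is.na(tt$p[1]))
  expect_true(tt$tested[2])
  expect_error(moderated_two_group_test(X[, 1:3], two_group_meta(2, 1)),
               ">= 2 samples")
})
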