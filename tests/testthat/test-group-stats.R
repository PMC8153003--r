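test_that("D'Agostino-Pearson omnibus matches a reference implementation", {
  x <- c(2.1, 3.4, 1.9, 5.6, 4.4, 3.3, 2.8, 6.1, 0.7, 3.9,
         4.8, 2.2, 3.1, 5.0, 1.4, 3.7, 2.9, 4.1, 3.5, 2.6)
  res <- dagostino_pearson(x)
  # frozen from an independent implementation of the same omnibus test
  expect_equal(res$statistic, 0.06607284166803813, tolerance = 1e-6)
  expect_equal(res$p.value, 0.9675033216694473, tolerance = 1e-6)
  expect_equal(res$z_skewness, 0.2522950826179614, tolerance = 1e-6)
  expect_equal(res$z_kurtosis, -0.0491938304549885, tolerance = 1e-6)
  expect_gte(res$statistic, 0)
  expect_error(dagostino_pearson(rnorm(7)), "n >= 8")
})

test_that("D'Agostino-Pearson p-values are near-uniform under normality", {
  set.seed(301)
  ps <- vapply(1:400, function(i) dagostino_pearson(rnorm(100))$p.value, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
})

test_that("one-way ANOVA matches the hand sum-of-squares oracle", {
  # groups {1,2,3},{2,3,4},{3,4,5}: SSB = 6 (df 2), SSW = 6 (df 6) -> F = 3
  res <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(res$F, 3)
  expect_equal(res$p.value, pf(3, 2, 6, lower.tail = FALSE))
  # identical groups: F = 0, p = 1
  null <- one_way_anova(rep(list(c(1, 2, 3)), 3))
  expect_equal(null$F, 0)
  expect_equal(null$p.value, 1)
  # zero within-group variance with distinct means
  sep <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p.value, 0)
  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 observations")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(302)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(11, mean = 0.5)
    f <- one_way_anova(list(a, b))$F
    t <- t.test(a, b, var.equal = TRUE)$statistic
    expect_equal(f, unname(t^2), tolerance = 1e-9)
  }
})

test_that("Tukey-Kramer q and p match hand computation and stats::TukeyHSD", {
  # balanced toy: means 2, 4, 7; each group var 1 over n = 3 -> MSE = 1,
  # SE = sqrt(MSE/n) = 1/sqrt(3), q12 = 2*sqrt(3), q13 = 5*sqrt(3)
  g <- list(a = c(1, 2, 3), b = c(3, 4, 5), c = c(6, 7, 8))
  tk <- tukey_hsd(g)
  expect_equal(tk$q[tk$pair == "b-a"], 2 * sqrt(3))
  expect_equal(tk$q[tk$pair == "c-a"], 5 * sqrt(3))
  expect_equal(tk$p.adj,
               ptukey(tk$q, nmeans = 3, df = 6, lower.tail = FALSE))
  # at the tabled 5% critical value q(0.05; k=3, df=12) the p is 0.05
  qcrit <- qtukey(0.95, nmeans = 3, df = 12)
  expect_equal(round(qcrit, 2), 3.77) # published studentized-range table
  expect_equal(ptukey(qcrit, 3, 12, lower.tail = FALSE), 0.05,
               tolerance = 1e-6)

  # unbalanced groups against the stats reference implementation
  set.seed(303)
  y <- c(rnorm(12), rnorm(7, 1), rnorm(11, 0.5))
  gf <- factor(rep(c("C", "S", "R"), c(12, 7, 11)), c("C", "S", "R"))
  mine <- tukey_hsd(split(y, gf))
  ref <- stats::TukeyHSD(stats::aov(y ~ gf))$gf
  for (pair in rownames(ref)) {
    row <- mine[mine$pair == pair, ]
    expect_equal(row$diff, ref[pair, "diff"], tolerance = 1e-9)
    expect_equal(row$p.adj, ref[pair, "p adj"], tolerance = 1e-6)
  }
})

test_that("Tukey adjusted p is never below the pairwise two-sample p", {
  set.seed(304)
  for (i in 1:10) {
    g <- list(a = rnorm(6), b = rnorm(8, 0.8), c = rnorm(7, -0.3))
    tk <- tukey_hsd(g)
    for (pr in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      praw <- t.test(g[[pr[1]]], g[[pr[2]]], var.equal = TRUE)$p.value
      padj <- tk$p.adj[tk$pair %in% c(paste(pr[2], pr[1], sep = "-"),
                                      paste(pr[1], pr[2], sep = "-"))]
      expect_gte(padj + 1e-12, praw)
    }
  }
  expect_error(tukey_hsd(list(c(1, 1), c(1, 1))), "zero pooled")
})

test_that("Pearson correlation matches hand arithmetic and symmetry", {
  x <- c(1, 2, 3, 4); y <- c(2, 1, 4, 3)
  # hand product-moment: cov = 1, sd both sqrt(5/3) -> r = 0.6
  res <- pearson_cor(x, y)
  expect_equal(res$r, 0.6)
  expect_equal(pearson_cor(y, x)$r, res$r)
  expect_equal(pearson_cor(x, x)$r, 1)
  # affine invariance with a sign flip under negative scaling
  expect_equal(pearson_cor(2 * x + 3, y)$r, res$r)
  expect_equal(pearson_cor(-2 * x, y)$r, -res$r)
  expect_error(pearson_cor(c(1, 1, 1), y[1:3]), "zero variance")
})

test_that("printed cohort-size p-values are reproduced from r and n", {
  p_from_r <- function(r, n) {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(t), n - 2)
  }
  # hippocampal cohort: n = 30
  expect_equal(round(p_from_r(-0.40, 30), 2), 0.03)
  # hypothalamic cohort: n = 16
  expect_equal(round(p_from_r(0.66, 16), 3), 0.005)
  # the t-based p is exactly what pearson_cor computes
  set.seed(305)
  x <- rnorm(16); y <- 0.6 * x + rnorm(16)
  res <- pearson_cor(x, y)
  expect_equal(res$p.value, p_from_r(res$r, 16), tolerance = 1e-12)
})

test_that("correlation matrix agrees with pairwise calls and flags gaps", {
  set.seed(306)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  cm <- correlation_matrix(m)
  expect_equal(diag(cm$r), setNames(rep(1, 4), c("w", "x", "y", "z")))
  for (i in 2:4) {
    for (j in 1:(i - 1)) {
      ref <- pearson_cor(m[, i], m[, j])
      expect_equal(cm$r[i, j], ref$r)
      expect_equal(cm$p[i, j], ref$p.value)
      expect_equal(cm$r[i, j], cm$r[j, i])
    }
  }
  # a requested variable missing from the data is marked not computable
  cm2 <- correlation_matrix(m[, 1:3], variables = c("w", "x", "y", "absent"))
  expect_true(is.na(cm2$r["absent", "w"]))
  expect_equal(cm2$stars["absent", "w"], "na")
  # strong planted correlation earns stars
  mm <- cbind(a = 1:10, b = (1:10) + rnorm(10, 0, 0.1))
  cm3 <- correlation_matrix(mm)
  expect_equal(cm3$stars["b", "a"], "***")
})
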