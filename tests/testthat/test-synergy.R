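test_that("ols_fit recovers exact fits and the analytic single-predictor case", {
  set.seed(401)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 + X %*% c(1, -2, 0.5)
  fit <- ols_fit(as.numeric(y), X)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  expect_equal(fit$R, 1, tolerance = 1e-12)

  # single predictor: R = |r| and overall-F p equals the correlation p
  x1 <- rnorm(25); y1 <- 0.4 * x1 + rnorm(25)
  f1 <- ols_fit(y1, cbind(a = x1))
  ct <- pearson_cor(x1, y1)
  expect_equal(f1$R, abs(ct$r), tolerance = 1e-9)
  expect_equal(f1$p.value, ct$p.value, tolerance = 1e-9)

  expect_error(ols_fit(y1[1:3], cbind(a = x1[1:3], b = x1[1:3] * 2)),
               "n > predictors")
  expect_error(ols_fit(y1, cbind(a = x1, b = 2 * x1)), "collinear.*b")
})

test_that("overall-F p is approximately uniform under the null", {
  set.seed(402)
  ps <- vapply(1:400, function(i) {
    X <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
    ols_fit(rnorm(50), X)$p.value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("admissibility keeps only negatively correlated predictors", {
  set.seed(403)
  n <- 40
  neg1 <- rnorm(n); neg2 <- rnorm(n); pos <- rnorm(n)
  target <- -0.7 * neg1 - 0.5 * neg2 + 0.6 * pos + rnorm(n, 0, 0.3)
  wide <- cbind(FKBP5 = target, m1 = neg1, m2 = neg2, m3 = pos)
  pool <- admissible_predictors("FKBP5", c("m1", "m2", "m3"), wide, "strict")
  # cross-check against the pairwise correlation signs
  expected <- c("m1", "m2", "m3")[vapply(c("m1", "m2", "m3"), function(m) {
    pearson_cor(wide[, m], target)$r < 0
  }, NA)]
  expect_setequal(pool, expected)
  expect_setequal(
    admissible_predictors("FKBP5", c("m1", "m2", "m3"), wide, "permissive"),
    c("m1", "m2", "m3"))
  # all-positive candidates -> empty pool, search skipped for that target
  wide2 <- cbind(BDNF = neg1, m1 = neg1 + rnorm(n, 0, 0.1),
                 m2 = neg1 + rnorm(n, 0, 0.2))
  expect_length(admissible_predictors("BDNF", c("m1", "m2"), wide2), 0)
})

test_that("best-subset search is exhaustive-optimal against brute force", {
  set.seed(404)
  for (rep in 1:30) {
    n <- 25
    wide <- matrix(rnorm(n * 6), n, 6,
                   dimnames = list(NULL, paste0("m", 1:6)))
    y <- as.numeric(wide %*% rnorm(6) + rnorm(n))
    res <- best_subset_search(y, wide, colnames(wide), sizes = c(2, 3))
    for (size in c(2, 3)) {
      oracle <- bruteforce_best(y, wide, colnames(wide), size)
      row <- res$best[res$best$size == size, ]
      expect_equal(row$predictors, oracle$predictors)
      expect_equal(row$R, oracle$R, tolerance = 1e-9)
    }
    # ledger covers every subset exactly once
    expect_equal(sum(res$ledger$size == 2), choose(6, 2))
    expect_equal(sum(res$ledger$size == 3), choose(6, 3))
  }
})

test_that("suppressor structure is found only by joint search", {
  # y = A - C with A, C independent: each alone explains half the variance,
  # B is a moderate direct correlate; only the pair {A, C} is perfect.
  set.seed(405)
  n <- 60
  A <- rnorm(n); C <- rnorm(n)
  y <- A - C
  B <- 0.5 * y + rnorm(n, 0, 0.8)
  wide <- cbind(A = A, B = B, C = C)
  res <- best_subset_search(y, wide, c("A", "B", "C"), sizes = 2)
  expect_equal(res$best$predictors, "A, C")
  expect_equal(res$best$R2, 1, tolerance = 1e-12)
  oracle <- bruteforce_best(y, wide, c("A", "B", "C"), 2)
  expect_equal(res$best$predictors, oracle$predictors)
})

test_that("a pool of exactly two forces the single 2-subset", {
  set.seed(406)
  wide <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("p", "q")))
  y <- rnorm(20)
  res <- best_subset_search(y, wide, c("q", "p"), sizes = c(4, 3, 2))
  expect_equal(nrow(res$ledger), 1L)
  expect_equal(res$best$predictors, "p, q")
  expect_error(best_subset_search(y, wide, character(0)), "empty")
})

test_that("nesting monotonicity: adding predictors never lowers R2", {
  set.seed(407)
  n <- 30
  wide <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rnorm(n)
  for (rep in 1:5) {
    small <- sample(colnames(wide), 2)
    big <- c(small, sample(setdiff(colnames(wide), small), 2))
    r2_small <- ols_fit(y, wide[, small])$R2
    r2_big <- ols_fit(y, wide[, big])$R2
    expect_gte(r2_big + 1e-12, r2_small)
  }
})

test_that("orthonormal predictors give additive squared correlations", {
  n <- 32
  qr_dec <- qr(matrix(rnorm(n * 3), n, 3))
  Q <- qr.Q(qr_dec)
  Q <- scale(Q, center = TRUE, scale = FALSE)
  Q <- apply(Q, 2, function(v) v / sd(v))
  colnames(Q) <- c("a", "b", "c")
  # re-orthogonalize after scaling to make columns exactly uncorrelated
  Q[, "b"] <- residuals(lm(Q[, "b"] ~ Q[, "a"]))
  Q[, "c"] <- residuals(lm(Q[, "c"] ~ Q[, "a"] + Q[, "b"]))
  y <- rnorm(n)
  r2_joint <- ols_fit(y, Q)$R2
  r2_sum <- sum(vapply(colnames(Q), function(cn) {
    cor(y, Q[, cn])^2
  }, 0))
  expect_equal(r2_joint, r2_sum, tolerance = 1e-9)
})

test_that("synergy_search skips targets with no admissible miRNA", {
  # BDNF positively correlated with every miRNA (as in hypothalamus) must
  # yield no BDNF models for that area.
  set.seed(408)
  n <- 16
  shared <- rnorm(n)
  ct_list <- list()
  analytes <- c(MIRNA_PANEL, "FKBP5", "BDNF", "GAPDH", "U6")
  mice <- sprintf("H%02d", 1:n)
  vals <- cbind(
    sapply(MIRNA_PANEL, function(m) 5 + shared + rnorm(n, 0, 0.4)),
    FKBP5 = 6 - shared + rnorm(n, 0, 0.4),
    BDNF = 6 + shared + rnorm(n, 0, 0.4),
    GAPDH = 17, U6 = 18
  )
  grid <- expand.grid(replicate = 1:3, analyte = analytes, mouse_id = mice,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$area <- "HT"
  grid$ct <- vals[cbind(match(grid$mouse_id, mice),
                        match(grid$analyte, colnames(vals)))]
  phen <- data.frame(mouse_id = mice,
                     phenotype = rep(c("control", "susceptible"), each = 8))
  rq <- quantify_cohort(grid[c("mouse_id", "area", "analyte", "replicate",
                               "ct")], phen)
  res <- synergy_search(rq)
  expect_length(res$pools[["HT:BDNF"]], 0)
  expect_false("BDNF" %in% res$best$target)
  expect_setequal(res$pools[["HT:FKBP5"]], MIRNA_PANEL)
  expect_true(all(res$best$target == "FKBP5"))
  # best models per size attain the ledger maximum
  for (size in unique(res$best$size)) {
    led <- res$ledger[res$ledger$size == size, ]
    expect_equal(res$best$R[res$best$size == size], max(led$R))
  }
})

test_that("score regressions obey OLS nesting and find planted fits", {
  co <- generate_cohort(small_config(), seed = 409)
  sc <- composite_scores(co$behavior)
  rq <- quantify_cohort(co$ct, sc)
  reg <- score_regressions(sc, rq)
  expect_setequal(unique(reg$model), c("miRNAs_mRNAs", "miRNAs", "mRNAs"))
  expect_equal(nrow(reg), 4 * 3 * 3) # 4 scores x 3 areas x 3 predictor sets
  for (area in unique(reg$area)) {
    for (s in unique(reg$score)) {
      sub <- reg[reg$area == area & reg$score == s, ]
      full <- sub$R2[sub$model == "miRNAs_mRNAs"]
      expect_gte(full + 1e-9, max(sub$R2[sub$model != "miRNAs_mRNAs"]))
    }
  }

  # plant a score that is an exact linear combination of miRNA RQs
  wide <- rq_wide(rq, "HIP")
  stressed <- rownames(wide)[attr(wide, "phenotype") != "control"]
  sc2 <- sc
  sc2$arousal <- as.numeric(wide[match(sc$mouse_id, rownames(wide)),
                                 MIRNA_PANEL] %*% c(1, -2, 0.5, 1))
  reg2 <- score_regressions(sc2, rq)
  hit <- reg2[reg2$area == "HIP" & reg2$score == "arousal" &
                reg2$model == "miRNAs", ]
  expect_equal(hit$R2, 1, tolerance = 1e-9)
})
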