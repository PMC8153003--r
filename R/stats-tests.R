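#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transforms of sample skewness (D'Agostino 1970) and sample
#' kurtosis (Anscombe-Glynn 1983) into the omnibus statistic
#' `K2 = Z1^2 + Z2^2`, referred to a chi-square distribution with 2 df.
#'
#' @param x Numeric vector, n >= 8.
#' @return List with `statistic` (K2), `p.value`, `z_skewness`,
#'   `z_kurtosis` and `n`.
#' @export
dagostino_pearson <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop_ais("dagostino_pearson does not accept missing values")
  n <- length(x)
  if (n < 8L) {
    stop_ais("D'Agostino-Pearson test requires n >= 8 (got ", n, ")")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_ais("input has zero variance")
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5 # sample skewness g1
  b2 <- m4 / m2^2   # sample kurtosis g2 + 3

  # Skewness transform.
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # Kurtosis transform.
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term <- (1 - 2 / a) / denom
  z2 <- ((1 - 2 / (9 * a)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p.value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skewness = z1, z_kurtosis = z2, n = n)
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (between/within mean-square ratio,
#' fitted through [stats::lm()]), with the degenerate zero-within-variance
#' case handled explicitly: identical group means give F = 0, p = 1, while
#' distinct means over zero residual variance give F = Inf, p = 0.
#'
#' @param groups List of numeric vectors, one per group (k >= 2, each
#'   n >= 2).
#' @return List with `F`, `p.value`, `df` (numerator, denominator) and
#'   `group_ns`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_ais("one_way_anova needs a list of at least 2 groups")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) {
    stop_ais("every group needs at least 2 observations (sizes: ",
             paste(ns, collapse = ", "), ")")
  }
  y <- unlist(groups, use.names = FALSE)
  if (anyNA(y)) stop_ais("one_way_anova does not accept missing values")
  g <- factor(rep(seq_along(groups), ns))
  k <- length(groups)
  N <- length(y)
  ssw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  means <- tapply(y, g, mean)
  ssb <- sum(ns * (means - mean(y))^2)
  if (ssw <= .Machine$double.eps * sum(y^2)) {
    if (ssb <= .Machine$double.eps * max(sum(y^2), 1)) {
      return(list(F = 0, p.value = 1, df = c(k - 1L, N - k), group_ns = ns))
    }
    return(list(F = Inf, p.value = 0, df = c(k - 1L, N - k), group_ns = ns))
  }
  fit <- anova(lm(y ~ g))
  list(F = fit[1, "F value"], p.value = fit[1, "Pr(>F)"],
       df = c(k - 1L, N - k), group_ns = ns)
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Pairwise comparisons after a one-way ANOVA using the studentized range
#' statistic with the pooled within-group variance. Unbalanced designs use
#' the Tukey-Kramer denominator `sqrt(MSE/2 * (1/ni + 1/nj))`; adjusted
#' p-values come from the studentized range distribution with parameters
#' (k, N - k).
#'
#' @param groups Named (or unnamed) list of numeric vectors, one per group.
#' @return Data.frame with one row per unordered pair: `pair`, `diff` (mean
#'   difference), `q` (studentized range statistic), `p.adj`.
#' @export
tukey_hsd <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_ais("tukey_hsd needs a list of at least 2 groups")
  }
  ns <- lengths(groups)
  if (any(ns < 2L)) stop_ais("every group needs at least 2 observations")
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  k <- length(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  mse <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0)) / (N - k)
  if (mse <= 0) stop_ais("zero pooled within-group variance")
  pairs <- combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    d <- unname(means[j] - means[i])
    se <- sqrt(mse / 2 * (1 / ns[[i]] + 1 / ns[[j]]))
    q <- abs(d) / se
    c(d, q, ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE))
  })
  out <- data.frame(
    pair = apply(pairs, 2, function(ij) {
      paste(names(groups)[ij[2]], names(groups)[ij[1]], sep = "-")
    }),
    diff = res[1, ], q = res[2, ], p.adj = res[3, ],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pearson correlation with two-sided significance
#'
#' Product-moment correlation with the t-based two-sided p-value
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on n - 2 df.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, nonzero variance.
#' @param alpha Significance flag level (default 0.05).
#' @return List of class `cor_result`: `r`, `p.value`, `n`, `significant`.
#' @export
pearson_cor <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop_ais("x and y must have equal length")
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop_ais("Pearson correlation requires n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop_ais("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p.value = ct$p.value, n = n,
                 significant = ct$p.value < alpha),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("r = %.3f (p = %.3g, n = %d)%s\n", x$r, x$p.value, x$n,
              if (x$significant) " *" else ""))
  invisible(x)
}

star_code <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Pairwise Pearson correlation matrix with significance stars
#'
#' Computes all pairwise correlations among the columns of an expression (or
#' score) matrix. Pairs with fewer than 3 complete observations, or with a
#' fully missing variable, are marked not computable (NA entries, star code
#' `"na"`), mirroring the grey cells of database-wide co-expression
#' matrices.
#'
#' @param mat Numeric matrix or data.frame, variables in columns.
#' @param variables Optional subset/order of column names.
#' @return Object of class `cor_matrix`: list of matrices `r`, `p`, `n`,
#'   and character matrix `stars` (`*` p<0.05, `**` p<0.01, `***` p<0.001).
#' @export
correlation_matrix <- function(mat, variables = colnames(mat)) {
  mat <- as.matrix(mat)
  missing_vars <- setdiff(variables, colnames(mat))
  k <- length(variables)
  r <- p <- nmat <- matrix(NA_real_, k, k,
                           dimnames = list(variables, variables))
  diag(r) <- 1
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      vi <- variables[i]; vj <- variables[j]
      if (vi %in% missing_vars || vj %in% missing_vars) next
      x <- mat[, vi]; y <- mat[, vj]
      keep <- complete.cases(x, y)
      if (sum(keep) < 3L || sd(x[keep]) == 0 || sd(y[keep]) == 0) next
      ct <- pearson_cor(x[keep], y[keep])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p.value
      nmat[i, j] <- nmat[j, i] <- ct$n
    }
  }
  stars <- star_code(p)
  stars[is.na(p)] <- "na"
  diag(stars) <- ""
  dim(stars) <- dim(p)
  dimnames(stars) <- dimnames(p)
  structure(list(r = r, p = p, n = nmat, stars = stars),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 2, ...) {
  k <- ncol(x$r)
  vars <- colnames(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      out[i, j] <- if (is.na(x$r[i, j]) && x$stars[i, j] == "na") "n.c." else
        paste0(formatC(x$r[i, j], digits = digits, format = "f"),
               x$stars[i, j])
    }
  }
  cat("Pearson correlation matrix (lower triangle; * p<0.05, ** p<0.01,",
      "*** p<0.001; n.c. = not computable)\n")
  print(out[-1, -k, drop = FALSE], quote = FALSE)
  invisible(x)
}

#' Heatmap of a correlation matrix
#'
#' Base-graphics image of the correlation matrix with significance stars
#' overprinted; not-computable cells are drawn grey.
#'
#' @param x A `cor_matrix`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.cor_matrix <- function(x, ...) {
  k <- ncol(x$r)
  z <- x$r[, k:1, drop = FALSE]
  pal <- grDevices::colorRampPalette(c("darkgreen", "white", "firebrick"))(61)
  graphics::image(seq_len(k), seq_len(k), z, zlim = c(-1, 1), col = pal,
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(k), rownames(z), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), colnames(z), las = 2, cex.axis = 0.8)
  nc <- which(is.na(z), arr.ind = TRUE)
  if (nrow(nc)) {
    graphics::rect(nc[, 1] - 0.5, nc[, 2] - 0.5, nc[, 1] + 0.5,
                   nc[, 2] + 0.5, col = "grey80", border = NA)
  }
  st <- x$stars[, k:1, drop = FALSE]
  idx <- which(st %in% c("*", "**", "***"), arr.ind = TRUE)
  if (nrow(idx)) {
    graphics::text(idx[, 1], idx[, 2], st[idx], cex = 0.9)
  }
  invisible(x)
}
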