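#' Ordinary least squares fit with model-level summary
#'
#' Fits `y ~ X` by OLS through [stats::lm()] and reports the model-level
#' quantities used throughout the synergy analyses: the multiple correlation
#' `R = sqrt(R^2)`, the coefficient of determination `R^2`, and the overall
#' F-test p-value of the fitted model.
#'
#' @param y Response vector.
#' @param X Numeric predictor matrix (named columns); `n` must exceed the
#'   number of predictors + 1 and `X` must have full column rank.
#' @return List of class `ols_fit`: `R`, `R2`, `p.value`, `n`, `predictors`,
#'   `coefficients`.
#' @export
ols_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(y) || anyNA(X)) stop_ais("ols_fit does not accept missing values")
  n <- length(y)
  if (nrow(X) != n) stop_ais("y and X row counts differ")
  p <- ncol(X)
  if (n <= p + 1L) {
    stop_ais("need n > predictors + 1 (n = ", n, ", predictors = ", p, ")")
  }
  qx <- qr(cbind(1, X))
  if (qx$rank < p + 1L) {
    aliased <- qx$pivot[(qx$rank + 1L):(p + 1L)]
    aliased <- aliased[aliased > 1L] - 1L
    stop_ais("predictor matrix is rank deficient; collinear predictor(s): ",
             paste(colnames(X)[aliased], collapse = ", "))
  }
  dat <- data.frame(.y = y, X, check.names = FALSE)
  fit <- lm(.y ~ ., data = dat)
  sm <- summary(fit)
  r2 <- sm$r.squared
  fstat <- sm$fstatistic
  pval <- if (is.null(fstat)) NA_real_ else {
    pf(fstat[["value"]], fstat[["numdf"]], fstat[["dendf"]],
       lower.tail = FALSE)
  }
  structure(list(R = sqrt(max(r2, 0)), R2 = r2, p.value = pval, n = n,
                 predictors = colnames(X), coefficients = coef(fit)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: %s\n  R = %.3f, R2 = %.3f, p = %.4g, n = %d\n",
              paste(x$predictors, collapse = " + "),
              x$R, x$R2, x$p.value, x$n))
  invisible(x)
}

#' Admissible miRNA predictors for a target transcript
#'
#' The synergy search only admits miRNAs whose expression is negatively
#' correlated with the target in that area (`strict` mode, the default,
#' matching the biological expectation that a repressing miRNA
#' anti-correlates with its target). `permissive` mode admits every
#' candidate.
#'
#' @param target Column name of the response in `wide`.
#' @param candidates Candidate predictor column names.
#' @param wide Numeric matrix, mice in rows (e.g. from [rq_wide()]).
#' @param mode `"strict"` or `"permissive"`.
#' @return Character vector of admissible predictor names (possibly empty).
#' @export
admissible_predictors <- function(target, candidates, wide,
                                  mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  candidates <- intersect(candidates, colnames(wide))
  if (mode == "permissive") return(candidates)
  keep <- vapply(candidates, function(cand) {
    cor(wide[, cand], wide[, target],
        use = "complete.obs") < 0
  }, logical(1))
  candidates[keep]
}

#' Exhaustive best-subset regression search
#'
#' Enumerates every subset of the admissible predictor pool at each
#' requested size, fits each by OLS, and reports the subset with the highest
#' multiple correlation R per size (ties broken by lexicographic
#' predictor-name order). The complete enumeration ledger is retained so the
#' search is auditable and post-hoc multiplicity corrections remain
#' possible.
#'
#' @param y Response vector.
#' @param wide Numeric predictor matrix (mice in rows).
#' @param pool Admissible predictor names.
#' @param sizes Subset sizes to enumerate (default 4, 3, 2). Sizes larger
#'   than the pool, or too large for the sample size, are skipped with a
#'   message.
#' @return Object of class `subset_search`: list with `best` (data.frame,
#'   one row per size) and `ledger` (data.frame over every fitted subset:
#'   `size`, `predictors`, `R`, `R2`, `p.value`, `n`).
#' @export
best_subset_search <- function(y, wide, pool, sizes = c(4L, 3L, 2L)) {
  if (!length(pool)) stop_ais("empty predictor pool")
  pool <- sort(pool)
  n <- length(y)
  ledger <- list()
  for (size in sort(unique(as.integer(sizes)), decreasing = TRUE)) {
    if (size > length(pool)) {
      message("subset size ", size, " exceeds pool (", length(pool),
              "); skipped")
      next
    }
    if (n <= size + 1L) {
      message("subset size ", size, " too large for n = ", n, "; skipped")
      next
    }
    subsets <- combn(pool, size, simplify = FALSE)
    for (s in subsets) {
      fit <- ols_fit(y, wide[, s, drop = FALSE])
      ledger[[length(ledger) + 1L]] <- data.frame(
        size = size, predictors = paste(s, collapse = ", "),
        R = fit$R, R2 = fit$R2, p.value = fit$p.value, n = fit$n,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(ledger)) {
    return(structure(list(best = NULL, ledger = NULL),
                     class = "subset_search"))
  }
  ledger <- do.call(rbind, ledger)
  best <- do.call(rbind, lapply(split(ledger, ledger$size), function(df) {
    df <- df[order(-df$R, df$predictors), ]
    df[1, ]
  }))
  best <- best[order(-best$size), ]
  rownames(best) <- rownames(ledger) <- NULL
  structure(list(best = best, ledger = ledger), class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  if (is.null(x$best)) {
    cat("Best-subset search: no fitted models\n")
    return(invisible(x))
  }
  cat("Best model per subset size (full enumeration in $ledger):\n")
  print.data.frame(x$best, digits = 3)
  invisible(x)
}

#' Synergic miRNA regression search over targets and brain areas
#'
#' For every target transcript and brain area, filters the miRNA panel to
#' the admissible (negatively correlated) predictors and runs the exhaustive
#' best-subset search of [best_subset_search()] on the target's RQ,
#' reporting the best model of each size with R, R-squared and overall-F
#' p-value. Targets with an empty admissible pool in an area are skipped.
#'
#' @param rq An `rq_table`.
#' @param targets Target transcripts (default FKBP5, BDNF).
#' @param mirnas Candidate miRNA predictors.
#' @param mode Admissibility mode, see [admissible_predictors()].
#' @param sizes Subset sizes to enumerate.
#' @param mice `"all"` (default) or `"stressed"`.
#' @return Object of class `synergy_search`: list with `best` (data.frame
#'   over all target/area/size rows), `ledger`, and `pools` (admissible
#'   pool per target/area).
#' @export
synergy_search <- function(rq, targets = MRNA_PANEL, mirnas = MIRNA_PANEL,
                           mode = c("strict", "permissive"),
                           sizes = c(4L, 3L, 2L),
                           mice = c("all", "stressed")) {
  mode <- match.arg(mode)
  mice <- match.arg(mice)
  best <- list(); ledger <- list(); pools <- list()
  for (area in sort(unique(rq$area))) {
    wide <- rq_wide(rq, area)
    if (mice == "stressed") {
      wide <- wide[attr(wide, "phenotype") != "control", , drop = FALSE]
    }
    for (tg in intersect(targets, colnames(wide))) {
      pool <- admissible_predictors(tg, mirnas, wide, mode)
      pools[[paste(area, tg, sep = ":")]] <- pool
      if (!length(pool)) next
      res <- best_subset_search(wide[, tg], wide, pool, sizes)
      if (is.null(res$best)) next
      res$best <- cbind(area = area, target = tg, res$best,
                        stringsAsFactors = FALSE)
      res$ledger <- cbind(area = area, target = tg, res$ledger,
                          stringsAsFactors = FALSE)
      best[[length(best) + 1L]] <- res$best
      ledger[[length(ledger) + 1L]] <- res$ledger
    }
  }
  structure(list(
    best = if (length(best)) do.call(rbind, best) else NULL,
    ledger = if (length(ledger)) do.call(rbind, ledger) else NULL,
    pools = pools, mode = mode
  ), class = "synergy_search")
}

#' @export
print.synergy_search <- function(x, ...) {
  cat(sprintf("Synergy regression search (%s admissibility)\n", x$mode))
  if (is.null(x$best)) {
    cat("No admissible models.\n")
    return(invisible(x))
  }
  df <- x$best
  df$signif <- star_code(df$p.value)
  print.data.frame(df, digits = 3)
  invisible(x)
}

#' @export
summary.synergy_search <- function(object, ...) {
  print(object)
  if (!is.null(object$ledger)) {
    cat(sprintf("\nFull enumeration: %d fitted models\n",
                nrow(object$ledger)))
  }
  for (key in names(object$pools)) {
    cat(sprintf("  pool %s: %s\n", key,
                if (length(object$pools[[key]])) {
                  paste(object$pools[[key]], collapse = ", ")
                } else "(empty; search skipped)"))
  }
  invisible(object)
}

#' Combined-predictor regressions of behavioral scores on expression
#'
#' For each composite behavioral score and brain area, fits three OLS
#' models on the stressed mice: all miRNAs + mRNAs (6 predictors), miRNAs
#' only (4), and mRNAs only (2), reporting R, R-squared and the overall-F
#' p-value of each. Models whose predictor count reaches the sample size
#' are skipped with a message.
#'
#' @param scores An `ais_scores` data.frame.
#' @param rq An `rq_table`.
#' @param mirnas,mrnas Predictor analyte names.
#' @param mice `"stressed"` (default) or `"all"`.
#' @return Data.frame with `score`, `area`, `model` (miRNAs_mRNAs, miRNAs,
#'   mRNAs), `R`, `R2`, `p.value`, `n`, `signif`.
#' @export
score_regressions <- function(scores, rq, mirnas = MIRNA_PANEL,
                              mrnas = MRNA_PANEL,
                              mice = c("stressed", "all")) {
  mice <- match.arg(mice)
  score_cols <- c("arousal", "avoidance", "social_memory", "ptsd_like")
  model_sets <- list(
    miRNAs_mRNAs = c(mirnas, mrnas),
    miRNAs = mirnas,
    mRNAs = mrnas
  )
  rows <- list()
  for (area in sort(unique(rq$area))) {
    wide <- rq_wide(rq, area)
    keep <- rownames(wide)
    if (mice == "stressed") {
      keep <- keep[attr(wide, "phenotype")[keep] != "control"]
    }
    sc <- scores[match(keep, scores$mouse_id), ]
    for (s in score_cols) {
      for (mn in names(model_sets)) {
        preds <- intersect(model_sets[[mn]], colnames(wide))
        if (length(keep) <= length(preds) + 1L) {
          message("score model ", s, "/", area, "/", mn,
                  " skipped: n = ", length(keep), " too small for ",
                  length(preds), " predictors")
          next
        }
        fit <- ols_fit(sc[[s]], wide[keep, preds, drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          score = s, area = area, model = mn, R = fit$R, R2 = fit$R2,
          p.value = fit$p.value, n = fit$n, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- star_code(out$p.value)
  rownames(out) <- NULL
  out
}
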