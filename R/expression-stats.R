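#' Per-analyte group comparison across phenotypes
#'
#' For every (area, analyte) pair in an RQ table, runs a one-way ANOVA of RQ
#' across the control/susceptible/resilient phenotypes followed by the
#' Tukey-Kramer post hoc test, and reports the D'Agostino-Pearson normality
#' p-value of the pooled sample where n allows it.
#'
#' @param rq An `rq_table` from [quantify_cohort()].
#' @param min_group_n Groups smaller than this are dropped from the ANOVA of
#'   that analyte (default 2, the minimum the test admits).
#' @return Object of class `expression_anova`: data.frame with one row per
#'   (area, analyte) carrying `F`, `p.value`, group sizes and the normality
#'   p, plus a `tukey` attribute (named list of per-row post hoc tables).
#' @export
expression_anova <- function(rq, min_group_n = 2L) {
  stopifnot(inherits(rq, "data.frame"))
  combos <- unique(rq[c("area", "analyte")])
  rows <- vector("list", nrow(combos))
  tukey <- vector("list", nrow(combos))
  names(tukey) <- paste(combos$area, combos$analyte, sep = ":")
  for (i in seq_len(nrow(combos))) {
    sub <- rq[rq$area == combos$area[i] & rq$analyte == combos$analyte[i], ]
    groups <- split(sub$rq, sub$phenotype)
    groups <- groups[lengths(groups) >= min_group_n]
    if (length(groups) < 2L) {
      rows[[i]] <- data.frame(
        area = combos$area[i], analyte = combos$analyte[i],
        F = NA_real_, p.value = NA_real_,
        n_control = sum(sub$phenotype == "control"),
        n_susceptible = sum(sub$phenotype == "susceptible"),
        n_resilient = sum(sub$phenotype == "resilient"),
        normality_p = NA_real_, stringsAsFactors = FALSE
      )
      next
    }
    av <- one_way_anova(groups)
    norm_p <- if (nrow(sub) >= 8L && sd(sub$rq) > 0) {
      dagostino_pearson(sub$rq)$p.value
    } else {
      NA_real_
    }
    rows[[i]] <- data.frame(
      area = combos$area[i], analyte = combos$analyte[i],
      F = av$F, p.value = av$p.value,
      n_control = sum(sub$phenotype == "control"),
      n_susceptible = sum(sub$phenotype == "susceptible"),
      n_resilient = sum(sub$phenotype == "resilient"),
      normality_p = norm_p, stringsAsFactors = FALSE
    )
    tukey[[i]] <- tukey_hsd(groups)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_anova", "data.frame")
  attr(out, "tukey") <- tukey
  out
}

#' @export
print.expression_anova <- function(x, ...) {
  cat("One-way ANOVA of RQ across phenotypes (Tukey tables in",
      "attr(, 'tukey'))\n")
  df <- as.data.frame(x)
  df$signif <- star_code(df$p.value)
  print.data.frame(df, digits = 3)
  invisible(x)
}

#' miRNA:target correlation table per brain area
#'
#' Pearson correlation of each target transcript's RQ against each miRNA's
#' RQ within every brain area. By default all mice measured in the area
#' enter the correlation; `mice = "stressed"` restricts to the two stressed
#' phenotypes.
#'
#' @param rq An `rq_table`.
#' @param targets Target transcripts (default FKBP5, BDNF).
#' @param mirnas miRNA analytes (default the four-miRNA panel).
#' @param mice `"all"` (default) or `"stressed"`.
#' @return Data.frame with `area`, `target`, `mirna`, `r`, `p.value`, `n`,
#'   `signif`.
#' @export
target_mirna_correlations <- function(rq, targets = MRNA_PANEL,
                                      mirnas = MIRNA_PANEL,
                                      mice = c("all", "stressed")) {
  mice <- match.arg(mice)
  rows <- list()
  for (area in sort(unique(rq$area))) {
    wide <- rq_wide(rq, area)
    if (mice == "stressed") {
      wide <- wide[attr(wide, "phenotype") != "control", , drop = FALSE]
    }
    for (tg in intersect(targets, colnames(wide))) {
      for (mi in intersect(mirnas, colnames(wide))) {
        ct <- pearson_cor(wide[, mi], wide[, tg])
        rows[[length(rows) + 1L]] <- data.frame(
          area = area, target = tg, mirna = mi, r = ct$r,
          p.value = ct$p.value, n = ct$n, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$signif <- star_code(out$p.value)
  rownames(out) <- NULL
  out
}

#' miRNA:miRNA correlation matrices per brain area
#'
#' @inheritParams target_mirna_correlations
#' @return Named list (one `cor_matrix` per area).
#' @export
mirna_correlations <- function(rq, mirnas = MIRNA_PANEL,
                               mice = c("all", "stressed")) {
  mice <- match.arg(mice)
  out <- list()
  for (area in sort(unique(rq$area))) {
    wide <- rq_wide(rq, area)
    if (mice == "stressed") {
      wide <- wide[attr(wide, "phenotype") != "control", , drop = FALSE]
    }
    out[[area]] <- correlation_matrix(wide, intersect(mirnas,
                                                      colnames(wide)))
  }
  out
}

#' Correlations between expression and behavioral scores
#'
#' Pearson correlation of each analyte's RQ against each composite
#' behavioral score, per brain area, in stressed (susceptible + resilient)
#' mice by default.
#'
#' @param rq An `rq_table`.
#' @param scores An `ais_scores` data.frame from [composite_scores()].
#' @param mice `"stressed"` (default) or `"all"`.
#' @return Data.frame with `area`, `analyte`, `score`, `r`, `p.value`, `n`,
#'   `signif`.
#' @export
score_correlations <- function(rq, scores, mice = c("stressed", "all")) {
  mice <- match.arg(mice)
  score_cols <- c("arousal", "avoidance", "social_memory", "ptsd_like")
  rows <- list()
  for (area in sort(unique(rq$area))) {
    wide <- rq_wide(rq, area)
    keep <- rownames(wide)
    if (mice == "stressed") {
      keep <- keep[attr(wide, "phenotype")[keep] != "control"]
    }
    sc <- scores[match(keep, scores$mouse_id), ]
    for (an in colnames(wide)) {
      for (s in score_cols) {
        ct <- pearson_cor(wide[keep, an], sc[[s]])
        rows[[length(rows) + 1L]] <- data.frame(
          area = area, analyte = an, score = s, r = ct$r,
          p.value = ct$p.value, n = ct$n, stringsAsFactors = FALSE
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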