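#' Z-normalize values against a reference population
#'
#' @param values Numeric vector to standardize.
#' @param reference Numeric vector defining the norm (at least two values
#'   with nonzero sample SD; the SD uses the n-1 denominator).
#' @return `(values - mean(reference)) / sd(reference)`, elementwise.
#' @examples
#' zscore(4, c(1, 2, 3)) # 2
#' @export
zscore <- function(values, reference) {
  if (length(reference) < 2L) {
    stop_ais("reference population needs at least 2 values")
  }
  if (anyNA(reference) || anyNA(values)) {
    stop_ais("zscore inputs must not contain missing values")
  }
  s <- sd(reference)
  if (!is.finite(s) || s == 0) {
    stop_ais("reference population has zero standard deviation")
  }
  (values - mean(reference)) / s
}

#' Configuration of the arousal-score segregation
#'
#' @param threshold Arousal-score cutoff (z units) at and above which a
#'   stressed mouse is labelled susceptible. The cutoff is inclusive:
#'   a score of exactly `threshold` is susceptible.
#' @param reference Population whose mean/SD define the z-transform:
#'   `"controls"` (default: the unstressed norm), `"stressed"`, or `"all"`.
#' @param session_aggregation How the two post-stress ASR sessions combine
#'   into one arousal score: `"mean_of_z"` (default) averages the two
#'   per-session z-scores; `"z_of_mean"` z-normalizes the per-mouse mean of
#'   the two sessions against the reference distribution of session means.
#' @param orientation Named sign map (+1/-1) per behavioral measure so that
#'   larger oriented z = more PTSD-like. Defaults: `asr = +1` (startle
#'   sensitization), `of = -1` (less center time), `epm = -1` (less open-arm
#'   time), `sm = -1` (worse social discrimination).
#' @return Object of class `segregation_config`.
#' @export
segregation_config <- function(threshold = 1,
                               reference = c("controls", "stressed", "all"),
                               session_aggregation = c("mean_of_z",
                                                       "z_of_mean"),
                               orientation = c(asr = 1, of = -1,
                                               epm = -1, sm = -1)) {
  if (!is.finite(threshold)) stop_ais("threshold must be finite")
  needed <- c("asr", "of", "epm", "sm")
  if (!all(needed %in% names(orientation))) {
    stop_ais("orientation must cover: ", paste(needed, collapse = ", "))
  }
  if (!all(orientation[needed] %in% c(-1, 1))) {
    stop_ais("orientation entries must be +1 or -1")
  }
  structure(list(
    threshold = threshold,
    reference = match.arg(reference),
    session_aggregation = match.arg(session_aggregation),
    orientation = orientation[needed]
  ), class = "segregation_config")
}

reference_rows <- function(behavior, config) {
  rows <- switch(config$reference,
    controls = behavior$group == "control",
    stressed = behavior$group == "stressed",
    all = rep(TRUE, nrow(behavior))
  )
  if (sum(rows) < 2L) {
    stop_ais("reference population '", config$reference,
             "' has fewer than 2 mice")
  }
  rows
}

#' Per-mouse arousal score from post-stress ASR changes
#'
#' Each post-stress ASR session (percent of the pre-trauma baseline) is
#' z-normalized against the reference population's same-session values; the
#' arousal score aggregates the two sessions according to the configuration.
#'
#' @param behavior Behavior data.frame with columns `mouse_id`, `group`,
#'   `asr1_pct`, `asr2_pct` (as produced by [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [segregation_config()].
#' @return Named numeric vector of arousal scores (z units), one per mouse.
#' @export
arousal_score <- function(behavior, config = segregation_config()) {
  missing_val <- is.na(behavior$asr1_pct) | is.na(behavior$asr2_pct)
  if (any(missing_val)) {
    stop_ais("missing ASR session value for mouse ",
             behavior$mouse_id[which(missing_val)[1]])
  }
  ref <- reference_rows(behavior, config)
  orient <- config$orientation[["asr"]]
  score <- switch(config$session_aggregation,
    mean_of_z = {
      z1 <- zscore(behavior$asr1_pct, behavior$asr1_pct[ref])
      z2 <- zscore(behavior$asr2_pct, behavior$asr2_pct[ref])
      (z1 + z2) / 2
    },
    z_of_mean = {
      m <- (behavior$asr1_pct + behavior$asr2_pct) / 2
      zscore(m, m[ref])
    }
  )
  setNames(orient * score, behavior$mouse_id)
}

#' Segregate stressed mice into susceptible and resilient
#'
#' Stressed mice with arousal score greater than or equal to the threshold
#' are susceptible; the rest are resilient. Control mice keep the label
#' `control`.
#'
#' @param scores Named numeric vector of arousal scores (one per mouse).
#' @param group Character vector (`control`/`stressed`) aligned with
#'   `scores`.
#' @param threshold Inclusive susceptibility cutoff in z units (default 1).
#' @return Object of class `ais_segregation`: list with `phenotype` (named
#'   character vector) and `counts` (named integer vector).
#' @export
segregate <- function(scores, group, threshold = 1) {
  if (length(scores) != length(group)) {
    stop_ais("scores and group must have the same length")
  }
  if (any(!is.finite(scores))) stop_ais("arousal scores must be finite")
  phenotype <- ifelse(group == "control", "control",
                      ifelse(scores >= threshold, "susceptible", "resilient"))
  names(phenotype) <- names(scores)
  counts <- c(
    control = sum(phenotype == "control"),
    susceptible = sum(phenotype == "susceptible"),
    resilient = sum(phenotype == "resilient")
  )
  structure(list(phenotype = phenotype, counts = counts,
                 threshold = threshold),
            class = "ais_segregation")
}

#' @export
print.ais_segregation <- function(x, ...) {
  cat(sprintf(
    "AIS segregation (threshold %.3g): %d control, %d susceptible, %d resilient\n",
    x$threshold, x$counts["control"], x$counts["susceptible"],
    x$counts["resilient"]))
  invisible(x)
}

#' Behavioral composite scores and phenotype labels
#'
#' Computes the four composite behavioral scores used in the correlation and
#' regression analyses, all in z units against the reference population:
#' \describe{
#'   \item{arousal}{aggregated z of the two post-stress ASR sessions
#'     ([arousal_score()]).}
#'   \item{avoidance}{mean of the sign-oriented z-scores of the open-field
#'     and elevated-plus-maze measures.}
#'   \item{social_memory}{sign-oriented z of the social-memory measure.}
#'   \item{ptsd_like}{mean of the arousal, avoidance and social-memory
#'     scores.}
#' }
#' Orientation signs make larger scores more PTSD-like. Stressed mice are
#' segregated on the arousal score at the configured threshold.
#'
#' @param behavior Behavior data.frame (see [arousal_score()]) additionally
#'   carrying `of_measure`, `epm_measure`, `sm_measure`.
#' @param config A [segregation_config()].
#' @return Data.frame of class `ais_scores` with columns `mouse_id`,
#'   `group`, `arousal`, `avoidance`, `social_memory`, `ptsd_like`,
#'   `phenotype`.
#' @export
composite_scores <- function(behavior, config = segregation_config()) {
  for (col in c("of_measure", "epm_measure", "sm_measure")) {
    if (!col %in% names(behavior)) stop_ais("missing measure column: ", col)
    if (anyNA(behavior[[col]])) {
      stop_ais("missing ", col, " for mouse ",
               behavior$mouse_id[which(is.na(behavior[[col]]))[1]])
    }
  }
  ref <- reference_rows(behavior, config)
  zcol <- function(col, key) {
    v <- behavior[[col]]
    if (sd(v[ref]) == 0) stop_ais("zero variance in reference for ", col)
    config$orientation[[key]] * zscore(v, v[ref])
  }
  arousal <- arousal_score(behavior, config)
  avoidance <- (zcol("of_measure", "of") + zcol("epm_measure", "epm")) / 2
  social <- zcol("sm_measure", "sm")
  ptsd <- (arousal + avoidance + social) / 3
  seg <- segregate(arousal, behavior$group, config$threshold)

  out <- data.frame(
    mouse_id = behavior$mouse_id,
    group = behavior$group,
    arousal = as.numeric(arousal),
    avoidance = avoidance,
    social_memory = social,
    ptsd_like = ptsd,
    phenotype = unname(seg$phenotype),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ais_scores", "data.frame")
  attr(out, "config") <- config
  out
}

#' @export
print.ais_scores <- function(x, ...) {
  counts <- table(x$phenotype)
  cat(sprintf("Behavioral scores for %d mice (%s)\n", nrow(x),
              paste(sprintf("%d %s", counts, names(counts)),
                    collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 3)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
summary.ais_scores <- function(object, ...) {
  stressed <- object[object$group == "stressed", ]
  cat("Stressed mice:", nrow(stressed), "\n")
  cat(sprintf("Susceptible fraction: %.3f\n",
              mean(stressed$phenotype == "susceptible")))
  cat("Score ranges (z units):\n")
  print(vapply(object[c("arousal", "avoidance", "social_memory",
                        "ptsd_like")], range, numeric(2)), digits = 3)
  invisible(object)
}
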