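#' Generate a synthetic stress cohort
#'
#' Simulates one cohort under a [cohort_config()]: a behavioral table (one row
#' per mouse) and a long-format Ct table (technical triplicates per mouse,
#' brain area and analyte, including the U6 and GAPDH reference analytes).
#'
#' Stressed mice carry a standard-normal latent susceptibility trait that
#' (a) raises their post-stress ASR sessions by `susceptibility_asr_gain`
#' percent of baseline per SD, and (b) moves their expression profile from
#' the resilient toward the susceptible delta-Ct shifts through a logistic
#' mixing weight `plogis(susceptibility_link * trait)`. The trait itself is
#' returned in the behavior table (column `latent_susceptibility`) for
#' simulation diagnostics only; no analysis stage reads it, and phenotype
#' labels are only ever assigned downstream by the arousal-score rule.
#'
#' All Ct and behavioral values are rounded to 6 significant digits so that
#' a write/read round trip through TSV is the identity.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; the same config and seed give bit-identical
#'   tables.
#' @param include_expression If `FALSE`, skip Ct simulation and return only
#'   the behavior table (used for behavioral calibration studies).
#'
#' @return Object of class `ais_cohort`: list with elements `behavior`
#'   (data.frame: mouse_id, group, asr_baseline, asr1_pct, asr2_pct,
#'   of_measure, epm_measure, sm_measure, latent_susceptibility) and `ct`
#'   (data.frame: mouse_id, area, analyte, replicate, ct).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            include_expression = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  validate_expression_models(config)
  set.seed(as.integer(seed))

  nc <- config$n_control
  ns <- config$n_stressed
  n <- nc + ns
  ids <- sprintf("M%02d", seq_len(n))
  group <- rep(c("control", "stressed"), c(nc, ns))

  latent <- rnorm(ns)
  a <- config$asr
  baseline <- pmax(rnorm(n, a$baseline_mean, a$baseline_sd),
                   a$baseline_mean / 10)
  pct <- matrix(NA_real_, n, 2)
  for (s in 1:2) {
    pct[seq_len(nc), s] <- rnorm(nc, a$control_pct_mean[s], a$control_pct_sd[s])
    pct[nc + seq_len(ns), s] <-
      a$control_pct_mean[s] + a$stressed_pct_shift[s] +
      a$susceptibility_asr_gain * latent +
      rnorm(ns, 0, a$stressed_session_sd[s])
  }
  pct <- pmax(pct, 0)

  beh_val <- function(p) {
    v <- numeric(n)
    v[seq_len(nc)] <- rnorm(nc, p$control_mean, p$control_sd)
    v[nc + seq_len(ns)] <- p$control_mean + p$stressed_shift +
      p$susceptibility_gain * latent + rnorm(ns, 0, p$control_sd)
    v
  }
  of <- beh_val(config$behavior$of)
  epm <- beh_val(config$behavior$epm)
  sm <- beh_val(config$behavior$sm)

  behavior <- data.frame(
    mouse_id = ids,
    group = group,
    asr_baseline = signif(baseline, 6),
    asr1_pct = signif(pct[, 1], 6),
    asr2_pct = signif(pct[, 2], 6),
    of_measure = signif(of, 6),
    epm_measure = signif(epm, 6),
    sm_measure = signif(sm, 6),
    latent_susceptibility = signif(c(rep(NA_real_, nc), latent), 6),
    stringsAsFactors = FALSE
  )

  ct <- NULL
  if (include_expression) {
    # Susceptible-profile mixing weight per stressed mouse.
    w <- plogis(config$susceptibility_link * latent)
    ct_parts <- vector("list", length(config$expression))
    names(ct_parts) <- names(config$expression)
    for (area in names(config$expression)) {
      idx <- config$area_allocation[[area]]
      m <- config$expression[[area]]
      na <- length(m$analytes)
      sigma <- diag(m$sd, na) %*% m$corr %*% diag(m$sd, na)
      resid <- MASS::mvrnorm(length(idx), mu = rep(0, na), Sigma = sigma)
      if (is.null(dim(resid))) resid <- matrix(resid, nrow = 1)
      colnames(resid) <- m$analytes

      # Reference-gene Ct varies per mouse (RNA input), cancelling in dCt.
      ref_ct <- cbind(
        GAPDH = 17 + rnorm(length(idx), 0, config$reference_ct_sd),
        U6 = 18 + rnorm(length(idx), 0, config$reference_ct_sd)
      )
      refmap <- default_reference_map()[m$analytes]

      shift <- matrix(0, length(idx), na, dimnames = list(NULL, m$analytes))
      stressed_rows <- which(group[idx] == "stressed")
      if (length(stressed_rows)) {
        wi <- w[idx[stressed_rows] - nc]
        shift[stressed_rows, ] <-
          outer(1 - wi, m$shift_resilient) + outer(wi, m$shift_susceptible)
      }

      true_ct <- cbind(
        ref_ct,
        ref_ct[, refmap, drop = FALSE] +
          matrix(m$base_dct, length(idx), na, byrow = TRUE) + shift + resid
      )
      colnames(true_ct) <- c(colnames(ref_ct), m$analytes)

      all_an <- colnames(true_ct)
      grid <- expand.grid(
        replicate = 1:3, analyte = all_an, mouse = seq_along(idx),
        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
      )
      noise <- rnorm(nrow(grid), 0, config$replicate_sd)
      vals <- true_ct[cbind(grid$mouse, match(grid$analyte, all_an))] + noise
      vals <- pmin(pmax(vals, 1), 44.9)
      ct_parts[[area]] <- data.frame(
        mouse_id = ids[idx][grid$mouse],
        area = area,
        analyte = grid$analyte,
        replicate = grid$replicate,
        ct = signif(vals, 6),
        stringsAsFactors = FALSE
      )
    }
    ct <- do.call(rbind, ct_parts)
    rownames(ct) <- NULL
    ct <- ct[order(ct$area, ct$mouse_id, ct$analyte, ct$replicate), ]
    rownames(ct) <- NULL
  }

  structure(list(behavior = behavior, ct = ct, seed = as.integer(seed)),
            class = "ais_cohort")
}

#' @export
print.ais_cohort <- function(x, ...) {
  tab <- table(x$behavior$group)
  cat(sprintf("Synthetic cohort: %d mice (%s)\n", nrow(x$behavior),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", ")))
  if (!is.null(x$ct)) {
    cat(sprintf("Ct table: %d rows, areas %s\n", nrow(x$ct),
                paste(sort(unique(x$ct$area)), collapse = ", ")))
  }
  invisible(x)
}
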