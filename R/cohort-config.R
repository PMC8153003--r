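#' Configuration for the synthetic stress-cohort generator
#'
#' Builds the parameter set that [generate_cohort()] turns into behavioral and
#' Ct tables. Defaults emulate a 46-mouse restraint-stress study: 18 controls
#' and 28 stressed mice, of which 30 (12 control + 18 stressed) provide
#' hippocampus and medial prefrontal cortex tissue and the remaining 16
#' (6 + 10) provide hypothalamus. Post-stress acoustic startle reactivity
#' (ASR, percent of the pre-trauma baseline) is shifted upward in stressed
#' mice and coupled to a latent susceptibility trait so that, after
#' z-normalization against controls and thresholding at 1, roughly 25-35% of
#' stressed mice segregate as susceptible.
#'
#' Expression is generated on the delta-Ct scale (cycles relative to the
#' reference gene), the additive scale on which qPCR noise is naturally
#' Gaussian and on which `RQ = 2^-ddCt` is log-linear. Each brain area has a
#' per-analyte mean delta-Ct shift for the susceptible and resilient
#' expression profiles (negative shift = upregulation) and a correlation
#' matrix over analyte residuals, so both group effects and co-expression
#' structure can be planted and later recovered.
#'
#' @param n_control,n_stressed Group sizes. Must be at least 2 and 4.
#' @param asr List of ASR-model parameters: `baseline_mean`, `baseline_sd`
#'   (startle amplitude, arbitrary units), `control_pct_mean`,
#'   `control_pct_sd` (length-2, per post-stress session, percent of
#'   baseline), `stressed_pct_shift` (added to the control mean for stressed
#'   mice), `stressed_session_sd` (session noise for stressed mice), and
#'   `susceptibility_asr_gain` (percent-of-baseline increase per SD of the
#'   latent susceptibility trait).
#' @param behavior List with one sublist per behavioral readout (`of` open
#'   field center time, `epm` elevated-plus-maze open-arm time, `sm` social
#'   memory discrimination), each containing `control_mean`, `control_sd`,
#'   `stressed_shift`, `susceptibility_gain`.
#' @param expression Named list (one element per brain area) of expression
#'   models as returned by [expression_model()].
#' @param replicate_sd Within-triplicate technical Ct standard deviation
#'   (cycles).
#' @param susceptibility_link Slope of the logistic map from the latent
#'   susceptibility trait to the mixing weight between the resilient and
#'   susceptible expression profiles.
#' @param reference_ct_sd Mouse-level SD (cycles) of reference-gene Ct,
#'   modelling RNA input variation; cancels in delta-Ct.
#' @param area_allocation Named list mapping each brain area to the integer
#'   indices of the mice dissected for it. The default reproduces the
#'   12/18 (HIP, mPFC) and 6/10 (HT) control/stressed split.
#' @param null_effects If `TRUE`, every group shift, susceptibility gain and
#'   expression shift is set to zero and stressed session noise matched to
#'   the control SD, so stressed and control mice are exchangeable. Used for
#'   calibration checks of downstream tests.
#'
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [expression_model()]
#' @export
cohort_config <- function(n_control = 18L,
                          n_stressed = 28L,
                          asr = list(),
                          behavior = list(),
                          expression = NULL,
                          replicate_sd = 0.15,
                          susceptibility_link = 1.5,
                          reference_ct_sd = 0.4,
                          area_allocation = NULL,
                          null_effects = FALSE) {
  asr_def <- list(
    baseline_mean = 250, baseline_sd = 40,
    control_pct_mean = c(100, 100), control_pct_sd = c(15, 15),
    stressed_pct_shift = c(8, 8), stressed_session_sd = c(9, 9),
    susceptibility_asr_gain = 12
  )
  beh_def <- list(
    of  = list(control_mean = 120, control_sd = 30,
               stressed_shift = -25, susceptibility_gain = -15),
    epm = list(control_mean = 35, control_sd = 10,
               stressed_shift = -8, susceptibility_gain = -5),
    sm  = list(control_mean = 60, control_sd = 15,
               stressed_shift = -12, susceptibility_gain = -8)
  )
  asr <- utils::modifyList(asr_def, asr)
  behavior <- utils::modifyList(beh_def, behavior)
  expression_defaulted <- is.null(expression)
  if (expression_defaulted) expression <- default_expression_models()

  n_control <- as.integer(n_control)
  n_stressed <- as.integer(n_stressed)
  if (n_control < 2L) stop_ais("n_control must be at least 2")
  if (n_stressed < 4L) stop_ais("n_stressed must be at least 4")
  if (replicate_sd < 0) stop_ais("replicate_sd must be non-negative")

  if (is.null(area_allocation)) {
    area_allocation <- default_area_allocation(n_control, n_stressed)
  } else if (expression_defaulted) {
    # a custom allocation with defaulted expression models restricts the
    # simulated areas to the allocated ones
    keep <- intersect(names(expression), names(area_allocation))
    if (!length(keep)) {
      stop_ais("area_allocation names none of the modelled areas")
    }
    expression <- expression[keep]
  }
  n <- n_control + n_stressed
  for (area in names(area_allocation)) {
    idx <- area_allocation[[area]]
    if (any(idx < 1L | idx > n)) {
      stop_ais("area_allocation for ", area, " indexes mice outside the cohort")
    }
  }
  if (!all(names(expression) %in% names(area_allocation))) {
    missing <- setdiff(names(expression), names(area_allocation))
    stop_ais("no area_allocation for expression area(s): ",
             paste(missing, collapse = ", "))
  }

  if (null_effects) {
    asr$stressed_pct_shift <- c(0, 0)
    asr$susceptibility_asr_gain <- 0
    asr$stressed_session_sd <- asr$control_pct_sd
    for (b in names(behavior)) {
      behavior[[b]]$stressed_shift <- 0
      behavior[[b]]$susceptibility_gain <- 0
    }
    for (a in names(expression)) {
      expression[[a]]$shift_susceptible[] <- 0
      expression[[a]]$shift_resilient[] <- 0
    }
  }

  cfg <- list(
    n_control = n_control, n_stressed = n_stressed,
    asr = asr, behavior = behavior, expression = expression,
    replicate_sd = replicate_sd,
    susceptibility_link = susceptibility_link,
    reference_ct_sd = reference_ct_sd,
    area_allocation = area_allocation
  )
  class(cfg) <- "cohort_config"
  validate_expression_models(cfg)
  cfg
}

# Controls first (1..n_control), stressed after. HIP and mPFC share the first
# 12 controls and first 18 stressed mice; HT takes the remainder.
default_area_allocation <- function(n_control, n_stressed) {
  ctrl <- seq_len(n_control)
  strs <- n_control + seq_len(n_stressed)
  hip_ctrl <- ctrl[seq_len(min(12L, n_control))]
  hip_strs <- strs[seq_len(min(18L, n_stressed))]
  ht_ctrl <- setdiff(ctrl, hip_ctrl)
  ht_strs <- setdiff(strs, hip_strs)
  if (length(ht_ctrl) == 0L) ht_ctrl <- hip_ctrl
  if (length(ht_strs) == 0L) ht_strs <- hip_strs
  list(
    HIP = c(hip_ctrl, hip_strs),
    mPFC = c(hip_ctrl, hip_strs),
    HT = c(ht_ctrl, ht_strs)
  )
}

#' Per-area expression model for the synthetic generator
#'
#' @param analytes Character vector of target analytes (reference genes are
#'   modelled separately).
#' @param base_dct Named numeric, baseline delta-Ct (cycles above the
#'   reference gene) per analyte in control mice.
#' @param shift_susceptible,shift_resilient Named numeric, mean delta-Ct
#'   shift (cycles; negative = higher expression) of each phenotype profile
#'   relative to controls.
#' @param sd Named numeric, biological SD of delta-Ct per analyte (cycles).
#' @param corr Correlation matrix over analyte delta-Ct residuals; must be
#'   symmetric with unit diagonal and positive semidefinite.
#'
#' @return List of class `expression_model`.
#' @export
expression_model <- function(analytes, base_dct, shift_susceptible,
                             shift_resilient, sd, corr) {
  pick <- function(x) {
    if (is.null(names(x))) {
      if (length(x) == 1L) x <- rep(x, length(analytes))
      if (length(x) != length(analytes)) {
        stop_ais("unnamed parameter vectors must match the analyte count")
      }
      return(setNames(x, analytes))
    }
    x[analytes]
  }
  m <- list(
    analytes = analytes,
    base_dct = pick(base_dct),
    shift_susceptible = pick(shift_susceptible),
    shift_resilient = pick(shift_resilient),
    sd = pick(sd),
    corr = corr
  )
  class(m) <- "expression_model"
  m
}

# Defaults encode the direction of the reported area-specific group effects:
# delta-Ct shifts of +/- ~0.8 cycles (about 1.7-fold on the RQ scale) against
# a biological SD of 0.7 cycles, positive miRNA co-expression (r = 0.45) and
# negative miRNA:FKBP5 coupling (r = -0.35) in HIP and HT.
default_expression_models <- function() {
  an <- c(MIRNA_PANEL, MRNA_PANEL)
  base <- setNames(c(5, 5, 5, 5, 6, 6), an)
  sds <- setNames(rep(0.7, 6), an)

  corr_area <- function(mirna_fkbp5, mirna_bdnf, bdnf_fkbp5) {
    k <- length(an)
    m <- diag(k)
    dimnames(m) <- list(an, an)
    for (i in MIRNA_PANEL) for (j in MIRNA_PANEL) if (i != j) m[i, j] <- 0.45
    m[MIRNA_PANEL, "FKBP5"] <- m["FKBP5", MIRNA_PANEL] <- mirna_fkbp5
    m[MIRNA_PANEL, "BDNF"] <- m["BDNF", MIRNA_PANEL] <- mirna_bdnf
    m["BDNF", "FKBP5"] <- m["FKBP5", "BDNF"] <- bdnf_fkbp5
    m
  }

  sh <- function(...) setNames(c(...), an)
  list(
    # HIP: miR-15a up in resilient; miR-511/miR-497a down in susceptible;
    # let-7d flat; FKBP5 and BDNF down in resilient.
    HIP = expression_model(
      an, base,
      shift_susceptible = sh(0, 0, 0.8, 0.8, 0, 0),
      shift_resilient   = sh(-0.8, 0, 0, 0, 0.9, 0.8),
      sd = sds,
      corr = corr_area(mirna_fkbp5 = -0.35, mirna_bdnf = 0, bdnf_fkbp5 = 0.3)
    ),
    # HT: miR-15a/miR-511 up in resilient (also vs control); miR-497a up in
    # resilient vs susceptible; let-7d up in both stressed groups; FKBP5 down
    # and BDNF up in resilient.
    HT = expression_model(
      an, base,
      shift_susceptible = sh(0, -0.8, 0.3, 0, 0, 0),
      shift_resilient   = sh(-0.9, -0.8, -0.6, -0.9, 0.9, -0.9),
      sd = sds,
      corr = corr_area(mirna_fkbp5 = -0.35, mirna_bdnf = 0.45,
                       bdnf_fkbp5 = -0.35)
    ),
    # mPFC: miR-15a/miR-511/let-7d down in both stressed groups; miR-497a
    # weakly down; FKBP5 and BDNF up in susceptible mice.
    mPFC = expression_model(
      an, base,
      shift_susceptible = sh(0.8, 0.8, 0.3, 0.8, -0.8, -0.8),
      shift_resilient   = sh(0.8, 0.8, 0.3, 0.8, 0, 0),
      sd = sds,
      corr = corr_area(mirna_fkbp5 = 0, mirna_bdnf = 0, bdnf_fkbp5 = 0.3)
    )
  )
}

validate_expression_models <- function(cfg) {
  for (area in names(cfg$expression)) {
    m <- cfg$expression[[area]]
    corr <- m$corr
    if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10))) {
      stop_ais("correlation matrix for area ", area, " is not symmetric")
    }
    if (any(abs(diag(corr) - 1) > 1e-10)) {
      stop_ais("correlation matrix for area ", area,
               " does not have a unit diagonal")
    }
    ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop_ais("correlation matrix for area ", area,
               " is not positive semidefinite (min eigenvalue ",
               format_num(min(ev)), ")")
    }
    if (any(m$sd < 0) || anyNA(m$sd)) {
      stop_ais("expression SDs for area ", area, " must be non-negative")
    }
    if (!identical(rownames(corr), m$analytes) ||
        !identical(colnames(corr), m$analytes)) {
      stop_ais("correlation matrix dimnames for area ", area,
               " must match the analyte list")
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  mice: %d control + %d stressed\n", x$n_control, x$n_stressed))
  cat(sprintf("  ASR: stressed shift %+.1f%%, susceptibility gain %.1f%%/SD\n",
              x$asr$stressed_pct_shift[1], x$asr$susceptibility_asr_gain))
  cat(sprintf("  areas: %s\n", paste(names(x$expression), collapse = ", ")))
  cat(sprintf("  replicate Ct SD: %.3g cycles\n", x$replicate_sd))
  invisible(x)
}
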