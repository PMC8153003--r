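#' Aggregate technical triplicate Ct values
#'
#' Triplicates are averaged on the Ct scale; the replicate SD is reported and
#' flagged when it exceeds `max_sd` (default 0.5 cycles, a conventional
#' qPCR quality cutoff).
#'
#' @param cts Numeric vector of exactly three replicate Ct values.
#' @param max_sd Replicate-SD flag threshold in cycles.
#' @return List with `mean`, `sd` and logical `flagged`.
#' @examples
#' aggregate_replicates(c(19.8, 20.0, 20.2))
#' @export
aggregate_replicates <- function(cts, max_sd = 0.5) {
  if (length(cts) != 3L || anyNA(cts)) {
    stop_ais("exactly 3 non-missing replicate Ct values are required")
  }
  s <- sd(cts)
  list(mean = mean(cts), sd = s, flagged = s > max_sd)
}

#' Relative quantity by the 2^-ddCt method
#'
#' `dCt = Ct(target) - Ct(reference)`, `ddCt = dCt - dCt(calibrator)`,
#' `RQ = 2^-ddCt`.
#'
#' @param ct_target,ct_reference Mean Ct of the target and of the endogenous
#'   reference analyte (cycles).
#' @param calibrator_delta_ct Calibrator dCt (cycles) subtracted to form
#'   ddCt; 0 gives the unscaled `2^-dCt`.
#' @return Relative quantity (positive scalar or vector).
#' @examples
#' relative_quantity(22, 18, 4)  # ddCt = 0 -> RQ = 1
#' relative_quantity(24, 18, 4)  # ddCt = 2 -> RQ = 0.25
#' @export
relative_quantity <- function(ct_target, ct_reference, calibrator_delta_ct) {
  if (anyNA(ct_target) || anyNA(ct_reference) || anyNA(calibrator_delta_ct) ||
      any(!is.finite(c(ct_target, ct_reference, calibrator_delta_ct)))) {
    stop_ais("relative_quantity inputs must be finite")
  }
  ddct <- (ct_target - ct_reference) - calibrator_delta_ct
  2^(-ddct)
}

#' Quantify a cohort's Ct table into relative quantities
#'
#' Converts a long-format Ct table into one relative quantity per (mouse,
#' area, analyte): triplicates are averaged on the Ct scale, each target is
#' normalized to its reference analyte within the same mouse and area
#' (`dCt`), and the calibrator `dCt` for each (area, analyte) is the mean
#' `dCt` of the calibrator group (default: controls), so that the geometric
#' mean RQ of the calibrator group is exactly 1.
#'
#' @param ct Long-format Ct data.frame (`mouse_id`, `area`, `analyte`,
#'   `replicate`, `ct`).
#' @param phenotypes Either an `ais_scores` data.frame (from
#'   [composite_scores()]) or a data.frame with `mouse_id` and `phenotype`.
#' @param reference_map Named map target analyte -> reference analyte
#'   (default [default_reference_map()]).
#' @param calibrator_group Phenotype whose mean dCt calibrates each (area,
#'   analyte); default `"control"`.
#' @param max_replicate_sd QC flag threshold passed to
#'   [aggregate_replicates()].
#' @return Data.frame of class `rq_table` with columns `mouse_id`, `area`,
#'   `analyte`, `delta_ct`, `rq`, `phenotype`, plus a `qc` attribute listing
#'   flagged triplicates (mouse, area, analyte, replicate SD).
#' @export
quantify_cohort <- function(ct, phenotypes,
                            reference_map = default_reference_map(),
                            calibrator_group = "control",
                            max_replicate_sd = 0.5) {
  if (inherits(ct, "ais_cohort")) ct <- ct$ct
  validate_ct_table(ct, reference_map)
  if (!is.data.frame(phenotypes) ||
      !all(c("mouse_id", "phenotype") %in% names(phenotypes))) {
    stop_ais("phenotypes must be a data.frame with mouse_id and phenotype")
  }
  phen <- setNames(phenotypes$phenotype, phenotypes$mouse_id)

  key <- interaction(ct$mouse_id, ct$area, ct$analyte, drop = TRUE)
  agg_mean <- tapply(ct$ct, key, mean)
  agg_sd <- tapply(ct$ct, key, sd)
  parts <- strsplit(names(agg_mean), ".", fixed = TRUE)
  mc <- data.frame(
    mouse_id = vapply(parts, `[`, "", 1L),
    area = vapply(parts, `[`, "", 2L),
    analyte = vapply(parts, `[`, "", 3L),
    mean_ct = as.numeric(agg_mean),
    rep_sd = as.numeric(agg_sd),
    stringsAsFactors = FALSE
  )
  qc <- mc[mc$rep_sd > max_replicate_sd,
           c("mouse_id", "area", "analyte", "rep_sd")]

  targets <- mc[mc$analyte %in% names(reference_map), ]
  refs <- mc[mc$analyte %in% reference_map, ]
  ref_lookup <- setNames(refs$mean_ct,
                         paste(refs$mouse_id, refs$area, refs$analyte))
  ref_key <- paste(targets$mouse_id, targets$area,
                   reference_map[targets$analyte])
  ref_ct <- ref_lookup[ref_key]
  if (anyNA(ref_ct)) {
    bad <- targets[is.na(ref_ct), c("mouse_id", "area")]
    stop_ais("missing reference Ct for: ",
             paste(unique(paste(bad$mouse_id, bad$area, sep = "/")),
                   collapse = ", "))
  }
  targets$delta_ct <- targets$mean_ct - ref_ct
  targets$phenotype <- unname(phen[targets$mouse_id])
  if (anyNA(targets$phenotype)) {
    stop_ais("no phenotype for mouse ",
             targets$mouse_id[which(is.na(targets$phenotype))[1]])
  }

  cal_rows <- targets$phenotype == calibrator_group
  if (!any(cal_rows)) {
    stop_ais("no mice with calibrator phenotype '", calibrator_group, "'")
  }
  cal_key <- paste(targets$area, targets$analyte)
  cal_dct <- tapply(targets$delta_ct[cal_rows], cal_key[cal_rows], mean)
  if (anyNA(cal_dct[unique(cal_key)])) {
    missing <- unique(cal_key)[is.na(cal_dct[unique(cal_key)])]
    stop_ais("calibrator group has no data for: ",
             paste(missing, collapse = ", "))
  }
  targets$rq <- as.numeric(2^(-(targets$delta_ct - cal_dct[cal_key])))

  out <- targets[order(targets$area, targets$mouse_id, targets$analyte),
                 c("mouse_id", "area", "analyte", "delta_ct", "rq",
                   "phenotype")]
  rownames(out) <- NULL
  class(out) <- c("rq_table", "data.frame")
  attr(out, "qc") <- qc
  attr(out, "calibrator_group") <- calibrator_group
  out
}

#' @export
print.rq_table <- function(x, ...) {
  cat(sprintf("Relative quantities: %d rows (%d mice, areas %s)\n",
              nrow(x), length(unique(x$mouse_id)),
              paste(sort(unique(x$area)), collapse = ", ")))
  qc <- attr(x, "qc")
  if (!is.null(qc) && nrow(qc)) {
    cat(sprintf("QC: %d triplicate(s) flagged for high replicate SD\n",
                nrow(qc)))
  }
  print.data.frame(utils::head(as.data.frame(x), 6), digits = 4)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Wide expression matrix for one brain area
#'
#' @param rq An `rq_table` from [quantify_cohort()].
#' @param area Brain area to extract.
#' @param value `"rq"` (default) or `"log2_rq"`.
#' @return Numeric matrix, mice in rows (named), analytes in columns, with a
#'   `phenotype` attribute aligned with the rows.
#' @export
rq_wide <- function(rq, area, value = c("rq", "log2_rq")) {
  value <- match.arg(value)
  sub <- rq[rq$area == area, ]
  if (!nrow(sub)) stop_ais("no RQ rows for area ", area)
  mice <- sort(unique(sub$mouse_id))
  analytes <- sort(unique(sub$analyte))
  m <- matrix(NA_real_, length(mice), length(analytes),
              dimnames = list(mice, analytes))
  m[cbind(match(sub$mouse_id, mice), match(sub$analyte, analytes))] <-
    if (value == "rq") sub$rq else log2(sub$rq)
  phen <- sub$phenotype[match(mice, sub$mouse_id)]
  attr(m, "phenotype") <- setNames(phen, mice)
  m
}
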