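#' Write a cohort to TSV files
#'
#' Writes `behavior.tsv` (one row per mouse) and `ct.tsv` (long format:
#' mouse_id, area, analyte, replicate, ct) into `directory`, with all numeric
#' columns formatted to 6 significant digits.
#'
#' @param cohort An `ais_cohort` as returned by [generate_cohort()] or
#'   [read_cohort()].
#' @param directory Output directory, created if absent.
#' @return Invisibly, the named character vector of file paths.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "ais_cohort"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(
    behavior = file.path(directory, "behavior.tsv"),
    ct = file.path(directory, "ct.tsv")
  )
  write_tsv(cohort$behavior, paths[["behavior"]])
  if (is.null(cohort$ct)) stop_ais("cohort has no Ct table to write")
  write_tsv(cohort$ct, paths[["ct"]])
  invisible(paths)
}

#' Read a cohort from TSV files
#'
#' Reads and validates `behavior.tsv` and `ct.tsv` written by
#' [write_cohort()] (or prepared externally in the same layout). Validation
#' is strict: malformed or missing numeric values raise a parse error naming
#' the file and line; every (mouse, area, analyte) must carry exactly three
#' technical replicates with Ct in (0, 45); and every area must contain the
#' reference analytes its targets are normalized to.
#'
#' @param directory Directory containing `behavior.tsv` and `ct.tsv`.
#' @param reference_map Analyte-to-reference map used to check reference
#'   availability; defaults to [default_reference_map()].
#' @return An `ais_cohort` list with `behavior` and `ct` data frames.
#' @export
read_cohort <- function(directory, reference_map = default_reference_map()) {
  bpath <- file.path(directory, "behavior.tsv")
  cpath <- file.path(directory, "ct.tsv")
  for (p in c(bpath, cpath)) {
    if (!file.exists(p)) stop_ais("missing cohort file: ", p)
  }

  behavior <- read.delim(bpath, colClasses = "character",
                         stringsAsFactors = FALSE)
  need_b <- c("mouse_id", "group", "asr_baseline", "asr1_pct", "asr2_pct",
              "of_measure", "epm_measure", "sm_measure")
  miss <- setdiff(need_b, names(behavior))
  if (length(miss)) {
    stop_ais("behavior.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }
  numcols <- setdiff(names(behavior), c("mouse_id", "group"))
  for (col in numcols) {
    behavior[[col]] <- parse_numeric(behavior[[col]], col, bpath,
                                     allow_na = col == "latent_susceptibility")
  }
  bad_group <- !behavior$group %in% c("control", "stressed")
  if (any(bad_group)) {
    stop_ais(bpath, ": invalid group at line ",
             which(bad_group)[1] + 1L, " (must be control/stressed)")
  }
  if (any(behavior$asr_baseline <= 0)) {
    stop_ais(bpath, ": asr_baseline must be positive (line ",
             which(behavior$asr_baseline <= 0)[1] + 1L, ")")
  }
  if (anyDuplicated(behavior$mouse_id)) {
    stop_ais(bpath, ": duplicated mouse_id ",
             behavior$mouse_id[anyDuplicated(behavior$mouse_id)])
  }

  ct <- read.delim(cpath, colClasses = "character", stringsAsFactors = FALSE)
  need_c <- c("mouse_id", "area", "analyte", "replicate", "ct")
  miss <- setdiff(need_c, names(ct))
  if (length(miss)) {
    stop_ais("ct.tsv lacks column(s): ", paste(miss, collapse = ", "))
  }
  ct$replicate <- as.integer(parse_numeric(ct$replicate, "replicate", cpath))
  ct$ct <- parse_numeric(ct$ct, "ct", cpath)
  out_of_range <- ct$ct <= 0 | ct$ct >= 45
  if (any(out_of_range)) {
    stop_ais(cpath, ": Ct out of (0, 45) at line ",
             which(out_of_range)[1] + 1L)
  }
  unknown <- !ct$mouse_id %in% behavior$mouse_id
  if (any(unknown)) {
    stop_ais(cpath, ": unknown mouse_id '", ct$mouse_id[which(unknown)[1]],
             "' at line ", which(unknown)[1] + 1L)
  }
  validate_ct_table(ct, reference_map)

  structure(list(behavior = behavior, ct = ct, seed = NA_integer_),
            class = "ais_cohort")
}

parse_numeric <- function(x, col, path, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) & !(allow_na & (is.na(x) | x %in% c("NA", "")))
  if (any(bad)) {
    stop_ais(path, ": cannot parse numeric value '", x[which(bad)[1]],
             "' in column ", col, " at line ", which(bad)[1] + 1L)
  }
  v
}

validate_ct_table <- function(ct, reference_map = default_reference_map()) {
  counts <- table(ct$mouse_id, ct$area, ct$analyte)
  bad <- which(counts != 3L & counts != 0L, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_ais("Ct table: (",
             dimnames(counts)[[1]][bad[1, 1]], ", ",
             dimnames(counts)[[2]][bad[1, 2]], ", ",
             dimnames(counts)[[3]][bad[1, 3]],
             ") has ", counts[bad[1, , drop = FALSE]],
             " replicates; exactly 3 required")
  }
  for (area in unique(ct$area)) {
    present <- unique(ct$analyte[ct$area == area])
    needed_refs <- unique(reference_map[intersect(present,
                                                  names(reference_map))])
    missing_ref <- setdiff(needed_refs, present)
    if (length(missing_ref)) {
      stop_ais("Ct table: area ", area, " lacks reference analyte(s) ",
               paste(missing_ref, collapse = ", "))
    }
  }
  invisible(ct)
}
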