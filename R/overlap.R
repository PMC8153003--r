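#' Read regulator sets from a two-column TSV
#'
#' The file maps miRNAs to their candidate regulators (transcription factors
#' with ChIP evidence on the miRNA promoter, or lncRNAs predicted to bind
#' and sequester the miRNA). Identifiers are whitespace-trimmed and matched
#' case-sensitively; duplicates within one miRNA's set are collapsed.
#'
#' @param path TSV with columns `mirna` and `regulator`.
#' @param provenance Free-text label stored on the object (e.g.
#'   `"ChIP-derived TF"` or `"predicted lncRNA"`).
#' @return Named list of class `regulator_sets` (one sorted character
#'   vector per miRNA).
#' @export
read_regulator_sets <- function(path, provenance = NA_character_) {
  df <- read.delim(path, colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("mirna", "regulator") %in% names(df))) {
    stop_ais(path, " must have columns: mirna, regulator")
  }
  regulator_sets(split(df$regulator, df$mirna), provenance)
}

#' Construct a validated regulator-set collection
#'
#' @param sets Named list of character vectors (miRNA -> regulators).
#' @param provenance Optional provenance label.
#' @return Object of class `regulator_sets`.
#' @export
regulator_sets <- function(sets, provenance = NA_character_) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_ais("every regulator set must be named by its miRNA")
  }
  sets <- lapply(sets, function(v) {
    v <- trimws(as.character(v))
    v <- v[nzchar(v)]
    sort(unique(v))
  })
  structure(sets, class = "regulator_sets", provenance = provenance)
}

#' @export
print.regulator_sets <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("Regulator sets (%s)\n",
              if (is.na(prov)) "unlabelled" else prov))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d regulators\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

#' Pairwise regulator overlap matrix
#'
#' Exact set intersection of the regulator sets of every unordered miRNA
#' pair, with deterministic (sorted) element order, plus the set common to
#' all miRNAs.
#'
#' @param sets A `regulator_sets` object (or named list coercible to one);
#'   at least two miRNAs.
#' @param mirnas Optional subset/order of miRNA names; unknown names are an
#'   error.
#' @return Object of class `overlap_matrix`: list with `shared` (named list
#'   of sorted intersections per pair, names `"a|b"`), `counts` (symmetric
#'   integer matrix; diagonal = set sizes), and `common_all`.
#' @export
pairwise_overlap <- function(sets, mirnas = names(sets)) {
  if (!inherits(sets, "regulator_sets")) sets <- regulator_sets(sets)
  unknown <- setdiff(mirnas, names(sets))
  if (length(unknown)) {
    stop_ais("unknown miRNA key(s): ", paste(unknown, collapse = ", "))
  }
  if (length(mirnas) < 2L) stop_ais("need at least 2 miRNA sets")
  k <- length(mirnas)
  counts <- matrix(0L, k, k, dimnames = list(mirnas, mirnas))
  diag(counts) <- vapply(sets[mirnas], length, 0L)
  shared <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(i - 1L)) {
      s <- sort(intersect(sets[[mirnas[i]]], sets[[mirnas[j]]]))
      shared[[paste(mirnas[j], mirnas[i], sep = "|")]] <- s
      counts[i, j] <- counts[j, i] <- length(s)
    }
  }
  structure(list(shared = shared, counts = counts,
                 common_all = common_to_all(sets, mirnas)),
            class = "overlap_matrix")
}

#' Regulators common to all miRNAs
#'
#' @inheritParams pairwise_overlap
#' @return Sorted character vector: the intersection of every miRNA's set.
#' @export
common_to_all <- function(sets, mirnas = names(sets)) {
  if (!inherits(sets, "regulator_sets")) sets <- regulator_sets(sets)
  unknown <- setdiff(mirnas, names(sets))
  if (length(unknown)) {
    stop_ais("unknown miRNA key(s): ", paste(unknown, collapse = ", "))
  }
  if (length(mirnas) < 2L) stop_ais("need at least 2 miRNA sets")
  sort(Reduce(intersect, sets[mirnas]))
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("Pairwise shared-regulator counts (diagonal = set size):\n")
  print(x$counts)
  cat(sprintf("Common to all %d miRNAs (%d): %s\n",
              ncol(x$counts), length(x$common_all),
              if (length(x$common_all)) {
                paste(x$common_all, collapse = ", ")
              } else "(none)"))
  invisible(x)
}

#' Write an overlap matrix as a long-format TSV
#'
#' @param x An `overlap_matrix`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_overlap <- function(x, path) {
  stopifnot(inherits(x, "overlap_matrix"))
  pairs <- names(x$shared)
  df <- data.frame(
    pair = pairs,
    n_shared = vapply(x$shared, length, 0L),
    shared = vapply(x$shared, paste, "", collapse = ", "),
    stringsAsFactors = FALSE
  )
  df <- rbind(df, data.frame(
    pair = "all",
    n_shared = length(x$common_all),
    shared = paste(x$common_all, collapse = ", "),
    stringsAsFactors = FALSE
  ))
  write_tsv(df, path)
}
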