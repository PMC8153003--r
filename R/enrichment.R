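#' Read a gene-set collection in GMT format
#'
#' Standard GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are collapsed.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_ais(path, " contains no gene sets")
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop_ais(path, ": line ", i, " has fewer than 3 tab-separated fields")
    }
    genes <- unique(trimws(parts[-(1:2)]))
    sets[[parts[1]]] <- genes[nzchar(genes)]
  }
  sets
}

#' One-sided Fisher exact over-representation p-value
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of observing at least
#' `k` pathway genes in a target list of the given size drawn from the
#' background universe.
#'
#' @param k Observed overlap between the target list and the pathway.
#' @param list_size Target-list size.
#' @param pathway_size Pathway size within the background.
#' @param background_size Background-universe size.
#' @return One-sided p-value in (0, 1].
#' @export
fisher_overrep <- function(k, list_size, pathway_size, background_size) {
  vals <- c(k, list_size, pathway_size, background_size)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop_ais("all counts must be non-negative integers")
  }
  if (k > list_size || k > pathway_size) {
    stop_ais("overlap k cannot exceed list or pathway size")
  }
  if (list_size > background_size || pathway_size > background_size ||
      list_size + pathway_size - k > background_size) {
    stop_ais("inconsistent contingency counts for the given background")
  }
  phyper(k - 1, pathway_size, background_size - pathway_size, list_size,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted values in the input order, with the step-up monotonicity
#'   enforced.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop_ais("p-values must lie in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Pathway over-representation analysis of a target gene list
#'
#' One Fisher exact test per pathway against the background universe
#' (default: the union of all pathway genes), Benjamini-Hochberg FDR across
#' all pathways tested, results ranked by FDR then raw p. Target genes
#' absent from the background are dropped with a warning.
#'
#' @param targets Character vector of target genes (e.g. the miRNA target
#'   network).
#' @param collection Named list of pathway gene sets (see [read_gmt()]).
#' @param background Optional explicit background universe.
#' @param fdr_threshold Significance flag level on the FDR (default 0.05).
#' @return Data.frame of class `enrichment_result`: `pathway`, `overlap`
#'   (k), `list_size`, `pathway_size`, `background_size`, `p.value`, `fdr`,
#'   `neg_log10_fdr`, `significant`, plus a `genes` attribute with the
#'   per-pathway overlapping genes.
#' @export
enrich <- function(targets, collection, background = NULL,
                   fdr_threshold = 0.05) {
  if (!length(collection)) stop_ais("empty pathway collection")
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    stop_ais("every pathway must be named")
  }
  targets <- unique(as.character(targets))
  if (is.null(background)) {
    background <- sort(unique(unlist(collection, use.names = FALSE)))
  } else {
    background <- unique(as.character(background))
    outside <- lapply(collection, setdiff, y = background)
    if (any(lengths(outside) > 0)) {
      stop_ais("pathway gene(s) outside the background universe, e.g. ",
               outside[[which(lengths(outside) > 0)[1]]][1])
    }
  }
  dropped <- setdiff(targets, background)
  if (length(dropped)) {
    warning(length(dropped), " target gene(s) absent from background ",
            "dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "", call. = FALSE)
    targets <- intersect(targets, background)
  }
  if (!length(targets)) stop_ais("no target genes left after filtering")

  bg_n <- length(background)
  list_n <- length(targets)
  hits <- lapply(collection, intersect, y = targets)
  pvals <- vapply(names(collection), function(pw) {
    fisher_overrep(length(hits[[pw]]), list_n,
                   length(intersect(collection[[pw]], background)), bg_n)
  }, 0)
  fdr <- bh_fdr(pvals)
  out <- data.frame(
    pathway = names(collection),
    overlap = vapply(hits, length, 0L),
    list_size = list_n,
    pathway_size = vapply(collection, function(s) {
      length(intersect(s, background))
    }, 0L),
    background_size = bg_n,
    p.value = pvals,
    fdr = fdr,
    neg_log10_fdr = -log10(fdr),
    significant = fdr < fdr_threshold,
    stringsAsFactors = FALSE
  )
  ord <- order(out$fdr, out$p.value, out$pathway)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "genes") <- hits[ord]
  attr(out, "fdr_threshold") <- fdr_threshold
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Pathway over-representation: %d pathways, %d significant at FDR < %g\n",
    nrow(x), sum(x$significant), attr(x, "fdr_threshold")))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Horizontal bar chart of enrichment results
#'
#' Plots `-log10(FDR)` per pathway for the top `n` pathways, with the
#' significance threshold marked.
#'
#' @param x An `enrichment_result`.
#' @param n Number of top pathways to draw.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.enrichment_result <- function(x, n = 15, ...) {
  top <- utils::head(x, n)
  top <- top[rev(seq_len(nrow(top))), ]
  graphics::par(mar = c(4, 12, 2, 1))
  graphics::barplot(top$neg_log10_fdr, names.arg = top$pathway, horiz = TRUE,
                    las = 1, xlab = expression(-log[10] ~ FDR),
                    col = ifelse(top$significant, "steelblue", "grey70"),
                    cex.names = 0.7, ...)
  graphics::abline(v = -log10(attr(x, "fdr_threshold")), lty = 2)
  invisible(x)
}
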