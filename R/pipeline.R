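#' Configuration of a full pipeline run
#'
#' Bundles the cohort source (a synthetic [cohort_config()] or a directory
#' of TSVs), the segregation settings and the analysis switches into one
#' reproducible run description.
#'
#' @param cohort Either a [cohort_config()] (synthetic cohort, the default)
#'   or a directory path readable by [read_cohort()].
#' @param segregation A [segregation_config()].
#' @param seed Integer seed recorded in the manifest and driving all
#'   randomness of the run.
#' @param admissibility `"strict"` or `"permissive"` predictor filtering for
#'   the synergy search.
#' @param tf_sets,lncrna_sets Optional paths to regulator-set TSVs (default:
#'   the packaged fixtures).
#' @param gmt,targets Optional paths to a GMT pathway collection and a
#'   plain-text target gene list (default: the packaged fixtures).
#' @param fdr_threshold Enrichment significance level.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       segregation = segregation_config(),
                       seed = 1L,
                       admissibility = c("strict", "permissive"),
                       tf_sets = aismir_example("tf_regulator_sets_synthetic.tsv"),
                       lncrna_sets = aismir_example("lncrna_decoy_sets_synthetic.tsv"),
                       gmt = aismir_example("pathways_synthetic.gmt"),
                       targets = aismir_example("mirna_targets_synthetic.txt"),
                       fdr_threshold = 0.05) {
  admissibility <- match.arg(admissibility)
  if (is.character(cohort)) {
    if (!dir.exists(cohort)) stop_ais("cohort directory not found: ", cohort)
  } else {
    stopifnot(inherits(cohort, "cohort_config"))
  }
  for (p in c(tf_sets, lncrna_sets, gmt, targets)) {
    if (!file.exists(p)) stop_ais("input file not found: ", p)
  }
  structure(list(
    cohort = cohort, segregation = segregation, seed = as.integer(seed),
    admissibility = admissibility, tf_sets = tf_sets,
    lncrna_sets = lncrna_sets, gmt = gmt, targets = targets,
    fdr_threshold = fdr_threshold
  ), class = "run_config")
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata`; with no argument,
#'   lists the available files.
#' @return File path (or vector of file names).
#' @export
aismir_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "aismir")))
  }
  path <- system.file("extdata", file, package = "aismir")
  if (!nzchar(path)) stop_ais("no packaged file named ", file)
  path
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_ais("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full screening and expression-analysis pipeline
#'
#' Executes generate/load -> segregate -> quantify -> group statistics ->
#' correlation tables -> synergy regression search -> regulator overlaps ->
#' pathway enrichment, writing every result table as TSV into `out_dir`
#' together with a manifest (seed, package version, config hash, and the
#' MD5 checksum of every output). Reruns with the same configuration and
#' seed are bit-identical.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a list with every in-memory stage result plus
#'   `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (missing(out_dir)) stop_ais("out_dir is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  cohort <- pipeline_stage("cohort", {
    if (is.character(config$cohort)) {
      read_cohort(config$cohort)
    } else {
      generate_cohort(config$cohort, seed = config$seed)
    }
  })
  write_cohort(cohort, file.path(out_dir, "cohort"))

  scores <- pipeline_stage("segregate",
    composite_scores(cohort$behavior, config$segregation))
  write_tsv(as.data.frame(scores), file.path(out_dir, "scores.tsv"))

  rq <- pipeline_stage("quantify", quantify_cohort(cohort$ct, scores))
  write_tsv(as.data.frame(rq), file.path(out_dir, "rq.tsv"))

  anova_tab <- pipeline_stage("anova", expression_anova(rq))
  write_tsv(as.data.frame(anova_tab), file.path(out_dir, "anova.tsv"))

  corr_targets <- pipeline_stage("correlations",
    target_mirna_correlations(rq))
  write_tsv(corr_targets, file.path(out_dir, "corr_target_mirna.tsv"))

  corr_mirna <- pipeline_stage("correlations", mirna_correlations(rq))
  mirna_long <- do.call(rbind, lapply(names(corr_mirna), function(area) {
    cm <- corr_mirna[[area]]
    idx <- which(lower.tri(cm$r), arr.ind = TRUE)
    data.frame(area = area,
               mirna_a = rownames(cm$r)[idx[, 1]],
               mirna_b = colnames(cm$r)[idx[, 2]],
               r = cm$r[idx], p.value = cm$p[idx], n = cm$n[idx],
               signif = cm$stars[idx], stringsAsFactors = FALSE)
  }))
  write_tsv(mirna_long, file.path(out_dir, "corr_mirna_mirna.tsv"))

  corr_scores <- pipeline_stage("correlations", score_correlations(rq, scores))
  write_tsv(corr_scores, file.path(out_dir, "corr_scores.tsv"))

  synergy <- pipeline_stage("synergy",
    synergy_search(rq, mode = config$admissibility))
  if (!is.null(synergy$best)) {
    write_tsv(synergy$best, file.path(out_dir, "synergy_best.tsv"))
    write_tsv(synergy$ledger, file.path(out_dir, "synergy_ledger.tsv"))
  }

  score_reg <- pipeline_stage("synergy-scores", score_regressions(scores, rq))
  write_tsv(score_reg, file.path(out_dir, "score_regressions.tsv"))

  tf <- pipeline_stage("overlap",
    pairwise_overlap(read_regulator_sets(config$tf_sets, "ChIP-derived TF")))
  write_overlap(tf, file.path(out_dir, "tf_overlap.tsv"))
  lnc <- pipeline_stage("overlap",
    pairwise_overlap(read_regulator_sets(config$lncrna_sets,
                                         "predicted lncRNA")))
  write_overlap(lnc, file.path(out_dir, "lncrna_overlap.tsv"))

  enr <- pipeline_stage("enrich", {
    enrich(readLines(config$targets, warn = FALSE),
           read_gmt(config$gmt), fdr_threshold = config$fdr_threshold)
  })
  write_tsv(as.data.frame(enr), file.path(out_dir, "enrich.tsv"))

  manifest <- pipeline_stage("manifest", {
    files <- sort(setdiff(dir(out_dir, recursive = TRUE),
                          "manifest.tsv"))
    cfg_hash <- config_hash(config)
    df <- data.frame(
      file = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE
    )
    header <- data.frame(
      file = c("#seed", "#package_version", "#config_md5"),
      md5 = c(as.character(config$seed),
              as.character(packageVersion("aismir")), cfg_hash),
      stringsAsFactors = FALSE
    )
    rbind(header, df)
  })
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  invisible(list(cohort = cohort, scores = scores, rq = rq,
                 anova = anova_tab, corr_targets = corr_targets,
                 corr_mirna = corr_mirna, corr_scores = corr_scores,
                 synergy = synergy, score_regressions = score_reg,
                 tf_overlap = tf, lncrna_overlap = lnc, enrichment = enr,
                 manifest = manifest, out_dir = out_dir))
}

# Stable hash of the run configuration: serialize to YAML text and digest.
config_hash <- function(config) {
  txt <- yaml::as.yaml(unclass_recursive(config))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_recursive)
  } else if (is.matrix(x)) {
    apply(x, 1, as.numeric, simplify = FALSE)
  } else {
    unclass(x)
  }
}
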