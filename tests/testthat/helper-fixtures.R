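# Small in-code fixtures shared across test files.

# Minimal behavior table: 3 controls with hand-set ASR values, one stressed
# mouse; used for hand-arithmetic oracles of the scoring rules.
toy_behavior <- function() {
  data.frame(
    mouse_id = c("C1", "C2", "C3", "S1"),
    group = c("control", "control", "control", "stressed"),
    asr_baseline = c(250, 250, 250, 250),
    asr1_pct = c(90, 100, 110, 120),
    asr2_pct = c(95, 100, 105, 115),
    of_measure = c(100, 120, 140, 90),
    epm_measure = c(30, 35, 40, 25),
    sm_measure = c(55, 60, 65, 40),
    stringsAsFactors = FALSE
  )
}

# Long-format Ct table for 3 mice x 1 area x (1 target + its reference),
# constant within triplicate so dCt values are exact by construction.
toy_ct <- function(target_cts = c(A = 24, B = 25, C = 26),
                   ref_ct = 18, analyte = "FKBP5", reference = "GAPDH",
                   area = "HIP") {
  mice <- names(target_cts)
  rows <- expand.grid(replicate = 1:3, analyte = c(analyte, reference),
                      mouse_id = mice, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows$area <- area
  rows$ct <- ifelse(rows$analyte == reference, ref_ct,
                    target_cts[rows$mouse_id])
  rows[c("mouse_id", "area", "analyte", "replicate", "ct")]
}

toy_phenotypes <- function(mice = c("A", "B", "C"),
                           phen = c("control", "susceptible", "resilient")) {
  data.frame(mouse_id = mice, phenotype = phen, stringsAsFactors = FALSE)
}

# A small but complete synthetic cohort for integration-level tests.
small_config <- function(...) {
  cohort_config(n_control = 8L, n_stressed = 12L,
                area_allocation = list(HIP = 1:20, HT = 1:20, mPFC = 1:20),
                ...)
}

# Independent brute-force R^2: solve the normal equations directly, no lm.
bruteforce_r2 <- function(y, X) {
  X1 <- cbind(1, as.matrix(X))
  beta <- solve(crossprod(X1), crossprod(X1, y))
  fitted <- X1 %*% beta
  1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
}

# Independent brute-force best subset: enumerate with bruteforce_r2 only.
bruteforce_best <- function(y, wide, pool, size) {
  subsets <- combn(sort(pool), size, simplify = FALSE)
  r2 <- vapply(subsets, function(s) {
    bruteforce_r2(y, wide[, s, drop = FALSE])
  }, 0)
  keys <- vapply(subsets, paste, "", collapse = ", ")
  ord <- order(-r2, keys)
  list(predictors = keys[ord[1]], R = sqrt(r2[ord[1]]))
}

# Term-wise hypergeometric upper tail, summed from the definition.
bruteforce_fisher <- function(k, list_size, pathway_size, background_size) {
  kmax <- min(list_size, pathway_size)
  if (k > kmax) return(0)
  terms <- vapply(k:kmax, function(i) {
    exp(lchoose(pathway_size, i) +
          lchoose(background_size - pathway_size, list_size - i) -
          lchoose(background_size, list_size))
  }, 0)
  sum(terms)
}
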