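test_that("identical config and seed give bit-identical cohorts", {
  cfg <- small_config()
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$ct, b$ct)
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(a$ct$ct, c$ct$ct))
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_control = 1), "n_control")
  expect_error(cohort_config(n_stressed = 3), "n_stressed")
  expect_error(cohort_config(replicate_sd = -0.1), "replicate_sd")
  # non-PSD correlation matrix is rejected and the area named
  an <- c("miR-15a-5p", "let-7d-5p", "miR-497a-5p", "miR-511-5p",
          "FKBP5", "BDNF")
  bad <- diag(6); dimnames(bad) <- list(an, an)
  bad[1, 2] <- bad[2, 1] <- 0.9
  bad[1, 3] <- bad[3, 1] <- 0.9
  bad[2, 3] <- bad[3, 2] <- -0.9
  em <- expression_model(an, base_dct = setNames(rep(5, 6), an),
                         shift_susceptible = setNames(rep(0, 6), an),
                         shift_resilient = setNames(rep(0, 6), an),
                         sd = setNames(rep(0.7, 6), an), corr = bad)
  expect_error(
    cohort_config(expression = list(HIP = em),
                  area_allocation = list(HIP = 1:46)),
    "HIP.*positive semidefinite"
  )
})

test_that("triplicate structure and reference analytes are generated", {
  co <- generate_cohort(small_config(), seed = 5)
  counts <- table(co$ct$mouse_id, co$ct$area, co$ct$analyte)
  expect_true(all(counts %in% c(0L, 3L)))
  for (area in unique(co$ct$area)) {
    expect_true(all(c("GAPDH", "U6") %in%
                      co$ct$analyte[co$ct$area == area]))
  }
  expect_true(all(co$ct$ct > 0 & co$ct$ct < 45))
})

test_that("null configuration produces exchangeable groups", {
  # With every shift and gain zeroed, control and stressed means should
  # differ only by sampling error: the two-sample t-test at alpha = 0.01
  # should reject rarely across 50 seeds.
  rej_asr <- 0L
  rej_ct <- 0L
  for (s in 1:50) {
    co <- generate_cohort(small_config(null_effects = TRUE), seed = s)
    b <- co$behavior
    rej_asr <- rej_asr +
      (t.test(asr1_pct ~ group, data = b)$p.value < 0.01)
    sub <- co$ct[co$ct$area == "HIP" & co$ct$analyte == "FKBP5", ]
    mct <- tapply(sub$ct, sub$mouse_id, mean)
    grp <- b$group[match(names(mct), b$mouse_id)]
    rej_ct <- rej_ct + (t.test(mct ~ grp)$p.value < 0.01)
  }
  # Binomial(50, 0.01): P(X > 5) < 1e-5
  expect_lte(rej_asr, 5L)
  expect_lte(rej_ct, 5L)
})

test_that("stressed mice with higher latent susceptibility startle more", {
  co <- generate_cohort(cohort_config(n_stressed = 100L), seed = 11)
  st <- co$behavior[co$behavior$group == "stressed", ]
  expect_gt(cor(st$latent_susceptibility, st$asr1_pct), 0.3)
  expect_gt(cor(st$latent_susceptibility, st$asr2_pct), 0.3)
})

test_that("planted analyte correlation is recovered at large n", {
  # Two-analyte model with rho = -0.6 between miR-15a-5p and FKBP5 on the
  # dCt scale; the sample correlation of log2(RQ) over 200 mice must land
  # within +/-0.1 in the bulk of replicates. The oracle expectation comes
  # from the bivariate normal model itself (planted rho, attenuated only
  # by the replicate-noise variance 2*sd^2/3 on each dCt).
  an <- c("miR-15a-5p", "FKBP5")
  corr <- matrix(c(1, -0.6, -0.6, 1), 2, dimnames = list(an, an))
  em <- expression_model(an, base_dct = c(5, 6),
                         shift_susceptible = c(0, 0),
                         shift_resilient = c(0, 0),
                         sd = c(0.7, 0.7), corr = corr)
  cfg <- cohort_config(n_control = 100L, n_stressed = 100L,
                       expression = list(HIP = em),
                       area_allocation = list(HIP = 1:200),
                       null_effects = TRUE)
  hits <- 0L
  rs <- numeric(25)
  for (s in 1:25) {
    co <- generate_cohort(cfg, seed = 100 + s)
    phen <- data.frame(mouse_id = co$behavior$mouse_id,
                       phenotype = co$behavior$group)
    rq <- quantify_cohort(co$ct, phen, calibrator_group = "control")
    wide <- rq_wide(rq, "HIP", value = "log2_rq")
    rs[s] <- cor(wide[, "miR-15a-5p"], wide[, "FKBP5"])
  }
  expect_true(all(rs < 0))
  expect_gte(mean(abs(rs - (-0.6)) <= 0.1), 0.9)
  expect_lt(abs(mean(rs) - (-0.6)), 0.05)
})

test_that("write/read round trip is the identity", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(small_config(), seed = 3)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$behavior, co$behavior)
  expect_equal(back$ct, co$ct)
})

test_that("malformed and degenerate cohort files are rejected loudly", {
  dir <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_control = 2, n_stressed = 4,
                                      area_allocation = list(HIP = 1:6)),
                        seed = 1)
  write_cohort(co, dir)

  # A Ct of NA must be a parse error naming the line, not a silent drop.
  ct_lines <- readLines(file.path(dir, "ct.tsv"))
  ct_lines[5] <- sub("\t[0-9.]+$", "\tNA", ct_lines[5])
  writeLines(ct_lines, file.path(dir, "ct.tsv"))
  expect_error(read_cohort(dir), "cannot parse numeric.*line 5")

  # Dropping a reference analyte is a validation error.
  write_cohort(co, dir)
  ct <- read.delim(file.path(dir, "ct.tsv"))
  ct <- ct[ct$analyte != "GAPDH", ]
  write.table(ct, file.path(dir, "ct.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_cohort(dir), "reference analyte.*GAPDH")

  # Losing one replicate violates the triplicate invariant.
  write_cohort(co, dir)
  ct <- read.delim(file.path(dir, "ct.tsv"))
  ct <- ct[-1, ]
  write.table(ct, file.path(dir, "ct.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_cohort(dir), "exactly 3")
})

test_that("the packaged demo cohort has 46 mice with the published split", {
  co <- read_cohort(aismir_example("demo_cohort"))
  expect_equal(nrow(co$behavior), 46L)
  expect_equal(sum(co$behavior$group == "control"), 18L)
  expect_equal(sum(co$behavior$group == "stressed"), 28L)
  hip <- unique(co$ct$mouse_id[co$ct$area == "HIP"])
  ht <- unique(co$ct$mouse_id[co$ct$area == "HT"])
  expect_equal(length(hip), 30L)
  expect_equal(length(ht), 16L)
})
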