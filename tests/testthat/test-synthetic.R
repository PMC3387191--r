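test_that("generation is deterministic given a seed", {
  c1 <- generate_cohort(cohort_config(seed = 123, n_subjects = 200))
  c2 <- generate_cohort(cohort_config(seed = 123, n_subjects = 200))
  expect_identical(unclass(c1$genotypes), unclass(c2$genotypes))
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cohort_config(seed = 124, n_subjects = 200))
  expect_false(identical(c1$phenotypes, c3$phenotypes))
  # the global RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_cohort(cohort_config(seed = 1,
                                                        n_subjects = 50)))
  expect_identical(runif(1), before)
})

test_that("realized prevalences match the calibration targets", {
  prevs <- sapply(1:10, function(s) {
    co <- generate_cohort(cohort_config(seed = s))
    cl <- classify_glycemia(co$phenotypes$glucose_0_mmol_l,
                            co$phenotypes$glucose_120_mmol_l)
    c(pred = mean(cl[cl != "DIABETES"] != "NGT"),
      obese = mean(co$phenotypes$bmi >= 30),
      female = mean(co$phenotypes$sex == "female"))
  })
  expect_true(all(abs(prevs["pred", ] - 0.28) <= 0.02))
  expect_equal(mean(prevs["obese", ]), 0.32, tolerance = 0.15)
  expect_equal(unname(prevs["female", 1]), 959 / 1442, tolerance = 1e-3)
})

test_that("simulated genotypes sit in Hardy-Weinberg equilibrium", {
  pvals <- unlist(lapply(1:30, function(s) {
    co <- generate_cohort(cohort_config(seed = 200 + s))
    hwe_qc(co$genotypes)$p_exact
  }))
  expect_lt(mean(pvals < 0.05), 0.10)   # 270 tests at nominal 5%
  expect_gt(min(pvals), 1e-6)
})

test_that("genetic effect lands on post-load, not fasting, glucose", {
  hits <- t(sapply(1:20, function(s) {
    co <- generate_cohort(cohort_config(seed = 300 + s,
                                        beta_score = log(1.3)))
    ph <- co$phenotypes
    rho <- weighted_score(unclass(co$genotypes), co$panel)
    pf <- summary(lm(glucose_0_mmol_l ~ rho + age + bmi,
                     ph))$coefficients["rho", 4]
    pg <- summary(lm(glucose_120_mmol_l ~ rho + age + bmi,
                     ph))$coefficients["rho", 4]
    c(fasting_sig = pf < 0.05, postload_sig = pg < 0.05)
  }))
  expect_lte(sum(hits[, "fasting_sig"]), 4)     # nominal false positives
  expect_gte(sum(hits[, "postload_sig"]), 18)   # near-certain detection
})

test_that("fixtures round-trip and record the full truth", {
  co <- generate_cohort(cohort_config(seed = 17, n_subjects = 30))
  dir <- tempfile()
  paths <- write_cohort_fixture(co, dir)
  expect_true(all(file.exists(paths)))
  g_tab <- read_genotypes(paths[["genotypes"]], co$panel)
  g_vcf <- read_genotypes(paths[["vcf"]], co$panel)
  expect_identical(unclass(g_tab), unclass(co$genotypes))
  expect_identical(unclass(g_vcf), unclass(co$genotypes))
  vcf_records <- sum(!startsWith(readLines(paths[["vcf"]]), "#"))
  expect_equal(vcf_records, 9L)
  truth <- jsonlite::read_json(paths[["truth"]])
  cfg_fields <- setdiff(names(unclass(cohort_config(seed = 1))), "panel")
  expect_true(all(cfg_fields %in% names(truth)))
})

test_that("config validation refuses degenerate settings", {
  expect_error(cohort_config(), "seed")
  expect_error(cohort_config(seed = 1, n_subjects = 5), "n_subjects")
  expect_error(cohort_config(seed = 1, target_prediabetes_prev = 1.2))
  expect_error(cohort_config(seed = 1, allele_freqs = rep(0.5, 3)))
})
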