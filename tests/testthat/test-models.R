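lev <- c("NGT", "ISOLATED_IFG", "ISOLATED_IGT", "IFG_IGT", "DIABETES")

test_that("unadjusted model on a 2x2 table recovers the cross-product OR", {
  # score 1: 30 cases / 70 controls; score 0: 10 cases / 90 controls
  d <- data.frame(
    category = factor(rep(c("ISOLATED_IGT", "NGT", "ISOLATED_IGT", "NGT"),
                          c(30, 70, 10, 90)), levels = lev),
    grs = rep(c(1, 1, 0, 0), c(30, 70, 10, 90)))
  m <- fit_score_model(d, "IGT_combined", "grs", covariates = character(0))
  expect_equal(m$or_per_allele, (30 * 90) / (70 * 10), tolerance = 1e-6)
  expect_equal(m$n, 200L)
  expect_equal(m$n_cases, 40L)
  expect_true(m$ci[1] < m$or_per_allele && m$or_per_allele < m$ci[2])
})

test_that("LRT p is invariant to affine rescaling; OR transforms with it", {
  d <- small_analysis_table(seed = 31, n = 1000, beta_score = log(1.25))
  m1 <- fit_score_model(d, "IGT_combined", "grs_weighted")
  d$grs_x10 <- 10 * d$grs_weighted + 3
  m2 <- fit_score_model(d, "IGT_combined", "grs_x10")
  expect_equal(m2$lrt_p, m1$lrt_p, tolerance = 1e-6)
  expect_equal(m2$or_per_allele^10, m1$or_per_allele, tolerance = 1e-6)
})

test_that("estimates tighten as the cohort grows (consistency)", {
  true_beta <- log(1.25)
  rmse <- sapply(c(500, 2000, 8000), function(n) {
    errs <- sapply(1:20, function(r) {
      d <- small_analysis_table(seed = 1000 * n + r, n = n,
                                beta_score = true_beta)
      log(fit_score_model(d, "IGT_combined", "grs_weighted")$or_per_allele) -
        true_beta
    })
    sqrt(mean(errs^2))
  })
  expect_gt(rmse[1], rmse[2])
  expect_gt(rmse[2], rmse[3])
})

test_that("separation is reported as an error, not a silent fit", {
  d <- data.frame(
    category = factor(rep(c("ISOLATED_IGT", "NGT"), each = 30), levels = lev),
    grs = rep(c(1, 0), each = 30))
  expect_error(fit_score_model(d, "IGT_combined", "grs",
                               covariates = character(0)), "separation")
})

test_that("model preconditions are enforced", {
  d <- small_analysis_table(seed = 5, n = 300)
  expect_error(fit_score_model(d, "IGT_combined", "grs_weighted",
                               covariates = "age", log_transform = "bmi"),
               "subset")
  expect_error(fit_score_model(d, "nonsense", "grs_weighted"), "outcome")
  d$neg <- -1
  expect_error(fit_score_model(d, "IGT_combined", "grs_weighted",
                               covariates = "neg", log_transform = "neg"),
               "non-positive")
  d$category[1] <- "DIABETES"
  expect_error(fit_score_model(d, "IGT_combined", "grs_weighted"),
               "diabetic")
})

test_that("primary grid contains the configured model set", {
  d <- small_analysis_table(seed = 77)
  res <- run_primary_analyses(d)
  expect_equal(length(res$models), 11L)
  expect_equal(nrow(res$grid), 11L)
  expect_setequal(
    unique(res$grid$outcome[res$grid$score == "grs_weighted"]),
    c("IGT_combined", "prediabetes", "isolated_IGT", "isolated_IFG"))
  expect_true("grs7_simple" %in% res$grid$score)
  ext <- res$models[["grs_weighted.IGT_combined.extended"]]
  expect_true("family_history" %in% ext$covariates)
  expect_true(all(res$grid$lrt_p > 0 & res$grid$lrt_p <= 1))
})

test_that("strata partition the cohort and the forest has 7 rows", {
  d <- small_analysis_table(seed = 78)
  res <- run_stratified_analyses(d)
  f <- res$forest
  expect_equal(nrow(f), 7L)
  expect_equal(f$stratum,
               c("overall", "female", "male", "lean", "obese", "sensitive",
                 "resistant"))
  n_tot <- f$n[f$stratum == "overall"]
  expect_equal(f$n[f$stratum == "female"] + f$n[f$stratum == "male"], n_tot)
  expect_equal(f$n[f$stratum == "lean"] + f$n[f$stratum == "obese"], n_tot)
  expect_equal(f$n[f$stratum == "sensitive"] +
                 f$n[f$stratum == "resistant"], n_tot)
  expect_true(all(f$ci_lower < f$or_per_allele &
                    f$or_per_allele < f$ci_upper, na.rm = TRUE))
})

test_that("tiny strata are flagged and skipped rather than fitted", {
  d <- small_analysis_table(seed = 79, n = 600)
  # thin the male stratum to ~6 cases, keeping some in every stratum so no
  # sex-by-stratum cell separates
  male_case <- which(d$sex == "male" & d$igt_combined)
  keep <- c(head(male_case[d$bmi[male_case] >= 30], 3),
            head(male_case[d$bmi[male_case] < 30], 3))
  d$category[setdiff(male_case, keep)] <- "NGT"
  w <- capture_warnings(res <- run_stratified_analyses(d))
  expect_true(any(grepl("male", w)))
  expect_false(res$forest$fitted[res$forest$stratum == "male"])
  expect_true(is.na(res$forest$or_per_allele[res$forest$stratum == "male"]))
})
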