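# Outcome definitions over the non-diabetic glycemic categories. Each
# at-risk subgroup is compared against the remainder of the full cohort
# (not against NGT alone), matching the group sizes used throughout.
outcome_indicator <- function(category, outcome) {
  stopifnot(is.factor(category))
  if (any(category == "DIABETES"))
    stop("diabetic subjects must be excluded before model fitting")
  switch(outcome,
    IGT_combined = category %in% c("ISOLATED_IGT", "IFG_IGT"),
    prediabetes  = category != "NGT",
    isolated_IGT = category == "ISOLATED_IGT",
    isolated_IFG = category == "ISOLATED_IFG",
    stop("unknown outcome: ", outcome))
}

#' Logistic model for a glycemic outcome with a genetic risk score
#'
#' Fits a maximum-likelihood logistic regression of a dichotomous glycemic
#' outcome on a genetic risk score plus covariates. Covariates listed in
#' \code{log_transform} are replaced by their natural logarithms (they must
#' be strictly positive). The score term's p-value comes from an effect
#' likelihood-ratio test (deviance difference against the model without the
#' score, 1 df); the per-allele odds ratio is \code{exp(score coefficient)}
#' with a Wald 95\% confidence interval.
#'
#' @param data Analysis table containing a \code{category} factor (from
#'   \code{\link{classify_glycemia}}), the score column and all covariates.
#' @param outcome One of \code{"IGT_combined"}, \code{"prediabetes"},
#'   \code{"isolated_IGT"}, \code{"isolated_IFG"}.
#' @param score Name of the score column (e.g. \code{"grs_weighted"}).
#' @param covariates Character vector of adjustment covariates.
#' @param log_transform Subset of \code{covariates} to ln-transform;
#'   defaults to the insulin sensitivity index, which is right-skewed.
#' @param stratum Optional label recorded in the result.
#' @return Object of class \code{grs_model}: list with \code{n},
#'   \code{n_cases}, \code{coefficients} (estimate/SE/z/Wald p per term),
#'   \code{or_per_allele}, \code{ci} (95\% Wald), \code{lrt_p},
#'   \code{converged}, plus the model metadata.
#' @export
fit_score_model <- function(data, outcome, score,
                            covariates = c("sex", "age", "bmi",
                                           "isi_matsuda"),
                            log_transform = intersect(covariates,
                                                      LOG_SKEWED_VARS),
                            stratum = NA_character_) {
  stopifnot(is.data.frame(data), score %in% names(data))
  if (!all(log_transform %in% covariates))
    stop("log_transform must be a subset of covariates")
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov) > 0L)
    stop("covariate(s) absent from data: ", paste(missing_cov, collapse = ", "))
  y <- outcome_indicator(data$category, outcome)
  mf <- data.frame(.y = as.integer(y), .score = data[[score]])
  for (v in covariates) {
    x <- data[[v]]
    if (v %in% log_transform) {
      if (is.factor(x) || is.character(x) || is.logical(x))
        stop("cannot log-transform non-numeric covariate: ", v)
      if (any(x <= 0, na.rm = TRUE))
        stop("log_transform covariate ", v, " has non-positive values")
      x <- log(x)
      v <- paste0("ln_", v)
    }
    mf[[v]] <- x
  }
  mf <- mf[stats::complete.cases(mf), , drop = FALSE]
  n <- nrow(mf)
  if (n <= ncol(mf))
    stop("too few complete observations (", n, ") for ", ncol(mf) - 1,
         " parameters")
  fit <- suppressWarnings(
    stats::glm(.y ~ ., family = stats::binomial(), data = mf))
  fit0 <- suppressWarnings(
    stats::glm(.y ~ . - .score, family = stats::binomial(), data = mf))
  slopes <- stats::coef(fit)[names(stats::coef(fit)) != "(Intercept)"]
  if (any(abs(slopes) > 15, na.rm = TRUE))
    stop("separation detected in logistic fit (outcome ", outcome,
         ", stratum ", stratum, "): a coefficient diverged")
  if (!fit$converged)
    warning("logistic fit did not converge (outcome ", outcome, ")")
  sm <- summary(fit)$coefficients
  beta <- sm[".score", "Estimate"]
  se <- sm[".score", "Std. Error"]
  lrt <- stats::pchisq(fit0$deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
  structure(list(
    outcome = outcome, score = score, stratum = stratum,
    covariates = covariates, log_transform = log_transform,
    n = n, n_cases = sum(mf$.y),
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, "Estimate"],
                              se = sm[, "Std. Error"],
                              z = sm[, "z value"],
                              p_wald = sm[, "Pr(>|z|)"],
                              row.names = NULL),
    or_per_allele = exp(beta),
    ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    lrt_p = lrt,
    converged = fit$converged), class = "grs_model")
}

# Variables treated as right-skewed and ln-transformed when used as
# covariates (the insulin-based measures and triglycerides).
LOG_SKEWED_VARS <- c("isi_matsuda", "homa_ir", "homa_b", "tg_mmol_l",
                     "insulin_0_pmol_l", "insulin_120_pmol_l")

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf(
    "Logistic model: %s ~ %s + %s%s\n  n = %d (%d cases); OR per allele = %.3f (95%% CI %.3f-%.3f); LRT p = %.4g\n",
    x$outcome, x$score, paste(x$covariates, collapse = " + "),
    if (is.na(x$stratum)) "" else paste0(" [stratum: ", x$stratum, "]"),
    x$n, x$n_cases, x$or_per_allele, x$ci[1], x$ci[2], x$lrt_p))
  invisible(x)
}

model_row <- function(m) {
  data.frame(outcome = m$outcome, score = m$score, stratum = m$stratum,
             n = m$n, n_cases = m$n_cases, or_per_allele = m$or_per_allele,
             ci_lower = m$ci[1], ci_upper = m$ci[2], lrt_p = m$lrt_p,
             converged = m$converged, stringsAsFactors = FALSE)
}

#' Primary model grid
#'
#' Fits the full set of whole-cohort models: both the simple and the
#' weighted 9-SNP score against each of the four outcomes (combined IGT,
#' prediabetes, isolated IGT, isolated IFG) adjusted for sex, age, BMI and
#' ln insulin sensitivity; the 7-SNP secretion-restricted scores against
#' prediabetes; and an extended combined-IGT model for the weighted score
#' adding LDL, HDL, ln triglycerides, lipid-lowering and antihypertensive
#' medication and family history of diabetes (total cholesterol excluded as
#' collinear with LDL).
#'
#' @param data Scored, classified, complete-case analysis table.
#' @return List with \code{models} (list of \code{grs_model}) and
#'   \code{grid} (one summary row per model).
#' @export
run_primary_analyses <- function(data) {
  base_cov <- c("sex", "age", "bmi", "isi_matsuda")
  ext_cov <- c(base_cov, "ldl_mmol_l", "hdl_mmol_l", "tg_mmol_l",
               "lipid_lowering", "antihypertensive", "family_history")
  models <- list()
  for (sc in c("grs_simple", "grs_weighted"))
    for (out in c("IGT_combined", "prediabetes", "isolated_IGT",
                  "isolated_IFG"))
      models[[paste(sc, out, sep = ".")]] <-
        fit_score_model(data, out, sc, base_cov)
  for (sc in c("grs7_simple", "grs7_weighted"))
    models[[paste(sc, "prediabetes", sep = ".")]] <-
      fit_score_model(data, "prediabetes", sc, base_cov)
  if (all(ext_cov %in% names(data)))
    models[["grs_weighted.IGT_combined.extended"]] <-
      fit_score_model(data, "IGT_combined", "grs_weighted", ext_cov)
  list(models = models,
       grid = do.call(rbind, lapply(models, model_row)))
}

#' Stratified combined-IGT models and forest table
#'
#' Fits the weighted-score model for combined IGT in the whole cohort and
#' within six strata: female/male, lean/obese (BMI < 30 vs >= 30 kg/m2) and
#' insulin sensitive/resistant (ISI at or above vs below the cohort
#' median). Each stratified model drops the stratifying covariate from the
#' adjustment set: sex strata adjust for age + BMI + ln ISI, BMI strata for
#' sex + age + ln ISI, ISI strata for sex + age + BMI. A stratum with fewer
#' than 10 cases is flagged and not fitted.
#'
#' @param data Scored, classified, complete-case analysis table.
#' @param score Score column; default the weighted 9-SNP score.
#' @return List with \code{models} and \code{forest} (a 7-row table:
#'   stratum, n, n_cases, OR, SE of log OR, 95\% CI, LRT p).
#' @export
run_stratified_analyses <- function(data, score = "grs_weighted") {
  split_isi <- median_isi_split(data$isi_matsuda)
  strata <- list(
    overall   = list(mask = rep(TRUE, nrow(data)),
                     cov = c("sex", "age", "bmi", "isi_matsuda")),
    female    = list(mask = data$sex == "female",
                     cov = c("age", "bmi", "isi_matsuda")),
    male      = list(mask = data$sex == "male",
                     cov = c("age", "bmi", "isi_matsuda")),
    lean      = list(mask = data$bmi < 30,
                     cov = c("sex", "age", "isi_matsuda")),
    obese     = list(mask = data$bmi >= 30,
                     cov = c("sex", "age", "isi_matsuda")),
    sensitive = list(mask = !split_isi$resistant,
                     cov = c("sex", "age", "bmi")),
    resistant = list(mask = split_isi$resistant,
                     cov = c("sex", "age", "bmi")))
  models <- list()
  rows <- lapply(names(strata), function(s) {
    mask <- strata[[s]]$mask
    d <- data[mask, , drop = FALSE]
    cases <- sum(outcome_indicator(d$category, "IGT_combined"))
    if (cases < 10) {
      warning("stratum ", s, " has ", cases, " cases (< 10): fit skipped")
      return(data.frame(stratum = s, n = nrow(d), n_cases = cases,
                        or_per_allele = NA_real_, log_or_se = NA_real_,
                        ci_lower = NA_real_, ci_upper = NA_real_,
                        lrt_p = NA_real_, fitted = FALSE))
    }
    m <- fit_score_model(d, "IGT_combined", score, strata[[s]]$cov,
                         stratum = s)
    models[[s]] <<- m
    se <- m$coefficients$se[m$coefficients$term == ".score"]
    data.frame(stratum = s, n = m$n, n_cases = m$n_cases,
               or_per_allele = m$or_per_allele, log_or_se = se,
               ci_lower = m$ci[1], ci_upper = m$ci[2], lrt_p = m$lrt_p,
               fitted = TRUE)
  })
  list(models = models,
       forest = do.call(rbind, rows),
       isi_threshold = split_isi$threshold)
}
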