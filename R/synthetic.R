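#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of a metabolically at-risk,
#' female-predominant European cohort: n = 1442 with 959 females, ~28\%
#' prediabetes prevalence, ~32\% obesity, age ~ 39 +/- 13 years (18-80),
#' and a logistic liability linking the weighted genetic risk score to
#' post-load (2-h) glucose only — the score is not given any effect on
#' fasting glucose unless \code{genetic_on_fasting} is set.
#'
#' @param seed Integer RNG seed (required; no hidden global state).
#' @param n_subjects Cohort size before diabetes exclusion; default 1442.
#' @param female_fraction Fraction of females; default 959/1442.
#' @param panel \code{snp_panel}; default \code{\link{default_panel}}.
#' @param allele_freqs Per-SNP risk-allele frequencies; default the panel
#'   file's \code{risk_allele_freq} column.
#' @param beta_score Log odds ratio per weighted-score unit on the 2-h
#'   (IGT) liability; default \code{log(1.1)}, a modest polygenic effect.
#' @param beta_age,beta_bmi,beta_res Liability coefficients for
#'   standardized age, standardized ln BMI and the latent insulin
#'   resistance (age raises risk; BMI is mildly protective conditional on
#'   resistance; resistance is the dominant driver).
#' @param target_prediabetes_prev Calibration target for the realized
#'   prediabetes prevalence among non-diabetic subjects; default 0.28.
#' @param obesity_prev Probability of BMI >= 30 kg/m2; default 0.32.
#' @param effect_modification \code{"none"}, \code{"obese_only"} (genetic
#'   effect only when BMI >= 30) or \code{"resistant_only"} (only when the
#'   latent resistance is above its median).
#' @param genetic_on_fasting Log-OR-scale genetic effect on the fasting
#'   glucose liability, for robustness testing; default 0.
#' @param liability_scale mmol/l of 2-h glucose per logistic liability
#'   unit; default 0.7.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(seed,
                          n_subjects = 1442,
                          female_fraction = 959 / 1442,
                          panel = default_panel(),
                          allele_freqs = panel$risk_allele_freq,
                          beta_score = log(1.1),
                          beta_age = 0.35,
                          beta_bmi = -0.15,
                          beta_res = 1.0,
                          target_prediabetes_prev = 0.28,
                          obesity_prev = 0.32,
                          effect_modification = c("none", "obese_only",
                                                  "resistant_only"),
                          genetic_on_fasting = 0,
                          liability_scale = 0.7) {
  if (missing(seed)) stop("an explicit RNG seed is required")
  effect_modification <- match.arg(effect_modification)
  stopifnot(n_subjects >= 10,
            female_fraction > 0, female_fraction < 1,
            inherits(panel, "snp_panel"),
            length(allele_freqs) == nrow(panel),
            all(allele_freqs > 0), all(allele_freqs < 1),
            target_prediabetes_prev > 0, target_prediabetes_prev < 1,
            obesity_prev > 0, obesity_prev < 1,
            liability_scale > 0)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 female_fraction = female_fraction, panel = panel,
                 allele_freqs = allele_freqs, beta_score = beta_score,
                 beta_age = beta_age, beta_bmi = beta_bmi,
                 beta_res = beta_res,
                 target_prediabetes_prev = target_prediabetes_prev,
                 obesity_prev = obesity_prev,
                 effect_modification = effect_modification,
                 genetic_on_fasting = genetic_on_fasting,
                 liability_scale = liability_scale),
            class = "cohort_config")
}

# bisection for a nondecreasing step function f; returns x with
# f(x) as close to target as the grid of jumps allows
bisect_shift <- function(f, target, lo = -4, hi = 4, iter = 60L) {
  if (f(lo) > target || f(hi) < target)
    stop("calibration failure: target ", target,
         " outside achievable range [", f(lo), ", ", f(hi), "]")
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < target) lo <- mid else hi <- mid
  }
  hi
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws genotypes per SNP as two independent Bernoulli(f) alleles (so
#' Hardy-Weinberg equilibrium holds by construction), builds phenotypes
#' from a latent insulin-resistance variable plus age and BMI, and
#' generates 2-h glucose from a logistic liability so that the IGT
#' indicator follows exactly a logistic model in the weighted score and
#' covariates. Intercepts of the fasting and 2-h liabilities are
#' auto-calibrated by bisection so that the realized prediabetes prevalence
#' among non-diabetic subjects hits the configured target within 0.02.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return Object of class \code{grs_cohort}: list with \code{genotypes}
#'   (a \code{genotype_matrix}), \code{phenotypes} (data.frame) and
#'   \code{truth} (all generating parameters and realized calibration
#'   values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n_subjects
  ids <- sprintf("S%05d", seq_len(n))

  n_f <- round(n * config$female_fraction)
  sex <- rep("male", n)
  sex[sample.int(n, n_f)] <- "female"
  male <- as.numeric(sex == "male")

  # age: truncated normal, mean 39, sd 13, range 18-80
  u <- stats::runif(n, stats::pnorm(18, 39, 13), stats::pnorm(80, 39, 13))
  age <- stats::qnorm(u, 39, 13)
  z_age <- (age - 39) / 13

  # BMI lognormal; location set so P(BMI >= 30) = obesity_prev
  sd_lnbmi <- 0.26
  mu_lnbmi <- log(30) - sd_lnbmi * stats::qnorm(1 - config$obesity_prev)
  ln_bmi <- stats::rnorm(n, mu_lnbmi, sd_lnbmi)
  bmi <- exp(ln_bmi)
  z_bmi <- (ln_bmi - mu_lnbmi) / sd_lnbmi

  # latent insulin resistance (unit variance), driven by adiposity and age
  resist <- 0.55 * z_bmi + 0.15 * z_age +
    sqrt(1 - 0.55^2 - 0.15^2) * stats::rnorm(n)

  # genotypes in HWE by construction
  counts <- vapply(config$allele_freqs,
                   function(f) stats::rbinom(n, 2L, f), integer(n))
  dimnames(counts) <- list(ids, config$panel$rsid)
  genotypes <- genotype_matrix(counts)
  rho <- weighted_score(counts, config$panel)
  rho_c <- rho - mean(rho)

  modifier <- switch(config$effect_modification,
    none = rep(1, n),
    obese_only = as.numeric(bmi >= 30),
    resistant_only = as.numeric(resist > stats::median(resist)))

  # insulin: fasting level and OGTT response both scale with resistance
  i0 <- exp(log(54) + 0.45 * resist + stats::rnorm(n, 0, 0.25))
  i30 <- i0 * exp(1.75 + 0.40 * resist + stats::rnorm(n, 0, 0.25))
  i60 <- i0 * exp(1.60 + 0.40 * resist + stats::rnorm(n, 0, 0.25))
  i90 <- i0 * exp(1.45 + 0.40 * resist + stats::rnorm(n, 0, 0.25))

  # fasting glucose: no genetic term unless genetic_on_fasting is set
  g0_base <- 4.93 + 0.10 * z_age + 0.06 * z_bmi + 0.22 * resist +
    config$genetic_on_fasting * rho_c + stats::rnorm(n, 0, 0.33)

  # 2-h glucose from a logistic liability: IGT (G120 >= 7.8) occurs with
  # probability plogis(eta), so a logistic model in score + covariates is
  # correctly specified for the IGT indicator
  eta_base <- config$beta_score * modifier * rho_c +
    config$beta_age * z_age + config$beta_bmi * z_bmi +
    config$beta_res * resist
  e_logis <- stats::rlogis(n)
  s <- config$liability_scale

  tp <- config$target_prediabetes_prev
  # composition of the prediabetes group: marginal IFG and IGT rates in
  # the proportions 256:254 of the 396-subject prediabetes group
  target_ifg <- tp * 256 / 396
  target_igt <- tp * 254 / 396
  shift_f <- bisect_shift(function(c) mean(g0_base + c >= 5.6), target_ifg,
                          lo = -3, hi = 3)
  alpha_g <- bisect_shift(function(a) mean(eta_base + a + e_logis >= 0),
                          target_igt, lo = -8, hi = 4)

  # joint shift on both liabilities so the realized union (prediabetes
  # among non-diabetic subjects) hits the target
  delta <- bisect_shift(function(d) {
    g0d <- g0_base + shift_f + 0.1 * d
    g120d <- 7.8 + s * (eta_base + alpha_g + d + e_logis)
    dm <- g0d >= 7.0 | g120d >= 11.1
    sum((g0d >= 5.6 | g120d >= 7.8) & !dm) / sum(!dm)
  }, tp, lo = -2, hi = 2)
  g0 <- g0_base + shift_f + 0.1 * delta
  alpha_g <- alpha_g + delta
  g120 <- pmax(2.5, 7.8 + s * (eta_base + alpha_g + e_logis))
  cls <- classify_glycemia(pmax(g0, 2.5), g120)
  nondm <- cls != "DIABETES"
  realized_prev <- mean(cls[nondm] != "NGT")
  # 0.02 tolerance at cohort scale; small cohorts are limited by the
  # 1/n granularity of a realized proportion
  prev_tol <- max(0.02, 2 / sum(nondm)) + 1e-9
  if (abs(realized_prev - tp) > prev_tol)
    stop("prevalence calibration failed: realized ", round(realized_prev, 3),
         " vs target ", tp)
  g0 <- pmax(g0, 2.5)

  # intermediate OGTT glucose: rise-and-fall interpolation with
  # multiplicative noise (shapes are a modelling choice, not data-derived)
  g30 <- (g0 + 0.55 * (g120 - g0) + 2.3) * exp(stats::rnorm(n, 0, 0.06))
  g60 <- (g0 + 0.75 * (g120 - g0) + 1.5) * exp(stats::rnorm(n, 0, 0.06))
  g90 <- (g0 + 0.88 * (g120 - g0) + 0.7) * exp(stats::rnorm(n, 0, 0.06))
  # 2-h insulin tracks 2-h glucose and resistance
  i120 <- i0 * exp(1.70 + 0.20 * (g120 - 6) + 0.10 * resist +
                   stats::rnorm(n, 0, 0.30))

  # lipids, medication, family history
  ldl <- pmax(0.8, 3.0 + 0.12 * z_age + 0.10 * resist +
                stats::rnorm(n, 0, 0.75))
  hdl <- exp(log(1.35) - 0.12 * resist - 0.12 * male +
               stats::rnorm(n, 0, 0.22))
  tg <- exp(log(1.25) + 0.30 * resist + 0.15 * male +
              stats::rnorm(n, 0, 0.45))
  tc <- ldl + hdl + 0.45 * tg + stats::rnorm(n, 0, 0.3)
  lipid_lowering <- stats::runif(n) < stats::plogis(-4.3 + 0.9 * z_age)
  antihypertensive <- stats::runif(n) < stats::plogis(-3.0 + 0.9 * z_age +
                                                      0.4 * z_bmi)
  family_history <- stats::runif(n) < 0.48

  phenotypes <- data.frame(
    subject_id = ids,
    sex = factor(sex, levels = c("female", "male")),
    age = age, bmi = bmi,
    glucose_0_mmol_l = g0, glucose_30_mmol_l = g30,
    glucose_60_mmol_l = g60, glucose_90_mmol_l = g90,
    glucose_120_mmol_l = g120,
    insulin_0_pmol_l = i0, insulin_30_pmol_l = i30,
    insulin_60_pmol_l = i60, insulin_90_pmol_l = i90,
    insulin_120_pmol_l = i120,
    ldl_mmol_l = ldl, hdl_mmol_l = hdl, tg_mmol_l = tg,
    total_cholesterol_mmol_l = tc,
    family_history = family_history,
    lipid_lowering = lipid_lowering,
    antihypertensive = antihypertensive,
    stringsAsFactors = FALSE)

  truth <- c(unclass(config)[setdiff(names(unclass(config)), "panel")],
             list(fasting_shift = shift_f, igt_intercept = alpha_g,
                  realized_prediabetes_prev = realized_prev,
                  realized_igt_prev = mean(cls[nondm] %in%
                                           c("ISOLATED_IGT", "IFG_IGT")),
                  n_diabetic = sum(!nondm),
                  score_mean = mean(rho), score_sd = stats::sd(rho),
                  effect_carriers = sum(modifier > 0)))
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 panel = config$panel, truth = truth),
            class = "grs_cohort")
}

#' @export
print.grs_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$phenotypes), "subjects,",
      ncol(x$genotypes), "SNPs; realized prediabetes prevalence",
      round(x$truth$realized_prediabetes_prev, 3), "\n")
  invisible(x)
}

#' Write a cohort to disk as plain-text fixtures
#'
#' Writes a VCF (v4.2, one biallelic record per panel SNP, REF = the
#' non-risk allele, ALT = the risk allele), the tabular genotype file, the
#' phenotype TSV and a JSON record of the generating truth. The VCF and
#' the tabular file both round-trip losslessly through
#' \code{\link{read_genotypes}}.
#'
#' @param cohort A \code{grs_cohort}.
#' @param dir Output directory (created if absent).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "grs_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             genotypes = file.path(dir, "genotypes.tsv"),
             phenotypes = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth.json"))
  write_genotypes(cohort$genotypes, paths["genotypes"])
  utils::write.table(cohort$phenotypes, paths["phenotypes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  write_vcf(cohort, paths["vcf"])
  invisible(paths)
}

write_vcf <- function(cohort, path) {
  panel <- cohort$panel
  counts <- unclass(cohort$genotypes)
  if (!"other_allele" %in% names(panel))
    stop("panel lacks other_allele column needed to write VCF")
  header <- c("##fileformat=VCFv4.2",
              "##source=prediabgrs",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(counts)), collapse = "\t"))
  gt_map <- c("0/0", "0/1", "1/1")
  records <- vapply(seq_len(nrow(panel)), function(i) {
    gt <- gt_map[counts[, i] + 1L]
    gt[is.na(gt)] <- "./."
    paste(c(as.character(i), as.character(1000L * i), panel$rsid[i],
            panel$other_allele[i], panel$risk_allele[i], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(header, records), path)
  invisible(path)
}
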