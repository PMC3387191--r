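#' Build the merged analysis table
#'
#' Complete-case filters genotypes against phenotypes, classifies glycemia,
#' computes metabolic indices and genetic risk scores, and excludes
#' subjects classified as diabetic. This is the table every model-fitting
#' function consumes.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param phenotypes Phenotype data.frame with OGTT columns.
#' @param panel A \code{snp_panel}.
#' @return List with \code{data} (analysis table incl. \code{category},
#'   indicator, index and score columns), \code{n_removed_incomplete},
#'   \code{n_removed_diabetic}.
#' @export
build_analysis_table <- function(genotypes, phenotypes, panel) {
  required <- c("sex", "age", "bmi",
                paste0("glucose_", c(0, 30, 60, 90, 120), "_mmol_l"),
                paste0("insulin_", c(0, 30, 60, 90, 120), "_pmol_l"))
  fc <- filter_complete(genotypes, phenotypes,
                        required = intersect(required, names(phenotypes)))
  ph <- add_metabolic_indices(fc$phenotypes)
  ph$category <- classify_glycemia(ph$glucose_0_mmol_l,
                                   ph$glucose_120_mmol_l)
  n_dm <- sum(ph$category == "DIABETES")
  keep <- ph$category != "DIABETES"
  ph <- ph[keep, , drop = FALSE]
  ph$category <- droplevels(ph$category)
  ph$category <- factor(as.character(ph$category),
                        levels = c("NGT", "ISOLATED_IFG", "ISOLATED_IGT",
                                   "IFG_IGT", "DIABETES"))
  g <- genotype_matrix(unclass(fc$genotypes)[keep, , drop = FALSE])
  ph <- cbind(ph, glycemic_indicators(ph$category))
  scores <- score_cohort(g, panel)
  stopifnot(identical(scores$subject_id, ph$subject_id))
  data <- cbind(ph, scores[, -1, drop = FALSE])
  list(data = data, genotypes = g,
       n_removed_incomplete = fc$n_removed, n_removed_diabetic = n_dm)
}

#' Run the full analysis pipeline
#'
#' Executes read -> Hardy-Weinberg QC -> classification -> metabolic
#' indices -> risk scores -> primary and stratified logistic models ->
#' power table, and writes every result as TSV plus a run log capturing
#' the seedless, deterministic settings in effect (exclusion counts,
#' weight function scale, log-transform set, ISI split threshold).
#'
#' @param panel_path Panel definition file (TSV).
#' @param genotype_path Genotype file (tabular TSV or VCF).
#' @param phenotype_path Phenotype TSV.
#' @param out_dir Output directory.
#' @return Invisibly, a list with every intermediate and result object.
#' @export
run_pipeline <- function(panel_path, genotype_path, phenotype_path,
                         out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("prediabgrs pipeline run,",
                       format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE))
  }
  panel <- stage("panel", load_panel(panel_path))
  genotypes <- stage("genotypes", read_genotypes(genotype_path, panel))
  phenotypes <- stage("phenotypes",
                      utils::read.table(phenotype_path, header = TRUE,
                                        sep = "\t", stringsAsFactors = FALSE))
  if ("sex" %in% names(phenotypes))
    phenotypes$sex <- factor(phenotypes$sex, levels = c("female", "male"))
  qc <- stage("hwe_qc", hwe_qc(genotypes))
  built <- stage("analysis_table",
                 build_analysis_table(genotypes, phenotypes, panel))
  data <- built$data
  groups <- derive_groups(data$category)
  primary <- stage("primary_models", run_primary_analyses(data))
  stratified <- stage("stratified_models", run_stratified_analyses(data))
  tab1 <- stage("table1", table1_summary(data))
  pw <- stage("power", power_table(data.frame(
    label = c("prediabetes", "IGT_combined", "isolated_IGT", "isolated_IFG"),
    n1 = as.integer(groups[c("prediabetes", "IGT_combined", "ISOLATED_IGT",
                             "ISOLATED_IFG")]),
    n2 = as.integer(groups[["total"]] -
                    groups[c("prediabetes", "IGT_combined", "ISOLATED_IGT",
                             "ISOLATED_IFG")]))))

  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(qc, "hwe_qc.tsv")
  wt(primary$grid, "model_grid.tsv")
  wt(stratified$forest, "forest_igt.tsv")
  wt(tab1, "table1.tsv")
  wt(pw, "power_table.tsv")
  wt(data.frame(group = names(groups), n = as.integer(groups)),
     "group_counts.tsv")

  log_lines <- c(log_lines,
    paste("subjects removed (incomplete):", built$n_removed_incomplete),
    paste("subjects removed (diabetic):", built$n_removed_diabetic),
    paste("subjects analyzed:", nrow(data)),
    paste("weight function: ln(OR)"),
    paste("log-transform set:", paste(LOG_SKEWED_VARS, collapse = ", ")),
    paste("insulin conversion: 1 uU/ml =", PMOL_PER_UU, "pmol/l"),
    paste("ISI median split threshold:",
          format(stratified$isi_threshold, digits = 6)),
    paste("alpha: 0.05 two-sided; LRT for score terms; Wald CIs"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))
  invisible(list(panel = panel, qc = qc, data = data, groups = groups,
                 primary = primary, stratified = stratified,
                 table1 = tab1, power = pw,
                 n_removed_incomplete = built$n_removed_incomplete,
                 n_removed_diabetic = built$n_removed_diabetic))
}

#' Group-wise characteristics table
#'
#' Summarises the cohort by glycemic category in the column order NGT,
#' isolated IFG, isolated IGT, IFG+IGT: means +/- SD for continuous
#' variables and percentages for binary ones, with each at-risk group
#' compared against NGT by Student's t test (approximately normal
#' variables), Wilcoxon rank-sum test (the right-skewed ln-transform set)
#' or Fisher's exact test (binary variables).
#'
#' @param data Classified analysis table (with \code{category}).
#' @param variables Variables to summarise; defaults to the standard
#'   demographic, glycemic, insulin, index, lipid and medication columns
#'   present in the data.
#' @param skewed Variables compared by Wilcoxon instead of t test; defaults
#'   to the package's ln-transform set.
#' @return Long-format data.frame: variable, group, summary, p_vs_NGT,
#'   test.
#' @export
table1_summary <- function(data,
                           variables = intersect(
                             c("age", "bmi", "glucose_0_mmol_l",
                               "glucose_120_mmol_l", "insulin_0_pmol_l",
                               "insulin_120_pmol_l", "isi_matsuda",
                               "homa_ir", "homa_b", "tg_mmol_l",
                               "total_cholesterol_mmol_l", "hdl_mmol_l",
                               "ldl_mmol_l", "family_history",
                               "lipid_lowering", "antihypertensive"),
                             names(data)),
                           skewed = LOG_SKEWED_VARS) {
  stopifnot("category" %in% names(data))
  groups <- c("NGT", "ISOLATED_IFG", "ISOLATED_IGT", "IFG_IGT")
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    binary <- is.logical(x) ||
      (is.numeric(x) && all(x %in% 0:1, na.rm = TRUE))
    for (g in groups) {
      xi <- x[data$category == g]
      if (binary) {
        summ <- sprintf("%.1f%%", 100 * mean(xi, na.rm = TRUE))
      } else {
        sdv <- if (sum(!is.na(xi)) < 2) NA_real_ else stats::sd(xi,
                                                                na.rm = TRUE)
        summ <- sprintf("%.2f ± %s", mean(xi, na.rm = TRUE),
                        ifelse(is.na(sdv), "NA", sprintf("%.2f", sdv)))
      }
      x0 <- x[data$category == "NGT"]
      if (g == "NGT") {
        p <- NA_real_; test <- ""
      } else if (sum(!is.na(xi)) < 2 || sum(!is.na(x0)) < 2) {
        p <- NA_real_; test <- "insufficient n"
      } else {
        if (binary) {
          tab <- rbind(c(sum(x0, na.rm = TRUE), sum(!x0, na.rm = TRUE)),
                       c(sum(xi, na.rm = TRUE), sum(!xi, na.rm = TRUE)))
          p <- stats::fisher.test(tab)$p.value; test <- "fisher"
        } else if (v %in% skewed) {
          p <- stats::wilcox.test(xi, x0, exact = FALSE)$p.value
          test <- "wilcoxon"
        } else {
          p <- stats::t.test(xi, x0)$p.value; test <- "t"
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, group = g, summary = summ,
                   p_vs_NGT = p, test = test, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
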