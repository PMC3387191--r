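#' Simple (unweighted) genetic risk score
#'
#' Sum of risk-allele counts across the panel SNPs for one subject or, for a
#' matrix, per subject. Missing genotypes are an error: scores are computed
#' on complete rows only, so that the allele-count scale is comparable
#' across subjects.
#'
#' @param counts Vector (one subject) or matrix (subjects x SNPs) of
#'   risk-allele counts in \{0,1,2\}.
#' @return Integer score(s) in [0, 2N].
#' @export
simple_score <- function(counts) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (anyNA(counts))
    stop("missing genotype in score computation: apply filter_complete first")
  if (!all(counts %in% 0:2)) stop("risk-allele counts must be 0, 1 or 2")
  as.integer(rowSums(counts))
}

#' Weighted genetic risk score
#'
#' Each risk-allele count is multiplied by the SNP's effect size
#' \code{w_i = ln(OR_i)} and the sum is rescaled by the normalization
#' constant \code{N / sum(w_i)} so that the weighted score lives on the
#' allele-count scale and is directly comparable with the simple score:
#' \deqn{\rho_j = \frac{N}{\sum_i w_i} \sum_i w_i a_{ij}.}
#' With equal ORs across the panel the weighted score equals the simple
#' score exactly, and an all-homozygous-risk subject scores 2N regardless
#' of the weights.
#'
#' @param counts Vector or matrix of risk-allele counts.
#' @param panel A \code{snp_panel} whose rows match the count columns.
#' @param weight_fun Function mapping per-allele OR to weight; default
#'   \code{log}. Must return non-negative weights with a positive sum.
#' @return Numeric score(s) in [0, 2N].
#' @export
weighted_score <- function(counts, panel, weight_fun = log) {
  stopifnot(inherits(panel, "snp_panel"))
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(panel))
    stop("count columns (", ncol(counts), ") do not match panel size (",
         nrow(panel), ")")
  if (anyNA(counts))
    stop("missing genotype in score computation: apply filter_complete first")
  w <- weight_fun(panel$or_literature)
  if (any(w < 0)) stop("negative weight from weight_fun")
  if (sum(w) <= 0)
    stop("all SNP weights are zero: weighted score undefined")
  as.numeric((nrow(panel) / sum(w)) * (counts %*% w))
}

#' Score a cohort: simple, weighted and secretion-restricted scores
#'
#' Computes the four genetic risk scores per subject: the simple and
#' weighted 9-SNP (full-panel) scores and their 7-SNP secretion-restricted
#' counterparts obtained by dropping the adiposity/insulin-sensitivity loci
#' (FTO, PPARG for the default panel). The secretion scores renormalize by
#' the sub-panel size.
#'
#' @param genotypes A complete-case \code{genotype_matrix} whose columns
#'   match the panel.
#' @param panel A \code{snp_panel}.
#' @param weight_fun Weight function, default \code{log}.
#' @return Data.frame with columns \code{subject_id}, \code{grs_simple},
#'   \code{grs_weighted}, \code{grs7_simple}, \code{grs7_weighted}.
#' @export
score_cohort <- function(genotypes, panel, weight_fun = log) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!identical(colnames(genotypes), panel$rsid))
    stop("genotype columns do not match panel rsIDs (order matters)")
  sub <- secretion_subset(panel)
  m <- unclass(genotypes)
  m7 <- m[, sub$rsid, drop = FALSE]
  data.frame(subject_id = rownames(genotypes),
             grs_simple = simple_score(m),
             grs_weighted = weighted_score(m, panel, weight_fun),
             grs7_simple = simple_score(m7),
             grs7_weighted = weighted_score(m7, sub, weight_fun),
             stringsAsFactors = FALSE)
}
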