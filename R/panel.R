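#' Load a SNP panel definition
#'
#' Reads a delimited panel file (one row per SNP) and derives per-SNP weights
#' for the weighted genetic risk score as \code{w_i = ln(OR_i)}, the natural
#' logarithm of the literature per-allele odds ratio for type 2 diabetes.
#' All odds ratios must already be oriented to the risk allele (OR >= 1);
#' the loader refuses ambiguous rows rather than silently flipping alleles.
#'
#' @param path Path to a TSV/CSV panel file with columns \code{rsid},
#'   \code{gene}, \code{risk_allele}, \code{or_literature},
#'   \code{secretion_related}, and optionally \code{other_allele} and
#'   \code{risk_allele_freq}. Lines starting with \code{#} are comments.
#' @param sep Field separator; \code{"\t"} by default, \code{","} also works.
#' @return An object of class \code{snp_panel}: a data.frame with one row per
#'   SNP (file order preserved) and a derived \code{weight} column, plus an
#'   \code{n_snps} attribute.
#' @examples
#' panel <- default_panel()
#' panel$weight  # ln(OR) per SNP
#' @export
load_panel <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "\"")
  required <- c("rsid", "gene", "risk_allele", "or_literature",
                "secretion_related")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("panel file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  new_snp_panel(df)
}

new_snp_panel <- function(df) {
  if (nrow(df) < 1L) stop("panel must contain at least one SNP")
  if (anyDuplicated(df$rsid))
    stop("duplicate rsid in panel: ",
         paste(unique(df$rsid[duplicated(df$rsid)]), collapse = ", "))
  if (any(!nzchar(df$risk_allele)) ||
      any(!df$risk_allele %in% c("A", "C", "G", "T")))
    stop("risk_allele must be a single nucleotide A/C/G/T")
  if (!is.numeric(df$or_literature) || any(!is.finite(df$or_literature)) ||
      any(df$or_literature <= 0))
    stop("or_literature must be a positive finite number")
  if (any(df$or_literature < 1))
    stop("or_literature < 1 for ",
         paste(df$rsid[df$or_literature < 1], collapse = ", "),
         ": re-orient these rows to the risk allele (swap alleles and ",
         "invert the OR) so that all ORs are >= 1")
  df$secretion_related <- as.logical(df$secretion_related)
  if (anyNA(df$secretion_related))
    stop("secretion_related must be TRUE/FALSE")
  df$weight <- log(df$or_literature)
  rownames(df) <- NULL
  structure(df, class = c("snp_panel", "data.frame"),
            n_snps = nrow(df))
}

#' Default 9-SNP diabetes-risk panel
#'
#' The panel of nine established type-2-diabetes risk SNPs (TCF7L2, HHEX,
#' SLC30A8, WFS1, KCNJ11, KCNQ1, MTNR1B, FTO, PPARG) shipped with the
#' package. Odds ratios and allele frequencies in the file are editable
#' literature defaults, not cohort estimates.
#'
#' @return A \code{snp_panel} with 9 rows.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "panel_default.tsv",
                         package = "prediabgrs", mustWork = TRUE))
}

#' Restrict a panel to its insulin-secretion SNPs
#'
#' Returns the sub-panel of SNPs flagged \code{secretion_related}. For the
#' default panel this drops the FTO and PPARG loci, leaving the 7 SNPs that
#' primarily modulate insulin secretion.
#'
#' @param panel A \code{snp_panel}.
#' @return A \code{snp_panel} containing only secretion-related SNPs.
#' @export
secretion_subset <- function(panel) {
  stopifnot(inherits(panel, "snp_panel"))
  keep <- panel$secretion_related
  if (!any(keep))
    stop("no secretion-related SNPs in panel: secretion subset is empty")
  new_snp_panel(as.data.frame(panel)[keep, , drop = FALSE])
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("SNP panel:", nrow(x), "SNPs,",
      sum(x$secretion_related), "secretion-related\n")
  print.data.frame(x, ...)
  invisible(x)
}
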