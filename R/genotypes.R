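#' Construct a genotype matrix of risk-allele counts
#'
#' @param counts Integer matrix, subjects in rows, SNPs in columns, entries
#'   in \{0, 1, 2\} or NA for missing calls. Row names are subject ids,
#'   column names rsIDs in panel order.
#' @return An object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  ok <- is.na(counts) | counts %in% 0:2
  if (!all(ok))
    stop("genotype counts must be 0, 1, 2 or NA")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    stop("genotype matrix must have rsID column names")
  structure(counts, class = c("genotype_matrix", "matrix"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x), "subjects x", ncol(x), "SNPs;",
      sum(is.na(x)), "missing calls\n")
  invisible(x)
}

#' Read genotypes as risk-allele counts
#'
#' Reads either a tabular genotype file (subjects in rows, rsIDs in columns,
#' cells holding risk-allele counts 0/1/2 or NA, first column
#' \code{subject_id}) or a VCF (v4.x, biallelic SNP records with a GT field).
#' For VCF input the ALT dosage is mapped onto the panel's risk allele, so a
#' site whose risk allele is REF is inverted (count = 2 - ALT dosage).
#' Columns are reordered to match the panel.
#'
#' @param path File path.
#' @param panel A \code{snp_panel}; all panel rsIDs must be present.
#' @param format \code{"auto"} (by extension), \code{"table"} or \code{"vcf"}.
#' @return A \code{genotype_matrix} with columns in panel order.
#' @export
read_genotypes <- function(path, panel, format = c("auto", "table", "vcf")) {
  stopifnot(inherits(panel, "snp_panel"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "table"
  if (format == "vcf") read_genotypes_vcf(path, panel)
  else read_genotypes_table(path, panel)
}

read_genotypes_table <- function(path, panel) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "subject_id")
    stop("tabular genotype file must have 'subject_id' as first column")
  absent <- setdiff(panel$rsid, names(df))
  if (length(absent) > 0L)
    stop("panel rsID(s) absent from genotype file: ",
         paste(absent, collapse = ", "))
  m <- as.matrix(df[, panel$rsid, drop = FALSE])
  rownames(m) <- df$subject_id
  genotype_matrix(m)
}

read_genotypes_vcf <- function(path, panel) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  ids <- fix[, "ID"]
  absent <- setdiff(panel$rsid, ids)
  if (length(absent) > 0L)
    stop("panel rsID(s) absent from VCF: ", paste(absent, collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  counts <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(panel),
                   dimnames = list(colnames(gt), panel$rsid))
  for (i in seq_len(nrow(panel))) {
    row <- match(panel$rsid[i], ids)
    ref <- fix[row, "REF"]; alt <- fix[row, "ALT"]
    if (grepl(",", alt))
      stop("multi-allelic site not supported: ", panel$rsid[i])
    if (nchar(ref) != 1L || nchar(alt) != 1L)
      stop("non-SNP record at ", panel$rsid[i])
    risk <- panel$risk_allele[i]
    if (!risk %in% c(ref, alt))
      stop("risk allele ", risk, " for ", panel$rsid[i],
           " matches neither REF (", ref, ") nor ALT (", alt, ")")
    g <- if (is.null(dim(gt))) gt else gt[row, ]
    alt_dose <- vapply(strsplit(g, "[/|]"), function(a) {
      if (anyNA(a) || any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
    counts[, i] <- if (risk == alt) alt_dose else 2L - alt_dose
  }
  genotype_matrix(counts)
}

#' Write genotypes to the tabular format
#'
#' Writes the subjects-by-rsIDs risk-allele-count table read back losslessly
#' by \code{\link{read_genotypes}}.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param path Output path (TSV).
#' @export
write_genotypes <- function(genotypes, path) {
  df <- data.frame(subject_id = rownames(genotypes),
                   as.data.frame(unclass(genotypes), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact conditional test for a biallelic SNP. Conditional on the
#' observed allele counts, the probabilities of all possible heterozygote
#' counts are enumerated and the p-value is the sum over configurations no
#' more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (non-negative integers; at least one
#'   genotype observed).
#' @return Exact two-sided p-value in [0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # modal configuration, p = 1
#' hwe_exact_test(0, 100, 0)    # gross heterozygote excess
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (length(counts) != 3L || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0L) stop("at least one genotype must be observed")
  nA <- 2L * n_AA + n_Aa               # minor/major orientation irrelevant
  # possible heterozygote counts share the parity of the allele count
  het_max <- min(nA, 2L * n - nA)
  het <- seq.int(nA %% 2L, het_max, by = 2L)
  if (length(het) == 1L) return(1)
  naa_ <- (2L * n - nA - het) / 2L
  nAA_ <- (nA - het) / 2L
  # conditional log-probability: multinomial x 2^het over choose(2n, nA)
  logp <- lfactorial(n) - lfactorial(nAA_) - lfactorial(het) -
    lfactorial(naa_) + het * log(2) -
    (lfactorial(2L * n) - lfactorial(nA) - lfactorial(2L * n - nA))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, het)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Hardy-Weinberg QC over a genotype matrix
#'
#' Applies \code{\link{hwe_exact_test}} to every SNP column, treating the
#' risk-allele count as the genotype (2 = homozygous risk). P-values are
#' reported without automatic exclusion; rejection thresholds are left to
#' the analyst.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @return Data.frame with columns \code{rsid}, \code{n_AA} (homozygous
#'   risk), \code{n_Aa}, \code{n_aa}, \code{p_exact}.
#' @export
hwe_qc <- function(genotypes) {
  res <- lapply(colnames(genotypes), function(rs) {
    x <- genotypes[, rs]
    x <- x[!is.na(x)]
    data.frame(rsid = rs,
               n_AA = sum(x == 2L), n_Aa = sum(x == 1L), n_aa = sum(x == 0L),
               p_exact = hwe_exact_test(sum(x == 2L), sum(x == 1L),
                                        sum(x == 0L)))
  })
  do.call(rbind, res)
}

#' Complete-case filter over genotypes and phenotypes
#'
#' Retains only subjects with a complete genotype row and non-missing values
#' for all required phenotype columns, mirroring availability-based cohort
#' selection. No imputation is performed.
#'
#' @param genotypes A \code{genotype_matrix}.
#' @param phenotypes Data.frame with a \code{subject_id} column.
#' @param required Phenotype columns that must be non-missing.
#' @return List with elements \code{genotypes}, \code{phenotypes} (aligned,
#'   filtered) and \code{n_removed}.
#' @export
filter_complete <- function(genotypes, phenotypes,
                            required = setdiff(names(phenotypes),
                                               "subject_id")) {
  stopifnot("subject_id" %in% names(phenotypes))
  ids <- intersect(rownames(genotypes), phenotypes$subject_id)
  if (length(ids) == 0L) stop("no subjects shared between genotypes and phenotypes")
  g <- genotypes[ids, , drop = FALSE]
  p <- phenotypes[match(ids, phenotypes$subject_id), , drop = FALSE]
  complete_g <- rowSums(is.na(g)) == 0L
  complete_p <- stats::complete.cases(p[, required, drop = FALSE])
  keep <- complete_g & complete_p
  if (!any(keep))
    stop("no subjects with complete genotype and phenotype data")
  n_removed <- sum(!keep)
  message(n_removed, " subject(s) removed by complete-case filter")
  list(genotypes = genotype_matrix(g[keep, , drop = FALSE]),
       phenotypes = p[keep, , drop = FALSE],
       n_removed = n_removed)
}
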