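# Independent oracles and small fixture builders used across tests.

# Exact HWE p-value by the heterozygote-count recurrence: conditional on
# allele counts, P(h+2)/P(h) = 4*nAA(h)*naa(h) / ((h+2)*(h+1)). This is a
# numerically different route from the package's log-factorial enumeration.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2L * n_AA + n_Aa
  hets <- seq.int(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  if (length(hets) == 1L) return(1)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (k in 2:length(hets)) {
    h <- hets[k - 1L]
    probs[k] <- probs[k - 1L] * 4 * ((nA - h) / 2) * ((2 * n - nA - h) / 2) /
      ((h + 2) * (h + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hets)]
  min(1, sum(probs[probs <= obs * (1 + 1e-9)]))
}

# Write a panel definition file and load it.
make_panel <- function(ors,
                       rsids = paste0("rs", seq_along(ors)),
                       genes = paste0("G", seq_along(ors)),
                       risk = rep("A", length(ors)),
                       other = rep("G", length(ors)),
                       secretion = rep(TRUE, length(ors)),
                       freqs = rep(0.3, length(ors))) {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(rsid = rsids, gene = genes, risk_allele = risk,
                   other_allele = other, or_literature = ors,
                   secretion_related = secretion, risk_allele_freq = freqs)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_panel(path)
}

# Small synthetic cohort -> ready-to-model analysis table.
small_analysis_table <- function(seed, n = 1442, ...) {
  co <- generate_cohort(cohort_config(seed = seed, n_subjects = n, ...))
  suppressMessages(suppressWarnings(
    build_analysis_table(co$genotypes, co$phenotypes, co$panel)))$data
}
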