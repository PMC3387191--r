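test_that("tabular genotype format round-trips exactly", {
  set.seed(42)
  panel <- default_panel()
  m <- matrix(sample(0:2, 20 * 9, replace = TRUE), 20, 9,
              dimnames = list(sprintf("P%02d", 1:20), panel$rsid))
  m[3, 5] <- NA
  g <- genotype_matrix(m)
  path <- tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  g2 <- read_genotypes(path, panel)
  expect_identical(unclass(g2), unclass(g))
})

test_that("VCF dosage maps onto the risk allele, inverting REF-risk sites", {
  panel <- make_panel(c(1.2, 1.3), risk = c("A", "C"), other = c("G", "T"))
  # site rs1: risk allele is REF -> count = 2 - ALT dosage
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
           paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "0/1", "1/1"), collapse = "\t"),
           paste(c("2", "200", "rs2", "T", "C", ".", "PASS", ".", "GT",
                   "0/1", "1/1", "./."), collapse = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  g <- read_genotypes(path, panel)
  # rs1: ALT dosages 0,1,2 but risk = REF -> 2,1,0
  expect_equal(unname(g[, "rs1"]), c(2L, 1L, 0L))
  expect_equal(unname(g[, "rs2"]), c(1L, 2L, NA))
})

test_that("VCF reader rejects missing panel rsIDs", {
  panel <- make_panel(c(1.2, 1.3))
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "s1"), collapse = "\t"),
           paste(c("1", "100", "rs1", "G", "A", ".", "PASS", ".", "GT",
                   "0/0"), collapse = "\t"))
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_error(read_genotypes(path, panel), "rs2")
})

test_that("HWE exact test matches spec examples and rejects bad input", {
  expect_gt(hwe_exact_test(25, 50, 25), 0.97)   # modal configuration
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_lt(hwe_exact_test(0, 100, 0), 1e-10)   # extreme het excess
  expect_equal(hwe_exact_test(5, 0, 0), 1)      # monomorphic
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one")
})

test_that("HWE test holds its size on genotypes simulated under HWE", {
  set.seed(7)
  n <- 500
  reps <- 2000
  x <- matrix(rbinom(n * reps, 2, 0.3), n, reps)
  pvals <- apply(x, 2, function(g)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0)))
  rate <- mean(pvals < 0.05)
  # exact conditional tests are conservative: at or slightly under nominal
  expect_lt(rate, 0.065)
  expect_gt(rate, 0.02)
})

test_that("complete-case filter drops exactly the incomplete subjects", {
  panel <- make_panel(c(1.2, 1.3))
  m <- matrix(1L, 10, 2, dimnames = list(paste0("S", 1:10), panel$rsid))
  m[4, 1] <- NA
  ph <- data.frame(subject_id = paste0("S", 1:10), bmi = 25)
  res <- suppressMessages(filter_complete(genotype_matrix(m), ph))
  expect_equal(nrow(res$genotypes), 9L)
  expect_equal(res$n_removed, 1L)
  expect_false("S4" %in% res$phenotypes$subject_id)
  # no missing data -> identity
  m[4, 1] <- 1L
  res2 <- suppressMessages(filter_complete(genotype_matrix(m), ph))
  expect_equal(res2$n_removed, 0L)
  # all subjects missing a required phenotype -> error
  ph$bmi <- NA_real_
  expect_error(suppressMessages(filter_complete(genotype_matrix(m), ph)),
               "complete")
})
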