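test_that("expression TSV round-trips bit-identically and GCT agrees", {
  tsv <- write_toy_expression_tsv(withr::local_tempfile(fileext = ".tsv"))
  em <- read_expression(tsv, format = "tsv")
  expect_s3_class(em, "ExpressionMatrix")
  expect_identical(dim(em), c(2L, 3L))
  expect_identical(unname(em$values), matrix(as.numeric(1:6), 2, 3,
                                             byrow = TRUE))
  expect_identical(em$state, "rpkm")

  out <- withr::local_tempfile(fileext = ".tsv")
  write_expression(em, out)
  em2 <- read_expression(out)
  expect_identical(em2$values, em$values)

  gct <- withr::local_tempfile(fileext = ".gct")
  writeLines(c("#1.2", "2\t3",
               "Name\tDescription\tS1\tS2\tS3",
               "G1\tna\t1\t2\t3",
               "G2\tna\t4\t5\t6"), gct)
  emg <- read_expression(gct, format = "gct")
  expect_equal(emg$values, em$values)
})

test_that("expression reader rejects duplicates and non-numeric cells", {
  tsv <- write_toy_expression_tsv(withr::local_tempfile(fileext = ".tsv"),
                                  gene_ids = c("G1", "G1"))
  expect_error(read_expression(tsv), "G1")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS1\tS2", "G1\t1\toops", "G2\t3\t4"), bad)
  expect_error(read_expression(bad), "G1")
})

test_that("covariate table is parsed and typed with documented defaults", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tsex\tbmi",
               "S1\t45\tF\t24.3",
               "S2\t60\tM\t31.0"), path)
  covs <- read_covariates(path)
  expect_identical(covs$age, c(45, 60))
  expect_identical(covs$sex, c("female", "male"))
  expect_identical(covs$ancestry, c("unknown", "unknown"))
  expect_identical(covs$region, c("unknown", "unknown"))

  nobmi <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tsex", "S1\t45\tF"), nobmi)
  expect_error(read_covariates(nobmi), "missing column: bmi")

  badage <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tsex\tbmi", "S9\tforty\tF\t22"), badage)
  expect_error(read_covariates(badage), "S9")

  # numeric dbGaP coding: 1 = male, 2 = female
  coded <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tage\tsex\tbmi", "S1\t50\t1\t25", "S2\t51\t2\t26"),
             coded)
  expect_identical(read_covariates(coded)$sex, c("male", "female"))
})

test_that("VCF genotypes are coded as non-reference allele counts", {
  vcf <- write_toy_vcf(withr::local_tempfile(fileext = ".vcf"))
  expect_message(geno <- read_genotypes_vcf(vcf, c("S1", "S2", "S3", "S4")),
                 "multiallelic")
  expect_identical(attr(geno, "n_multiallelic_skipped"), 1L)
  expect_identical(geno$snp_ids, c("rs1", "rs2"))
  # 0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> NA
  expect_identical(unname(geno$codes["rs1", ]), c(0, 1, 2, NA))
  # phasing ignored
  expect_identical(unname(geno$codes["rs2", ]), c(1, 2, 0, 1))
  # sample order follows the request
  geno_rev <- suppressMessages(
    read_genotypes_vcf(vcf, c("S4", "S1")))
  expect_identical(unname(geno_rev$codes["rs1", ]), c(NA, 0))

  expect_error(suppressMessages(read_genotypes_vcf(vcf, c("S1", "SX"))), "SX")
})

test_that("genotype coding conserves allele counts and VCF writing round-trips", {
  sim <- simulate_dataset(12, 10, 8, seed = 5)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(sim$geno, path)
  back <- suppressMessages(read_genotypes_vcf(path, sim$geno$sample_ids))
  expect_equal(unname(back$codes), unname(sim$geno$codes))
  # diploid conservation: non-ref count + ref count = 2
  gt <- back$codes[!is.na(back$codes)]
  expect_true(all((2 - gt) + gt == 2))
  expect_true(all(gt %in% 0:2))
})

test_that("GMT parsing keys sets by term, de-duplicates genes and validates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GO:0001309\tage-dependent telomere shortening\tTERF1\tTERF2",
               "SET2\tdesc\tA\tB\tA"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2L)
  expect_identical(sets[["GO:0001309"]], c("TERF1", "TERF2"))
  expect_length(sets[["SET2"]], 2L)   # duplicate counted once

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("GOOD\tdesc\tA", "SHORT\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_warning(sets0 <- read_gmt(empty), "empty")
  expect_length(sets0, 0L)

  # write/read round trip preserves membership
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_identical(unclass(read_gmt(out))[], unclass(sets)[])
})
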