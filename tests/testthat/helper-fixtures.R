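# small programmatic fixtures shared across test files

write_toy_expression_tsv <- function(path, gene_ids = c("G1", "G2"),
                                     sample_ids = c("S1", "S2", "S3"),
                                     values = matrix(1:6, 2, 3, byrow = TRUE)) {
  lines <- c(paste(c("gene_id", sample_ids), collapse = "\t"),
             vapply(seq_along(gene_ids), function(i) {
               paste(c(gene_ids[i], values[i, ]), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

write_toy_covariates_tsv <- function(path, n = 6, with_bmi = TRUE,
                                     with_ancestry = TRUE) {
  header <- c("sample_id", "age", "sex", if (with_bmi) "bmi",
              if (with_ancestry) "ancestry")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(sprintf("S%d", i), 40 + i, c("M", "F")[1 + i %% 2],
            if (with_bmi) 24 + i / 10,
            if (with_ancestry) c("EUR", "AFR")[1 + (i > 4)]),
          collapse = "\t")
  }, "")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  path
}

write_toy_vcf <- function(path,
                          samples = c("S1", "S2", "S3", "S4"),
                          records = list(
                            c("1", "100", "rs1", "A", "G", "0/0", "0/1", "1/1", "./."),
                            c("1", "200", "rs2", "C", "T", "0|1", "1|1", "0/0", "0/1"),
                            c("1", "300", "rs3", "G", "A,T", "0/0", "0/1", "0/2", "1/1"))) {
  lines <- c("##fileformat=VCFv4.2",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             vapply(records, function(r) {
               paste(c(r[1:5], ".", "PASS", ".", "GT", r[-(1:5)]),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  path
}

rand_expression <- function(genes = 20, samples = 10, seed = 1,
                            state = "lognorm") {
  set.seed(seed)
  vals <- matrix(rnorm(genes * samples, 5, 1), genes, samples,
                 dimnames = list(sprintf("G%03d", seq_len(genes)),
                                 sprintf("S%03d", seq_len(samples))))
  expression_matrix(vals, state = state)
}

toy_covs <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.frame(sample_id = sprintf("S%03d", seq_len(n)),
             age = sample(20:70, n, replace = TRUE),
             sex = sample(c("male", "female"), n, replace = TRUE),
             bmi = rnorm(n, 27, 3),
             ancestry = "EUR", region = "r1",
             stringsAsFactors = FALSE)
}

# do two cluster labelings induce the same partition?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}
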