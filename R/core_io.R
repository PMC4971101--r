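#' Expression matrix container
#'
#' A genes x samples numeric matrix together with a processing-state tag
#' recording where the data stands in the pipeline: `"rpkm"` (raw
#' length/depth-normalized values), `"lognorm"` (quantile-normalized and
#' log2-transformed) or `"residual"` (confounder-corrected residuals).
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names and no missing or non-finite entries.
#' @param state one of `"rpkm"`, `"lognorm"`, `"residual"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `sample_ids` and `state`.
#' @export
expression_matrix <- function(values, state = c("rpkm", "lognorm", "residual")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("values must carry gene row names and sample column names")
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene ", gene_ids[bad[1L]],
         ", sample ", sample_ids[bad[2L]])
  }
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, state = state),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", length(x$gene_ids), "genes x",
      length(x$sample_ids), "samples, state =", x$state, "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or GCT
#'
#' TSV layout: a header row of sample ids, first column gene ids. GCT 1.2
#' layout: a `#1.2` version line, a dimensions line, then a table whose
#' first two columns are `Name` and `Description`. Lines starting with `#`
#' in a TSV are treated as comments.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return An [expression_matrix()] with `state = "rpkm"`.
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    if (!startsWith(header[1L], "#1.2")) {
      stop("not a GCT 1.2 file (missing '#1.2' version line): ", path)
    }
    tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    mat <- tab[, -(1:2), drop = FALSE]
  } else {
    tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    mat <- tab[, -1L, drop = FALSE]
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (anyNA(v) && !all(is.na(mat[[j]]) == is.na(v))) {
      i <- which(is.na(v) & !is.na(mat[[j]]))[1L]
      stop("non-numeric expression value at row ", i, " (gene ",
           gene_ids[i], "), column ", colnames(mat)[j])
    }
    mat[[j]] <- v
  }
  values <- as.matrix(mat)
  rownames(values) <- gene_ids
  expression_matrix(values, state = "rpkm")
}

#' Write an expression matrix as TSV
#'
#' Writes genes in rows with a header of sample ids, preceded by a comment
#' line carrying the package version and an optional configuration hash so
#' every result table records its provenance.
#'
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param config_hash optional string recorded in the comment line.
#' @export
write_expression <- function(expr, path, config_hash = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config_hash), con)
  tab <- data.frame(gene_id = expr$gene_ids, expr$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

provenance_line <- function(config_hash = NULL) {
  v <- as.character(utils::packageVersion("brainage"))
  if (is.null(config_hash)) {
    sprintf("# brainage %s", v)
  } else {
    sprintf("# brainage %s config=%s", v, config_hash)
  }
}

#' Read a sample covariate table
#'
#' Expects a TSV with required columns `sample_id`, `age`, `sex`, `bmi` and
#' optional `ischemic_time`, `ancestry`, `region`. Sex is parsed from
#' `M`/`F`, `male`/`female` or `1`/`2` (1 = male, 2 = female, the dbGaP
#' convention). Missing `ancestry` or `region` columns are filled with
#' `"unknown"`.
#'
#' @param path file path.
#' @return A data frame (one row per sample) with typed columns.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  for (col in c("sample_id", "age", "sex", "bmi")) {
    if (!col %in% names(tab)) stop("missing column: ", col)
  }
  age <- suppressWarnings(as.numeric(tab$age))
  if (anyNA(age)) {
    stop("unparseable age for sample ", tab$sample_id[which(is.na(age))[1L]])
  }
  bmi <- suppressWarnings(as.numeric(tab$bmi))
  if (anyNA(bmi)) {
    stop("unparseable bmi for sample ", tab$sample_id[which(is.na(bmi))[1L]])
  }
  out <- data.frame(
    sample_id = tab$sample_id,
    age = age,
    sex = parse_sex(tab$sex, tab$sample_id),
    bmi = bmi,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id)) {
    stop("duplicate sample id: ", out$sample_id[duplicated(out$sample_id)][1L])
  }
  if ("ischemic_time" %in% names(tab)) {
    out$ischemic_time <- suppressWarnings(as.numeric(tab$ischemic_time))
  }
  out$ancestry <- if ("ancestry" %in% names(tab)) tab$ancestry else "unknown"
  out$region <- if ("region" %in% names(tab)) tab$region else "unknown"
  out
}

parse_sex <- function(x, ids) {
  key <- tolower(trimws(x))
  map <- c(m = "male", male = "male", "1" = "male",
           f = "female", female = "female", "2" = "female")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop("unparseable sex '", x[which(is.na(out))[1L]], "' for sample ",
         ids[which(is.na(out))[1L]])
  }
  out
}

#' Write a covariate table as TSV
#' @param covs data frame from [read_covariates()] or the simulator.
#' @param path output path.
#' @export
write_covariates <- function(covs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(), con)
  utils::write.table(covs, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype matrix container
#'
#' SNP x sample allele-dosage codes: 0, 1 or 2 non-reference alleles, `NA`
#' for missing calls.
#'
#' @param codes integer matrix (SNPs x samples) with entries in
#'   `{0, 1, 2, NA}` and SNP/sample dimnames.
#' @param snp_meta data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, one row per SNP in `codes` order.
#' @return An object of class `GenotypeMatrix`.
#' @export
genotype_matrix <- function(codes, snp_meta) {
  stopifnot(is.matrix(codes), nrow(codes) == nrow(snp_meta))
  ok <- codes %in% c(0, 1, 2) | is.na(codes)
  if (!all(ok)) stop("genotype codes must be 0, 1, 2 or NA")
  if (anyDuplicated(rownames(codes))) {
    stop("duplicate snp id: ", rownames(codes)[duplicated(rownames(codes))][1L])
  }
  structure(list(codes = codes,
                 snp_ids = rownames(codes),
                 sample_ids = colnames(codes),
                 snp_meta = snp_meta),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", length(x$snp_ids), "SNPs x",
      length(x$sample_ids), "samples\n")
  invisible(x)
}

#' Read genotypes from a VCF into 0/1/2 dosage codes
#'
#' Each diploid GT call is coded as its count of non-reference alleles;
#' `./.` becomes `NA`; phasing is ignored. Only biallelic records are
#' retained; multiallelic records are skipped and counted (the count is
#' attached as attribute `n_multiallelic_skipped` and reported via a
#' message).
#'
#' @param path a VCF file (plain or bgzipped) with a GT field.
#' @param samples sample ids to extract, in the desired column order.
#' @return A [genotype_matrix()] whose columns follow `samples`.
#' @export
read_genotypes_vcf <- function(path, samples) {
  if (!file.exists(path)) stop("no such file: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT, fixed = TRUE) & fix$ALT != "."
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(samples, colnames(gt))
  if (length(missing_samples)) {
    stop("sample absent from VCF: ", missing_samples[1L])
  }
  gt <- gt[biallelic, samples, drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  codes <- apply(gt, c(1, 2), gt_to_dosage)
  snp_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", fix$POS), fix$ID)
  rownames(codes) <- snp_ids
  if (n_skipped > 0) {
    message(n_skipped, " multiallelic record(s) skipped")
  }
  meta <- data.frame(snp_id = snp_ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  out <- genotype_matrix(codes, meta)
  attr(out, "n_multiallelic_skipped") <- n_skipped
  out
}

gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1L]]
  if (any(alleles == ".")) return(NA_real_)
  sum(alleles != "0")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: `term_id TAB description TAB gene1 TAB gene2 ...`. Genes
#' duplicated within a set are counted once.
#'
#' @param path file path.
#' @return An object of class `GeneSetCollection`: a named list of gene-id
#'   character vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_collection(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  gene_set_collection(sets, descriptions = stats::setNames(desc, ids))
}

#' Gene-set collection constructor
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional named character vector of set descriptions.
#' @return An object of class `GeneSetCollection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (anyDuplicated(names(sets))) {
    stop("duplicate term id: ", names(sets)[duplicated(names(sets))][1L])
  }
  if (any(lengths(sets) == 0L)) {
    stop("empty gene list for term: ", names(sets)[lengths(sets) == 0L][1L])
  }
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat("GeneSetCollection:", length(x), "sets, median size",
      if (length(x)) stats::median(lengths(x)) else 0, "\n")
  invisible(x)
}

#' Write a GMT file
#' @param sets a [gene_set_collection()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write an association table as TSV with a provenance comment line
#' @param tab data frame of per-unit statistics.
#' @param path output path.
#' @param config_hash optional string recorded in the comment line.
#' @export
write_assoc_table <- function(tab, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(config_hash), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits unphased diploid GT calls reconstructed from dosage codes
#' (0 -> 0/0, 1 -> 0/1, 2 -> 1/1, NA -> ./.).
#'
#' @param geno a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "GenotypeMatrix"))
  gt_strings <- c("0/0", "0/1", "1/1")
  meta <- geno$snp_meta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$sample_ids), collapse = "\t")
  ), con)
  for (i in seq_along(geno$snp_ids)) {
    calls <- ifelse(is.na(geno$codes[i, ]), "./.",
                    gt_strings[geno$codes[i, ] + 1L])
    writeLines(paste(c(meta$chrom[i], meta$pos[i], meta$snp_id[i],
                       meta$ref[i], meta$alt[i], ".", "PASS", ".", "GT",
                       calls), collapse = "\t"), con)
  }
  invisible(path)
}
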