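#' Default per-region pipeline configuration
#'
#' Every analysis threshold is a config key with the study value as
#' default: 10% low-expression filter, up to 15 hidden factors, factor
#' age-filter P 0.05, FDR tiers 1/5/10%, MAF 0.15, nominal interaction
#' report P 1e-5, young/old boundary 60, MCD subset fraction 0.75.
#'
#' @param ... overrides for individual keys.
#' @return Config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    expr = NULL, covs = NULL, vcf = NULL, gmt = NULL,
    region = "*", ancestry = "*",
    low_frac = 0.10, pseudocount = 1,
    k_factors = 15, age_filter_p = 0.05,
    fdr_levels = c(0.01, 0.05, 0.10),
    pathway_k = 5,
    n_genes_interaction = 2000, maf_min = 0.15, p_report = 1e-5,
    cis_window = 1e6,
    dv_boundary = 60, dv_fdr = 0.05, mcd_fraction = 0.75,
    seed = 1, outdir = "brainage_out",
    stages = c("preprocess", "correct", "age_scan", "pathway_scan",
               "gxa_scan", "dv_scan"),
    gene_pos = NULL
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

## hash of the analysis parameters (the output location does not alter what
## is computed, so it is excluded)
config_hash <- function(config) {
  config <- config[setdiff(names(config), "outdir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[order(names(config))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full per-region analysis from one configuration
#'
#' Orchestrates preprocess -> confounder correction -> age scan ->
#' pathway scan -> genotype-by-age scan -> dispersion scans, writing one
#' TSV per stage plus a run manifest recording the config hash, package
#' version and per-stage row counts. Stages not named in `config$stages`
#' (or lacking their inputs, e.g. no VCF) are skipped. With
#' `resume = TRUE`, a stage whose output file already exists and whose
#' upstream stages were not recomputed is reused instead of recomputed.
#'
#' @param config a [default_config()] list or the path to a YAML file of
#'   the same keys.
#' @return Invisibly, a list with the manifest data frame, its file path
#'   and the manifest hash.
#' @param resume reuse existing stage outputs where valid (default FALSE).
#' @export
run_region <- function(config, resume = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- default_config()
  cfg[names(config)] <- config
  config <- cfg
  hash <- config_hash(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  recomputed <- character(0)

  stage_path <- function(stage) file.path(config$outdir, paste0(stage, ".tsv"))
  note <- function(stage, rows, params, reused = FALSE) {
    manifest[[stage]] <<- data.frame(
      stage = stage, rows = rows, params = params,
      reused = reused, stringsAsFactors = FALSE)
  }
  want <- function(stage) stage %in% config$stages
  can_resume <- function(stage, deps) {
    resume && file.exists(stage_path(stage)) &&
      !any(deps %in% recomputed)
  }

  expr_raw <- if (inherits(config$expr, "ExpressionMatrix")) config$expr
    else read_expression(config$expr)
  covs_all <- if (is.data.frame(config$covs)) config$covs
    else read_covariates(config$covs)

  ## preprocess
  flt <- filter_samples(expr_raw, covs_all, config$ancestry, config$region)
  covs <- flt$covs
  if (want("preprocess")) {
    if (can_resume("preprocess", character(0))) {
      lognorm <- read_expression(stage_path("preprocess"))
      lognorm <- expression_matrix(lognorm$values, state = "lognorm")
      note("preprocess", length(lognorm$gene_ids), "resumed", reused = TRUE)
    } else {
      lognorm <- preprocess_expression(flt$expr, fraction = config$low_frac,
                                       pseudocount = config$pseudocount)
      write_expression(lognorm, stage_path("preprocess"), hash)
      recomputed <- c(recomputed, "preprocess")
      note("preprocess", length(lognorm$gene_ids),
           sprintf("low_frac=%g pseudocount=%g", config$low_frac,
                   config$pseudocount))
    }
  } else {
    lognorm <- expression_matrix(flt$expr$values, state = "lognorm")
  }

  ## confounder correction
  resid <- lognorm
  kept_scores <- NULL
  if (want("correct")) {
    K <- clamp_K(config$k_factors, lognorm, covs)
    if (can_resume("correct", "preprocess")) {
      resid <- read_expression(stage_path("correct"))
      resid <- expression_matrix(resid$values, state = "residual")
      sc <- utils::read.delim(file.path(config$outdir, "factor_scores.tsv"),
                              comment.char = "#")
      kept_scores <- as.matrix(sc[, -1L, drop = FALSE])
      rownames(kept_scores) <- sc[[1L]]
      note("correct", length(resid$gene_ids), "resumed", reused = TRUE)
    } else {
      cc <- correct_confounders(lognorm, covs, K = K,
                                p_threshold = config$age_filter_p)
      resid <- cc$expr
      write_expression(resid, stage_path("correct"), hash)
      factors_tab <- data.frame(
        factor = seq_len(cc$model$K),
        age_corr = cc$model$age_corr,
        age_corr_p = cc$model$age_corr_p,
        kept = cc$model$kept)
      write_assoc_table(factors_tab,
                        file.path(config$outdir, "factors.tsv"), hash)
      kept_scores <- kept_factor_scores(cc$model)
      write_assoc_table(data.frame(sample_id = covs$sample_id, kept_scores),
                        file.path(config$outdir, "factor_scores.tsv"), hash)
      recomputed <- c(recomputed, "correct")
      note("correct", length(resid$gene_ids),
           sprintf("K=%d kept=%d age_filter_p=%g", K,
                   sum(cc$model$kept), config$age_filter_p))
    }
  }

  ## per-gene age scan
  if (want("age_scan")) {
    if (can_resume("age_scan", c("preprocess", "correct"))) {
      note("age_scan", nrow(utils::read.delim(stage_path("age_scan"),
                                              comment.char = "#")),
           "resumed", reused = TRUE)
    } else {
      # full regression: expression on age + sex + BMI + kept factors
      calls <- call_age_genes(age_scan(lognorm, covs, factors = kept_scores),
                              fdr_levels = config$fdr_levels)
      write_assoc_table(calls, stage_path("age_scan"), hash)
      recomputed <- c(recomputed, "age_scan")
      note("age_scan", nrow(calls),
           paste0("fdr=", paste(config$fdr_levels, collapse = ",")))
    }
  }

  ## pathway factor scan
  if (want("pathway_scan") && !is.null(config$gmt)) {
    sets <- if (inherits(config$gmt, "GeneSetCollection")) config$gmt
      else read_gmt(config$gmt)
    if (can_resume("pathway_scan", c("preprocess", "correct"))) {
      note("pathway_scan",
           nrow(utils::read.delim(stage_path("pathway_scan"),
                                  comment.char = "#")),
           "resumed", reused = TRUE)
    } else {
      ptab <- pathway_scan(resid, sets, covs$age, K = config$pathway_k)
      write_assoc_table(ptab, stage_path("pathway_scan"), hash)
      recomputed <- c(recomputed, "pathway_scan")
      note("pathway_scan", nrow(ptab), sprintf("K=%d", config$pathway_k))
    }
  }

  ## genotype-by-age scan
  if (want("gxa_scan") && !is.null(config$vcf)) {
    geno <- if (inherits(config$vcf, "GenotypeMatrix")) config$vcf
      else read_genotypes_vcf(config$vcf, covs$sample_id)
    if (can_resume("gxa_scan", c("preprocess", "correct"))) {
      note("gxa_scan", nrow(utils::read.delim(stage_path("gxa_scan"),
                                              comment.char = "#")),
           "resumed", reused = TRUE)
    } else {
      gtab <- interaction_scan(lognorm, geno, covs,
                               n_genes = config$n_genes_interaction,
                               maf_min = config$maf_min,
                               p_report = config$p_report,
                               seed = config$seed,
                               gene_pos = config$gene_pos,
                               cis_window = config$cis_window,
                               factors = kept_scores)
      write_assoc_table(gtab, stage_path("gxa_scan"), hash)
      recomputed <- c(recomputed, "gxa_scan")
      note("gxa_scan", nrow(gtab),
           sprintf("maf=%g p_report=%g seed=%d", config$maf_min,
                   config$p_report, as.integer(config$seed)))
    }
  }

  ## dispersion scans
  if (want("dv_scan")) {
    groups <- assign_age_groups(covs$age, boundary = config$dv_boundary)
    if (can_resume("dv_scan", c("preprocess", "correct"))) {
      note("dv_scan", nrow(utils::read.delim(stage_path("dv_scan"),
                                             comment.char = "#")),
           "resumed", reused = TRUE)
    } else {
      dtab <- dv_scan(resid, groups, fdr = config$dv_fdr)
      write_assoc_table(dtab, stage_path("dv_scan"), hash)
      recomputed <- c(recomputed, "dv_scan")
      note("dv_scan", nrow(dtab),
           sprintf("boundary=%d fdr=%g", as.integer(config$dv_boundary),
                   config$dv_fdr))
    }
    if (!is.null(config$gmt)) {
      sets <- if (inherits(config$gmt, "GeneSetCollection")) config$gmt
        else read_gmt(config$gmt)
      if (can_resume("dv_set_scan", c("preprocess", "correct"))) {
        note("dv_set_scan",
             nrow(utils::read.delim(stage_path("dv_set_scan"),
                                    comment.char = "#")),
             "resumed", reused = TRUE)
      } else {
        stab <- suppressMessages(
          dv_geneset_scan(resid, sets, groups, fdr = config$dv_fdr,
                          seed = config$seed))
        write_assoc_table(stab, stage_path("dv_set_scan"), hash)
        recomputed <- c(recomputed, "dv_set_scan")
        note("dv_set_scan", nrow(stab),
             sprintf("boundary=%d fdr=%g", as.integer(config$dv_boundary),
                     config$dv_fdr))
      }
    }
  }

  mtab <- do.call(rbind, manifest)
  mtab <- cbind(config_hash = hash,
                version = as.character(utils::packageVersion("brainage")),
                mtab)
  mpath <- file.path(config$outdir, "manifest.tsv")
  utils::write.table(mtab, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(manifest = mtab, path = mpath,
                 manifest_hash = unname(tools::md5sum(mpath))))
}
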