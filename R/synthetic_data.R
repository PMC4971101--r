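#' Generator settings for the synthetic cohort
#'
#' Defaults describe a single brain-region cohort of the kind the pipeline
#' targets: donors aged 20-70, a modest fraction of genes with a linear age
#' effect on the mean, a smaller fraction with age-group-dependent
#' variance, a couple of SNP-gene pairs with genotype-by-age interactions,
#' and structured hidden confounders on top of i.i.d. log-scale noise.
#'
#' @param frac_age_genes fraction of genes with a true linear age effect
#'   (default 0.10).
#' @param age_effect absolute age slope in log2 units per year for planted
#'   genes, sign randomized (default 0.02, i.e. one log2 unit across the
#'   50-year age span).
#' @param frac_dv_genes fraction of genes with age-group-dependent noise SD
#'   (default 0.05).
#' @param dv_sd_ratio old-group / young-group noise SD ratio for DV genes
#'   (default 3).
#' @param dv_boundary age boundary separating the two noise regimes
#'   (default 60).
#' @param n_interaction_pairs SNP-gene pairs with a planted
#'   genotype-by-age interaction (default 2).
#' @param interaction_slope interaction coefficient in log2 units per
#'   allele per year (default 0.02).
#' @param n_confounders number of hidden structured factors H (default 2).
#' @param confounder_age_r Pearson correlation of each hidden factor with
#'   age (recycled to H; default 0).
#' @param confounder_loading_sd SD of per-gene factor loadings (default 0.3).
#' @param noise_sd baseline residual SD on the log2 scale (default 0.5).
#' @param maf_range range of the uniform MAF distribution (default
#'   0.05-0.5).
#' @param sex_effect_sd,bmi_effect_sd SDs of per-gene sex and BMI
#'   coefficients (defaults 0.1 and 0.02).
#' @param baseline_mean,baseline_sd distribution of per-gene baseline log2
#'   expression (defaults 5 and 1).
#' @param n_sets,set_size random gene sets emitted with the data (defaults
#'   20 sets of 10).
#' @param pseudocount offset used when mapping log2 values back to the
#'   RPKM-like scale (default 1, matching the preprocessing default).
#' @param age_gene_ids optional explicit gene ids to plant age effects on
#'   (overrides `frac_age_genes`; used by the region-panel generator).
#' @return A config list, validated.
#' @export
sim_config <- function(frac_age_genes = 0.10, age_effect = 0.02,
                       frac_dv_genes = 0.05, dv_sd_ratio = 3,
                       dv_boundary = 60,
                       n_interaction_pairs = 2L, interaction_slope = 0.02,
                       n_confounders = 2L, confounder_age_r = 0,
                       confounder_loading_sd = 0.3,
                       noise_sd = 0.5, maf_range = c(0.05, 0.5),
                       sex_effect_sd = 0.1, bmi_effect_sd = 0.02,
                       baseline_mean = 5, baseline_sd = 1,
                       n_sets = 20L, set_size = 10L, pseudocount = 1,
                       age_gene_ids = NULL) {
  cfg <- as.list(environment())
  if (is.null(age_gene_ids) && frac_age_genes + frac_dv_genes > 1) {
    stop("planted fractions exceed 1")
  }
  if (dv_sd_ratio <= 0 || noise_sd <= 0) stop("SDs must be positive")
  cfg
}

#' Simulate a GTEx-like single-region dataset with known ground truth
#'
#' Donor ages are uniform integers on 20-70, sex is Bernoulli(0.5), BMI is
#' Normal(27, 4) truncated below at 15, and genotypes are Hardy-Weinberg
#' draws at MAFs uniform over the configured range. Expression is built on
#' the log2 scale as baseline + planted age / sex / BMI / hidden-factor /
#' interaction effects + Gaussian noise whose SD switches between age
#' groups for DV genes, then mapped to an RPKM-like scale via
#' `2^x - pseudocount` (floored at 0) so the standard preprocessing
#' round-trips. All planted effects are recorded in the truth object.
#'
#' @param n_samples number of donors (default 80, within the 54-110 range
#'   of the study's regional cohorts).
#' @param n_genes number of genes (default 1000).
#' @param n_snps number of SNPs (default 100).
#' @param config a [sim_config()] list.
#' @param seed integer seed; identical seeds give bit-identical datasets.
#' @param region region label written into the covariate table.
#' @return A list: `expr` ([expression_matrix()], state `"rpkm"`), `covs`
#'   (covariate data frame), `geno` ([genotype_matrix()]), `sets`
#'   ([gene_set_collection()]), `gene_pos` (gene coordinates for cis
#'   pairing) and `truth` (class `SimTruth`).
#' @export
simulate_dataset <- function(n_samples = 80L, n_genes = 1000L,
                             n_snps = 100L, config = sim_config(),
                             seed = 1L, region = "region1") {
  with_seed(seed, {
    sample_ids <- sprintf("S%03d", seq_len(n_samples))
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
    snp_ids <- sprintf("rs%04d", seq_len(n_snps))

    age <- sample(20:70, n_samples, replace = TRUE)
    sex <- ifelse(stats::rbinom(n_samples, 1L, 0.5) == 1L, "male", "female")
    bmi <- pmax(stats::rnorm(n_samples, 27, 4), 15)
    covs <- data.frame(sample_id = sample_ids, age = age, sex = sex,
                       bmi = bmi, ancestry = "EUR", region = region,
                       stringsAsFactors = FALSE)

    # genome layout: one chromosome, genes every 100 kb, SNPs uniform
    gene_pos <- data.frame(gene_id = gene_ids, chrom = "1",
                           pos = 1e5 * seq_len(n_genes),
                           stringsAsFactors = FALSE)
    snp_pos <- sort(sample.int(1e5 * n_genes, n_snps))
    maf <- stats::runif(n_snps, config$maf_range[1L], config$maf_range[2L])
    codes <- matrix(stats::rbinom(n_snps * n_samples, 2L, rep(maf, n_samples)),
                    nrow = n_snps, ncol = n_samples,
                    dimnames = list(snp_ids, sample_ids))
    snp_meta <- data.frame(snp_id = snp_ids, chrom = "1", pos = snp_pos,
                           ref = "A", alt = "G", maf_target = maf,
                           stringsAsFactors = FALSE)

    # planted effect assignments (disjoint pools)
    if (!is.null(config$age_gene_ids)) {
      age_genes <- intersect(config$age_gene_ids, gene_ids)
    } else {
      age_genes <- sample(gene_ids, round(config$frac_age_genes * n_genes))
    }
    remaining <- setdiff(gene_ids, age_genes)
    dv_genes <- sample(remaining, round(config$frac_dv_genes * n_genes))
    remaining <- setdiff(remaining, dv_genes)
    n_pairs <- min(config$n_interaction_pairs, length(remaining), n_snps)
    int_genes <- if (n_pairs > 0L) sample(remaining, n_pairs) else character(0)

    alpha <- stats::setNames(
      config$age_effect * sample(c(-1, 1), length(age_genes), replace = TRUE),
      age_genes)
    young_sd <- config$noise_sd
    old_sd <- config$noise_sd * config$dv_sd_ratio
    dv_truth <- data.frame(gene_id = dv_genes,
                           young_sd = rep_len(young_sd, length(dv_genes)),
                           old_sd = rep_len(old_sd, length(dv_genes)),
                           stringsAsFactors = FALSE)

    # each planted interaction SNP is relocated next to its gene so that
    # cis pairing (+/- 1 Mb) finds the pair
    int_pairs <- if (n_pairs > 0L) {
      pair_snps <- sample(snp_ids, n_pairs)
      for (j in seq_len(n_pairs)) {
        snp_meta$pos[snp_meta$snp_id == pair_snps[j]] <-
          gene_pos$pos[gene_pos$gene_id == int_genes[j]] + 1000L
      }
      data.frame(snp_id = pair_snps, gene_id = int_genes,
                 slope = config$interaction_slope, stringsAsFactors = FALSE)
    } else {
      data.frame(snp_id = character(0), gene_id = character(0),
                 slope = numeric(0))
    }

    # hidden structured confounders with a target age correlation
    H <- config$n_confounders
    conf_r <- rep_len(config$confounder_age_r, max(H, 1L))
    fscores <- matrix(0, n_samples, 0L)
    loadings <- matrix(0, n_genes, 0L)
    if (H > 0L) {
      zage <- as.numeric(scale(age))
      fscores <- vapply(seq_len(H), function(h) {
        r <- conf_r[h]
        f <- r * zage + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_samples)
        as.numeric(scale(f))
      }, numeric(n_samples))
      colnames(fscores) <- paste0("H", seq_len(H))
      loadings <- matrix(stats::rnorm(n_genes * H, 0,
                                      config$confounder_loading_sd),
                         n_genes, H, dimnames = list(gene_ids, NULL))
    }

    # assemble log2-scale expression
    mu <- stats::rnorm(n_genes, config$baseline_mean, config$baseline_sd)
    beta <- stats::rnorm(n_genes, 0, config$sex_effect_sd)
    gamma <- stats::rnorm(n_genes, 0, config$bmi_effect_sd)
    sex_num <- sex_to_numeric(sex)
    X <- matrix(mu, n_genes, n_samples,
                dimnames = list(gene_ids, sample_ids)) +
      outer(beta, sex_num) + outer(gamma, bmi - mean(bmi))
    if (H > 0L) X <- X + loadings %*% t(fscores)
    X[age_genes, ] <- X[age_genes, , drop = FALSE] +
      outer(alpha, age - mean(age))
    if (n_pairs > 0L) {
      for (j in seq_len(n_pairs)) {
        g <- codes[int_pairs$snp_id[j], ]
        X[int_pairs$gene_id[j], ] <- X[int_pairs$gene_id[j], ] +
          int_pairs$slope[j] * g * (age - mean(age))
      }
    }
    noise_sd_mat <- matrix(config$noise_sd, n_genes, n_samples,
                           dimnames = list(gene_ids, sample_ids))
    old <- age > config$dv_boundary
    noise_sd_mat[dv_genes, old] <- old_sd
    X <- X + matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples) *
      noise_sd_mat
    dimnames(X) <- list(gene_ids, sample_ids)

    rpkm <- pmax(2^X - config$pseudocount, 0)
    expr <- expression_matrix(rpkm, state = "rpkm")

    sets <- replicate(config$n_sets,
                      sample(gene_ids, min(config$set_size, n_genes)),
                      simplify = FALSE)
    names(sets) <- sprintf("SET:%04d", seq_len(config$n_sets))
    sets <- gene_set_collection(sets)

    truth <- structure(list(
      age_effect_genes = alpha,
      dv_genes = dv_truth,
      interaction_pairs = int_pairs,
      confounder_scores = fscores,
      confounder_age_r = if (H > 0L) conf_r[seq_len(H)] else numeric(0),
      confounder_loadings = loadings,
      set_assignments = sets,
      log_expression = X,
      config = config,
      seed = seed
    ), class = "SimTruth")

    list(expr = expr, covs = covs,
         geno = genotype_matrix(codes, snp_meta),
         sets = sets, gene_pos = gene_pos, truth = truth)
  })
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", length(x$age_effect_genes), "age genes,",
      nrow(x$dv_genes), "DV genes,", nrow(x$interaction_pairs),
      "interaction pair(s),", ncol(x$confounder_scores), "confounder(s)\n")
  invisible(x)
}

#' Simulate a panel of regions with block-shared age genes
#'
#' Regions are partitioned into blocks of anatomically "related" regions.
#' Every pair of regions inside a block shares `shared_fraction` of its
#' true age genes (the block pool); the rest are private, and no gene is an
#' age gene in more than one region outside its block pool -- so unrelated
#' regions share none. This is the design for exercising cross-region rank
#' concordance and region clustering.
#'
#' @param regions number of regions (>= 2).
#' @param shared_fraction fraction of each region's age genes drawn from
#'   its block pool (in `[0, 1]`).
#' @param seed integer seed.
#' @param n_blocks number of related-region blocks (default 2).
#' @param n_samples donors per region (default 60).
#' @param n_genes genes (shared id space across regions; default 400).
#' @param n_age_genes true age genes per region (default 40).
#' @param config base [sim_config()]; its age-gene settings are overridden
#'   per region.
#' @return Named list, one element per region, each as
#'   [simulate_dataset()]'s output; attribute `blocks` gives the region ->
#'   block assignment.
#' @export
simulate_region_panel <- function(regions, shared_fraction, seed = 1L,
                                  n_blocks = 2L, n_samples = 60L,
                                  n_genes = 400L, n_age_genes = 40L,
                                  config = sim_config(n_confounders = 0L,
                                                      frac_dv_genes = 0,
                                                      n_interaction_pairs = 0L)) {
  if (regions < 2L) stop("need at least 2 regions")
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  n_blocks <- min(n_blocks, regions)
  blocks <- rep(seq_len(n_blocks), length.out = regions)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  n_shared <- round(shared_fraction * n_age_genes)
  n_private <- n_age_genes - n_shared
  assignment <- with_seed(seed, {
    pool <- sample(gene_ids)   # disjoint allocation from a shuffled universe
    take <- function(k) {
      if (k == 0L) return(character(0))
      if (k > length(pool)) stop("gene universe too small for the design")
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    block_pools <- lapply(seq_len(n_blocks), function(b) take(n_shared))
    lapply(seq_len(regions), function(r) {
      c(block_pools[[blocks[r]]], take(n_private))
    })
  })
  out <- lapply(seq_len(regions), function(r) {
    cfg <- config
    cfg$age_gene_ids <- assignment[[r]]
    simulate_dataset(n_samples = n_samples, n_genes = n_genes,
                     n_snps = 10L, config = cfg, seed = seed + 1000L * r,
                     region = sprintf("region%02d", r))
  })
  names(out) <- sprintf("region%02d", seq_len(regions))
  attr(out, "blocks") <- stats::setNames(blocks, names(out))
  out
}
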