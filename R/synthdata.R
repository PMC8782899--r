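# Synthetic multi-omics cohort generator.
#
# Generates genotyped cohorts with the statistical structure the pipeline
# assumes downstream -- Hardy-Weinberg hard calls in LD blocks, mRNA/protein
# pairs with planted cis effects of the three regulatory classes, latent
# confounders, a polygenic trans architecture feeding a few core genes, a
# SNP-driven transcription factor propagating to binding-site-weighted
# targets, and a binary disease status driven by core-gene protein levels --
# together with a machine-readable truth registry used as the recovery
# oracle by the tests.
#
# Layout: variants come in LD blocks; blocks 1..n_genes host the genes (the
# cis-causal variant of a non-null gene is the middle variant of its block);
# subsequent blocks supply the PRS variants and the TF-driving variant (one
# per block, so trans predictors are mutually independent and disjoint from
# every cis-causal variant).

#' Simulation configuration
#'
#' All planted effect sizes are variance fractions of the affected trait.
#'
#' @param n_samples cohort size.
#' @param n_variants number of variants (must cover
#'   `n_genes + n_prs_snps + 1` LD blocks).
#' @param maf_range MAF sampling interval, within (0, 0.5].
#' @param ld_block_size variants per LD block.
#' @param ld_rho latent adjacent-variant correlation within a block, in
#'   \[0, 1).
#' @param n_genes number of genes measured on both layers.
#' @param category_counts named counts for `shared`, `independent_eqtl`,
#'   `independent_pqtl`; remaining genes are `null`.
#' @param cis_r2 variance fraction of a planted cis effect on its layer.
#' @param n_latent_factors,factor_strength hidden confounders shared by
#'   both layers and their per-factor variance fraction.
#' @param n_prs_snps number of trans variants carrying PRS weights.
#' @param n_core_genes number of core genes receiving the accumulated
#'   polygenic trans effect (the TF is one of them).
#' @param core_r2 variance fraction of the PRS on core-gene mRNA.
#' @param tf_bs_counts named integer vector: functional binding-site count
#'   per TF target gene; `NULL` plants 8 targets with counts 2..6.
#' @param n_decoy_bs number of non-target genes given nonzero binding-site
#'   annotations without any planted TF dependence (ChIP binding without
#'   function; exercises the mediation filter's specificity).
#' @param tf_trans_r2 variance fraction of the TF-driving variant on TF
#'   mRNA (the planted allelic effect is negative).
#' @param tf_target_r2 variance fraction of TF mRNA on its
#'   strongest-bound target; other targets scale proportionally to their
#'   binding-site count.
#' @param mrna_to_protein_r2 transmission fraction from mRNA to protein.
#' @param af_logit_coefs per-core-gene log-odds weights of protein level on
#'   disease status (recycled to `n_core_genes`).
#' @param af_logit_intercept intercept of the disease logit.
#' @param missing_protein_rate fraction of protein entries set missing at
#'   random.
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @return object of class `SimulationConfig`.
#' @export
simulation_config <- function(n_samples = 100,
                              n_variants = 600,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 5,
                              ld_rho = 0.6,
                              n_genes = 60,
                              category_counts = c(shared = 10,
                                                  independent_eqtl = 10,
                                                  independent_pqtl = 10),
                              cis_r2 = 0.1,
                              n_latent_factors = 3,
                              factor_strength = 0.05,
                              n_prs_snps = 50,
                              n_core_genes = 5,
                              core_r2 = 0.1,
                              tf_bs_counts = NULL,
                              n_decoy_bs = 8L,
                              tf_trans_r2 = 0.2,
                              tf_target_r2 = 0.5,
                              mrna_to_protein_r2 = 0.8,
                              af_logit_coefs = -0.8,
                              af_logit_intercept = -0.5,
                              missing_protein_rate = 0.005,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "SimulationConfig"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 2 || n_variants < 1) stop("n_samples >= 2 and n_variants >= 1 required")
    if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2])
      stop("maf_range must lie within (0, 0.5]")
    if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0,1)")
    fr <- c(cis_r2, factor_strength, core_r2, tf_trans_r2, tf_target_r2,
            mrna_to_protein_r2)
    if (any(fr < 0 | fr >= 1)) stop("variance fractions must be in [0,1)")
    if (!all(c("shared", "independent_eqtl", "independent_pqtl") %in%
             names(category_counts)))
      stop("category_counts needs shared, independent_eqtl, independent_pqtl")
    if (sum(category_counts) > n_genes)
      stop("category_counts exceed n_genes")
    n_blocks <- floor(n_variants / ld_block_size)
    if (n_blocks < n_genes + n_prs_snps + 1)
      stop("n_variants too small: need ", n_genes + n_prs_snps + 1,
           " LD blocks of size ", ld_block_size)
  })
  invisible(cfg)
}

# Blocks are laid out 3 Mb apart on one chromosome so cis windows (+-1 Mb)
# never straddle two blocks; variants within a block are 1 kb apart.
variant_positions <- function(cfg) {
  n_blocks <- floor(cfg$n_variants / cfg$ld_block_size)
  n_used <- n_blocks * cfg$ld_block_size
  block <- rep(seq_len(n_blocks), each = cfg$ld_block_size)
  within <- (seq_len(n_used) - 1L) %% cfg$ld_block_size
  pos <- (block - 1L) * 3e6L + 1e5L + within * 1000L
  list(n_blocks = n_blocks, n_used = n_used, block = block, pos = pos)
}

#' Simulate hard-call genotypes in LD blocks
#'
#' Each variant's MAF is drawn uniformly from `maf_range`; calls follow
#' Hardy-Weinberg proportions via a Gaussian copula whose latent process is
#' AR(1) with parameter `ld_rho` within a block (independent across
#' blocks), giving tunable adjacent-variant dosage correlation.
#'
#' @param config a [simulation_config()].
#' @return a [variant_table()]; deterministic per `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  validate_config(config)
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  lay <- variant_positions(config)
  n <- config$n_samples
  maf <- runif(lay$n_used, config$maf_range[1], config$maf_range[2])
  # latent AR(1) per block, shared across samples column-wise
  Z <- matrix(NA_real_, nrow = lay$n_used, ncol = n)
  rho <- config$ld_rho
  for (b in seq_len(lay$n_blocks)) {
    idx <- which(lay$block == b)
    E <- matrix(rnorm(length(idx) * n), nrow = length(idx))
    Zb <- E
    if (length(idx) > 1 && rho > 0)
      for (j in 2:length(idx))
        Zb[j, ] <- rho * Zb[j - 1, ] + sqrt(1 - rho^2) * E[j, ]
    Z[idx, ] <- Zb
  }
  U <- pnorm(Z)
  q0 <- (1 - maf)^2
  q1 <- q0 + 2 * maf * (1 - maf)
  G <- (U > q0) + (U > q1)
  storage.mode(G) <- "double"
  rownames(G) <- paste0("rs", seq_len(lay$n_used))
  colnames(G) <- paste0("S", sprintf("%04d", seq_len(n)))
  info <- data.frame(variant_id = rownames(G), chrom = "chr1",
                     pos = lay$pos, ref = "A", alt = "G",
                     block = lay$block, stringsAsFactors = FALSE)
  variant_table(info, G)
}

std <- function(x) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) return(x * 0)
  (x - mean(x, na.rm = TRUE)) / s
}

# mix a standardized signal into a standardized baseline at variance
# fraction r2
mix <- function(base, signal, r2) {
  if (r2 <= 0) return(base)
  sqrt(1 - r2) * std(base) + sqrt(r2) * std(signal)
}

#' Simulate the cis multi-omics layers
#'
#' Plants the three cis regulatory classes: `shared` genes carry one cis
#' variant affecting mRNA, with protein inheriting the (full) mRNA signal;
#' `independent_eqtl` genes carry a cis effect on mRNA only, with protein
#' coupled only to the non-genetic part of mRNA; `independent_pqtl` genes
#' carry a cis effect on protein only; `null` genes have no genetic effect.
#' Latent factors load on both layers; a small fraction of protein entries
#' is set missing at random.
#'
#' @param geno a [simulate_genotypes()] result built from `config`.
#' @param config the same [simulation_config()].
#' @return list `mrna`, `protein` ([omics_matrix()]), `covariates`
#'   (data.frame), `truth` (data.frame registry), `factors` (latent factor
#'   matrix), `gene_annotations`.
#' @export
simulate_multiomics <- function(geno, config) {
  validate_config(config)
  if (ncol(geno$geno) != config$n_samples)
    stop("genotype sample set does not match config")
  set.seed(config$seed + 1000L)
  n <- config$n_samples
  ng <- config$n_genes
  cc <- config$category_counts
  n_null <- ng - sum(cc)
  category <- c(rep("shared", cc[["shared"]]),
                rep("independent_eqtl", cc[["independent_eqtl"]]),
                rep("independent_pqtl", cc[["independent_pqtl"]]),
                rep("null", n_null))
  genes <- paste0("G", sprintf("%03d", seq_len(ng)))

  # gene g sits in block g; its causal variant is the middle of the block
  blk <- geno$info$block
  causal_idx <- vapply(seq_len(ng), function(g) {
    idx <- which(blk == g)
    idx[ceiling(length(idx) / 2)]
  }, integer(1))
  causal_id <- geno$info$variant_id[causal_idx]
  causal_id[category == "null"] <- NA_character_

  Fmat <- matrix(rnorm(n * config$n_latent_factors), nrow = n)
  m2p <- config$mrna_to_protein_r2
  fac_r2_tot <- config$n_latent_factors * config$factor_strength

  M <- matrix(NA_real_, ng, n, dimnames = list(genes, colnames(geno$geno)))
  P <- M
  beta_m <- beta_p <- numeric(ng)
  for (g in seq_len(ng)) {
    fload_m <- if (config$n_latent_factors > 0)
      std(Fmat %*% rnorm(config$n_latent_factors)) else 0
    fload_p <- if (config$n_latent_factors > 0)
      std(Fmat %*% rnorm(config$n_latent_factors)) else 0
    noise_m <- rnorm(n)
    base_m <- if (config$n_latent_factors > 0)
      sqrt(1 - fac_r2_tot) * std(noise_m) + sqrt(fac_r2_tot) * fload_m
      else noise_m
    gdos <- if (!is.na(causal_id[g])) std(geno$geno[causal_id[g], ]) else NULL
    cat_g <- category[g]
    r2 <- config$cis_r2
    if (cat_g %in% c("shared", "independent_eqtl")) {
      m <- mix(base_m, gdos, r2)
      beta_m[g] <- sqrt(r2)
    } else m <- std(base_m)
    noise_p <- rnorm(n)
    base_p <- if (config$n_latent_factors > 0)
      sqrt(1 - fac_r2_tot) * std(noise_p) + sqrt(fac_r2_tot) * fload_p
      else noise_p
    # Independent classes have fully decoupled layers: any mRNA-protein
    # coupling would leak the cis signal into the cross-layer residual
    # with the opposite sign and blur the residual-QTL definitions.
    p <- switch(cat_g,
      shared = mix(base_p, m, m2p),
      independent_eqtl = std(base_p),
      independent_pqtl = {
        beta_p[g] <- sqrt(r2)
        mix(base_p, gdos, r2)
      },
      null = mix(base_p, m, m2p))
    if (cat_g == "shared") beta_p[g] <- sqrt(m2p * r2)
    M[g, ] <- m
    P[g, ] <- p
  }
  # missing-at-random protein entries
  if (config$missing_protein_rate > 0) {
    nmiss <- rbinom(1, length(P), config$missing_protein_rate)
    if (nmiss > 0) P[sample(length(P), nmiss)] <- NA_real_
  }

  covs <- simulate_covariates(n, Fmat, colnames(geno$geno), config)

  truth <- data.frame(gene_id = genes, category = category,
                      causal_variant = causal_id,
                      beta_mrna = beta_m, beta_protein = beta_p,
                      core_gene = FALSE, is_tf = FALSE,
                      tf_target = FALSE, bs_count = 0L,
                      mediated = FALSE, stringsAsFactors = FALSE)

  ann_pos <- geno$info$pos[ifelse(is.na(match(causal_id, geno$info$variant_id)),
                                  causal_idx, match(causal_id, geno$info$variant_id))]
  gene_annotations <- data.frame(gene_id = genes, chrom = "chr1",
                                 start = pmax(1L, ann_pos - 500L),
                                 end = ann_pos + 500L, strand = "+",
                                 stringsAsFactors = FALSE)

  list(mrna = omics_matrix(M, "mrna"),
       protein = omics_matrix(P, "protein"),
       covariates = covs, truth = truth, factors = Fmat,
       gene_annotations = gene_annotations)
}

# Clinical and technical covariates as correlated Gaussians / Bernoullis;
# CRP and NT-proBNP are simulated on the log scale. The fibroblast score is
# tied to the first latent factor so factor adjustment matters.
simulate_covariates <- function(n, Fmat, ids, config) {
  f1 <- if (ncol(Fmat) > 0) std(Fmat[, 1]) else rnorm(n)
  covs <- data.frame(
    age = round(rnorm(n, 65, 8)),
    sex = rbinom(n, 1, 0.7),
    BMI = rnorm(n, 28, 4),
    sysBP = rnorm(n, 135, 15),
    CRP = exp(rnorm(n, 1, 1)),
    NT_proBNP = exp(rnorm(n, 6, 1)),
    diabetes = rbinom(n, 1, 0.25),
    htn_medication = rbinom(n, 1, 0.6),
    myocardial_infarction = rbinom(n, 1, 0.3),
    smoking = rbinom(n, 1, 0.2),
    AF = rbinom(n, 1, plogis(config$af_logit_intercept)),
    RIN = pmin(10, rnorm(n, 7.5, 0.8)),
    protein_concentration = rnorm(n, 10, 2),
    fibroblast_score = 2 * f1 + rnorm(n, 0, 1),
    row.names = ids)
  covs
}

#' Plant the polygenic trans architecture
#'
#' Assigns PRS weights to `n_prs_snps` trans variants (one per reserved LD
#' block, disjoint from every cis-causal variant); core genes gain an mRNA
#' component proportional to the weighted risk-allele sum, transmitted to
#' protein; one core gene becomes the TF, additionally driven (negatively)
#' by a dedicated trans variant; each TF target's mRNA gains a dependence
#' on TF mRNA proportional to its binding-site count, transmitted to
#' protein; disease status is redrawn from a logistic model on core-gene
#' protein levels.
#'
#' @param geno,config,sim genotypes, configuration, and the
#'   [simulate_multiomics()] result.
#' @return list with updated `mrna`, `protein`, `covariates`, `truth`, plus
#'   `prs_weights` (data.frame), `tf_gene`, `tf_variant`, `prs_raw`.
#' @export
simulate_trans_architecture <- function(geno, config, sim) {
  validate_config(config)
  set.seed(config$seed + 2000L)
  truth <- sim$truth
  M <- sim$mrna$values
  P <- sim$protein$values
  n <- config$n_samples
  ng <- config$n_genes

  blk <- geno$info$block
  trans_blocks <- (ng + 1):(ng + config$n_prs_snps + 1)
  pick_mid <- function(b) { idx <- which(blk == b); idx[ceiling(length(idx) / 2)] }
  trans_idx <- vapply(trans_blocks, pick_mid, integer(1))
  if (any(geno$info$variant_id[trans_idx] %in% truth$causal_variant))
    stop("trans variant overlaps a cis-causal variant")
  prs_idx <- trans_idx[seq_len(config$n_prs_snps)]
  tf_variant <- geno$info$variant_id[trans_idx[config$n_prs_snps + 1]]

  w <- rnorm(config$n_prs_snps, 0, 1)
  prs_weights <- data.frame(variant_id = geno$info$variant_id[prs_idx],
                            chrom = geno$info$chrom[prs_idx],
                            pos = geno$info$pos[prs_idx],
                            effect_allele = geno$info$alt[prs_idx],
                            other_allele = geno$info$ref[prs_idx],
                            weight = w,
                            freq = rowMeans(geno$geno[prs_idx, , drop = FALSE],
                                            na.rm = TRUE) / 2,
                            stringsAsFactors = FALSE)
  prs_raw <- as.vector(crossprod(geno$geno[prs_idx, , drop = FALSE], w))
  prs_std <- std(prs_raw)

  # core genes: chosen among null genes (no cis effect confounds the
  # polygenic signal); the first is the TF
  null_genes <- which(truth$category == "null")
  n_core <- config$n_core_genes
  if (n_core < 1) stop("trans architecture requires at least one core gene")
  n_targets <- if (is.null(config$tf_bs_counts)) 8L else length(config$tf_bs_counts)
  n_decoy <- config$n_decoy_bs
  if (length(null_genes) < n_core + n_targets + n_decoy)
    stop("not enough null genes for core genes, TF targets and decoys")
  core <- null_genes[seq_len(n_core)]
  tf <- core[1]
  truth$core_gene[core] <- TRUE
  truth$is_tf[tf] <- TRUE
  truth$tf_driving_variant <- NA_character_
  truth$tf_driving_variant[tf] <- tf_variant

  m2p <- config$mrna_to_protein_r2
  for (g in core) {
    M[g, ] <- mix(M[g, ], prs_std, config$core_r2)
    P[g, ] <- mix(P[g, ], M[g, ], m2p)
  }
  # TF driven negatively by its trans variant (risk allele lowers TF)
  gtf <- std(geno$geno[tf_variant, ])
  M[tf, ] <- mix(M[tf, ], -gtf, config$tf_trans_r2)
  P[tf, ] <- mix(P[tf, ], M[tf, ], m2p)

  # TF targets: binding-site-count-proportional dependence on TF mRNA
  if (is.null(config$tf_bs_counts)) {
    tgt <- null_genes[n_core + seq_len(n_targets)]
    bs <- sample(2:6, n_targets, replace = TRUE)
    names(bs) <- truth$gene_id[tgt]
  } else {
    bs <- config$tf_bs_counts
    tgt <- match(names(bs), truth$gene_id)
    if (anyNA(tgt)) stop("tf_bs_counts names unknown gene(s)")
    if (any(tgt %in% c(core))) stop("TF target overlaps a core gene")
  }
  tf_m <- std(M[tf, ])
  for (i in seq_along(tgt)) {
    g <- tgt[i]
    r2_t <- config$tf_target_r2 * bs[i] / max(bs)
    M[g, ] <- mix(M[g, ], tf_m, r2_t)
    P[g, ] <- mix(P[g, ], M[g, ], m2p)
    truth$tf_target[g] <- TRUE
    truth$bs_count[g] <- as.integer(bs[i])
    truth$mediated[g] <- bs[i] >= 1 && r2_t > 0
  }
  # decoy annotations: binding sites without any planted TF dependence
  if (n_decoy > 0) {
    decoy <- null_genes[n_core + n_targets + seq_len(n_decoy)]
    truth$bs_count[decoy] <- as.integer(sample(1:4, n_decoy, replace = TRUE))
  }

  # disease status from core-gene protein levels (missing entries enter at
  # the mean, i.e. zero on the standardized scale)
  coefs <- rep_len(config$af_logit_coefs, max(n_core, 1L))[seq_len(n_core)]
  Pc <- P[core, , drop = FALSE]
  Pc[is.na(Pc)] <- 0
  eta <- config$af_logit_intercept + as.vector(coefs %*% Pc)
  covs <- sim$covariates
  covs$AF <- rbinom(n, 1, plogis(eta))

  list(mrna = omics_matrix(M, "mrna"),
       protein = omics_matrix(P, "protein"),
       covariates = covs, truth = truth,
       prs_weights = prs_weights, prs_raw = prs_raw,
       tf_gene = truth$gene_id[tf], tf_variant = tf_variant,
       gene_annotations = sim$gene_annotations)
}

#' Simulate a complete cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_multiomics()] and [simulate_trans_architecture()].
#'
#' @param config a [simulation_config()].
#' @return the [simulate_trans_architecture()] list plus `geno` and
#'   `factors`.
#' @export
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  sim <- simulate_multiomics(geno, config)
  out <- simulate_trans_architecture(geno, config, sim)
  out$geno <- geno
  out$factors <- sim$factors
  out$config <- config
  out
}

#' Write a fixture bundle to disk
#'
#' Emits the cohort as the pipeline's on-disk formats: genotype TSV, layer
#' TSVs, covariate TSV, a GMT of synthetic gene sets (core-gene-enriched
#' and random), a BED of gene promoters, PRS weight TSV, a GWAS-hit TSV
#' (the trans variants annotated to the simulated disease), the truth
#' registry TSV and a JSON manifest with seed and config hash.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir_path output directory (created if needed).
#' @param n_sets number of gene sets in the GMT (half core-enriched).
#' @param set_size genes per set.
#' @return invisible manifest list.
#' @export
write_fixture_bundle <- function(cohort, dir_path, n_sets = 20, set_size = 15) {
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir_path, f)
  write_genotypes(cohort$geno, fp("genotypes.tsv"))
  write_omics(cohort$mrna, fp("mrna.tsv"))
  write_omics(cohort$protein, fp("protein.tsv"))
  data.table::fwrite(data.table::data.table(sample_id = rownames(cohort$covariates),
                                            cohort$covariates),
                     fp("covariates.tsv"), sep = "\t")
  data.table::fwrite(cohort$prs_weights, fp("prs_weights.tsv"), sep = "\t")
  data.table::fwrite(cohort$truth, fp("truth.tsv"), sep = "\t")
  data.table::fwrite(cohort$gene_annotations, fp("gene_annotations.tsv"), sep = "\t")

  gwas <- data.frame(variant_id = c(cohort$tf_variant,
                                    cohort$prs_weights$variant_id),
                     trait = "synthetic_af",
                     p_value = 10^-runif(1 + nrow(cohort$prs_weights), 8, 20))
  data.table::fwrite(gwas, fp("gwas_hits.tsv"), sep = "\t")

  sets <- synthetic_gene_sets(cohort$truth, n_sets = n_sets,
                              set_size = set_size, seed = cohort$config$seed)
  write_gmt(sets, fp("gene_sets.gmt"))

  ann <- cohort$gene_annotations
  bed <- data.frame(chrom = ann$chrom, start = ann$start - 1L, end = ann$end,
                    name = ann$gene_id)
  data.table::fwrite(bed, fp("promoters.bed"), sep = "\t", col.names = FALSE)

  cfg <- cohort$config
  manifest <- list(seed = cfg$seed,
                   config_hash = config_hash(cfg),
                   n_samples = cfg$n_samples, n_variants = cfg$n_variants,
                   n_genes = cfg$n_genes,
                   files = c("genotypes.tsv", "mrna.tsv", "protein.tsv",
                             "covariates.tsv", "prs_weights.tsv", "truth.tsv",
                             "gene_annotations.tsv", "gwas_hits.tsv",
                             "gene_sets.gmt", "promoters.bed"))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

#' Synthetic gene sets around the planted core genes
#'
#' Half of the sets contain the core genes plus random fill ("core-enriched"),
#' half are entirely random draws from the gene universe.
#'
#' @param truth truth registry from [simulate_cohort()].
#' @param n_sets,set_size collection shape.
#' @param seed RNG seed.
#' @return named list of gene-id vectors; attribute `core_enriched` marks
#'   the enriched half.
#' @export
synthetic_gene_sets <- function(truth, n_sets = 20, set_size = 15, seed = 1L) {
  set.seed(seed + 3000L)
  genes <- truth$gene_id
  core <- truth$gene_id[truth$core_gene]
  n_core_sets <- floor(n_sets / 2)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_core_sets) {
      fill <- sample(setdiff(genes, core), max(0, set_size - length(core)))
      sets[[i]] <- c(core, fill)
    } else {
      sets[[i]] <- sample(genes, min(set_size, length(genes)))
    }
  }
  names(sets) <- c(paste0("CORE_SET_", seq_len(n_core_sets)),
                   paste0("RANDOM_SET_", seq_len(n_sets - n_core_sets)))
  attr(sets, "core_enriched") <- names(sets)[seq_len(n_core_sets)]
  sets
}

#' Write a gene-set collection as GMT
#' @param sets named list of gene vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

# hash of the configuration (polynomial rolling hash over the serialized
# field values; avoids a digest dependency)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 15), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
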