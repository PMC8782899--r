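# Synthetic cohort generator: determinism, Hardy-Weinberg structure, LD
# control, planted-effect recoverability, and the truth registry.

test_that("genotype simulation is deterministic per seed", {
  cfg <- simulation_config(n_samples = 50, seed = 7)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$geno, g2$geno)
  expect_identical(g1$info, g2$info)
  co1 <- simulate_cohort(simulation_config(n_samples = 60, seed = 11))
  co2 <- simulate_cohort(simulation_config(n_samples = 60, seed = 11))
  expect_identical(co1$mrna$values, co2$mrna$values)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$covariates, co2$covariates)
})

test_that("genotype frequencies follow Hardy-Weinberg at the configured MAF", {
  # binomial sampling oracle: at maf 0.5 and n = 10000 the genotype
  # frequencies must fall within 3 SE of (0.25, 0.5, 0.25)
  cfg <- simulation_config(n_samples = 10000, n_variants = 25,
                           ld_block_size = 5, maf_range = c(0.5, 0.5),
                           n_genes = 3,
                           category_counts = c(shared = 1, independent_eqtl = 1,
                                               independent_pqtl = 1),
                           n_prs_snps = 1, seed = 5)
  g <- simulate_genotypes(cfg)$geno
  n <- ncol(g)
  # 75 dependent comparisons: assert family-level calibration (nearly all
  # deviations within 3 SE) plus a gross-error cap per comparison
  zs <- unlist(lapply(seq_len(nrow(g)), function(i)
    vapply(0:2, function(k) {
      p0 <- c(0.25, 0.5, 0.25)[k + 1]
      (mean(g[i, ] == k) - p0) / sqrt(p0 * (1 - p0) / n)
    }, numeric(1))))
  expect_gte(mean(abs(zs) <= 3), 0.95)
  expect_lt(max(abs(zs)), 6)
})

test_that("ld_rho = 0 gives independent adjacent variants", {
  cfg <- simulation_config(n_samples = 10000, n_variants = 25,
                           ld_block_size = 5, ld_rho = 0, n_genes = 3,
                           category_counts = c(shared = 1, independent_eqtl = 1,
                                               independent_pqtl = 1),
                           n_prs_snps = 1, seed = 3)
  g <- simulate_genotypes(cfg)$geno
  r2 <- vapply(seq_len(nrow(g) - 1), function(i)
    cor(g[i, ], g[i + 1, ])^2, numeric(1))
  expect_lt(median(r2), 0.01)
})

test_that("nonzero ld_rho produces correlated blocks with independent block boundaries", {
  cfg <- simulation_config(n_samples = 5000, n_variants = 20,
                           ld_block_size = 5, ld_rho = 0.8, n_genes = 2,
                           category_counts = c(shared = 1, independent_eqtl = 1,
                                               independent_pqtl = 0),
                           n_prs_snps = 1, seed = 9)
  g <- simulate_genotypes(cfg)$geno
  within_r2 <- cor(g[1, ], g[2, ])^2
  across_r2 <- cor(g[5, ], g[6, ])^2   # last of block 1, first of block 2
  expect_gt(within_r2, 0.2)
  expect_lt(across_r2, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(simulation_config(n_genes = 5,
                                 category_counts = c(shared = 3,
                                                     independent_eqtl = 2,
                                                     independent_pqtl = 1)),
               "category_counts")
  expect_error(simulation_config(cis_r2 = 1.2), "variance fractions")
})

test_that("zero effects and zero factors give pure-noise null layers", {
  cfg <- simulation_config(n_samples = 200, n_variants = 25, ld_block_size = 5,
                           n_genes = 3,
                           category_counts = c(shared = 0, independent_eqtl = 0,
                                               independent_pqtl = 0),
                           n_latent_factors = 0, n_prs_snps = 1,
                           missing_protein_rate = 0, seed = 2)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_multiomics(geno, cfg)
  expect_true(all(sim$truth$category == "null"))
  expect_true(all(is.na(sim$truth$causal_variant)))
  # no variant should explain expression beyond chance
  ps <- unlist(lapply(seq_len(3), function(g)
    vapply(seq_len(nrow(geno$geno)), function(v)
      ols_term(ols_test(sim$mrna$values[g, ],
                        cbind(dosage = geno$geno[v, ])), "dosage")$p_value,
      numeric(1))))
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("planted shared effects are jointly detectable (Monte-Carlo power oracle)", {
  hits <- 0
  for (i in 1:100) {
    cfg <- tiny_config(n_samples = 500, seed = 1000 + i)
    geno <- simulate_genotypes(cfg)
    sim <- simulate_multiomics(geno, cfg)
    g <- which(sim$truth$category == "shared")
    v <- sim$truth$causal_variant[g]
    p_m <- ols_term(ols_test(sim$mrna$values[g, ],
                             cbind(dosage = geno$geno[v, ])), "dosage")$p_value
    p_p <- ols_term(ols_test(sim$protein$values[g, ],
                             cbind(dosage = geno$geno[v, ])), "dosage")$p_value
    if (p_m < 1e-3 && p_p < 1e-3) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("independent-eQTL genes have a null protein association (KS oracle)", {
  tstats <- vapply(1:60, function(i) {
    cfg <- tiny_config(n_samples = 300, seed = 2000 + i)
    geno <- simulate_genotypes(cfg)
    sim <- simulate_multiomics(geno, cfg)
    g <- which(sim$truth$category == "independent_eqtl")
    v <- sim$truth$causal_variant[g]
    ols_term(ols_test(sim$protein$values[g, ],
                      cbind(dosage = geno$geno[v, ])), "dosage")$t_stat
  }, numeric(1))
  # under the null the t statistics are standard t with ~298 df
  expect_gt(suppressWarnings(ks.test(tstats, "pt", df = 298))$p.value, 0.01)
})

test_that("trans architecture plants the configured structure", {
  cfg <- simulation_config(n_samples = 300, seed = 21)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  # truth registry consistency
  expect_true(all(tr$bs_count[tr$mediated] >= 1))
  expect_true(all(tr$tf_target[tr$mediated]))
  expect_true(tr$is_tf[match(co$tf_gene, tr$gene_id)])
  expect_false(co$tf_variant %in% tr$causal_variant)
  expect_false(any(co$prs_weights$variant_id %in% tr$causal_variant))
  # categories partition the non-null genes
  expect_equal(sort(unique(tr$category)),
               c("independent_eqtl", "independent_pqtl", "null", "shared"))
  # SNP -> TF effect has the planted (negative) sign and is strong
  fit <- ols_test(co$mrna$values[co$tf_gene, ],
                  cbind(dosage = co$geno$geno[co$tf_variant, ]))
  expect_lt(ols_term(fit, "dosage")$beta, 0)
  expect_lt(ols_term(fit, "dosage")$p_value, 1e-4)
})

test_that("core_r2 = 0 leaves core genes uncorrelated with the PRS", {
  cors <- vapply(1:20, function(i) {
    cfg <- simulation_config(n_samples = 200, core_r2 = 0, seed = 3000 + i)
    co <- simulate_cohort(cfg)
    core <- co$truth$gene_id[co$truth$core_gene & !co$truth$is_tf]
    mean(vapply(core, function(g)
      cor(co$prs_raw, co$mrna$values[g, ]), numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 3 * sd(cors) / sqrt(length(cors)) + 0.05)
})

test_that("SNP-to-TF sign is recovered in at least 95% of replicates", {
  ok <- 0
  for (i in 1:40) {
    cfg <- simulation_config(n_samples = 300, tf_trans_r2 = 0.2, seed = 4000 + i)
    co <- simulate_cohort(cfg)
    b <- ols_term(ols_test(co$mrna$values[co$tf_gene, ],
                           cbind(dosage = co$geno$geno[co$tf_variant, ])),
                  "dosage")$beta
    if (b < 0) ok <- ok + 1
  }
  expect_gte(ok / 40, 0.95)
})

test_that("zero disease coefficients give prevalence near the logit intercept", {
  cfg <- simulation_config(n_samples = 4000, n_variants = 700,
                           af_logit_coefs = 0, af_logit_intercept = -0.5,
                           seed = 31)
  co <- simulate_cohort(cfg)
  prev <- mean(co$covariates$AF)
  p0 <- plogis(-0.5)
  expect_lt(abs(prev - p0), 3 * sqrt(p0 * (1 - p0) / 4000))
})

test_that("planted variance fractions are near their configured values", {
  # empirical cis r2 within 2 SE of the configuration at large n
  cfg <- tiny_config(n_samples = 10000, seed = 77, cis_r2 = 0.1)
  geno <- simulate_genotypes(cfg)
  sim <- simulate_multiomics(geno, cfg)
  g <- which(sim$truth$category == "shared")
  v <- sim$truth$causal_variant[g]
  r2 <- cor(sim$mrna$values[g, ], geno$geno[v, ])^2
  se_r2 <- 2 * sqrt(0.1) * sqrt((1 - 0.1)^2 / 10000)  # delta-method SE
  expect_lt(abs(r2 - 0.1), 2 * se_r2 + 0.01)
})

test_that("fixture bundle round-trips through the readers", {
  co <- simulate_cohort(simulation_config(n_samples = 40, seed = 13))
  dir <- withr::local_tempdir()
  man <- write_fixture_bundle(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  vt <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_equal(vt$geno, co$geno$geno[, colnames(vt$geno)], tolerance = 1e-12)
  m <- read_omics(file.path(dir, "mrna.tsv"))
  expect_equal(m$values, co$mrna$values, tolerance = 1e-12)
  sets <- read_gmt(file.path(dir, "gene_sets.gmt"))
  expect_length(sets, 20)
  # config hash changes iff the configuration changes
  co2 <- simulate_cohort(simulation_config(n_samples = 40, seed = 14))
  man2 <- write_fixture_bundle(co2, withr::local_tempdir())
  expect_false(identical(man$config_hash, man2$config_hash))
  man3 <- write_fixture_bundle(co, withr::local_tempdir())
  expect_identical(man$config_hash, man3$config_hash)
})
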