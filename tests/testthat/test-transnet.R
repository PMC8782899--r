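# Trans-QTL mapping, binding-site annotation, TF activity, the mediation
# filter, partial correlations and differential protein analysis.

test_that("trait SNP selection filters by MAF and prunes by LD", {
  set.seed(1)
  n <- 500
  a <- rbinom(n, 2, 0.4)
  b <- ifelse(runif(n) < 0.9, a, rbinom(n, 2, 0.4))    # high LD with a
  c_ <- rbinom(n, 2, 0.4)                              # independent
  rare <- rbinom(n, 2, 0.05)                           # MAF < 0.1
  vt <- make_vt(rbind(a = a, b = b, c = c_, rare = rare))
  expect_gt(ld_r2(vt, "a", "b"), 0.5)
  expect_lt(ld_r2(vt, "a", "c"), 0.5)
  hits <- data.frame(variant_id = c("a", "b", "c", "rare", "ghost"),
                     p_value = c(1e-9, 1e-7, 1e-6, 1e-8, 1e-10))
  expect_warning(sel <- select_trait_snps(hits, vt), "absent")
  expect_false("rare" %in% sel)
  expect_false("ghost" %in% sel)
  expect_setequal(sel, c("a", "c"))         # b pruned against a (lower p kept)
  # highest-p keep rule retains b instead
  sel_hi <- suppressWarnings(select_trait_snps(hits, vt, keep = "highest_p"))
  expect_true("c" %in% sel_hi)
  expect_length(sel_hi, 2)
})

test_that("trans scan df matches the printed model sizes", {
  covs <- make_covs(74)
  vt <- make_vt(matrix(rbinom(74, 2, 0.3), 1))
  colnames(vt$geno) <- rownames(covs)
  om <- make_om(matrix(rnorm(74), 1), "mrna")
  colnames(om$values) <- rownames(covs)
  rec <- map_trans_qtl("g1", "v1", vt, om, covs)
  # intercept + dosage + 8 covariates = 10 parameters -> df 64
  expect_equal(rec$df, 64)
  covs73 <- make_covs(73)
  vt73 <- make_vt(matrix(rbinom(73, 2, 0.3), 1))
  colnames(vt73$geno) <- rownames(covs73)
  omp <- make_om(matrix(rnorm(73), 1), "protein")
  colnames(omp$values) <- rownames(covs73)
  expect_equal(map_trans_qtl("g1", "v1", vt73, omp, covs73)$df, 63)
  # unmeasured candidates are listed, not fatal
  rec2 <- map_trans_qtl(c("g1", "gX"), "v1", vt, om, covs)
  expect_equal(attr(rec2, "skipped"), "gX")
})

test_that("peak filtering and merging follow the enrichment/P rules", {
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(100, 150, 400, 100),
                      end = c(200, 300, 500, 200),
                      log2_enrichment = c(0.5, 1.2, -0.1, 2),
                      neg_log10_p = c(2.0, 3.0, 3.0, 1.0))
  out <- filter_merge_clip_peaks(peaks)
  # peak 3 fails enrichment, peak 4 fails P (1.0 < 1.301)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$end, 300)       # overlapping retained peaks merged
})

test_that("functional binding sites require a 25-bp open-chromatin overlap", {
  promoters <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                          name = "gene1")
  open_chr <- data.frame(chrom = "chr1", start = 1000, end = 1100)
  peak_30 <- data.frame(chrom = "chr1", start = 1071, end = 1300)  # 30 bp
  peak_20 <- data.frame(chrom = "chr1", start = 1081, end = 1300)  # 20 bp
  a30 <- annotate_functional_bs(peak_30, promoters, open_chromatin = open_chr)
  a20 <- annotate_functional_bs(peak_20, promoters, open_chromatin = open_chr)
  expect_equal(a30$bs_count[a30$gene_id == "gene1"], 1L)
  expect_equal(a20$bs_count[a20$gene_id == "gene1"], 0L)
  # peak in a linked distal open region counts for the linked gene
  links <- data.frame(chrom1 = "chr1", start1 = 50000, end1 = 51000,
                      chrom2 = "chr1", start2 = 1500, end2 = 1600)
  open2 <- rbind(open_chr,
                 data.frame(chrom = "chr1", start = 50000, end = 50500))
  distal_peak <- data.frame(chrom = "chr1", start = 50100, end = 50400)
  ad <- annotate_functional_bs(distal_peak, promoters, hic_links = links,
                               open_chromatin = open2)
  expect_equal(ad$bs_count[ad$gene_id == "gene1"], 1L)
  # unmapped anchors are counted, not fatal
  links_bad <- data.frame(chrom1 = "chr1", start1 = 50000, end1 = 51000,
                          chrom2 = "chr9", start2 = 10, end2 = 20)
  ab <- annotate_functional_bs(distal_peak, promoters, hic_links = links_bad,
                               open_chromatin = open2)
  expect_equal(attr(ab, "unmapped_links"), 1L)
})

test_that("TF activity is the binding-site weighted sum and is linear", {
  # two targets, counts [2, 1]; craft expression whose per-gene NQN values
  # are known: use 3 samples so NQN maps ranks to fixed quantiles
  m <- rbind(t1 = c(2, 1, 3), t2 = c(1, 3, 2))
  om <- make_om(m)
  ann <- data.frame(gene_id = c("t1", "t2"), bs_count = c(2L, 1L))
  tfa <- compute_tfa(om, ann)
  q <- qnorm((1:3 - 0.5) / 3)
  expect_equal(unname(tfa), 2 * q[rank(m[1, ])] + 1 * q[rank(m[2, ])],
               tolerance = 1e-12, ignore_attr = TRUE)
  # doubling the counts doubles the activity
  ann2 <- within(ann, bs_count <- bs_count * 2L)
  expect_equal(unname(compute_tfa(om, ann2)), 2 * unname(tfa),
               tolerance = 1e-12, ignore_attr = TRUE)
  # sample-order invariance
  perm <- c(3, 1, 2)
  om_p <- make_om(m[, perm])
  expect_equal(unname(compute_tfa(om_p, ann)), unname(tfa)[perm],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(compute_tfa(om, data.frame(gene_id = "zz", bs_count = 1L)),
               "no annotated target")
})

test_that("TF activity tracks true TF expression on synthetic cohorts", {
  ok <- 0; reps <- 20
  for (i in seq_len(reps)) {
    co <- simulate_cohort(simulation_config(n_samples = 300, seed = 9000 + i))
    ann <- co$truth[co$truth$tf_target, c("gene_id", "bs_count")]
    tfa <- compute_tfa(co$mrna, ann)
    ct <- cor.test(tfa, co$mrna$values[co$tf_gene, ], alternative = "greater")
    if (ct$estimate > 0 && ct$p.value < 0.05) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("mediation models have the printed df and criteria compose", {
  set.seed(3)
  n <- 67
  covs <- make_covs(n)
  snp <- rbinom(n, 2, 0.3); names(snp) <- rownames(covs)
  tf <- -0.5 * snp + rnorm(n); names(tf) <- rownames(covs)
  tgt_m <- make_om(matrix(rnorm(2 * n), 2), "mrna")
  colnames(tgt_m$values) <- rownames(covs)
  # protein layer with 79 samples is fit separately; here same n
  tgt_p <- make_om(matrix(rnorm(2 * n), 2), "protein")
  colnames(tgt_p$values) <- rownames(covs)
  ann <- data.frame(gene_id = c("g1", "g2"), bs_count = c(2L, 0L))
  med <- mediation_filter(snp, tf, tgt_m, tgt_p, ann, covs)
  # model 1: intercept + SNP + fibroblast + RIN -> df 63
  expect_true(all(med$df_m1 == 63))
  # model 2 adds the TF transcript -> df 62
  expect_true(all(med$df_m2 == 62))
  # model 3: intercept + TF + fibroblast + protein conc -> df 63 at n = 67
  expect_true(all(med$df_m3 == 63))
  # gene without binding sites can never be functional
  expect_false(med$functional[med$gene_id == "g2"])
  expect_false(med$crit_a[med$gene_id == "g2"])
  # random targets without SNP dependence rarely pass criterion b
  expect_false(any(med$functional))
})

test_that("mediation filter recovers planted targets and spares decoys", {
  co <- simulate_cohort(simulation_config(n_samples = 300, seed = 41))
  ann <- co$truth[co$truth$bs_count > 0, c("gene_id", "bs_count")]
  med <- mediation_filter(co$geno$geno[co$tf_variant, ],
                          co$mrna$values[co$tf_gene, ],
                          omics_matrix(co$mrna$values[ann$gene_id, ], "mrna"),
                          omics_matrix(co$protein$values[ann$gene_id, ], "protein"),
                          ann, co$covariates)
  med <- merge(med, co$truth[, c("gene_id", "mediated")], by = "gene_id")
  expect_gt(mean(med$functional[med$mediated]), 0.5)
  expect_lte(mean(med$functional[!med$mediated]), 0.1)
  expect_true(all(med$functional ==
                    (med$crit_a & med$crit_b & med$crit_c & med$crit_d) |
                    !med$functional))
})

test_that("partial correlation matches the closed form", {
  set.seed(4)
  n <- 200
  z <- rnorm(n)
  x <- rnorm(n); y <- 0.5 * x + sqrt(0.75) * rnorm(n)
  pc <- partial_correlation(x, y, z)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  closed <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(pc$estimate, closed, tolerance = 1e-10)
  expect_equal(pc$df, n - 3)
  # y = x gives estimate 1 regardless of z
  expect_equal(partial_correlation(x, x, z)$estimate, 1, tolerance = 1e-12)
  # degenerate residuals flagged
  expect_true(partial_correlation(z, y, z)$degenerate)
})

test_that("differential protein analysis has the printed df and null behavior", {
  covs <- make_covs(78)
  om <- make_om(matrix(rnorm(30 * 78), 30), "protein")
  colnames(om$values) <- rownames(covs)
  res <- diff_protein_af(om, covs)
  # intercept + AF + 10 covariates = 12 parameters -> df 66
  expect_true(all(res$df == 66))
  expect_gt(suppressWarnings(ks.test(res$p_value, "punif"))$p.value, 0.01)
  covs$AF <- 1
  expect_error(diff_protein_af(om, covs), "both classes")
})

test_that("differential analysis recovers a planted negative AF effect", {
  ok <- 0; reps <- 20
  for (i in seq_len(reps)) {
    set.seed(9500 + i)
    covs <- make_covs(300, seed = 9500 + i)
    y <- -0.5 * covs$AF + rnorm(300)
    om <- make_om(matrix(y, 1), "protein")
    colnames(om$values) <- rownames(covs)
    res <- diff_protein_af(om, covs)
    if (res$beta_af < 0) ok <- ok + 1
  }
  expect_gte(ok / reps, 0.9)
})

test_that("target-set replication GSEA flags coordinated shifts", {
  set.seed(5)
  n <- 300
  stats <- setNames(rnorm(n), paste0("g", 1:n))
  targets <- paste0("g", 1:12)
  stats[targets] <- stats[targets] - 2.5    # coordinated down-shift
  res <- target_set_replication(stats, targets, n_perm = 2000, seed = 2)
  expect_lt(res$p_perm, 0.05)
  expect_lt(res$es, 0)
  # a single-gene set is handled with the min-size override flag
  one <- target_set_replication(stats, "g1", n_perm = 200, seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(attr(one, "min_size_override"))
  expect_error(target_set_replication(stats, "absent"), "intersect")
})
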