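# End-to-end orchestration: layer preparation, the cis classification
# benchmark (planted-category recovery + colocalization), and the trans
# pipeline (PRS -> QTS -> GSEA candidate selection -> targeted trans scan
# -> TF activity and mediation filtering) on synthetic cohorts.

#' Prepare normalized omics layers from a simulated cohort
#'
#' KNN-imputes the protein layer, applies per-sample then per-gene
#' normal-quantile normalization to both layers, and derives the residual
#' and ratio phenotypes.
#'
#' @param cohort a [simulate_cohort()] (or [simulate_multiomics()]) result.
#' @param k_impute neighbours for [impute_knn()].
#' @return list `mrna, protein, residual_mrna, residual_protein, ratio`
#'   of [omics_matrix()] objects.
#' @export
prepare_layers <- function(cohort, k_impute = 10) {
  prot <- impute_knn(cohort$protein, k = k_impute)
  m <- normal_quantile_transform(
    normal_quantile_transform(cohort$mrna, "per_sample"), "per_gene")
  p <- normal_quantile_transform(
    normal_quantile_transform(prot, "per_sample"), "per_gene")
  res <- residual_phenotypes(m, p)
  list(mrna = m, protein = p,
       residual_mrna = res$residual_mrna,
       residual_protein = res$residual_protein,
       ratio = ratio_phenotype(m, p))
}

#' Cis lead SNPs per gene from a QTL record table
#'
#' Clumps each gene's records (on the supplied significance column) and
#' returns the clump leads passing `p1`.
#'
#' @param records QTL records for one layer (or a joint min-p table).
#' @param vt a [variant_table()].
#' @param on column used as the clumping p-value (`"fdr"` or `"p_value"`).
#' @param r2,kb,p1,p2 [ld_clump()] parameters.
#' @return named list: gene id -> character vector of lead variant ids.
#' @export
cis_lead_snps <- function(records, vt, on = "fdr", r2 = 0.5, kb = 250,
                          p1 = 0.05, p2 = 0.8) {
  rec <- as.data.frame(records)
  out <- list()
  for (g in unique(rec$gene_id)) {
    sub <- rec[rec$gene_id == g, , drop = FALSE]
    sub$p_value <- sub[[on]]
    cl <- ld_clump(sub, vt, r2 = r2, kb = kb, p1 = p1, p2 = p2)
    if (length(cl)) out[[g]] <- vapply(cl, `[[`, character(1), "lead")
  }
  out
}

#' Study conditions for the category-recovery benchmark
#'
#' 300 samples, 100 genes per planted cis class, cis r2 = 0.10, LD blocks
#' of 5 variants.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
category_study_config <- function(seed = 1L) {
  simulation_config(n_samples = 300, n_variants = 1530, ld_block_size = 5,
                    n_genes = 300,
                    category_counts = c(shared = 100, independent_eqtl = 100,
                                        independent_pqtl = 100),
                    cis_r2 = 0.10, n_latent_factors = 3,
                    factor_strength = 0.05,
                    n_prs_snps = 0L, n_core_genes = 0L, n_decoy_bs = 0L,
                    seed = seed)
}

#' Simulate a cis-only cohort (no trans architecture)
#'
#' Runs [simulate_genotypes()] and [simulate_multiomics()] and bundles the
#' result in the shape [run_cis_classification()] expects.
#'
#' @param config a [simulation_config()].
#' @return list with `geno`, `mrna`, `protein`, `covariates`, `truth`,
#'   `gene_annotations`, `config`.
#' @export
simulate_cis_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  sim <- simulate_multiomics(geno, config)
  sim$geno <- geno
  sim$config <- config
  sim
}

#' Cis scan + classification + colocalization on a simulated cohort
#'
#' Runs the four-layer cis scan with latent-factor adjustment, classifies
#' each gene's lead SNP into a regulatory category, colocalizes the
#' planted shared loci, and scores recovery against the truth registry.
#'
#' @param cohort a cohort from [simulate_genotypes()] +
#'   [simulate_multiomics()] (trans architecture not required).
#' @param k_factors latent factor count used for every layer (default 10).
#' @param alpha classification FDR threshold (default 0.05).
#' @return list with per-layer `records`, per-gene `calls`,
#'   `accuracy` (fraction of classified loci matching the planted class),
#'   `n_classified`, `coloc` (per shared gene) and `pp4_top_rate`.
#' @export
run_cis_classification <- function(cohort, k_factors = 10, alpha = 0.05) {
  geno <- cohort$geno
  layers <- prepare_layers(cohort)
  pairs <- enumerate_cis_pairs(geno, cohort$gene_annotations)
  scan_layer <- function(om) {
    lf <- fit_latent_factors(om, k_factors)
    fit_qtl_scan(pairs, geno, om, lf$factors)
  }
  rec <- list(mrna = scan_layer(layers$mrna),
              protein = scan_layer(layers$protein),
              residual_mrna = scan_layer(layers$residual_mrna),
              residual_protein = scan_layer(layers$residual_protein))

  genes <- cohort$truth$gene_id
  fdr_at <- function(tab, g, v) {
    i <- which(tab$gene_id == g & tab$variant_id == v)
    if (length(i)) tab$fdr[i[1]] else NA_real_
  }
  calls <- vector("list", length(genes))
  coloc <- list()
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    e <- rec$mrna[rec$mrna$gene_id == g]
    p <- rec$protein[rec$protein$gene_id == g]
    if (nrow(e) == 0) next
    # joint lead: smallest per-variant minimum p across the two layers
    minp <- pmin(e$p_value, p$p_value[match(e$variant_id, p$variant_id)],
                 na.rm = TRUE)
    lead <- e$variant_id[which.min(minp)]
    cl <- classify_locus(fdr_at(rec$mrna, g, lead),
                         fdr_at(rec$protein, g, lead),
                         fdr_at(rec$residual_mrna, g, lead),
                         fdr_at(rec$residual_protein, g, lead),
                         alpha = alpha)
    calls[[gi]] <- data.table::data.table(gene_id = g, lead = lead,
                                          category = cl$category,
                                          truth = cohort$truth$category[gi])
    if (cohort$truth$category[gi] == "shared" && nrow(e) >= 2) {
      co <- coloc_abf(e[, c("variant_id", "beta", "se")],
                      p[, c("variant_id", "beta", "se")])
      coloc[[g]] <- data.table::data.table(gene_id = g,
                                           t(co$pp), label = co$label,
                                           pp4_top = which.max(co$pp) == 5)
    }
  }
  calls <- data.table::rbindlist(calls)
  coloc <- data.table::rbindlist(coloc)
  classified <- calls[calls$category != "unclassified", ]
  list(records = rec, calls = calls,
       accuracy = if (nrow(classified)) mean(classified$category == classified$truth)
                  else NA_real_,
       n_classified = nrow(classified),
       coloc = coloc,
       pp4_top_rate = if (nrow(coloc)) mean(coloc$pp4_top) else NA_real_)
}

#' Study conditions for the trans-pipeline benchmark
#'
#' 300 samples; 40 genes (5 per cis class); 30 PRS variants and one
#' TF-driving variant on dedicated LD blocks; MAF at or above the trans
#' SNP filter (0.1) so the benchmark tests recovery, not the MAF filter.
#'
#' @param seed integer seed.
#' @return a [simulation_config()].
#' @export
trans_study_config <- function(seed = 1L) {
  simulation_config(n_samples = 300, n_variants = 660, ld_block_size = 5,
                    maf_range = c(0.1, 0.5),
                    n_genes = 100,
                    category_counts = c(shared = 5, independent_eqtl = 5,
                                        independent_pqtl = 5),
                    cis_r2 = 0.10, n_latent_factors = 3,
                    factor_strength = 0.05,
                    n_prs_snps = 30, n_core_genes = 5, core_r2 = 0.1,
                    tf_trans_r2 = 0.2, tf_target_r2 = 0.5,
                    mrna_to_protein_r2 = 0.8, n_decoy_bs = 8L,
                    seed = seed)
}

#' End-to-end trans pipeline on one synthetic cohort
#'
#' Simulates a cohort, scores and percentile-calibrates the PRS, ranks
#' genes by eQTS, selects trans candidates by GSEA leading-edge
#' recurrence, maps targeted trans-QTLs for the disease-annotated SNPs on
#' both layers, computes the TF activity, and applies the mediation filter
#' to the binding-site-annotated genes.
#'
#' @param config a [simulation_config()] (e.g. [trans_study_config()]).
#' @param n_perm GSEA permutations (default 500).
#' @param n_sets,set_size synthetic gene-set collection shape.
#' @param min_sets leading-edge recurrence threshold for candidate
#'   selection (default: half the core-enriched sets).
#' @param trans_fdr trans significance threshold (default 0.2).
#' @return list with `cohort`, `qts`, `gsea`, `candidates`, `trans_mrna`,
#'   `trans_protein`, `tf_selected`, `tf_recovered`, `tfa_cor` (correlation
#'   of TF activity with TF expression), `mediation`,
#'   `mediation_sensitivity`, `false_flag_rate`.
#' @export
run_trans_pipeline <- function(config, n_perm = 500, n_sets = 20,
                               set_size = 10, min_sets = NULL,
                               trans_fdr = 0.2) {
  cohort <- simulate_cohort(config)
  geno <- cohort$geno
  truth <- cohort$truth
  prot <- impute_knn(cohort$protein)
  m_nqn <- normal_quantile_transform(cohort$mrna, "per_gene")
  p_nqn <- normal_quantile_transform(prot, "per_gene")

  prs_raw <- score_prs(geno, cohort$prs_weights)
  prs_pct <- prs_percentiles(prs_raw, prs_raw)

  qts <- fit_qts(m_nqn, prs_pct, cohort$covariates)
  stats <- setNames(qts$t_stat, qts$gene_id)

  sets <- synthetic_gene_sets(truth, n_sets = n_sets, set_size = set_size,
                              seed = config$seed)
  gsea <- preranked_gsea(stats, sets, min_size = 5, max_size = 500,
                         n_perm = n_perm, seed = config$seed + 7L)
  counts <- leading_edge_counts(gsea, fdr_max = 0.05)
  if (is.null(min_sets))
    min_sets <- max(2L, floor(length(attr(sets, "core_enriched")) / 2))
  candidates <- select_candidates(counts, min_sets = min_sets)

  gwas <- data.frame(variant_id = c(cohort$tf_variant,
                                    cohort$prs_weights$variant_id),
                     p_value = 10^-(8 + seq_len(1 + nrow(cohort$prs_weights))))
  snps <- select_trait_snps(gwas, geno, maf_min = 0.1)

  trans_m <- if (length(candidates))
    map_trans_qtl(candidates, snps, geno, m_nqn, cohort$covariates,
                  fdr_max = trans_fdr) else NULL
  trans_p <- if (length(candidates))
    map_trans_qtl(candidates, snps, geno, p_nqn, cohort$covariates,
                  fdr_max = trans_fdr) else NULL
  tf_selected <- cohort$tf_gene %in% candidates
  tf_recovered <- !is.null(trans_m) &&
    any(trans_m$significant & trans_m$gene_id == cohort$tf_gene &
        trans_m$variant_id == cohort$tf_variant)

  ann <- truth[truth$bs_count > 0, c("gene_id", "bs_count")]
  tfa <- compute_tfa(m_nqn, ann[ann$gene_id %in%
                                  truth$gene_id[truth$tf_target], ,
                                drop = FALSE])
  tfa_cor <- cor(tfa, m_nqn$values[cohort$tf_gene, ])

  # mediation models run on the natural (already standard-normal) scale:
  # rank-normalizing both sides would perturb the exact linear mediation
  # that criterion (c) tests
  eval_genes <- setdiff(ann$gene_id, cohort$tf_gene)
  med <- mediation_filter(
    snp_dosage = geno$geno[cohort$tf_variant, ],
    tf_mrna = cohort$mrna$values[cohort$tf_gene, ],
    target_mrna = omics_matrix(cohort$mrna$values[eval_genes, , drop = FALSE], "mrna"),
    target_protein = omics_matrix(prot$values[eval_genes, , drop = FALSE], "protein"),
    ann = ann, covs = cohort$covariates)
  med <- merge(med, truth[, c("gene_id", "mediated")], by = "gene_id")
  sens <- if (any(med$mediated)) mean(med$functional[med$mediated]) else NA_real_
  ffr <- if (any(!med$mediated)) mean(med$functional[!med$mediated]) else NA_real_

  list(cohort = cohort, qts = qts, gsea = gsea, candidates = candidates,
       trans_mrna = trans_m, trans_protein = trans_p,
       tf_selected = tf_selected, tf_recovered = tf_recovered,
       tfa = tfa, tfa_cor = tfa_cor, mediation = med,
       mediation_sensitivity = sens, false_flag_rate = ffr)
}
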