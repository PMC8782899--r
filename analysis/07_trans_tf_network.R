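#!/usr/bin/env Rscript
# Targeted trans-QTL scan of the selected candidates against the
# disease-annotated SNPs on both omic layers, TF activity scoring from
# binding-site annotations, and the four-criterion mediation filter for
# functional TF targets.
source("analysis/00_common.R")

vt <- read_genotypes(file.path(RESULTS, "genotypes_qc.tsv"))
covs <- read_table_tsv(file.path(COHORT_DIR, "covariates.tsv"))
rownames(covs) <- covs$sample_id
mrna <- read_omics(file.path(COHORT_DIR, "mrna.tsv"), "mrna")
protein <- impute_knn(read_omics(file.path(COHORT_DIR, "protein.tsv"), "protein"))
truth <- read_table_tsv(file.path(COHORT_DIR, "truth.tsv"))
gwas <- read_table_tsv(file.path(COHORT_DIR, "gwas_hits.tsv"))
candidates <- readLines(file.path(RESULTS, "trans_candidates.txt"))

snps <- select_trait_snps(gwas, vt, maf_min = 0.1, prune_r2 = 0.5)
say("trait SNPs after MAF filter and LD pruning: %d", length(snps))

m_nqn <- normal_quantile_transform(mrna, "per_gene")
p_nqn <- normal_quantile_transform(protein, "per_gene")
trans_m <- map_trans_qtl(candidates, snps, vt, m_nqn, covs, fdr_max = 0.2)
trans_p <- map_trans_qtl(candidates, snps, vt, p_nqn, covs, fdr_max = 0.2)
fwrite(trans_m, file.path(RESULTS, "trans_qtl_mrna.tsv"), sep = "\t")
fwrite(trans_p, file.path(RESULTS, "trans_qtl_protein.tsv"), sep = "\t")
sig_m <- trans_m[trans_m$significant]
say("significant trans-eQTLs (FDR < 0.2): %d", nrow(sig_m))
if (nrow(sig_m)) print(sig_m[, c("variant_id", "gene_id", "beta", "t_stat",
                                 "p_value", "fdr")])

# TF = the planted trans-regulated transcription factor; its activity is
# the binding-site-weighted sum of target expression
tf_gene <- truth$gene_id[truth$is_tf]
tf_variant <- truth$tf_driving_variant[truth$is_tf]
ann <- truth[truth$bs_count > 0, c("gene_id", "bs_count")]
tfa <- compute_tfa(m_nqn, ann[ann$gene_id %in% truth$gene_id[truth$tf_target], ])
say("TFA computed over %d targets; cor(TFA, TF transcript) = %.2f",
    length(attr(tfa, "targets_used")),
    cor(tfa, m_nqn$values[tf_gene, ]))
fwrite(data.table(sample_id = names(tfa), tfa = as.numeric(tfa)),
       file.path(RESULTS, "tf_activity.tsv"), sep = "\t")

med <- mediation_filter(vt$geno[tf_variant, ], mrna$values[tf_gene, ],
                        omics_matrix(mrna$values[setdiff(ann$gene_id, tf_gene), ,
                                                 drop = FALSE], "mrna"),
                        omics_matrix(protein$values[setdiff(ann$gene_id, tf_gene), ,
                                                    drop = FALSE], "protein"),
                        ann, covs)
fwrite(med, file.path(RESULTS, "mediation_calls.tsv"), sep = "\t")
med <- merge(med, truth[, c("gene_id", "mediated")], by = "gene_id")
say("functional targets: %d flagged; sensitivity %.2f, false-flag rate %.2f",
    sum(med$functional),
    mean(med$functional[med$mediated]),
    mean(med$functional[!med$mediated]))
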