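#!/usr/bin/env Rscript
# Differential protein abundance for disease status with the stringent
# covariate set, and replication-style GSEA asking whether the functional
# TF target set shifts coordinately in the differential ranking.
source("analysis/00_common.R")

covs <- read_table_tsv(file.path(COHORT_DIR, "covariates.tsv"))
rownames(covs) <- covs$sample_id
protein <- impute_knn(read_omics(file.path(COHORT_DIR, "protein.tsv"), "protein"))
truth <- read_table_tsv(file.path(COHORT_DIR, "truth.tsv"))

p_nqn <- normal_quantile_transform(protein, "per_gene")
diff <- diff_protein_af(p_nqn, covs)
fwrite(diff, file.path(RESULTS, "diff_protein_af.tsv"), sep = "\t")
say("differential protein: %d genes at FDR < 0.05 (df = %d)",
    sum(diff$fdr < 0.05), diff$df[1])
top <- head(diff[order(diff$p_value)], 3)
say("strongest AF effects: %s",
    paste(sprintf("%s (beta=%.2f, P=%.2g)", top$gene_id, top$beta_af,
                  top$p_value), collapse = "; "))

# do the planted core genes (negative AF logit weights -> lower protein in
# cases) shift coordinately?
targets <- truth$gene_id[truth$core_gene]
ranking <- setNames(diff$t_stat, diff$gene_id)
rep_gsea <- target_set_replication(ranking, targets, n_perm = 10000,
                                   seed = SEED)
say("core-gene set replication GSEA: ES = %.2f, P = %.3g",
    rep_gsea$es, rep_gsea$p_perm)
out <- data.table::copy(rep_gsea)
out[, leading_edge := vapply(leading_edge, paste, character(1), collapse = ",")]
fwrite(out, file.path(RESULTS, "target_set_replication.tsv"), sep = "\t")
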