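#!/usr/bin/env Rscript
# Polygenic score: weighted allele-dosage sum, percentile calibration, and
# the eQTS/pQTS regressions ranking genes by their correlation with the
# score (aggregated trans effects), correcting for cis lead SNPs.
source("analysis/00_common.R")

vt <- read_genotypes(file.path(RESULTS, "genotypes_qc.tsv"))
weights <- read_table_tsv(file.path(COHORT_DIR, "prs_weights.tsv"))
covs <- read_table_tsv(file.path(COHORT_DIR, "covariates.tsv"))
rownames(covs) <- covs$sample_id
mrna <- read_omics(file.path(COHORT_DIR, "mrna.tsv"), "mrna")
protein <- impute_knn(read_omics(file.path(COHORT_DIR, "protein.tsv"), "protein"))

prs_raw <- score_prs(vt, weights)
prs_pct <- prs_percentiles(prs_raw, prs_raw)
say("PRS over %d variants (%d imputed from frequency, %d skipped)",
    nrow(weights), attr(prs_raw, "n_missing_imputed"),
    attr(prs_raw, "n_skipped"))

leads_tab <- fread(file.path(RESULTS, "cis_clump_leads.tsv"))
leads <- split(leads_tab$lead, leads_tab$gene_id)

m_nqn <- normal_quantile_transform(mrna, "per_gene")
p_nqn <- normal_quantile_transform(protein, "per_gene")
eqts <- fit_qts(m_nqn, prs_pct, covs, cis_lead_snps = leads, vt = vt)
pqts <- fit_qts(p_nqn, prs_pct, covs, cis_lead_snps = leads, vt = vt)

fwrite(eqts, file.path(RESULTS, "eqts.tsv"), sep = "\t")
fwrite(pqts, file.path(RESULTS, "pqts.tsv"), sep = "\t")
top <- head(eqts[order(-abs(eqts$t_stat))], 5)
say("top eQTS genes by |T|: %s",
    paste(sprintf("%s (T=%.2f)", top$gene_id, top$t_stat), collapse = ", "))
truth <- read_table_tsv(file.path(COHORT_DIR, "truth.tsv"))
core <- truth$gene_id[truth$core_gene]
ranks <- rank(-abs(eqts$t_stat))[match(core, eqts$gene_id)]
say("planted core genes rank (of %d): %s", nrow(eqts),
    paste(sort(ranks), collapse = ", "))
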