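#!/usr/bin/env Rscript
# Locus definition by LD clumping, classification of each gene's lead SNP
# into shared / independent regulatory categories from the four FDR
# values, colocalization of the two association signals by approximate
# Bayes factors, and recovery scoring against the planted truth.
source("analysis/00_common.R")

cohort <- list(
  geno = read_genotypes(file.path(RESULTS, "genotypes_qc.tsv")),
  mrna = read_omics(file.path(COHORT_DIR, "mrna.tsv"), "mrna"),
  protein = read_omics(file.path(COHORT_DIR, "protein.tsv"), "protein"),
  gene_annotations = read_table_tsv(file.path(COHORT_DIR, "gene_annotations.tsv")),
  truth = read_table_tsv(file.path(COHORT_DIR, "truth.tsv")))

res <- run_cis_classification(cohort, k_factors = 10)
fwrite(res$calls, file.path(RESULTS, "category_calls.tsv"), sep = "\t")
fwrite(res$coloc[, !"pp4_top"], file.path(RESULTS, "coloc_posteriors.tsv"),
       sep = "\t")

say("classified %d loci; accuracy vs planted classes: %.3f",
    res$n_classified, res$accuracy)
print(table(truth = res$calls$truth, call = res$calls$category))
say("coloc: pp4 is the top posterior for %.0f%% of planted shared loci",
    100 * res$pp4_top_rate)

# clumps per gene on the joint (min-p) statistics of the mRNA layer
rec_m <- fread(file.path(RESULTS, "cis_qtl_mrna_full.tsv"))
leads <- cis_lead_snps(rec_m, cohort$geno, on = "fdr")
say("genes with at least one significant cis clump (mRNA): %d", length(leads))
fwrite(data.table(gene_id = rep(names(leads), lengths(leads)),
                  lead = unlist(leads)),
       file.path(RESULTS, "cis_clump_leads.tsv"), sep = "\t")
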