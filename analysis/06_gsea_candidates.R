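#!/usr/bin/env Rscript
# Preranked GSEA on the eQTS T statistics, leading-edge recurrence
# counting, F-test power sizing of the targeted trans scan, and candidate
# selection.
source("analysis/00_common.R")

eqts <- fread(file.path(RESULTS, "eqts.tsv"))
sets <- read_gmt(file.path(COHORT_DIR, "gene_sets.gmt"))
stats <- setNames(eqts$t_stat, eqts$gene_id)

gsea <- preranked_gsea(stats, sets, min_size = 5, max_size = 500,
                       n_perm = 10000, seed = SEED)
say("significant gene sets (FDR < 0.05): %d / %d",
    sum(gsea$fdr < 0.05), nrow(gsea))
out <- data.table::copy(gsea)
out[, leading_edge := vapply(leading_edge, paste, character(1), collapse = ",")]
fwrite(out, file.path(RESULTS, "gsea_eqts.tsv"), sep = "\t")

counts <- leading_edge_counts(gsea, fdr_max = 0.05)
fwrite(data.table(gene_id = names(counts), n_sets = counts),
       file.path(RESULTS, "leading_edge_counts.tsv"), sep = "\t")

# power sizing: how many genes can the targeted scan afford at 50% power?
n_snps <- nrow(fread(file.path(COHORT_DIR, "gwas_hits.tsv")))
covs <- read_table_tsv(file.path(COHORT_DIR, "covariates.tsv"))
k_max <- max_testable_genes(n = nrow(covs), r2 = 0.218, n_snps = n_snps,
                            alpha_total = 0.05, power_min = 0.5)
if (k_max >= .Machine$integer.max) {
  say("power sizing: not limiting at n = %d (any candidate count keeps 50%% power)",
      nrow(covs))
} else {
  say("power sizing: up to %d genes testable against %d SNPs at n = %d",
      k_max, n_snps, nrow(covs))
}

min_sets <- max(2L, floor(sum(startsWith(names(sets), "CORE_SET")) / 2))
candidates <- select_candidates(counts, min_sets = min_sets)
if (length(candidates) > k_max) candidates <- candidates[seq_len(k_max)]
say("selected %d trans candidates (leading edge of >= %d sets): %s",
    length(candidates), min_sets, paste(candidates, collapse = ", "))
writeLines(candidates, file.path(RESULTS, "trans_candidates.txt"))
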