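#!/usr/bin/env Rscript
# Cis-QTL scans on five phenotype layers (mRNA, protein, the two
# cross-layer residuals, and the protein-per-mRNA ratio), each adjusted
# for latent expression factors, with BH FDR per layer. Also runs the
# factor-count optimization on the mRNA layer.
source("analysis/00_common.R")

vt <- read_genotypes(file.path(RESULTS, "genotypes_qc.tsv"))
mrna <- read_omics(file.path(COHORT_DIR, "mrna.tsv"), "mrna")
protein <- read_omics(file.path(COHORT_DIR, "protein.tsv"), "protein")
genes <- read_table_tsv(file.path(COHORT_DIR, "gene_annotations.tsv"))

layers <- prepare_layers(list(mrna = mrna, protein = protein))
pairs <- enumerate_cis_pairs(vt, genes, window = 1e6)
say("cis pairs: %d", nrow(pairs))

# factor-count optimization on the mRNA layer
opt <- optimize_factor_count(vt, layers$mrna, pairs,
                             candidate_ks = c(0, 2, 5, 10, 15))
say("factor-count optimization (mRNA): k* = %d", opt$k_best)
print(opt$table)

records <- list()
for (ly in names(layers)) {
  lf <- fit_latent_factors(layers[[ly]], opt$k_best)
  rec <- fit_qtl_scan(pairs, vt, layers[[ly]], lf$factors)
  records[[ly]] <- rec
  say("%s: %d QTL genes at FDR < 0.05", ly,
      length(unique(rec$gene_id[!is.na(rec$fdr) & rec$fdr < 0.05])))
  fwrite(rec[, !"se"], file.path(RESULTS, sprintf("cis_qtl_%s.tsv", ly)),
         sep = "\t")
  fwrite(rec, file.path(RESULTS, sprintf("cis_qtl_%s_full.tsv", ly)),
         sep = "\t")
}
say("wrote per-layer cis-QTL tables under %s", RESULTS)
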