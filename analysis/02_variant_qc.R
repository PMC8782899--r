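#!/usr/bin/env Rscript
# Variant quality control on the written cohort: MAF > 0.01, HWE exact
# P > 1e-6, call rate > 98%, then recoding of rare homozygous-minor calls
# (< 3 carriers) to heterozygous.
source("analysis/00_common.R")

vt <- read_genotypes(file.path(COHORT_DIR, "genotypes.tsv"))
say("read %d variants x %d samples", nrow(vt$geno), ncol(vt$geno))

vt_qc <- qc_filter_variants(vt, maf_min = 0.01, hwe_p_min = 1e-6,
                            call_rate_min = 0.98)
say("QC kept %d / %d variants", nrow(vt_qc$geno), nrow(vt$geno))

n_hom_before <- sum(vt_qc$geno == 2, na.rm = TRUE)
vt_rec <- recode_rare_genotypes(vt_qc, min_hom = 3)
say("recoded %d rare homozygous-minor calls",
    n_hom_before - sum(vt_rec$geno == 2, na.rm = TRUE))

write_genotypes(vt_rec, file.path(RESULTS, "genotypes_qc.tsv"))
say("wrote %s", file.path(RESULTS, "genotypes_qc.tsv"))
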