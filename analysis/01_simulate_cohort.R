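#!/usr/bin/env Rscript
# Generate the synthetic multi-omics cohort used by every downstream step
# and write it out as the pipeline's on-disk formats plus the truth
# registry. The cohort carries planted cis effects of all three regulatory
# classes, three latent confounders, a 30-SNP polygenic trans architecture
# on five core genes, a SNP-driven TF with binding-site-weighted targets,
# and a disease status driven by core-gene protein levels.
source("analysis/00_common.R")

cfg <- study_config()
cohort <- simulate_cohort(cfg)
man <- write_fixture_bundle(cohort, COHORT_DIR)

say("cohort: %d samples, %d variants, %d genes (seed %d, config %s)",
    cfg$n_samples, nrow(cohort$geno$geno), cfg$n_genes, cfg$seed,
    man$config_hash)
say("planted classes: %s",
    paste(names(table(cohort$truth$category)),
          table(cohort$truth$category), collapse = ", "))
say("TF %s driven by %s; %d mediated targets, %d decoy annotations",
    cohort$tf_gene, cohort$tf_variant, sum(cohort$truth$mediated),
    sum(cohort$truth$bs_count > 0 & !cohort$truth$mediated))
say("disease prevalence: %.2f", mean(cohort$covariates$AF))
say("wrote %s", COHORT_DIR)
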