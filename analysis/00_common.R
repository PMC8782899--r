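# Shared setup for the analysis drivers: library, seed, output locations.
# Each numbered script can be run from the repository root in order:
#   Rscript analysis/01_simulate_cohort.R
#   Rscript analysis/02_variant_qc.R
#   ...
suppressPackageStartupMessages(library(moqtl))
suppressPackageStartupMessages(library(data.table))

SEED <- as.integer(Sys.getenv("MOQTL_SEED", "1"))
RESULTS <- "results"
COHORT_DIR <- file.path(RESULTS, "cohort")
dir.create(RESULTS, showWarnings = FALSE, recursive = TRUE)

study_config <- function() {
  simulation_config(n_samples = 300, n_variants = 660, ld_block_size = 5,
                    maf_range = c(0.1, 0.5), n_genes = 100,
                    category_counts = c(shared = 5, independent_eqtl = 5,
                                        independent_pqtl = 5),
                    cis_r2 = 0.10, n_latent_factors = 3,
                    factor_strength = 0.05,
                    n_prs_snps = 30, n_core_genes = 5, core_r2 = 0.1,
                    tf_trans_r2 = 0.2, tf_target_r2 = 0.5,
                    mrna_to_protein_r2 = 0.8, n_decoy_bs = 8L, seed = SEED)
}

say <- function(...) cat(sprintf(...), "\n")
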