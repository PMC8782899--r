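# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no binary fixtures.

# small variant table with explicit dosages
make_vt <- function(geno, pos = NULL, chrom = "chr1") {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno))) rownames(geno) <- paste0("v", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("s", seq_len(ncol(geno)))
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 1000L
  info <- data.frame(variant_id = rownames(geno), chrom = chrom, pos = pos,
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  variant_table(info, geno)
}

# omics matrix from a plain matrix, default gene/sample names
make_om <- function(m, layer = "mrna") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  omics_matrix(m, layer)
}

# random HWE dosage vector
rdosage <- function(n, maf) rbinom(n, 2, maf)

# covariate frame with the clinical/technical columns the fitters expect
make_covs <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(age = rnorm(n, 65, 8), sex = rbinom(n, 1, 0.5),
             BMI = rnorm(n, 28, 4), sysBP = rnorm(n, 135, 15),
             CRP = exp(rnorm(n)), NT_proBNP = exp(rnorm(n, 6, 1)),
             diabetes = rbinom(n, 1, 0.3), htn_medication = rbinom(n, 1, 0.5),
             myocardial_infarction = rbinom(n, 1, 0.3),
             smoking = rbinom(n, 1, 0.2), AF = rbinom(n, 1, 0.4),
             RIN = rnorm(n, 7.5, 0.5), protein_concentration = rnorm(n, 10, 2),
             fibroblast_score = rnorm(n),
             row.names = paste0("s", seq_len(n)))
}

# tiny simulation config for Monte-Carlo loops (one gene per class)
tiny_config <- function(n_samples, seed, ...) {
  simulation_config(n_samples = n_samples, n_variants = 25, ld_block_size = 5,
                    n_genes = 3,
                    category_counts = c(shared = 1, independent_eqtl = 1,
                                        independent_pqtl = 1),
                    n_latent_factors = 0, n_prs_snps = 1, n_core_genes = 0,
                    n_decoy_bs = 0, missing_protein_rate = 0,
                    seed = seed, ...)
}
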