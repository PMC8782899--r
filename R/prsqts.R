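# Polygenic risk scoring with percentile calibration, and the eQTS/pQTS
# regressions ranking genes by aggregated trans-effects of the score.

#' Polygenic risk score from weighted allele dosages
#'
#' score = sum over weight variants of weight x (dosage of the effect
#' allele). Variants absent from the genotype table contribute
#' `weight * 2 * freq` (the expected dosage at the risk-allele frequency)
#' to every sample; variants whose effect allele matches neither ref nor
#' alt are skipped with a warning.
#'
#' @param vt a [variant_table()].
#' @param weights data.frame `variant_id, effect_allele, other_allele,
#'   weight, freq`.
#' @return numeric per-sample score; attributes `n_missing_imputed` and
#'   `n_skipped`.
#' @export
score_prs <- function(vt, weights) {
  if (anyDuplicated(weights$variant_id)) stop("duplicate variant ids in weights")
  if (any(weights$freq <= 0 | weights$freq >= 1))
    stop("risk-allele frequencies must lie in (0, 1)")
  n <- ncol(vt$geno)
  score <- numeric(n)
  n_missing <- 0L; n_skipped <- 0L
  for (i in seq_len(nrow(weights))) {
    w <- weights[i, ]
    j <- match(w$variant_id, vt$info$variant_id)
    if (is.na(j)) {
      score <- score + w$weight * 2 * w$freq
      n_missing <- n_missing + 1L
      next
    }
    if (w$effect_allele == vt$info$alt[j]) {
      dos <- vt$geno[j, ]
    } else if (w$effect_allele == vt$info$ref[j]) {
      dos <- 2 - vt$geno[j, ]
    } else {
      warning("unresolvable effect allele for ", w$variant_id, "; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    dos[is.na(dos)] <- 2 * w$freq
    score <- score + w$weight * dos
  }
  names(score) <- colnames(vt$geno)
  attr(score, "n_missing_imputed") <- n_missing
  attr(score, "n_skipped") <- n_skipped
  score
}

#' Percentile calibration of PRS values against a reference panel
#'
#' Each cohort sample's percentile rank within the pooled cohort + panel
#' score vector (ties by average rank), on (0, 100].
#'
#' @param cohort_scores,panel_scores numeric score vectors.
#' @return percentiles for the cohort samples.
#' @export
prs_percentiles <- function(cohort_scores, panel_scores) {
  stopifnot(length(panel_scores) > 0)
  pooled <- c(cohort_scores, panel_scores)
  r <- rank(pooled, ties.method = "average")
  pct <- 100 * r / length(pooled)
  out <- pct[seq_along(cohort_scores)]
  names(out) <- names(cohort_scores)
  out
}

#' QTS covariate sets per layer
#'
#' Shared clinical covariates plus the layer's technical covariate (RIN
#' for mRNA, protein concentration for protein).
#' @param layer `"mrna"` or `"protein"`.
#' @return character vector of covariate column names.
#' @export
qts_covariates <- function(layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  c("age", "sex", "BMI", "sysBP", "CRP", "NT_proBNP",
    if (layer == "mrna") "RIN" else "protein_concentration")
}

#' eQTS / pQTS: regress each gene on the polygenic score
#'
#' Per gene, OLS of abundance on intercept + PRS + clinical covariates +
#' the layer's technical covariate + that gene's cis lead-SNP dosages
#' (none for genes without significant cis loci); reports the t-test on
#' the PRS coefficient. Collinear cis SNP columns are dropped in id order
#' until the design has full rank. Fits use complete cases; n and df are
#' recorded per gene.
#'
#' @param om an [omics_matrix()] (`mrna` or `protein` layer).
#' @param prs per-sample PRS values (typically percentiles).
#' @param covs covariate data.frame (rownames = sample ids).
#' @param cis_lead_snps named list: gene id -> character vector of cis
#'   lead variant ids (may be empty / absent).
#' @param vt [variant_table()] supplying the lead-SNP dosages (only needed
#'   when `cis_lead_snps` is non-empty).
#' @return data.table `gene_id, layer, beta_prs, t_stat, p_value, n, df`.
#' @export
fit_qts <- function(om, prs, covs, cis_lead_snps = list(), vt = NULL) {
  layer <- if (om$layer == "protein") "protein" else "mrna"
  C <- covariate_matrix(covs, qts_covariates(layer))
  samples <- colnames(om$values)
  stopifnot(identical(rownames(covs), samples),
            identical(names(prs), samples) || is.null(names(prs)))
  res <- vector("list", nrow(om$values))
  genes <- gene_ids(om)
  for (i in seq_along(genes)) {
    g <- genes[i]
    X <- cbind(PRS = as.numeric(prs), C)
    leads <- cis_lead_snps[[g]]
    if (!is.null(leads) && length(leads)) {
      if (is.null(vt)) stop("vt required when cis lead SNPs are supplied")
      D <- t(vt$geno[leads, samples, drop = FALSE])
      colnames(D) <- leads
      X <- cbind(X, D)
    }
    fit <- ols_test(om$values[g, ], X)
    tr <- ols_term(fit, "PRS")
    res[[i]] <- data.table::data.table(gene_id = g, layer = om$layer,
                                       beta_prs = tr$beta, t_stat = tr$t_stat,
                                       p_value = tr$p_value, n = tr$n,
                                       df = tr$df)
  }
  data.table::rbindlist(res)
}
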