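# The linear-model QTL engine: cis-pair enumeration, additive-genotype
# regression with covariates (blocked via Frisch-Waugh residualization, but
# exactly equal to the per-pair OLS), latent-factor adjustment with
# factor-count optimization, residual/ratio phenotype construction, and
# Benjamini-Hochberg FDR.

#' Enumerate cis variant-gene pairs
#'
#' A pair is included iff variant and gene share a chromosome and the
#' variant position lies within `[gene_start - window, gene_end + window]`
#' (closed boundaries).
#'
#' @param vt a [variant_table()].
#' @param gene_annotations data.frame `gene_id, chrom, start, end, strand`.
#' @param window cis range in bp (default 1e6).
#' @return data.frame `variant_id, gene_id`.
#' @export
enumerate_cis_pairs <- function(vt, gene_annotations, window = 1e6) {
  ga <- gene_annotations
  bad <- !complete.cases(ga[, c("chrom", "start", "end")])
  if (any(bad)) {
    warning("excluding ", sum(bad), " gene(s) without coordinates")
    ga <- ga[!bad, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(ga)), function(i) {
    hit <- vt$info$chrom == ga$chrom[i] &
      vt$info$pos >= ga$start[i] - window &
      vt$info$pos <= ga$end[i] + window
    if (!any(hit)) return(NULL)
    data.frame(variant_id = vt$info$variant_id[hit],
               gene_id = ga$gene_id[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(variant_id = character(0),
                                      gene_id = character(0))
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement; callers apply it
#' separately per omic layer.
#'
#' @param p_values numeric vector in \[0, 1\] (NA allowed, passed through).
#' @return adjusted values.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' QTL scan for a list of variant-gene pairs
#'
#' For each pair, ordinary least squares of expression on
#' intercept + dosage + covariates, reporting the dosage coefficient's
#' two-sided t-test. Pairs whose samples are complete are computed in a
#' vectorized block (covariates residualized out once), which equals the
#' per-pair regression exactly; pairs with missing dosages fall back to a
#' per-pair fit on complete cases.
#'
#' @param pairs data.frame `variant_id, gene_id`.
#' @param vt a [variant_table()].
#' @param om an [omics_matrix()] sharing the sample set.
#' @param covs numeric covariate matrix (samples x q) or NULL.
#' @param compute_fdr append a BH FDR column over all returned pairs
#'   (default TRUE; callers scanning several layers adjust per layer).
#' @return data.table of QTL records: `variant_id, gene_id, layer, beta,
#'   se, t_stat, p_value, fdr, n, df`.
#' @export
fit_qtl_scan <- function(pairs, vt, om, covs = NULL, compute_fdr = TRUE) {
  if (nrow(pairs) == 0)
    return(data.table::data.table(variant_id = character(0),
                                  gene_id = character(0), layer = character(0),
                                  beta = numeric(0), se = numeric(0),
                                  t_stat = numeric(0), p_value = numeric(0),
                                  fdr = numeric(0), n = integer(0),
                                  df = integer(0)))
  samples <- colnames(om$values)
  if (!identical(colnames(vt$geno), samples))
    stop("samples not aligned between genotypes and expression")
  if (!is.null(covs)) {
    covs <- as.matrix(covs)
    if (anyNA(covs)) stop("missing values in covariates")
  }
  n <- length(samples)
  q <- if (is.null(covs)) 0L else ncol(covs)
  G <- vt$geno[unique(pairs$variant_id), , drop = FALSE]
  E <- om$values[unique(pairs$gene_id), , drop = FALSE]
  complete_v <- rownames(G)[!apply(is.na(G), 1, any)]
  complete_g <- rownames(E)[!apply(is.na(E), 1, any)]

  # block path: residualize genotypes and expression on [1, covs] once
  Gr <- if (is.null(covs)) sweep(G[complete_v, , drop = FALSE], 1,
                                 rowMeans(G[complete_v, , drop = FALSE]))
        else residualize_rows(G[complete_v, , drop = FALSE], covs)
  Er <- if (is.null(covs)) sweep(E[complete_g, , drop = FALSE], 1,
                                 rowMeans(E[complete_g, , drop = FALSE]))
        else residualize_rows(E[complete_g, , drop = FALSE], covs)
  gss <- rowSums(Gr^2)
  ess <- rowSums(Er^2)

  blocked <- pairs$variant_id %in% complete_v & pairs$gene_id %in% complete_g
  res <- vector("list", nrow(pairs))
  df_block <- n - (q + 2L)
  for (i in seq_len(nrow(pairs))) {
    v <- pairs$variant_id[i]; g <- pairs$gene_id[i]
    if (blocked[i]) {
      sxy <- sum(Gr[v, ] * Er[g, ])
      sxx <- gss[[v]]
      if (sxx < 1e-12) {   # monomorphic after residualization
        res[[i]] <- list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                         p_value = NA_real_, n = n, df = df_block)
        next
      }
      beta <- sxy / sxx
      rss <- ess[[g]] - beta * sxy
      se <- sqrt(pmax(rss, 0) / df_block / sxx)
      tv <- beta / se
      res[[i]] <- list(beta = beta, se = se, t_stat = tv,
                       p_value = 2 * pt(abs(tv), df_block, lower.tail = FALSE),
                       n = n, df = df_block)
    } else {
      X <- cbind(dosage = vt$geno[v, ], covs)
      fit <- try(ols_test(om$values[g, ], X), silent = TRUE)
      if (inherits(fit, "try-error") ||
          "dosage" %in% fit$dropped) {
        res[[i]] <- list(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                         p_value = NA_real_, n = NA_integer_, df = NA_integer_)
      } else {
        tr <- ols_term(fit, "dosage")
        res[[i]] <- list(beta = tr$beta, se = tr$se, t_stat = tr$t_stat,
                         p_value = tr$p_value, n = tr$n, df = tr$df)
      }
    }
  }
  dt <- data.table::rbindlist(res)
  out <- data.table::data.table(variant_id = pairs$variant_id,
                                gene_id = pairs$gene_id,
                                layer = om$layer, dt)
  out[, fdr := if (compute_fdr) bh_fdr(p_value) else NA_real_]
  data.table::setcolorder(out, c("variant_id", "gene_id", "layer", "beta",
                                 "se", "t_stat", "p_value", "fdr", "n", "df"))
  out[]
}

#' Latent expression factors (deterministic principal-factor estimate)
#'
#' Top-`k` left singular factors of standardized expression (samples in
#' rows), after regressing out `known_covs` if supplied. This is a
#' deterministic confounder-capture device used in place of a Bayesian
#' factor model; factors have zero mean, are mutually orthogonal, and each
#' factor's sign is fixed by making its largest-magnitude loading positive.
#'
#' @param om an [omics_matrix()].
#' @param k number of factors (must satisfy `k < n_samples`); `k = 0`
#'   returns an empty factor set.
#' @param known_covs optional covariate matrix regressed out first.
#' @return list `k`, `factors` (samples x k), `method = "principal_factor"`.
#' @export
fit_latent_factors <- function(om, k, known_covs = NULL) {
  n <- ncol(om$values)
  if (k >= n) stop("k must be smaller than the number of samples")
  if (k == 0)
    return(list(k = 0L, factors = matrix(numeric(0), nrow = n, ncol = 0,
                                         dimnames = list(colnames(om$values), NULL)),
                method = "principal_factor"))
  V <- om$values
  if (!is.null(known_covs)) V <- residualize_rows(V, as.matrix(known_covs))
  # standardize genes, drop constants
  sds <- apply(V, 1, sd)
  V <- V[sds > 0, , drop = FALSE]
  Z <- (V - rowMeans(V)) / apply(V, 1, sd)
  Zc <- sweep(Z, 2, colMeans(Z))   # center samples so factors have zero mean
  sv <- svd(t(Zc), nu = k, nv = 0)
  Fm <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(Fm[, j]))
    if (Fm[i_max, j] < 0) Fm[, j] <- -Fm[, j]
  }
  Fm <- sweep(Fm, 2, colMeans(Fm))
  rownames(Fm) <- colnames(om$values)
  colnames(Fm) <- paste0("factor", seq_len(k))
  list(k = as.integer(k), factors = Fm, method = "principal_factor")
}

#' Choose the factor count maximizing QTL-gene yield
#'
#' Runs the cis scan for each candidate `k` and counts genes with at least
#' one association at FDR < `fdr_max`; returns the `k` with the highest
#' count (ties broken towards the smallest `k`).
#'
#' @param vt,om,pairs scan inputs as in [fit_qtl_scan()].
#' @param candidate_ks integer vector of factor counts to try.
#' @param covs optional known covariates included alongside the factors.
#' @param fdr_max significance threshold on the per-layer FDR (default 0.05).
#' @return list `k_best`, `table` (data.frame k, qtl_genes).
#' @export
optimize_factor_count <- function(vt, om, pairs, candidate_ks, covs = NULL,
                                  fdr_max = 0.05) {
  stopifnot(length(candidate_ks) > 0)
  counts <- integer(length(candidate_ks))
  for (i in seq_along(candidate_ks)) {
    k <- candidate_ks[i]
    lf <- fit_latent_factors(om, k, known_covs = covs)
    cv <- if (is.null(covs)) lf$factors else cbind(as.matrix(covs), lf$factors)
    if (ncol(cv) == 0) cv <- NULL
    rec <- fit_qtl_scan(pairs, vt, om, cv)
    counts[i] <- length(unique(rec$gene_id[!is.na(rec$fdr) & rec$fdr < fdr_max]))
  }
  ord <- order(-counts, candidate_ks)
  list(k_best = as.integer(candidate_ks[ord[1]]),
       table = data.frame(k = candidate_ks, qtl_genes = counts))
}

#' Residual phenotypes across the two omic layers
#'
#' Per gene, `residual_mrna` holds the residuals of mRNA ~ intercept +
#' protein, and `residual_protein` the residuals of protein ~ intercept +
#' mRNA; no other covariates enter at this step. Genes where the predictor
#' layer is constant get the centered response, flagged in attribute
#' `constant_predictor`.
#'
#' @param mrna,protein [omics_matrix()] objects on shared gene/sample sets.
#' @return list of two `OmicsMatrix` (`residual_mrna`, `residual_protein`).
#' @export
residual_phenotypes <- function(mrna, protein) {
  genes <- intersect(gene_ids(mrna), gene_ids(protein))
  samples <- colnames(mrna$values)
  stopifnot(identical(samples, colnames(protein$values)))
  M <- mrna$values[genes, , drop = FALSE]
  P <- protein$values[genes, , drop = FALSE]
  res_one <- function(Y, X) {
    out <- Y
    flagged <- character(0)
    for (g in genes) {
      x <- X[g, ]; y <- Y[g, ]
      if (sd(x) == 0) {
        out[g, ] <- y - mean(y)
        flagged <- c(flagged, g)
      } else {
        b <- cov(y, x) / var(x)
        out[g, ] <- y - mean(y) - b * (x - mean(x))
      }
    }
    attr(out, "constant_predictor") <- flagged
    out
  }
  list(residual_mrna = omics_matrix(res_one(M, P), "residual_mrna"),
       residual_protein = omics_matrix(res_one(P, M), "residual_protein"))
}

#' Protein-per-mRNA ratio phenotype
#'
#' Both layers are per-gene normal-quantile normalized, then the ratio is
#' the gene-wise difference protein - mRNA (a difference on the normalized
#' scale standing in for a ratio on the raw scale). Genes absent from
#' either layer are excluded.
#'
#' @param mrna,protein [omics_matrix()] objects (per-sample normalized).
#' @return an [omics_matrix()] on the `ratio` layer.
#' @export
ratio_phenotype <- function(mrna, protein) {
  genes <- intersect(gene_ids(mrna), gene_ids(protein))
  m <- normal_quantile_transform(
    omics_matrix(mrna$values[genes, , drop = FALSE], "mrna", mrna$norm_state),
    "per_gene")
  p <- normal_quantile_transform(
    omics_matrix(protein$values[genes, , drop = FALSE], "protein", protein$norm_state),
    "per_gene")
  omics_matrix(p$values - m$values, "ratio",
               c(per_sample_nqn = FALSE, per_gene_nqn = TRUE))
}

#' Per-omic factor counts used for the final scans
#'
#' Reference per-layer factor counts for a cohort of ~75 samples, as
#' selected by [optimize_factor_count()] on each layer (eQTL 12, pQTL 10,
#' residual-mRNA 8, residual-protein 12, ratio 9 plus the fibroblast
#' score). Re-optimize for other cohorts.
#' @export
DEFAULT_FACTOR_COUNTS <- c(mrna = 12L, protein = 10L, residual_mrna = 8L,
                           residual_protein = 12L, ratio = 9L)
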