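# Targeted trans-QTL mapping on the sized candidate set, binding-site
# fine-mapping, TF activity scoring, the four-criterion mediation filter
# for functional TF targets, partial correlations, and the differential
# protein analysis with target-set replication GSEA.

#' Select trait-associated SNPs for targeted trans mapping
#'
#' GWAS hits are filtered by MAF (>= `maf_min`), grouped greedily at
#' r2 > `prune_r2`, and one representative kept per group. The default
#' keep rule retains the smallest GWAS P per group (`keep = "lowest_p"`);
#' `keep = "highest_p"` is available as well.
#'
#' @param gwas_hits data.frame `variant_id, p_value` (GWAS association P).
#' @param vt a [variant_table()].
#' @param maf_min MAF filter (default 0.1).
#' @param prune_r2 LD pruning threshold (default 0.5, strict >).
#' @param keep representative rule per LD group.
#' @return character vector of selected variant ids; dropped hits (absent
#'   from the genotypes) recorded in attribute `dropped`.
#' @export
select_trait_snps <- function(gwas_hits, vt, maf_min = 0.1, prune_r2 = 0.5,
                              keep = c("lowest_p", "highest_p")) {
  keep <- match.arg(keep)
  hits <- as.data.frame(gwas_hits)
  present <- hits$variant_id %in% vt$info$variant_id
  dropped <- hits$variant_id[!present]
  if (length(dropped)) warning(length(dropped), " GWAS hit(s) absent from genotypes")
  hits <- hits[present, , drop = FALSE]
  maf <- vt$info$maf[match(hits$variant_id, vt$info$variant_id)]
  hits <- hits[maf >= maf_min, , drop = FALSE]
  if (nrow(hits) == 0) return(structure(character(0), dropped = dropped))
  hits <- hits[order(if (keep == "lowest_p") hits$p_value else -hits$p_value,
                     hits$variant_id), , drop = FALSE]
  selected <- character(0)
  remaining <- hits$variant_id
  while (length(remaining)) {
    head_v <- remaining[1]
    selected <- c(selected, head_v)
    remaining <- remaining[-1]
    if (length(remaining)) {
      r2v <- ld_r2_vec(vt, head_v, remaining)
      remaining <- remaining[is.na(r2v) | r2v <= prune_r2]
    }
  }
  structure(selected, dropped = dropped)
}

#' Trans covariate sets per layer
#' @param layer `"mrna"` or `"protein"`.
#' @return covariate column names (clinical set + fibroblast score + the
#'   layer's technical covariate).
#' @export
trans_covariates <- function(layer = c("mrna", "protein")) {
  layer <- match.arg(layer)
  c("age", "sex", "BMI", "sysBP", "CRP", "NT_proBNP", "fibroblast_score",
    if (layer == "mrna") "RIN" else "protein_concentration")
}

#' Targeted trans-QTL scan
#'
#' OLS of each candidate gene's abundance on intercept + dosage + the
#' trans covariate set; BH FDR per layer over the candidates x SNPs grid;
#' records are flagged significant at FDR < `fdr_max`. No latent factors
#' are used at this step.
#'
#' @param candidates gene ids measured on the layer (unmeasured ones are
#'   skipped and listed in attribute `skipped`).
#' @param snps variant ids to test.
#' @param vt a [variant_table()].
#' @param om an [omics_matrix()].
#' @param covs covariate data.frame.
#' @param fdr_max significance threshold (default 0.2).
#' @return QTL record data.table with a `significant` flag.
#' @export
map_trans_qtl <- function(candidates, snps, vt, om, covs, fdr_max = 0.2) {
  measured <- intersect(candidates, gene_ids(om))
  skipped <- setdiff(candidates, measured)
  layer <- if (om$layer == "protein") "protein" else "mrna"
  C <- covariate_matrix(covs, trans_covariates(layer))
  pairs <- expand.grid(variant_id = snps, gene_id = measured,
                       stringsAsFactors = FALSE)
  rec <- fit_qtl_scan(pairs, vt, om, C)
  rec[, significant := !is.na(fdr) & fdr < fdr_max]
  attr(rec, "skipped") <- skipped
  rec[]
}

#' Filter and merge ChIP/eCLIP peaks
#'
#' Retains peaks with log2 enrichment > 0 and -log10 P > -log10(0.05),
#' then merges overlapping retained intervals per chromosome.
#'
#' @param peaks data.frame `chrom, start, end, log2_enrichment,
#'   neg_log10_p` (1-based inclusive).
#' @return merged interval data.frame.
#' @export
filter_merge_clip_peaks <- function(peaks) {
  keep <- peaks$log2_enrichment > 0 & peaks$neg_log10_p > -log10(0.05)
  p <- peaks[keep, , drop = FALSE]
  if (nrow(p) == 0) return(p[, c("chrom", "start", "end")])
  p <- p[order(p$chrom, p$start, p$end), ]
  out <- list()
  cur <- p[1, c("chrom", "start", "end")]
  for (i in seq_len(nrow(p))[-1]) {
    if (p$chrom[i] == cur$chrom && p$start[i] <= cur$end + 1) {
      cur$end <- max(cur$end, p$end[i])
    } else {
      out[[length(out) + 1]] <- cur
      cur <- p[i, c("chrom", "start", "end")]
    }
  }
  out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

overlap_bp <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)

#' Annotate functional TF binding sites per gene
#'
#' A ChIP peak counts towards a gene iff it overlaps an open-chromatin
#' region by at least `min_overlap` bp and lies in the gene's promoter or
#' in a region linked to that promoter (promoter-capture interactions).
#' All intervals use the internal 1-based inclusive convention (see
#' [read_bed()]).
#'
#' @param chip_peaks data.frame `chrom, start, end`.
#' @param promoters data.frame `chrom, start, end, name` (name = gene id).
#' @param hic_links data.frame from [read_links()]: anchor
#'   (`chrom1,start1,end1`) linked to promoter (`chrom2,start2,end2`);
#'   anchors that overlap no promoter are ignored and counted.
#' @param open_chromatin data.frame `chrom, start, end` (the permissive
#'   chromatin-state regions).
#' @param min_overlap minimal open-chromatin overlap in bp (default 25).
#' @return data.frame `gene_id, bs_count`; unmapped link anchors counted
#'   in attribute `unmapped_links`.
#' @export
annotate_functional_bs <- function(chip_peaks, promoters, hic_links = NULL,
                                   open_chromatin = NULL, min_overlap = 25) {
  open_ok <- function(chrom, s, e) {
    if (is.null(open_chromatin)) return(rep(TRUE, length(s)))
    vapply(seq_along(s), function(i) {
      oc <- open_chromatin[open_chromatin$chrom == chrom[i], , drop = FALSE]
      any(overlap_bp(s[i], e[i], oc$start, oc$end) >= min_overlap)
    }, logical(1))
  }
  peaks <- chip_peaks
  peaks_open <- peaks[open_ok(peaks$chrom, peaks$start, peaks$end), , drop = FALSE]

  # regions attributable to each gene: its promoter plus linked regions
  regions <- data.frame(chrom = promoters$chrom, start = promoters$start,
                        end = promoters$end, gene_id = promoters$name,
                        stringsAsFactors = FALSE)
  unmapped <- 0L
  if (!is.null(hic_links) && nrow(hic_links)) {
    for (i in seq_len(nrow(hic_links))) {
      pr <- promoters[promoters$chrom == hic_links$chrom2[i] &
                      overlap_bp(hic_links$start2[i], hic_links$end2[i],
                                 promoters$start, promoters$end) > 0, ,
                      drop = FALSE]
      if (nrow(pr) == 0) { unmapped <- unmapped + 1L; next }
      regions <- rbind(regions,
                       data.frame(chrom = hic_links$chrom1[i],
                                  start = hic_links$start1[i],
                                  end = hic_links$end1[i],
                                  gene_id = pr$name,
                                  stringsAsFactors = FALSE))
    }
  }
  genes <- unique(promoters$name)
  counts <- integer(length(genes)); names(counts) <- genes
  if (nrow(peaks_open)) {
    for (g in genes) {
      rg <- regions[regions$gene_id == g, , drop = FALSE]
      hit <- vapply(seq_len(nrow(peaks_open)), function(i) {
        any(peaks_open$chrom[i] == rg$chrom &
            overlap_bp(peaks_open$start[i], peaks_open$end[i],
                       rg$start, rg$end) > 0)
      }, logical(1))
      counts[g] <- sum(hit)
    }
  }
  out <- data.frame(gene_id = genes, bs_count = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "unmapped_links") <- unmapped
  out
}

#' Transcription-factor activity per sample
#'
#' Target expression is optionally residualized on `adjust_covs`, per-gene
#' normal-quantile normalized, and the activity is the binding-site-count
#' weighted sum over targets: TFA(sample) = sum_t bs_count_t x expr(t, s).
#'
#' @param mrna an [omics_matrix()].
#' @param ann data.frame `gene_id, bs_count` (targets with bs_count >= 1).
#' @param adjust_covs optional numeric covariate matrix (samples x q).
#' @return per-sample numeric activity vector; attributes `targets_used`
#'   and `weights`.
#' @export
compute_tfa <- function(mrna, ann, adjust_covs = NULL) {
  ann <- ann[ann$bs_count >= 1, , drop = FALSE]
  targets <- intersect(ann$gene_id, gene_ids(mrna))
  if (length(targets) == 0) stop("no annotated target is measured")
  V <- mrna$values[targets, , drop = FALSE]
  if (!is.null(adjust_covs)) V <- residualize_rows(V, as.matrix(adjust_covs))
  V <- normal_quantile_transform(omics_matrix(V, mrna$layer), "per_gene")$values
  w <- ann$bs_count[match(targets, ann$gene_id)]
  tfa <- as.vector(w %*% V)
  names(tfa) <- colnames(V)
  attr(tfa, "targets_used") <- targets
  attr(tfa, "weights") <- setNames(w, targets)
  tfa
}

#' Mediation-style filter for functional TF targets
#'
#' Per target gene, four criteria:
#' (a) at least one functional binding site;
#' (b) model 1 (target mRNA ~ SNP + fibroblast score + RIN): SNP
#'     coefficient P < 0.05 with sign concordant with the SNP-to-TF
#'     direction (or literally negative when `sign_rule = "negative"`);
#' (c) model 2 (model 1 + TF mRNA): SNP coefficient P > 0.2 (the
#'     association vanishes given the TF transcript);
#' (d) model 3 (target protein ~ TF mRNA + fibroblast score + protein
#'     concentration): BH FDR over the (a-c) survivors < 0.05 with T > 0.
#' The final functional flag is a & b & c & d.
#'
#' @param snp_dosage named per-sample dosage vector of the driving SNP.
#' @param tf_mrna named per-sample TF transcript vector.
#' @param target_mrna,target_protein [omics_matrix()] objects holding the
#'   candidate targets (genes missing a layer are marked not evaluable).
#' @param ann data.frame `gene_id, bs_count` (criterion a).
#' @param covs covariate data.frame with `fibroblast_score`, `RIN`,
#'   `protein_concentration`.
#' @param sign_rule `"concordant"` (default; concordant with the fitted
#'   SNP-to-TF direction) or `"negative"` (the literal rule for a
#'   repressive risk allele).
#' @param alpha_b,alpha_c,alpha_d criterion thresholds (0.05, 0.2, 0.05).
#' @return data.table per target: criterion flags, per-model statistics,
#'   `functional` flag, `evaluable` flag.
#' @export
mediation_filter <- function(snp_dosage, tf_mrna, target_mrna, target_protein,
                             ann, covs, sign_rule = c("concordant", "negative"),
                             alpha_b = 0.05, alpha_c = 0.2, alpha_d = 0.05) {
  sign_rule <- match.arg(sign_rule)
  samples <- colnames(target_mrna$values)
  snp <- snp_dosage[samples]
  tf <- tf_mrna[samples]

  # SNP -> TF direction for the concordance rule
  tf_fit <- ols_test(tf, cbind(SNP = snp,
                               covariate_matrix(covs, c("fibroblast_score", "RIN"))))
  tf_dir <- sign(ols_term(tf_fit, "SNP")$beta)
  want_sign <- if (sign_rule == "negative") -1 else tf_dir

  genes <- gene_ids(target_mrna)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    bs <- ann$bs_count[match(g, ann$gene_id)]
    a_ok <- !is.na(bs) && bs >= 1
    has_prot <- g %in% gene_ids(target_protein)
    if (!has_prot) {
      res[[i]] <- data.table::data.table(gene_id = g, bs_count = bs,
        crit_a = a_ok, crit_b = NA, crit_c = NA, crit_d = NA,
        b1_m1 = NA_real_, t_m1 = NA_real_, p_m1 = NA_real_, df_m1 = NA_integer_,
        b1_m2 = NA_real_, t_m2 = NA_real_, p_m2 = NA_real_, df_m2 = NA_integer_,
        b1_m3 = NA_real_, t_m3 = NA_real_, p_m3 = NA_real_, df_m3 = NA_integer_,
        fdr_m3 = NA_real_, functional = FALSE, evaluable = FALSE)
      next
    }
    y_m <- target_mrna$values[g, samples]
    y_p <- target_protein$values[g, samples]
    C1 <- covariate_matrix(covs, c("fibroblast_score", "RIN"))
    m1 <- ols_test(y_m, cbind(SNP = snp, C1))
    t1 <- ols_term(m1, "SNP")
    m2 <- ols_test(y_m, cbind(SNP = snp, TF = tf, C1))
    t2 <- ols_term(m2, "SNP")
    C3 <- covariate_matrix(covs, c("fibroblast_score", "protein_concentration"))
    m3 <- ols_test(y_p, cbind(TF = tf, C3))
    t3 <- ols_term(m3, "TF")
    b_ok <- t1$p_value < alpha_b && sign(t1$beta) == want_sign
    c_ok <- t2$p_value > alpha_c
    res[[i]] <- data.table::data.table(gene_id = g, bs_count = bs,
      crit_a = a_ok, crit_b = b_ok, crit_c = c_ok, crit_d = NA,
      b1_m1 = t1$beta, t_m1 = t1$t_stat, p_m1 = t1$p_value, df_m1 = t1$df,
      b1_m2 = t2$beta, t_m2 = t2$t_stat, p_m2 = t2$p_value, df_m2 = t2$df,
      b1_m3 = t3$beta, t_m3 = t3$t_stat, p_m3 = t3$p_value, df_m3 = t3$df,
      fdr_m3 = NA_real_, functional = FALSE, evaluable = TRUE)
  }
  out <- data.table::rbindlist(res)
  surv <- which(out$evaluable & out$crit_a &
                !is.na(out$crit_b) & out$crit_b &
                !is.na(out$crit_c) & out$crit_c)
  if (length(surv)) {
    out$fdr_m3[surv] <- bh_fdr(out$p_m3[surv])
    out$crit_d[surv] <- out$fdr_m3[surv] < alpha_d & out$t_m3[surv] > 0
    out$functional[surv] <- out$crit_d[surv]
  }
  out[]
}

#' Partial correlation given conditioning variables
#'
#' Correlation of the OLS residuals of x given z and y given z, with the
#' t-transform P at n - 2 - ncol(z) degrees of freedom.
#'
#' @param x,y numeric vectors (length >= 4).
#' @param z numeric vector or matrix of conditioning variables.
#' @return list `estimate, statistic, p_value, df`; degenerate residuals
#'   yield `estimate = NA` with `degenerate = TRUE`.
#' @export
partial_correlation <- function(x, y, z) {
  z <- as.matrix(z)
  stopifnot(length(x) == length(y), length(x) == nrow(z), length(x) >= 4)
  X <- cbind(1, z)
  qr_ <- qr(X)
  rx <- qr.resid(qr_, x)
  ry <- qr.resid(qr_, y)
  tol <- 1e-10
  if (sd(rx) <= tol * (sd(x) + tol) || sd(ry) <= tol * (sd(y) + tol))
    return(list(estimate = NA_real_, statistic = NA_real_,
                p_value = NA_real_, df = NA_integer_, degenerate = TRUE))
  r <- cor(rx, ry)
  df <- length(x) - 2 - ncol(z)
  tv <- r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = tv,
       p_value = 2 * pt(abs(tv), df, lower.tail = FALSE),
       df = df, degenerate = FALSE)
}

#' Differential protein analysis for disease status
#'
#' Per gene, OLS of protein abundance on intercept + AF status + the
#' adjustment covariates (age, sex, BMI, diabetes, sysBP, hypertension
#' medication, myocardial infarction, smoking, fibroblast score, protein
#' concentration), reporting the AF coefficient with BH FDR across genes.
#'
#' @param protein an [omics_matrix()].
#' @param covs covariate data.frame with binary `AF` column (both classes
#'   present; post-operative-only cases are expected to be excluded
#'   upstream).
#' @return data.table `gene_id, beta_af, t_stat, p_value, fdr, n, df`.
#' @export
diff_protein_af <- function(protein, covs) {
  if (length(unique(covs$AF[!is.na(covs$AF)])) < 2)
    stop("AF status must contain both classes")
  C <- covariate_matrix(covs, c("age", "sex", "BMI", "diabetes", "sysBP",
                                "htn_medication", "myocardial_infarction",
                                "smoking", "fibroblast_score",
                                "protein_concentration"))
  genes <- gene_ids(protein)
  res <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    fit <- ols_test(protein$values[genes[i], ], cbind(AF = covs$AF, C))
    tr <- ols_term(fit, "AF")
    res[[i]] <- data.table::data.table(gene_id = genes[i], beta_af = tr$beta,
                                       t_stat = tr$t_stat, p_value = tr$p_value,
                                       n = tr$n, df = tr$df)
  }
  out <- data.table::rbindlist(res)
  out[, fdr := bh_fdr(p_value)]
  out[]
}

#' Replication GSEA of a target set against a differential ranking
#'
#' Preranked GSEA of the single target set against the differential
#' statistic; reports the directional permutation P. Sets smaller than the
#' usual minimum are allowed (min-size override), flagged in the result.
#'
#' @param diff_ranking named numeric statistic (e.g. t-statistics or a
#'   [replication_ranking()]).
#' @param target_set character vector of gene ids.
#' @param n_perm,seed permutation settings.
#' @return one-row [preranked_gsea()] table with attribute
#'   `min_size_override`.
#' @export
target_set_replication <- function(diff_ranking, target_set, n_perm = 10000,
                                   seed = 1L) {
  inter <- intersect(target_set, names(diff_ranking))
  if (length(inter) == 0) stop("target set does not intersect the ranking")
  res <- preranked_gsea(diff_ranking, list(target_set = target_set),
                        min_size = 1, max_size = length(diff_ranking) - 1,
                        n_perm = n_perm, seed = seed)
  attr(res, "min_size_override") <- length(inter) < 15
  res
}
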