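# Locus-level machinery: LD r2, greedy clumping, the shared/independent
# regulatory classification of lead-SNP-gene pairs, approximate-Bayes-factor
# colocalization, and the annotation/GWAS enrichment tests.

#' LD between two variants
#'
#' Squared Pearson correlation of the dosage vectors over shared
#' non-missing samples.
#'
#' @param vt a [variant_table()].
#' @param a,b variant ids.
#' @return r-squared, or NA for a monomorphic variant.
#' @export
ld_r2 <- function(vt, a, b) {
  x <- vt$geno[a, ]; y <- vt$geno[b, ]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)^2
}

# r2 of one variant against many (complete-data fast path with pairwise
# fallback)
ld_r2_vec <- function(vt, a, ids) {
  vapply(ids, function(b) ld_r2(vt, a, b), numeric(1))
}

#' Greedy LD clumping of QTL records
#'
#' Repeatedly takes the unassigned variant with the smallest p-value
#' (<= `p1`) as a clump lead, then assigns every unassigned variant with
#' p <= `p2`, within `kb` kilobases of the lead and r2 >= `r2` with the
#' lead, to that clump. Ties on p are broken by position, then id.
#'
#' @param records data.frame/data.table with `variant_id` and `p_value`
#'   (records for one gene; a layer or the per-variant minimum across
#'   layers, caller's choice).
#' @param vt a [variant_table()] providing dosages and positions.
#' @param r2 clump r2 threshold (default 0.5).
#' @param kb clump distance in kb (default 250).
#' @param p1 lead significance threshold.
#' @param p2 member significance threshold.
#' @return list of clumps: each `lead`, `members` (including the lead),
#'   `lead_p`.
#' @export
ld_clump <- function(records, vt, r2 = 0.5, kb = 250, p1 = 0.05, p2 = 0.8) {
  rec <- as.data.frame(records)[, c("variant_id", "p_value")]
  rec <- rec[!is.na(rec$p_value), , drop = FALSE]
  rec <- rec[!duplicated(rec$variant_id), , drop = FALSE]
  pos <- vt$info$pos[match(rec$variant_id, vt$info$variant_id)]
  ord <- order(rec$p_value, pos, rec$variant_id)
  rec <- rec[ord, , drop = FALSE]; pos <- pos[ord]
  assigned <- rep(FALSE, nrow(rec))
  clumps <- list()
  repeat {
    cand <- which(!assigned & rec$p_value <= p1)
    if (length(cand) == 0) break
    lead <- cand[1]
    members <- lead
    others <- which(!assigned & seq_len(nrow(rec)) != lead &
                    rec$p_value <= p2 &
                    abs(pos - pos[lead]) <= kb * 1000)
    if (length(others)) {
      r2v <- ld_r2_vec(vt, rec$variant_id[lead], rec$variant_id[others])
      members <- c(lead, others[!is.na(r2v) & r2v >= r2])
    }
    assigned[members] <- TRUE
    clumps[[length(clumps) + 1]] <- list(lead = rec$variant_id[lead],
                                         members = rec$variant_id[members],
                                         lead_p = rec$p_value[lead])
  }
  clumps
}

#' Classify a locus into a regulatory category
#'
#' Rule table on the four FDR values of the same lead-SNP-gene pair at
#' threshold `alpha`:
#' shared iff eQTL and pQTL significant but neither residual QTL is;
#' independent eQTL iff eQTL and residual-eQTL significant but neither
#' protein test is; independent pQTL symmetrically; everything else is
#' unclassified.
#'
#' @param fdr_e,fdr_p,fdr_res_e,fdr_res_p the four FDR values.
#' @param alpha significance threshold (default 0.05).
#' @return list `category` and the four FDRs used.
#' @export
classify_locus <- function(fdr_e, fdr_p, fdr_res_e, fdr_res_p, alpha = 0.05) {
  vals <- c(e = fdr_e, p = fdr_p, res_e = fdr_res_e, res_p = fdr_res_p)
  if (anyNA(vals))
    return(list(category = "unclassified", reason = "missing FDR value",
                fdr = vals))
  sig <- vals < alpha
  category <-
    if (sig[["e"]] && sig[["p"]] && !sig[["res_e"]] && !sig[["res_p"]]) "shared"
    else if (sig[["e"]] && sig[["res_e"]] && !sig[["p"]] && !sig[["res_p"]]) "independent_eqtl"
    else if (sig[["p"]] && sig[["res_p"]] && !sig[["e"]] && !sig[["res_e"]]) "independent_pqtl"
    else "unclassified"
  list(category = category, fdr = vals)
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' With V = se^2, W = w_sd^2 and z = beta/se:
#' log ABF = 0.5 log(V / (V + W)) + z^2/2 * W / (V + W).
#' (ABF > 1 favours association.)
#'
#' @param beta,se effect estimate and standard error (se > 0).
#' @param w_sd prior effect standard deviation (default 0.15, the
#'   quantitative-trait default).
#' @return log approximate Bayes factor.
#' @export
wakefield_log_abf <- function(beta, se, w_sd = 0.15) {
  if (any(se <= 0)) stop("se must be positive")
  V <- se^2; W <- w_sd^2; z <- beta / se
  0.5 * log(V / (V + W)) + (z^2 / 2) * (W / (V + W))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Colocalization by approximate Bayes factors
#'
#' Enumerates the five hypotheses (H0 no association; H1/H2 one trait
#' only; H3 two distinct causal variants; H4 one shared causal variant)
#' from per-variant ABFs of the two traits with prior probabilities `p1`,
#' `p2`, `p12`, and labels the locus `shared_causal` if pp4 > 0.5,
#' `independent_signals` if pp1+pp2+pp3 > 0.5, else `underpowered`.
#'
#' @param stats_e,stats_p data.frames with columns `variant_id, beta, se`
#'   over the same variant set (>= 2 variants).
#' @param p1,p2,p12 prior probabilities (defaults 1e-4, 1e-4, 1e-5).
#' @param w_sd ABF prior sd (default 0.15).
#' @return list `pp` (named pp0..pp4, summing to 1) and `label`.
#' @export
coloc_abf <- function(stats_e, stats_p, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      w_sd = 0.15) {
  ids <- intersect(stats_e$variant_id, stats_p$variant_id)
  if (length(ids) < 2) stop("colocalization needs at least 2 shared variants")
  e <- stats_e[match(ids, stats_e$variant_id), ]
  p <- stats_p[match(ids, stats_p$variant_id), ]
  l1 <- wakefield_log_abf(e$beta, e$se, w_sd)
  l2 <- wakefield_log_abf(p$beta, p$se, w_sd)
  lsum1 <- log_sum_exp(l1)
  lsum2 <- log_sum_exp(l2)
  lsum12 <- log_sum_exp(l1 + l2)
  # sum over ordered pairs (i, j) with i != j:
  # log( exp(lsum1 + lsum2) - exp(lsum12) ), computed stably
  lsum3 <- {
    tot <- lsum1 + lsum2
    if (lsum12 >= tot) -Inf else tot + log1p(-exp(lsum12 - tot))
  }
  lh <- c(h0 = 0,
          h1 = log(p1) + lsum1,
          h2 = log(p2) + lsum2,
          h3 = log(p1) + log(p2) + lsum3,
          h4 = log(p12) + lsum12)
  pp <- exp(lh - log_sum_exp(lh))
  names(pp) <- paste0("pp", 0:4)
  label <- if (pp[["pp4"]] > 0.5) "shared_causal"
    else if (pp[["pp1"]] + pp[["pp2"]] + pp[["pp3"]] > 0.5) "independent_signals"
    else "underpowered"
  list(pp = pp, label = label)
}

#' MAF- and TSS-distance-matched background variants
#'
#' Samples `n` variants without replacement from the pool members whose
#' MAF differs by at most `maf_tol` and whose TSS distance differs by at
#' most `tss_tol` from the index SNP; if fewer qualify, all are returned
#' and the result is flagged.
#'
#' @param snp one-row data.frame/list with `maf` and `tss_dist`.
#' @param pool data.frame with `variant_id, maf, tss_dist`.
#' @param maf_tol,tss_tol matching tolerances (defaults 0.05 and 1000 bp).
#' @param n background size per index SNP (default 100).
#' @param seed RNG seed for the draw.
#' @return character vector of variant ids with attribute `exhausted`.
#' @export
matched_background <- function(snp, pool, maf_tol = 0.05, tss_tol = 1000,
                               n = 100, seed = 1L) {
  ok <- abs(pool$maf - snp$maf) <= maf_tol &
    abs(pool$tss_dist - snp$tss_dist) <= tss_tol
  cand <- pool$variant_id[ok]
  if (length(cand) == 0) {
    warning("empty matched background pool")
    out <- character(0)
  } else if (length(cand) <= n) {
    out <- cand
  } else {
    set.seed(seed)
    out <- sample(cand, n)
  }
  attr(out, "exhausted") <- length(cand) < n
  out
}

#' Annotation enrichment of top QTL SNPs vs matched background
#'
#' Two-sided Fisher's exact test on the 2x2 table of
#' (QTL vs background) x (annotated vs not); the sample (cross-product)
#' odds ratio is reported alongside.
#'
#' @param top_snps,backgrounds character vectors of variant ids.
#' @param annotated character vector: variant ids overlapping the
#'   annotation.
#' @return list `table`, `odds_ratio` (sample OR; Haldane 0.5 correction
#'   note when a cell is zero), `p_value`.
#' @export
annotation_enrichment <- function(top_snps, backgrounds, annotated) {
  a <- sum(top_snps %in% annotated)
  b <- length(top_snps) - a
  c_ <- sum(backgrounds %in% annotated)
  d <- length(backgrounds) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("qtl", "background"),
                                c("annotated", "not_annotated")))
  haldane <- any(tab == 0)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  p <- fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, haldane = haldane, p_value = p)
}

#' GWAS-hit enrichment among QTL SNPs
#'
#' Every tested SNP is cross-classified by (has a QTL with
#' p < `qtl_p`) x (is a GWAS hit or an r2 > `proxy_r2` proxy of one);
#' two-sided Fisher's exact test per trait group. Also reports, per GWAS
#' hit, the best proxy-gene pair (strongest QTL).
#'
#' @param qtl_records QTL records (`variant_id, gene_id, p_value`).
#' @param vt a [variant_table()].
#' @param gwas_hits data.frame `variant_id, trait`.
#' @param proxy_r2 LD threshold for proxies (default 0.8, strict >).
#' @param qtl_p QTL significance threshold (default 1e-5).
#' @param proxy_window_bp window around a hit within which proxies are
#'   sought (default 5e5).
#' @return list per trait group: `table`, `odds_ratio`, `p_value`,
#'   `overlap` (per-hit best proxy-gene pair).
#' @export
gwas_overlap_enrichment <- function(qtl_records, vt, gwas_hits,
                                    proxy_r2 = 0.8, qtl_p = 1e-5,
                                    proxy_window_bp = 5e5) {
  rec <- as.data.frame(qtl_records)
  tested <- unique(rec$variant_id)
  best_p <- tapply(rec$p_value, rec$variant_id, min, na.rm = TRUE)[tested]
  has_qtl <- !is.na(best_p) & best_p < qtl_p

  out <- list()
  for (trait in unique(gwas_hits$trait)) {
    hits <- intersect(gwas_hits$variant_id[gwas_hits$trait == trait],
                      vt$info$variant_id)
    annotated <- rep(FALSE, length(tested))
    names(annotated) <- tested
    overlap <- list()
    for (h in hits) {
      hpos <- vt$info$pos[match(h, vt$info$variant_id)]
      hchr <- vt$info$chrom[match(h, vt$info$variant_id)]
      near <- tested[tested %in% vt$info$variant_id[
        vt$info$chrom == hchr & abs(vt$info$pos - hpos) <= proxy_window_bp]]
      if (length(near) == 0) next
      r2v <- ld_r2_vec(vt, h, near)
      proxies <- near[near == h | (!is.na(r2v) & r2v > proxy_r2)]
      annotated[proxies] <- TRUE
      sub <- rec[rec$variant_id %in% proxies, , drop = FALSE]
      if (nrow(sub)) {
        b <- sub[which.min(sub$p_value), , drop = FALSE]
        overlap[[h]] <- data.frame(gwas_hit = h, proxy = b$variant_id,
                                   gene_id = b$gene_id, p_value = b$p_value)
      }
    }
    tab <- table(factor(has_qtl, c(TRUE, FALSE)),
                 factor(annotated, c(TRUE, FALSE)))
    dimnames(tab) <- list(qtl = c("sig", "nonsig"),
                          gwas = c("annotated", "not"))
    if (all(tab[, "annotated"] == 0)) {
      out[[trait]] <- list(table = tab, odds_ratio = NA_real_,
                           p_value = NA_real_,
                           note = "no annotated SNPs in group",
                           overlap = data.table::rbindlist(overlap))
      next
    }
    ft <- fisher.test(tab)
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    out[[trait]] <- list(table = tab, odds_ratio = or, p_value = ft$p.value,
                         overlap = data.table::rbindlist(overlap))
  }
  out
}
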