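# Preranked gene-set enrichment (weighted Kolmogorov-Smirnov running sum
# with gene-label permutation), leading-edge candidate selection, and the
# F-test power analysis that sizes the targeted trans gene set.

# Weighted KS enrichment score (exponent 1 on |stat|) plus the leading
# edge: the hit genes at or before the running-sum extremum.
gsea_es <- function(stats_sorted, hit_idx) {
  n <- length(stats_sorted)
  nh <- length(hit_idx)
  if (nh == 0 || nh == n) return(list(es = NA_real_, leading_edge = integer(0)))
  w <- abs(stats_sorted[hit_idx])
  wsum <- sum(w)
  if (wsum == 0) w <- rep(1 / nh, nh) else w <- w / wsum
  run <- numeric(n)
  run[hit_idx] <- w
  run[-hit_idx] <- -1 / (n - nh)
  cs <- cumsum(run)
  i_max <- which.max(cs); i_min <- which.min(cs)
  # extremum of largest magnitude; magnitude ties (within numerical noise)
  # resolve to the positive extremum
  es <- if (cs[i_max] >= -cs[i_min] - 1e-12) cs[i_max] else cs[i_min]
  peak <- if (es >= 0) i_max else i_min
  le <- if (es >= 0) hit_idx[hit_idx <= peak] else hit_idx[hit_idx >= peak]
  list(es = es, leading_edge = le)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score with hit
#' increments proportional to |stat| (exponent 1); the ES is the running
#' sum's extremum of largest magnitude (an exact magnitude tie resolves to
#' the positive extremum). The permutation P comes
#' from `n_perm` random gene-label sets of equal size, matched on ES sign;
#' NES is the ES normalized by the mean |permutation ES| of the same sign;
#' FDR is Benjamini-Hochberg across sets. The leading edge contains the
#' hits at or before the ES extremum. The permutation P is floored at
#' `1/(n_perm + 1)`.
#'
#' @param stats named numeric vector (gene-level statistic, finite).
#' @param sets named list of gene vectors.
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked universe (defaults 15 and 500).
#' @param n_perm number of gene-label permutations (default 1000).
#' @param seed RNG seed.
#' @return data.table `set, size, es, nes, p_perm, fdr` with a
#'   `leading_edge` list-column; skipped sets recorded in attribute
#'   `skipped`.
#' @export
preranked_gsea <- function(stats, sets, min_size = 15, max_size = 500,
                           n_perm = 1000, seed = 1L) {
  stopifnot(!is.null(names(stats)), all(is.finite(stats)))
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  universe <- names(s)
  n <- length(s)

  sizes <- vapply(sets, function(g) length(intersect(g, universe)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(sets)[!keep]
  sets_used <- sets[keep]
  if (length(sets_used) == 0) {
    out <- data.table::data.table(set = character(0), size = integer(0),
                                  es = numeric(0), nes = numeric(0),
                                  p_perm = numeric(0), fdr = numeric(0),
                                  leading_edge = list())
    attr(out, "skipped") <- skipped
    return(out)
  }

  set.seed(seed)
  res <- vector("list", length(sets_used))
  for (k in seq_along(sets_used)) {
    hit_idx <- sort(match(intersect(sets_used[[k]], universe), universe))
    obs <- gsea_es(s, hit_idx)
    m <- length(hit_idx)
    perm_es <- vapply(seq_len(n_perm), function(b)
      gsea_es(s, sort(sample.int(n, m)))$es, numeric(1))
    same_sign <- if (obs$es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
    p_perm <- if (length(same_sign) == 0) 1 / (n_perm + 1)
      else max(sum(abs(same_sign) >= abs(obs$es)) / length(same_sign),
               1 / (n_perm + 1))
    denom <- if (length(same_sign) == 0) NA_real_ else mean(abs(same_sign))
    nes <- if (is.na(denom) || denom == 0) NA_real_ else obs$es / denom
    res[[k]] <- data.table::data.table(set = names(sets_used)[k],
                                       size = m, es = obs$es, nes = nes,
                                       p_perm = p_perm,
                                       leading_edge = list(universe[obs$leading_edge]))
  }
  out <- data.table::rbindlist(res)
  out[, fdr := bh_fdr(p_perm)]
  data.table::setcolorder(out, c("set", "size", "es", "nes", "p_perm", "fdr",
                                 "leading_edge"))
  attr(out, "skipped") <- skipped
  out[]
}

#' Count leading-edge memberships across significant gene sets
#'
#' @param results a [preranked_gsea()] table.
#' @param fdr_max significance threshold on the set FDR (default 0.05).
#' @return named integer vector: gene -> number of significantly enriched
#'   sets whose leading edge contains it (empty when no set is
#'   significant).
#' @export
leading_edge_counts <- function(results, fdr_max = 0.05) {
  sig <- results[!is.na(results$fdr) & results$fdr < fdr_max, ]
  if (nrow(sig) == 0) return(integer(0))
  tab <- table(unlist(sig$leading_edge))
  out <- as.integer(tab)
  names(out) <- names(tab)
  sort(out, decreasing = TRUE)
}

#' Select trans candidates by leading-edge recurrence
#'
#' Genes appearing in the leading edge of at least `min_sets` significant
#' sets, ordered by count (descending) then id.
#'
#' @param counts result of [leading_edge_counts()].
#' @param min_sets recurrence threshold (default 14).
#' @return character vector of gene ids.
#' @export
select_candidates <- function(counts, min_sets = 14) {
  if (length(counts) == 0) return(character(0))
  sel <- counts[counts >= min_sets]
  names(sel)[order(-sel, names(sel))]
}

#' Power of the F test for one regression coefficient
#'
#' Simple linear model convention: numerator df u = 1, denominator
#' df v = n - 2 - n_covariates, effect size f2 = r2/(1 - r2),
#' noncentrality lambda = f2 (u + v + 1):
#' power = P( noncentral F(u, v, lambda) > F_crit(u, v, 1 - alpha) ).
#'
#' @param r2 variance fraction explained, in (0, 1).
#' @param n sample size (> n_covariates + 2).
#' @param n_covariates additional adjusting covariates (default 0).
#' @param alpha significance level.
#' @return power in (0, 1).
#' @export
f_test_power <- function(r2, n, n_covariates = 0, alpha = 0.05) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must lie in (0, 1)")
  if (n <= n_covariates + 2) stop("n too small for the model")
  u <- 1
  v <- n - u - 1 - n_covariates
  f2 <- r2 / (1 - r2)
  lambda <- f2 * (u + v + 1)
  fc <- qf(1 - alpha, u, v)
  pf(fc, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Maximum number of testable genes at fixed power
#'
#' Largest integer k such that the F-test power at the Bonferroni level
#' `alpha_total / (n_snps * k)` still reaches `power_min`; 0 if even k = 1
#' fails. Power is compared at `resolution` (default one percentage
#' point, i.e. a 50% requirement is read the way it is read off a power
#' curve reported in percent); set `resolution = 0` for a strict
#' comparison.
#'
#' @param n sample size.
#' @param r2 targeted effect size (variance fraction).
#' @param n_snps number of SNPs in the targeted scan.
#' @param alpha_total family-wise level (default 0.05).
#' @param power_min required power (default 0.5).
#' @param n_covariates passed to [f_test_power()] (default 0).
#' @param resolution rounding unit applied to the power before the
#'   comparison (default 0.01).
#' @return integer k_max.
#' @export
max_testable_genes <- function(n, r2, n_snps, alpha_total = 0.05,
                               power_min = 0.5, n_covariates = 0,
                               resolution = 0.01) {
  stopifnot(n > 0, r2 > 0, n_snps > 0)
  pw <- function(k) {
    p <- f_test_power(r2, n, n_covariates,
                      alpha = alpha_total / (n_snps * k))
    if (resolution > 0) round(p / resolution) * resolution else p
  }
  if (pw(1) < power_min) return(0L)
  # power is non-increasing in k: exponential bracketing + bisection
  lo <- 1; hi <- 2
  kmax_cap <- .Machine$integer.max
  while (pw(hi) >= power_min) {
    lo <- hi
    hi <- hi * 2
    if (hi > kmax_cap) return(kmax_cap)     # effectively unbounded
  }
  while (hi - lo > 1) {
    mid <- floor((lo + hi) / 2)
    if (pw(mid) >= power_min) lo <- mid else hi <- mid
  }
  as.integer(lo)
}

#' Replication-mode ranking of a differential result
#'
#' Orders genes for preranked GSEA by significance flag first (significant
#' genes before non-significant ones), then by log fold change. Returns a
#' numeric ranking statistic that induces that order.
#'
#' @param lfc named log-fold-change vector.
#' @param significant logical vector aligned with `lfc`.
#' @return named numeric ranking statistic (higher = earlier).
#' @export
replication_ranking <- function(lfc, significant) {
  stopifnot(length(lfc) == length(significant))
  offset <- max(abs(lfc), na.rm = TRUE) + 1
  out <- ifelse(significant, lfc + sign(lfc) * 2 * offset, lfc)
  names(out) <- names(lfc)
  out
}
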