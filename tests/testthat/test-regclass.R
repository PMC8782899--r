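# LD, clumping, regulatory-category rules, ABF colocalization and the
# enrichment tests.

test_that("ld_r2 handles identity, allele flips and monomorphic variants", {
  set.seed(1)
  x <- rbinom(200, 2, 0.3)
  vt <- make_vt(rbind(a = x, b = 2 - x, mono = rep(0, 200)))
  expect_equal(ld_r2(vt, "a", "a"), 1)
  expect_equal(ld_r2(vt, "a", "b"), 1)       # sign invariance
  expect_true(is.na(ld_r2(vt, "a", "mono")))
  # independent variants at large n
  set.seed(2)
  vt2 <- make_vt(rbind(u = rbinom(10000, 2, 0.4), v = rbinom(10000, 2, 0.4)))
  expect_lt(ld_r2(vt2, "u", "v"), 0.01)
})

test_that("ld_clump applies the greedy lead/member rule", {
  # construct dosages with controlled correlation: B in LD with A, C not
  set.seed(3)
  n <- 400
  a <- rbinom(n, 2, 0.5)
  b <- ifelse(runif(n) < 0.85, a, rbinom(n, 2, 0.5))
  c_ <- rbinom(n, 2, 0.5)
  vt <- make_vt(rbind(A = a, B = b, C = c_), pos = c(1e5, 1.1e5, 1.2e5))
  expect_gt(ld_r2(vt, "A", "B"), 0.5)
  expect_lt(ld_r2(vt, "A", "C"), 0.3)
  rec <- data.frame(variant_id = c("A", "B", "C"),
                    p_value = c(1e-8, 1e-6, 1e-7))
  cl <- ld_clump(rec, vt, r2 = 0.5, kb = 250, p1 = 0.05, p2 = 0.8)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$lead, "A")
  expect_setequal(cl[[1]]$members, c("A", "B"))
  expect_equal(cl[[2]]$lead, "C")
  # no lead below p1 -> empty
  expect_length(ld_clump(data.frame(variant_id = "A", p_value = 0.5), vt,
                         p1 = 0.05, p2 = 0.8), 0)
  # distance rule: member beyond kb stays out
  vt_far <- make_vt(rbind(A = a, B = b), pos = c(1e5, 1e5 + 3e5))
  cl_far <- ld_clump(rec[1:2, ], vt_far, p1 = 0.05, p2 = 0.8, kb = 250)
  expect_length(cl_far, 2)
})

test_that("ld_clump equals an independent exhaustive-order oracle", {
  # oracle: re-derivation with explicit repeated scans over a copy
  oracle_clump <- function(rec, vt, r2, kb, p1, p2) {
    pos <- vt$info$pos[match(rec$variant_id, vt$info$variant_id)]
    o <- order(rec$p_value, pos, rec$variant_id)
    rec <- rec[o, ]; pos <- pos[o]
    taken <- rep(FALSE, nrow(rec)); out <- list()
    while (TRUE) {
      lead <- NA
      for (i in seq_len(nrow(rec)))
        if (!taken[i] && rec$p_value[i] <= p1) { lead <- i; break }
      if (is.na(lead)) break
      mem <- lead
      for (j in seq_len(nrow(rec))) {
        if (taken[j] || j == lead || rec$p_value[j] > p2) next
        if (abs(pos[j] - pos[lead]) > kb * 1000) next
        r <- ld_r2(vt, rec$variant_id[lead], rec$variant_id[j])
        if (!is.na(r) && r >= r2) mem <- c(mem, j)
      }
      taken[mem] <- TRUE
      out[[length(out) + 1]] <- sort(rec$variant_id[mem])
    }
    out
  }
  set.seed(4)
  for (rep in 1:10) {
    n <- 300; nv <- 15
    base <- rbinom(n, 2, 0.4)
    G <- t(sapply(seq_len(nv), function(i)
      ifelse(runif(n) < runif(1, 0.3, 0.95), base, rbinom(n, 2, 0.4))))
    vt <- make_vt(G, pos = sort(sample.int(4e5, nv)))
    rec <- data.frame(variant_id = rownames(vt$geno),
                      p_value = runif(nv)^3)
    got <- ld_clump(rec, vt, r2 = 0.5, kb = 250, p1 = 0.05, p2 = 0.8)
    want <- oracle_clump(rec, vt, 0.5, 250, 0.05, 0.8)
    expect_equal(lapply(got, function(cl) sort(cl$members)), want)
    # partition property: every variant with p <= p1 in exactly one clump
    eligible <- rec$variant_id[rec$p_value <= 0.05]
    members <- unlist(lapply(got, `[[`, "members"))
    expect_true(all(table(members) == 1))
    expect_true(all(eligible %in% members))
  }
})

test_that("classify_locus implements the category rule table", {
  expect_equal(classify_locus(0.01, 0.01, 0.30, 0.30)$category, "shared")
  expect_equal(classify_locus(0.01, 0.20, 0.01, 0.90)$category,
               "independent_eqtl")
  expect_equal(classify_locus(0.20, 0.01, 0.90, 0.01)$category,
               "independent_pqtl")
  expect_equal(classify_locus(0.01, 0.01, 0.01, 0.01)$category, "unclassified")
  expect_equal(classify_locus(0.5, 0.5, 0.5, 0.5)$category, "unclassified")
  expect_equal(classify_locus(NA, 0.01, 0.3, 0.3)$category, "unclassified")
})

test_that("Wakefield log-ABF matches its closed forms", {
  # z = 0: ABF = (1 + W/V)^(-1/2)
  expect_equal(exp(wakefield_log_abf(0, 0.1, 0.15)),
               (1 + 0.15^2 / 0.1^2)^(-0.5), tolerance = 1e-12)
  # W -> 0: ABF -> 1
  expect_equal(exp(wakefield_log_abf(0.5, 0.1, 1e-8)), 1, tolerance = 1e-6)
  # monotone in |z| at fixed V, W
  z <- seq(0, 5, 0.5)
  l <- wakefield_log_abf(z * 0.1, 0.1, 0.15)
  expect_true(all(diff(l) > 0))
  expect_error(wakefield_log_abf(1, 0), "positive")
})

test_that("coloc posteriors are a proper distribution and detect sharing", {
  set.seed(5)
  mk_stats <- function(ids, beta, se) data.frame(variant_id = ids,
                                                 beta = beta, se = se)
  ids <- paste0("v", 1:5)
  co <- coloc_abf(mk_stats(ids, rnorm(5), runif(5, 0.05, 0.2)),
                  mk_stats(ids, rnorm(5), runif(5, 0.05, 0.2)))
  expect_equal(sum(co$pp), 1, tolerance = 1e-12)
  expect_true(all(co$pp >= 0))
  expect_error(coloc_abf(mk_stats(ids[1], 0, 1), mk_stats(ids[1], 0, 1)),
               "2 shared")

  scan_stats <- function(y, G) {
    t(sapply(seq_len(nrow(G)), function(v) {
      tr <- ols_term(ols_test(y, cbind(dosage = G[v, ])), "dosage")
      c(beta = tr$beta, se = tr$se)
    }))
  }
  # planted single shared causal variant: pp4 top in >= 80% of 100 reps
  top4 <- 0
  for (i in 1:100) {
    cfg <- tiny_config(n_samples = 500, seed = 6000 + i, cis_r2 = 0.05,
                       ld_rho = 0.4)
    geno <- simulate_genotypes(cfg)
    G <- geno$geno[1:5, ]   # block hosting the shared gene's causal variant
    causal <- scale(G[3, ])[, 1]
    y1 <- sqrt(0.05) * causal + sqrt(0.95) * rnorm(500)
    y2 <- sqrt(0.05) * causal + sqrt(0.95) * rnorm(500)
    s1 <- scan_stats(y1, G); s2 <- scan_stats(y2, G)
    co <- coloc_abf(data.frame(variant_id = rownames(G), s1),
                    data.frame(variant_id = rownames(G), s2))
    if (which.max(co$pp) == 5) top4 <- top4 + 1
  }
  expect_gte(top4 / 100, 0.8)

  # two distinct causal variants in low LD: pp3 top in >= 70% of reps
  top3 <- 0
  for (i in 1:100) {
    cfg <- tiny_config(n_samples = 500, seed = 7000 + i, ld_rho = 0.1)
    geno <- simulate_genotypes(cfg)
    G <- geno$geno[1:5, ]
    y1 <- sqrt(0.08) * scale(G[1, ])[, 1] + sqrt(0.92) * rnorm(500)
    y2 <- sqrt(0.08) * scale(G[5, ])[, 1] + sqrt(0.92) * rnorm(500)
    co <- coloc_abf(data.frame(variant_id = rownames(G), scan_stats(y1, G)),
                    data.frame(variant_id = rownames(G), scan_stats(y2, G)))
    if (which.max(co$pp) == 4) top3 <- top3 + 1
  }
  expect_gte(top3 / 100, 0.7)
})

test_that("matched background respects tolerances and determinism", {
  pool <- data.frame(variant_id = paste0("v", 1:300),
                     maf = c(rep(0.2, 150), rep(0.4, 150)),
                     tss_dist = c(rep(500, 150), rep(5000, 150)))
  snp <- list(maf = 0.22, tss_dist = 600)
  bg <- matched_background(snp, pool, n = 100, seed = 1)
  expect_length(bg, 100)
  expect_true(all(bg %in% pool$variant_id[1:150]))   # only matched half
  # |dMAF| = 0.06 never sampled
  pool2 <- data.frame(variant_id = "x", maf = 0.28, tss_dist = 600)
  expect_warning(bg2 <- matched_background(list(maf = 0.22, tss_dist = 600),
                                           pool2), "empty")
  expect_length(bg2, 0)
  # exactly n qualifying -> all returned regardless of seed
  pool3 <- pool[1:100, ]
  expect_setequal(matched_background(snp, pool3, n = 100, seed = 5),
                  pool3$variant_id)
  # fixed seed reproduces the draw
  expect_identical(matched_background(snp, pool, n = 100, seed = 9),
                   matched_background(snp, pool, n = 100, seed = 9))
})

test_that("annotation enrichment matches Fisher and the hypergeometric oracle", {
  top <- paste0("t", 1:100); bg <- paste0("b", 1:1000)
  annotated <- c(top[1:10], bg[1:10])
  out <- annotation_enrichment(top, bg, annotated)
  expect_equal(out$odds_ratio, (10 * 990) / (90 * 10))   # = 11
  # hypergeometric enumeration oracle on a small table
  top2 <- paste0("t", 1:20); bg2 <- paste0("b", 1:30)
  ann2 <- c(top2[1:8], bg2[1:5])
  out2 <- annotation_enrichment(top2, bg2, ann2)
  # enumerate all tables with the observed margins
  m <- 13; n_tot <- 50; k <- 20
  probs <- dhyper(0:m, m, n_tot - m, k)
  p_oracle <- sum(probs[probs <= dhyper(8, m, n_tot - m, k) * (1 + 1e-7)])
  expect_equal(out2$p_value, p_oracle, tolerance = 1e-8)
})

test_that("GWAS overlap enrichment counts proxies by the r2 rule", {
  set.seed(6)
  n <- 500
  hit <- rbinom(n, 2, 0.5)
  strong_proxy <- ifelse(runif(n) < 0.95, hit, rbinom(n, 2, 0.5))
  weak_proxy <- ifelse(runif(n) < 0.55, hit, rbinom(n, 2, 0.5))
  indep <- rbinom(n, 2, 0.5)
  vt <- make_vt(rbind(hit = hit, strong = strong_proxy, weak = weak_proxy,
                      other = indep),
                pos = c(1e5, 1.1e5, 1.2e5, 1.3e5))
  expect_gt(ld_r2(vt, "hit", "strong"), 0.8)
  expect_lt(ld_r2(vt, "hit", "weak"), 0.8)
  rec <- data.frame(variant_id = c("hit", "strong", "weak", "other"),
                    gene_id = "g1",
                    p_value = c(1e-8, 1e-7, 1e-6, 0.5))
  res <- gwas_overlap_enrichment(rec, vt,
                                 data.frame(variant_id = "hit", trait = "af"))
  tab <- res$af$table
  # hit and strong proxy annotated; weak and other not
  expect_equal(sum(tab[, "annotated"]), 2)
  expect_equal(unname(tab["sig", "annotated"]), 2)
  expect_equal(res$af$overlap$proxy[1], "hit")
})
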