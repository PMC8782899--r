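# Readers/writers for the on-disk formats, variant QC, and the
# normalization / imputation primitives applied before any scan.
#
# Conventions: TSV matrices are genes (or variants) x samples with a header
# row of sample ids; BED is 0-based half-open on disk and converted to the
# internal 1-based inclusive convention at this boundary (the single
# conversion point in the package).

#' Read a genotype matrix
#'
#' TSV dialect: one row per variant with leading columns
#' `variant_id, chrom, pos, ref, alt` followed by per-sample hard calls.
#' VCF (v4.2, uncompressed) support converts GT fields to alt-allele
#' counts; multi-allelic records are rejected.
#'
#' @param path file path.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [variant_table()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1:2))
    req <- c("variant_id", "chrom", "pos", "ref", "alt")
    if (!all(req %in% names(dt)))
      stop("genotype TSV must carry columns ", paste(req, collapse = ", "))
    info <- as.data.frame(dt[, req, with = FALSE])
    g <- as.matrix(dt[, setdiff(names(dt), req), with = FALSE])
    rownames(g) <- info$variant_id
    bad <- which(!is.na(g) & !(g %in% c(0, 1, 2)))
    if (length(bad))
      stop("malformed dosage at row ", ((bad[1] - 1) %% nrow(g)) + 1,
           ": hard calls must be 0/1/2 or missing")
    return(variant_table(info, g))
  }
  read_vcf_genotypes(path)
}

# Minimal VCF v4.2 GT reader (uncompressed, biallelic records only).
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  body_at <- which(!startsWith(lines, "##"))
  header <- lines[body_at[1]]
  if (!startsWith(header, "#CHROM")) stop("VCF header line (#CHROM) not found")
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[body_at[-1]]
  body <- body[nzchar(body)]
  info <- data.frame(variant_id = character(0), chrom = character(0),
                     pos = integer(0), ref = character(0), alt = character(0))
  geno <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(NULL, samples))
  ids <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t")[[1]]
    line_no <- body_at[1] + i
    if (length(f) < 9 + length(samples))
      stop("malformed VCF record at line ", line_no)
    if (grepl(",", f[5], fixed = TRUE))
      stop("multi-allelic VCF record at line ", line_no, " (", f[3], ")")
    fmt <- strsplit(f[9], ":")[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("no GT field at line ", line_no)
    gt <- vapply(strsplit(f[-(1:9)], ":"), `[`, character(1), gt_i)
    alleles <- strsplit(gt, "[/|]")
    dose <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a) || any(a > 1)) return(NA_real_)
      sum(a)
    }, numeric(1))
    geno[i, ] <- dose
    ids[i] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    info[i, ] <- list(ids[i], f[1], as.integer(f[2]), f[4], f[5])
  }
  info$pos <- as.integer(info$pos)
  rownames(geno) <- ids
  variant_table(info, geno)
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test (Wigginton-style, non-mid-P) by enumeration over
#' heterozygote counts conditional on the observed allele counts; no
#' chi-square approximation.
#'
#' @param n_aa,n_ab,n_bb genotype counts (bb = homozygous minor).
#' @return exact P-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab           # minor allele count
  if (n_b > n) {                   # ensure b is the minor allele
    tmp <- n_aa; n_aa <- n_bb; n_bb <- tmp
    n_b <- 2 * n_bb + n_ab
  }
  het_vals <- seq(n_b %% 2, n_b, by = 2)
  # unnormalized conditional probabilities, computed in log space
  logp <- vapply(het_vals, function(h) {
    hom_b <- (n_b - h) / 2
    hom_a <- n - h - hom_b
    lgamma(n + 1) - lgamma(hom_a + 1) - lgamma(h + 1) - lgamma(hom_b + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[match(n_ab, het_vals)]
  sum(p[p <= p_obs + 1e-12])
}

#' Variant quality control
#'
#' Removes variants failing any of: minor allele frequency, Hardy-Weinberg
#' exact-test P, call rate.
#'
#' @param vt a [variant_table()].
#' @param maf_min keep variants with MAF > `maf_min` (default 0.01).
#' @param hwe_p_min keep variants with HWE exact P > `hwe_p_min`
#'   (default 1e-6).
#' @param call_rate_min keep variants with call rate > `call_rate_min`
#'   (default 0.98).
#' @return filtered `VariantTable` (possibly with zero variants).
#' @export
qc_filter_variants <- function(vt, maf_min = 0.01, hwe_p_min = 1e-6,
                               call_rate_min = 0.98) {
  stopifnot(inherits(vt, "VariantTable"), nrow(vt$geno) > 0)
  g <- vt$geno
  call_rate <- rowMeans(!is.na(g))
  maf <- variant_maf(g)
  hwe_p <- apply(g, 1, function(x) {
    x <- x[!is.na(x)]
    hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
  })
  keep <- which(maf > maf_min & hwe_p > hwe_p_min & call_rate > call_rate_min)
  subset_variants(vt, keep)
}

#' Recode rare homozygous-minor genotypes to heterozygous
#'
#' For variants carried homozygous for the minor allele by fewer than
#' `min_hom` samples, those calls are recoded to heterozygous; all other
#' variants are untouched.
#'
#' @param vt a [variant_table()].
#' @param min_hom threshold (default 3).
#' @return recoded `VariantTable`.
#' @export
recode_rare_genotypes <- function(vt, min_hom = 3) {
  g <- vt$geno
  for (i in seq_len(nrow(g))) {
    x <- g[i, ]
    af <- mean(x, na.rm = TRUE) / 2
    hom_minor <- if (af <= 0.5) 2 else 0
    idx <- which(!is.na(x) & x == hom_minor)
    if (length(idx) > 0 && length(idx) < min_hom) g[i, idx] <- 1
  }
  variant_table(vt$info, g)
}

#' K-nearest-neighbour imputation of missing abundances
#'
#' Each missing value of a gene is replaced by the mean, in that sample, of
#' the `k` genes closest to it (Euclidean distance over shared non-missing
#' samples, scaled per shared sample count). Observed values are never
#' altered.
#'
#' @param om an [omics_matrix()] (missing fraction must be < 50% per gene).
#' @param k number of neighbours (default 10).
#' @return imputed `OmicsMatrix`.
#' @export
impute_knn <- function(om, k = 10) {
  V <- om$values
  miss_frac <- rowMeans(is.na(V))
  if (any(miss_frac >= 1))
    stop("gene missing in all samples: ",
         paste(rownames(V)[miss_frac >= 1], collapse = ", "))
  if (any(miss_frac >= 0.5))
    stop("missing fraction >= 50% for gene(s): ",
         paste(rownames(V)[miss_frac >= 0.5], collapse = ", "))
  gaps <- which(rowSums(is.na(V)) > 0)
  if (length(gaps) == 0) return(om)
  for (i in gaps) {
    obs_i <- !is.na(V[i, ])
    # scaled Euclidean distance to every other gene on shared samples
    d <- rep(Inf, nrow(V))
    for (j in seq_len(nrow(V))) {
      if (j == i) next
      shared <- obs_i & !is.na(V[j, ])
      if (!any(shared)) next
      d[j] <- sqrt(mean((V[i, shared] - V[j, shared])^2))
    }
    for (s in which(!obs_i)) {
      cand <- which(is.finite(d) & !is.na(V[, s]))
      if (length(cand) == 0)
        stop("no neighbour with data for gene ", rownames(V)[i],
             " in sample ", colnames(V)[s])
      nn <- cand[order(d[cand])][seq_len(min(k, length(cand)))]
      V[i, s] <- mean(V[nn, s])
    }
  }
  omics_matrix(V, om$layer, om$norm_state)
}

#' Normal-quantile (inverse-normal) transform
#'
#' Along the chosen axis, values are replaced by
#' `qnorm((rank - 0.5) / n)` with ties broken by average rank.
#'
#' @param om an [omics_matrix()] with finite values.
#' @param axis `"per_gene"` (transform each row) or `"per_sample"`
#'   (transform each column).
#' @return transformed `OmicsMatrix` with its `norm_state` flag updated.
#' @export
normal_quantile_transform <- function(om, axis = c("per_gene", "per_sample")) {
  axis <- match.arg(axis)
  V <- om$values
  if (any(!is.finite(V))) stop("values must be finite before NQN")
  nqn <- function(x) {
    if (length(unique(x)) == 1) {
      warning("constant vector in normal-quantile transform; returning zeros")
      return(rep(0, length(x)))
    }
    qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  }
  if (axis == "per_gene") V <- t(apply(V, 1, nqn)) else V <- apply(V, 2, nqn)
  dimnames(V) <- dimnames(om$values)
  ns <- om$norm_state
  ns[[if (axis == "per_gene") "per_gene_nqn" else "per_sample_nqn"]] <- TRUE
  omics_matrix(V, om$layer, ns)
}

#' Fibroblast signature genes
#'
#' Genes upregulated in fibroblasts relative to cardiomyocytes, used to
#' build a cell-composition covariate for bulk atrial tissue.
#' @export
FIBROBLAST_SIGNATURE <- c("ELN", "FGF10", "FOSB", "FCRL2", "SCN7A",
                          "ARHGAP20", "CILP", "FRAS1", "DCDC2", "NRG1",
                          "AFAP1L2", "ITGBL1", "NOV", "CLEC3B")

#' Fibroblast cell-composition score
#'
#' Per-sample sum of the expression of the fibroblast signature genes
#' present in the matrix.
#'
#' @param mrna an [omics_matrix()] on the mrna layer.
#' @param signature gene list (default [FIBROBLAST_SIGNATURE]).
#' @return numeric per-sample score vector with attribute `absent_genes`.
#' @export
compute_fibroblast_score <- function(mrna, signature = FIBROBLAST_SIGNATURE) {
  present <- intersect(signature, gene_ids(mrna))
  if (length(present) == 0)
    stop("none of the signature genes are present in the expression matrix")
  sc <- colSums(mrna$values[present, , drop = FALSE])
  attr(sc, "absent_genes") <- setdiff(signature, present)
  sc
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (per line: set name, description, member genes,
#'   tab-separated).
#' @return named list of character vectors; descriptions in attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) stop("malformed GMT line ", bad[1])
  nm <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set name: ", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, character(1), 2), nm)
  sets
}

#' Read a BED interval file
#'
#' On-disk BED is 0-based half-open; returned intervals use the internal
#' 1-based inclusive convention.
#'
#' @param path BED file (>= 3 columns; 4th column, if present, is `name`).
#' @return data.frame `chrom, start, end[, name, score]`, 1-based inclusive.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 3) stop("BED needs >= 3 columns")
  out <- data.frame(chrom = as.character(dt[[1]]),
                    start = as.integer(dt[[2]]) + 1L,
                    end = as.integer(dt[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$end < out$start))
    stop("BED end <= start at line ", which(out$end < out$start)[1])
  if (ncol(dt) >= 4) out$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) out$score <- suppressWarnings(as.numeric(dt[[5]]))
  out
}

#' Read a paired-interval (BEDPE-like) link file
#'
#' @param path TSV with columns `chrom1 start1 end1 chrom2 start2 end2`
#'   (0-based half-open on disk), interpreted as (anchor, target) pairs.
#' @return data.frame with 1-based inclusive anchor and target intervals.
#' @export
read_links <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  if (ncol(dt) < 6) stop("link file needs >= 6 columns")
  out <- data.frame(chrom1 = as.character(dt[[1]]),
                    start1 = as.integer(dt[[2]]) + 1L,
                    end1 = as.integer(dt[[3]]),
                    chrom2 = as.character(dt[[4]]),
                    start2 = as.integer(dt[[5]]) + 1L,
                    end2 = as.integer(dt[[6]]),
                    stringsAsFactors = FALSE)
  if (any(out$end1 < out$start1) || any(out$end2 < out$start2))
    stop("link interval end <= start")
  out
}

#' Read a generic TSV table
#' @param path TSV file with header.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}

#' Read an omics abundance matrix
#' @param path TSV, rows = genes (first column `gene_id`), columns = samples.
#' @param layer omic layer tag for the result.
#' @return an [omics_matrix()].
#' @export
read_omics <- function(path, layer = "mrna") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  omics_matrix(m, layer)
}

#' Write an omics matrix as TSV
#' @param om an [omics_matrix()].
#' @param path output path.
#' @export
write_omics <- function(om, path) {
  dt <- data.table::data.table(gene_id = rownames(om$values), om$values)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write a variant table as genotype TSV
#' @param vt a [variant_table()].
#' @param path output path.
#' @export
write_genotypes <- function(vt, path) {
  dt <- data.table::data.table(vt$info[c("variant_id", "chrom", "pos", "ref", "alt")],
                               vt$geno)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
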