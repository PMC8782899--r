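# Core data containers shared by every stage of the pipeline.
#
# A VariantTable couples per-variant metadata with the hard-call dosage
# matrix (variants x samples, values 0/1/2/NA counting alt alleles).
# An OmicsMatrix is a genes x samples abundance matrix for one omic layer,
# carrying its normalization state so downstream scans can assert on it.

#' Construct a variant table
#'
#' @param info data.frame with columns `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`. A `maf` column is recomputed from the dosages if absent.
#' @param geno numeric matrix of alt-allele counts (variants x samples),
#'   entries in \{0, 1, 2, NA\}; rownames must equal `info$variant_id`.
#' @return An object of class `VariantTable`.
#' @export
variant_table <- function(info, geno) {
  stopifnot(is.data.frame(info), is.matrix(geno))
  req <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(info))
  if (length(miss)) stop("variant info lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(info$variant_id)) stop("duplicate variant ids")
  if (any(info$pos < 1)) stop("variant positions must be >= 1")
  if (is.null(rownames(geno))) rownames(geno) <- info$variant_id
  if (!identical(rownames(geno), as.character(info$variant_id)))
    stop("genotype rownames do not match variant ids")
  bad <- geno[!is.na(geno) & !(geno %in% c(0, 1, 2))]
  if (length(bad)) stop("dosages must be hard calls in {0,1,2}")
  info$maf <- variant_maf(geno)
  structure(list(info = info, geno = geno), class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat(sprintf("VariantTable: %d variants x %d samples\n",
              nrow(x$geno), ncol(x$geno)))
  invisible(x)
}

#' Minor allele frequencies from a dosage matrix
#'
#' @param geno variants x samples dosage matrix.
#' @return Numeric vector of per-variant MAFs (alt-allele frequency folded
#'   at 0.5).
#' @export
variant_maf <- function(geno) {
  af <- rowMeans(geno, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

#' @export
dim.VariantTable <- function(x) dim(x$geno)

#' Subset a variant table by variant ids or indices
#'
#' @param vt a `VariantTable`.
#' @param ids character vector of variant ids, or integer/logical index.
#' @return The subsetted `VariantTable`.
#' @export
subset_variants <- function(vt, ids) {
  if (is.character(ids)) {
    idx <- match(ids, vt$info$variant_id)
    if (anyNA(idx)) stop("unknown variant ids: ",
                         paste(ids[is.na(idx)], collapse = ", "))
  } else idx <- ids
  variant_table(vt$info[idx, , drop = FALSE],
                vt$geno[idx, , drop = FALSE])
}

OMICS_LAYERS <- c("mrna", "protein", "residual_mrna", "residual_protein", "ratio")

#' Construct an omics matrix for one layer
#'
#' @param values numeric matrix, genes x samples, with dimnames.
#' @param layer one of `"mrna"`, `"protein"`, `"residual_mrna"`,
#'   `"residual_protein"`, `"ratio"`.
#' @param norm_state named logical flags `per_sample_nqn`, `per_gene_nqn`.
#' @return An object of class `OmicsMatrix`.
#' @export
omics_matrix <- function(values, layer = "mrna",
                         norm_state = c(per_sample_nqn = FALSE,
                                        per_gene_nqn = FALSE)) {
  stopifnot(is.matrix(values))
  layer <- match.arg(layer, OMICS_LAYERS)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics matrix needs gene rownames and sample colnames")
  structure(list(values = values, layer = layer,
                 norm_state = norm_state),
            class = "OmicsMatrix")
}

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix [%s]: %d genes x %d samples (per_sample_nqn=%s, per_gene_nqn=%s)\n",
              x$layer, nrow(x$values), ncol(x$values),
              x$norm_state[["per_sample_nqn"]], x$norm_state[["per_gene_nqn"]]))
  invisible(x)
}

#' @export
dim.OmicsMatrix <- function(x) dim(x$values)

sample_ids <- function(x) {
  if (inherits(x, "VariantTable")) colnames(x$geno)
  else if (inherits(x, "OmicsMatrix")) colnames(x$values)
  else rownames(x)
}

gene_ids <- function(om) rownames(om$values)
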