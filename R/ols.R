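# Ordinary-least-squares helpers. Every association statistic in the
# pipeline is a two-sided t-test on one coefficient of an OLS fit, with
# df = n - (number of fitted parameters); this file is the single place
# where that bookkeeping lives.

#' OLS fit with per-coefficient t-tests
#'
#' Fits `y ~ X` by QR-based least squares (an intercept column is prepended
#' unless `add_intercept = FALSE`) and returns the coefficient table for a
#' two-sided t-test on each parameter.
#'
#' @param y numeric response vector.
#' @param X numeric matrix of predictors (columns named), or NULL for an
#'   intercept-only fit.
#' @param add_intercept prepend an intercept column (default TRUE).
#' @return list with `coef` (data.frame: term, beta, se, t_stat, p_value),
#'   `n`, `df`, `sigma2`, `rank_deficient` flag and `dropped` (names of
#'   columns dropped to reach full rank).
#' @export
ols_test <- function(y, X = NULL, add_intercept = TRUE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) {
    X <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    X <- as.matrix(X)
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  if (add_intercept) X <- cbind(`(Intercept)` = rep(1, n), X)
  keep <- complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X)) stop("not enough complete observations for the model")

  qr_ <- qr(X)
  rank_deficient <- qr_$rank < ncol(X)
  dropped <- character(0)
  if (rank_deficient) {
    # drop aliased columns (in column order) until full rank
    piv_keep <- qr_$pivot[seq_len(qr_$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), piv_keep)]
    X <- X[, sort(piv_keep), drop = FALSE]
    qr_ <- qr(X)
  }
  p <- ncol(X)
  beta <- qr.coef(qr_, y)
  res <- y - as.vector(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qr_))
  se <- sqrt(sigma2 * diag(XtXinv))
  # undo the pivoting applied inside qr
  se <- se[order(qr_$pivot)]
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df = df, lower.tail = FALSE)
  list(coef = data.frame(term = colnames(X), beta = unname(beta),
                         se = unname(se), t_stat = unname(tval),
                         p_value = unname(pval),
                         stringsAsFactors = FALSE),
       n = n, df = df, sigma2 = sigma2,
       rank_deficient = rank_deficient, dropped = dropped)
}

#' Extract the test for one term from an [ols_test()] fit
#'
#' @param fit result of [ols_test()].
#' @param term coefficient name.
#' @return one-row data.frame `beta, se, t_stat, p_value, n, df`.
#' @export
ols_term <- function(fit, term) {
  i <- match(term, fit$coef$term)
  if (is.na(i)) stop("term not in model: ", term)
  cbind(fit$coef[i, c("beta", "se", "t_stat", "p_value")],
        n = fit$n, df = fit$df, row.names = NULL)
}

# Residualize the rows of a (features x samples) matrix on covariates
# (samples x q, intercept added). Used by the blocked QTL scan.
residualize_rows <- function(M, C) {
  n <- ncol(M)
  X <- cbind(rep(1, n), C)
  qr_ <- qr(X)
  t(qr.resid(qr_, t(M)))
}

# Build a clean numeric covariate matrix from a covariate data.frame:
# keeps the requested columns, codes factors/characters as 0/1 dummies
# (first level reference), errors on missing values.
covariate_matrix <- function(covs, columns) {
  if (is.null(columns) || length(columns) == 0) return(NULL)
  miss <- setdiff(columns, colnames(covs))
  if (length(miss)) stop("covariate columns absent: ", paste(miss, collapse = ", "))
  out <- lapply(columns, function(cl) {
    v <- covs[[cl]]
    if (is.logical(v)) v <- as.numeric(v)
    if (is.character(v)) v <- factor(v)
    if (is.factor(v)) {
      lev <- levels(droplevels(v))
      if (length(lev) < 2) return(matrix(numeric(length(v)), ncol = 1,
                                         dimnames = list(NULL, cl)))
      m <- sapply(lev[-1], function(l) as.numeric(v == l))
      colnames(m) <- paste0(cl, lev[-1])
      m
    } else matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cl))
  })
  M <- do.call(cbind, out)
  rownames(M) <- rownames(covs)
  M
}
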