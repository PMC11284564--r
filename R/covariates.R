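#' Regress covariates out of an expression matrix
#'
#' Projects each expression column onto the orthogonal complement of the
#' covariate space (plus intercept) by least squares, returning residuals
#' that are exactly orthogonal to every covariate column. With zero
#' covariates this reduces to column centering. Rank-deficient covariate
#' matrices are rejected with the collinear columns named.
#'
#' @param expression Samples x genes numeric matrix (or data frame).
#' @param covariates Samples x covariates numeric matrix; `NULL` or
#'   zero-column for centering only.
#' @return The residual matrix, same dimensions as `expression`.
#' @examples
#' y <- matrix(rnorm(60), 20, 3)
#' covar <- cbind(age = rnorm(20), sex = rbinom(20, 1, 0.5))
#' res <- regress_out_covariates(y, covar)
#' max(abs(cor(res, covar)))  # ~ 0
#' @export
regress_out_covariates <- function(expression, covariates = NULL) {
  Y <- as.matrix(expression)
  if (is.null(covariates) || NCOL(covariates) == 0) {
    return(sweep(Y, 2L, colMeans(Y)))
  }
  C <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    abort(sprintf("Covariate matrix is rank deficient; collinear column(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  Y - C %*% qr.coef(qrC, Y)
}

#' Top expression principal components
#'
#' Principal-component scores of a (residualized) expression matrix, used as
#' stand-ins for data-driven hidden-factor covariates when building the
#' covariate matrix of an expression panel.
#'
#' @param expression Samples x genes matrix.
#' @param k Number of components (default 5, capped at the matrix rank).
#' @return Samples x `k` matrix of PC scores.
#' @export
expression_pcs <- function(expression, k = 5L) {
  Y <- scale(as.matrix(expression))
  k <- min(k, nrow(Y) - 1L, ncol(Y))
  pc <- prcomp(Y, center = FALSE, scale. = FALSE)
  pc$x[, seq_len(k), drop = FALSE]
}
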