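#' Pearson correlation matrix over listwise-complete rows
#'
#' @param scores Data frame or matrix of scores (e.g. [score_cohort()]
#'   output or item-level responses).
#' @param columns Columns to correlate; defaults to all.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(scores, columns = colnames(scores)) {
  x <- as.matrix(as.data.frame(scores)[, columns, drop = FALSE])
  storage.mode(x) <- "double"
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L) stop("need at least 3 complete rows")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("constant column(s): %s",
                 paste(columns[sds == 0], collapse = ", ")))
  }
  stats::cor(x)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares observed correlations with anti-image partial correlations:
#' `KMO = sum r_ij^2 / (sum r_ij^2 + sum q_ij^2)` over off-diagonal pairs,
#' where `q_ij = -s_ij / sqrt(s_ii s_jj)` and `S = R^-1`. Values near 1
#' indicate the correlation structure is dominated by shared factors and the
#' data suit factor analysis.
#'
#' @param R Correlation matrix (invertible).
#' @return KMO statistic in `[0, 1]`.
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  S <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; consider ridge regularization ",
         "(not applied automatically)")
  })
  d <- 1 / sqrt(diag(S))
  Q <- -S * tcrossprod(d)
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is the identity via
#' `chi2 = -(n - 1 - (2p + 5)/6) * ln det(R)` with `p(p-1)/2` degrees of
#' freedom, referred to the asymptotic chi-squared distribution.
#'
#' @param R Positive-definite correlation matrix.
#' @param n Number of observations the matrix was computed from (`n > p`).
#' @return List with `chi2`, `df` and `p_value`.
#' @export
bartlett_sphericity <- function(R, n) {
  R <- as.matrix(R)
  p <- ncol(R)
  stopifnot(n > p)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0) stop("correlation matrix is not positive definite")
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(ld$modulus)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Kaiser criterion for factor retention
#'
#' Number of correlation-matrix eigenvalues strictly greater than 1 (each
#' retained factor explains more variance than a single standardized
#' variable).
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @return Integer count of retained factors.
#' @export
kaiser_retain <- function(eigenvalues) {
  sum(eigenvalues > 1)
}

#' Cumulative proportion of variance explained
#'
#' @param eigenvalues Eigenvalues of a correlation matrix (they sum to the
#'   number of variables `p`).
#' @param p Total variance; defaults to `sum(eigenvalues)`.
#' @return Cumulative proportions, ending at 1 when all eigenvalues are
#'   supplied.
#' @export
variance_explained <- function(eigenvalues, p = sum(eigenvalues)) {
  cumsum(eigenvalues) / p
}

#' Varimax-rotated principal-component loadings
#'
#' Extracts `k` principal components of the correlation matrix (eigenvectors
#' scaled by the square root of their eigenvalues) and applies a varimax
#' rotation; rotation is orthogonal so row communalities are preserved.
#' Columns are ordered by explained variance (sum of squared loadings) and
#' signed so each column's largest-magnitude loading is positive.
#'
#' @param R Correlation matrix.
#' @param k Number of factors, `1 <= k <= p`.
#' @return `p x k` loading matrix.
#' @export
factor_loadings <- function(R, k) {
  R <- as.matrix(R)
  p <- ncol(R)
  if (k < 1L || k > p) stop("'k' must lie in 1..p")
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  if (k > 1L) {
    L <- stats::varimax(L, normalize = FALSE)$loadings
    L <- matrix(as.numeric(L), p, k)
  }
  ssq <- colSums(L^2)
  L <- L[, order(ssq, decreasing = TRUE), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(L[, j]))
    if (L[i, j] < 0) L[, j] <- -L[, j]
  }
  rownames(L) <- rownames(R)
  colnames(L) <- paste0("F", seq_len(k))
  L
}

#' Full psychometric validation report
#'
#' Bundles the validation stage applied to an instrument's item responses:
#' KMO sampling adequacy, Bartlett's sphericity test, eigenvalues and
#' cumulative variance explained, Kaiser retention count, and
#' varimax-rotated loadings for the retained factors.
#'
#' @param x Data frame of item-level responses (rows = respondents) or a
#'   correlation matrix (then `n` must be given).
#' @param n Number of observations; inferred from complete rows of `x` when
#'   `x` is data.
#' @return An object of class `factor_report` with fields `kmo`, `bartlett`,
#'   `eigenvalues`, `variance_explained`, `n_retained`, `loadings`, `n`.
#' @export
factor_report <- function(x, n = NULL) {
  if (is.matrix(x) && isTRUE(all.equal(unname(diag(x)),
                                       rep(1, ncol(x))))) {
    R <- x
    if (is.null(n)) stop("'n' is required when passing a correlation matrix")
  } else {
    xx <- as.matrix(as.data.frame(x))
    storage.mode(xx) <- "double"
    n <- sum(stats::complete.cases(xx))
    R <- correlation_matrix(x)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  k <- kaiser_retain(ev)
  structure(list(
    kmo = kmo(R),
    bartlett = bartlett_sphericity(R, n),
    eigenvalues = ev,
    variance_explained = variance_explained(ev),
    n_retained = k,
    loadings = if (k >= 1L) factor_loadings(R, k) else NULL,
    n = n
  ), class = "factor_report")
}

#' @export
print.factor_report <- function(x, ...) {
  cat(sprintf("Psychometric validation (n = %d, p = %d)\n", x$n,
              length(x$eigenvalues)))
  cat(sprintf("  KMO sampling adequacy: %.4f\n", x$kmo))
  cat(sprintf("  Bartlett sphericity: chi2(%d) = %.4f, p = %.3g\n",
              as.integer(x$bartlett$df), x$bartlett$chi2,
              x$bartlett$p_value))
  cat(sprintf("  Kaiser criterion retains %d factor(s); %0.1f%% variance\n",
              x$n_retained,
              100 * x$variance_explained[max(x$n_retained, 1L)]))
  invisible(x)
}
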