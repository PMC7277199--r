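#' Fit a bivariate Gaussian kernel density to score pairs
#'
#' Smooths an `n x 2` matrix of (factor score, ideation score) pairs into a
#' continuous joint density on the plane using a product of two univariate
#' standard-normal kernels (diagonal bandwidth matrix). Bandwidths default to
#' the normal-reference rule for a two-dimensional density,
#' `h_d = sigma_d * n^(-1/6)`, with `sigma_d` the per-coordinate sample
#' standard deviation.
#'
#' Integer scores are smoothed as-is: the fitted density is a smooth function
#' on the real plane whose mass extends slightly beyond the valid score
#' rectangle; binning into score intervals handles this by extending the
#' outermost bins to infinity (see [bin_samples()]).
#'
#' @param points Numeric `n x 2` matrix (or data frame) of score pairs,
#'   `n >= 2`, with nonzero spread in both coordinates.
#' @param bandwidth Optional length-2 positive numeric overriding the
#'   normal-reference bandwidths.
#' @return An object of class `score_kde` with fields `points`, `bandwidth`
#'   and `n`.
#' @export
fit_kde <- function(points, bandwidth = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must have exactly 2 columns")
  if (anyNA(points)) stop("'points' must not contain missing values")
  n <- nrow(points)
  if (n < 2L) stop("at least 2 points are required")
  if (is.null(bandwidth)) {
    sds <- apply(points, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("degenerate coordinate with zero variance; ",
           "jitter the scores or widen the cohort before fitting")
    }
    bandwidth <- sds * n^(-1 / 6)
  } else {
    stopifnot(length(bandwidth) == 2L, all(bandwidth > 0))
  }
  structure(list(points = unname(points), bandwidth = unname(bandwidth),
                 n = n),
            class = "score_kde")
}

#' @export
print.score_kde <- function(x, ...) {
  cat(sprintf(
    "Bivariate Gaussian KDE: n = %d, bandwidths h = (%.4g, %.4g)\n",
    x$n, x$bandwidth[1L], x$bandwidth[2L]))
  invisible(x)
}

#' Evaluate a fitted kernel density
#'
#' Computes `J(x) = (1 / (n h1 h2)) * sum_i phi((x1 - p_i1)/h1) *
#' phi((x2 - p_i2)/h2)` with `phi` the standard normal density.
#'
#' @param model A [fit_kde()] model.
#' @param x Query points: a length-2 vector or an `m x 2` matrix.
#' @return Numeric vector of nonnegative density values, one per query.
#' @export
kde_density <- function(model, x) {
  stopifnot(inherits(model, "score_kde"))
  if (is.null(dim(x))) x <- matrix(x, ncol = 2L)
  x <- as.matrix(x)
  h <- model$bandwidth
  p1 <- model$points[, 1L]
  p2 <- model$points[, 2L]
  vapply(seq_len(nrow(x)), function(i) {
    mean(stats::dnorm((x[i, 1L] - p1) / h[1L]) *
           stats::dnorm((x[i, 2L] - p2) / h[2L])) / (h[1L] * h[2L])
  }, numeric(1L))
}

#' @param object A `score_kde` model.
#' @param newdata Query points as in [kde_density()]; defaults to the fitted
#'   points.
#' @param ... Unused.
#' @rdname kde_density
#' @export
predict.score_kde <- function(object, newdata = object$points, ...) {
  kde_density(object, newdata)
}

#' Riemann mass of a kernel density over a rectangular grid
#'
#' Midpoint Riemann sum of the density over an `nx x ny` grid; on a grid
#' covering the fitted points plus/minus six bandwidths this approximates the
#' total mass 1 and serves as a normalization check.
#'
#' @param model A [fit_kde()] model.
#' @param xlim,ylim Length-2 numeric ranges; default to the point range
#'   extended by 6 bandwidths.
#' @param nx,ny Number of grid cells per axis; a zero count gives an empty
#'   grid with mass 0.
#' @return The Riemann-sum mass (a single number).
#' @export
grid_mass <- function(model, xlim = NULL, ylim = NULL, nx = 200L, ny = 200L) {
  stopifnot(inherits(model, "score_kde"))
  h <- model$bandwidth
  cover <- list(range(model$points[, 1L]) + c(-6, 6) * h[1L],
                range(model$points[, 2L]) + c(-6, 6) * h[2L])
  if (is.null(xlim)) xlim <- cover[[1L]]
  if (is.null(ylim)) ylim <- cover[[2L]]
  if (nx < 1L || ny < 1L) return(0)
  if (xlim[1L] > cover[[1L]][1L] || xlim[2L] < cover[[1L]][2L] ||
      ylim[1L] > cover[[2L]][1L] || ylim[2L] < cover[[2L]][2L]) {
    warning("grid does not cover the fitted points +/- 6 bandwidths; ",
            "mass will underestimate 1")
  }
  dx <- diff(xlim) / nx
  dy <- diff(ylim) / ny
  xs <- xlim[1L] + (seq_len(nx) - 0.5) * dx
  ys <- ylim[1L] + (seq_len(ny) - 0.5) * dy
  # separable kernel: column sums over each axis, combined per point
  a1 <- outer(xs, model$points[, 1L],
              function(x, p) stats::dnorm((x - p) / h[1L]))
  a2 <- outer(ys, model$points[, 2L],
              function(y, p) stats::dnorm((y - p) / h[2L]))
  total <- sum(colSums(a1) * colSums(a2)) / (model$n * h[1L] * h[2L])
  total * dx * dy
}

#' Evaluate a kernel density on a grid (for plotting or CSV export)
#'
#' @inheritParams grid_mass
#' @return List with `x`, `y` (grid midpoints) and `z` (density matrix,
#'   `nx x ny`), in the layout [graphics::contour()] expects.
#' @export
kde_grid <- function(model, xlim = NULL, ylim = NULL, nx = 80L, ny = 80L) {
  stopifnot(inherits(model, "score_kde"))
  h <- model$bandwidth
  if (is.null(xlim)) xlim <- range(model$points[, 1L]) + c(-3, 3) * h[1L]
  if (is.null(ylim)) ylim <- range(model$points[, 2L]) + c(-3, 3) * h[2L]
  xs <- seq(xlim[1L], xlim[2L], length.out = nx)
  ys <- seq(ylim[1L], ylim[2L], length.out = ny)
  a1 <- outer(xs, model$points[, 1L],
              function(x, p) stats::dnorm((x - p) / h[1L]))
  a2 <- outer(ys, model$points[, 2L],
              function(y, p) stats::dnorm((y - p) / h[2L]))
  z <- (a1 %*% t(a2)) / (model$n * h[1L] * h[2L])
  list(x = xs, y = ys, z = z)
}
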