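#' Default scale-level correlation targets
#'
#' The 9 x 9 correlation matrix among the battery's sub-scale scores used as
#' the default latent structure for synthetic cohorts, chosen to be
#' "study-shaped": weak school-adjustment / eating-behavior / family-function
#' cross-correlations, a strong positive correlation (0.558) between the two
#' suicide-ideation sub-scales, and moderate within-instrument structure.
#' Row/column order follows [subscale_columns()].
#'
#' @return Symmetric positive-definite 9 x 9 matrix with unit diagonal.
#' @export
default_scale_correlations <- function() {
  nm <- subscale_columns()$column
  rows <- list(
    #      SP      AE      IP      BP      CM       R   APGAR     NSI
    c( 0.122),
    c( 0.148,  0.490),
    c(-0.067, -0.116, -0.094),
    c(-0.099, -0.055, -0.034,  0.409),
    c( 0.012,  0.041,  0.016,  0.288,  0.207),
    c( 0.049, -0.037,  0.051, -0.021, -0.091,  0.015),
    c( 0.027,  0.024,  0.012, -0.014, -0.015,  0.032, -0.095),
    c(-0.006,  0.033, -0.061, -0.053, -0.020,  0.021, -0.114,  0.558)
  )
  R <- diag(9)
  for (i in 2:9) R[i, seq_len(i - 1L)] <- rows[[i - 1L]]
  R[upper.tri(R)] <- t(R)[upper.tri(R)]
  dimnames(R) <- list(nm, nm)
  R
}

#' Specify a synthetic questionnaire cohort
#'
#' Describes a Gaussian-copula generator of ordinal item responses: one
#' latent normal per sub-scale with a target correlation matrix, a common
#' item loading linking each item to its sub-scale's latent, equal-mass
#' normal-quantile thresholds mapping item latents to response categories,
#' and an optional ceiling skew that shifts all thresholds downward so the
#' top response category captures more mass (emulating the ceiling effect
#' typical of these instruments).
#'
#' @param n Number of respondents (default 413, the study cohort size).
#' @param latent_correlation Scale-level correlation matrix over the nine
#'   sub-scales in [subscale_columns()] order; must be symmetric with unit
#'   diagonal and positive semidefinite. Defaults to
#'   [default_scale_correlations()].
#' @param loading Common loading of each item on its sub-scale latent, in
#'   (0, 1); default 0.7.
#' @param ceiling_skew Nonnegative shift (in latent standard deviations)
#'   applied downward to all response thresholds; 0 gives symmetric
#'   equal-mass categories.
#' @param instruments Instrument battery, defaulting to
#'   [builtin_instruments()].
#' @param seed Optional integer seed making [generate_cohort()] fully
#'   reproducible.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 413L,
                        latent_correlation = default_scale_correlations(),
                        loading = 0.7, ceiling_skew = 0,
                        instruments = builtin_instruments(),
                        seed = NULL) {
  R <- as.matrix(latent_correlation)
  stopifnot(nrow(R) == ncol(R),
            isTRUE(all.equal(unname(diag(R)), rep(1, ncol(R)))),
            isTRUE(all.equal(R, t(R), tolerance = 1e-10)))
  stopifnot(n >= 1L, loading > 0, loading < 1, ceiling_skew >= 0)
  structure(list(n = as.integer(n), latent_correlation = R,
                 loading = loading, ceiling_skew = ceiling_skew,
                 instruments = instruments, seed = seed),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort spec: n = %d, item loading = %g, ",
                     "ceiling skew = %g%s\n"),
              x$n, x$loading, x$ceiling_skew,
              if (!is.null(x$seed)) sprintf(", seed = %d", x$seed) else ""))
  invisible(x)
}

#' Draw correlated latent variables
#'
#' Rows are independent multivariate-normal draws with the target correlation,
#' obtained by transforming independent standard normals through the
#' symmetric (eigen) square root of the correlation matrix.
#'
#' @param n Number of rows.
#' @param R Target correlation matrix (positive semidefinite).
#' @return `n x ncol(R)` numeric matrix. Consumes `n * ncol(R)` normal draws
#'   from R's RNG.
#' @export
generate_latent <- function(n, R) {
  R <- as.matrix(R)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    stop(sprintf(
      "correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
      min(e$values)))
  }
  root <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), ncol(R)) %*%
    t(e$vectors)
  Z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  out <- Z %*% root
  colnames(out) <- colnames(R)
  out
}

#' Equal-mass response thresholds for an item
#'
#' Standard-normal quantile cut points splitting the latent scale into
#' `n_categories` equally likely categories, then shifted down by
#' `ceiling_skew` latent standard deviations so the top category gains mass.
#'
#' @param n_categories Number of ordinal response categories (>= 2).
#' @param ceiling_skew Nonnegative downward shift.
#' @return Strictly increasing numeric vector of `n_categories - 1` cut
#'   points.
#' @export
item_thresholds <- function(n_categories, ceiling_skew = 0) {
  stopifnot(n_categories >= 2L, ceiling_skew >= 0)
  stats::qnorm(seq_len(n_categories - 1L) / n_categories) - ceiling_skew
}

#' Discretize latent values through thresholds
#'
#' Maps each latent value to the ordinal category whose interval (between
#' consecutive cut points, outermost intervals unbounded) contains it.
#'
#' @param latent Numeric vector or matrix of latent values.
#' @param thresholds Strictly increasing cut points.
#' @param min_response Integer response value of the lowest category.
#' @return Integer responses in
#'   `min_response .. min_response + length(thresholds)`.
#' @export
discretize_to_items <- function(latent, thresholds, min_response = 1L) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  out <- findInterval(latent, thresholds) + as.integer(min_response)
  if (is.matrix(latent)) dim(out) <- dim(latent)
  out
}

#' Generate a synthetic item-level cohort
#'
#' Draws the nine sub-scale latents with the spec's correlation structure,
#' builds each item's latent as `loading * subscale_latent +
#' sqrt(1 - loading^2) * noise`, and thresholds it into the item's response
#' range with equal-mass cuts shifted by the ceiling skew. Items that are
#' reverse-keyed in their sub-scale are generated against the sign of the
#' latent, so that after reverse coding every sub-scale *score* increases
#' with its latent and score-level correlations track the latent targets in
#' sign (attenuated by discretization).
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of integer responses with the 39 battery columns
#'   (`PANSI_1` ... `BQREB_10`), one respondent per row, directly scoreable
#'   by [score_cohort()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  cols <- subscale_columns()
  latents <- generate_latent(spec$n, spec$latent_correlation)
  lam <- spec$loading
  noise_sd <- sqrt(1 - lam^2)
  out <- list()
  for (i in seq_len(nrow(cols))) {
    inst <- spec$instruments[[cols$instrument[i]]]
    ss <- inst$subscales[[cols$subscale[i]]]
    eta <- latents[, i]
    for (j in seq_len(nrow(ss))) {
      item <- ss$item_id[j]
      it <- inst$items[match(item, inst$items$item_id), ]
      z <- lam * eta + noise_sd * stats::rnorm(spec$n)
      if (ss$reversed[j]) z <- -z
      cuts <- item_thresholds(it$max - it$min + 1L, spec$ceiling_skew)
      out[[paste0(inst$prefix, "_", item)]] <-
        discretize_to_items(z, cuts, it$min)
    }
  }
  # present columns in instrument/item order regardless of sub-scale order
  ordered <- unlist(lapply(spec$instruments, item_columns))
  as.data.frame(out)[, ordered[ordered %in% names(out)], drop = FALSE]
}
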