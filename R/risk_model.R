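#' Fit a Monte Carlo joint-density risk model for one score pair
#'
#' The core estimator of the package. For a chosen (risk/protective factor,
#' suicide-ideation) sub-scale pair it:
#' \enumerate{
#'   \item drops respondents without both scores and fits a bivariate
#'     Gaussian kernel density to the remaining score pairs ([fit_kde()]);
#'   \item runs a Metropolis-Hastings chain against that density
#'     ([run_chain()]) with Gaussian random-walk proposals, started at the
#'     scores of a randomly drawn individual, and discards the burn-in;
#'   \item bins the retained samples on the pair's score-interval grid and
#'     forms the joint and conditional probability tables
#'     ([joint_probabilities()], [conditional_probabilities()]).
#' }
#'
#' @param scores Score table from [score_cohort()] (or any data frame
#'   containing the two named columns).
#' @param factor Factor sub-scale column name, e.g. `"BSSA_SP"`.
#' @param pansi Ideation sub-scale column name, `"PANSI_NSI"` or
#'   `"PANSI_PI"`.
#' @param iterations,burnin,proposal_scale,seed Chain settings, passed to
#'   [run_chain()]; defaults: 20000 iterations, 10 percent burn-in. The
#'   default proposal scale `NULL` applies the random-walk Metropolis
#'   scaling rule `sigma_d = 2.38 * sd_d / sqrt(2)` per axis (Roberts,
#'   Gelman and Gilks), which keeps the chain well mixed on score scales as
#'   wide as 10-60; pass `proposal_scale = 1` for the identity-covariance
#'   proposal of the underlying method.
#' @param grid Score-interval grid; defaults to the published
#'   [builtin_grid()] for the pair.
#' @param bandwidth Optional KDE bandwidth override, see [fit_kde()].
#' @return An object of class `risk_model` with fields `pair`, `kde`,
#'   `chain`, `joint`, `conditional`, `n_respondents`, `call`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n = 200, seed = 1))
#' scores <- score_cohort(cohort)
#' fit <- risk_model(scores, "BSSA_SP", "PANSI_NSI",
#'                   iterations = 2000, seed = 1)
#' fit
#' summary(fit)
#' @export
risk_model <- function(scores, factor, pansi = "PANSI_NSI",
                       iterations = 20000L,
                       burnin = iterations %/% 10L,
                       proposal_scale = NULL, seed = NULL,
                       grid = builtin_grid(factor, pansi),
                       bandwidth = NULL) {
  scores <- as.data.frame(scores)
  for (nm in c(factor, pansi)) {
    if (!nm %in% names(scores)) {
      stop(sprintf("score column '%s' not found", nm))
    }
  }
  pts <- as.matrix(scores[, c(factor, pansi)])
  storage.mode(pts) <- "double"
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  kde <- fit_kde(pts, bandwidth = bandwidth)
  if (is.null(proposal_scale)) {
    proposal_scale <- 2.38 / sqrt(2) * apply(pts, 2L, stats::sd)
  }
  chain <- run_chain(kde, iterations = iterations, burnin = burnin,
                     proposal_scale = proposal_scale, init = pts,
                     seed = seed)
  retained <- discard_burnin(chain)
  joint <- joint_probabilities(bin_samples(retained, grid), grid)
  structure(list(pair = c(factor = factor, pansi = pansi),
                 kde = kde, chain = chain, joint = joint,
                 conditional = conditional_probabilities(joint),
                 n_respondents = nrow(pts),
                 call = match.call()),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Monte Carlo risk model: %s vs %s\n", x$pair[["factor"]],
              x$pair[["pansi"]]))
  cat(sprintf(
    "  %d respondents; KDE bandwidths (%.3g, %.3g); %d MH iterations,\n",
    x$n_respondents, x$kde$bandwidth[1L], x$kde$bandwidth[2L],
    length(x$chain$accepted)))
  cat(sprintf("  burn-in %d, acceptance rate %.3f\n", x$chain$burnin,
              acceptance_rate(x$chain)))
  invisible(x)
}

#' @export
summary.risk_model <- function(object, ...) {
  structure(list(model = object), class = "summary.risk_model")
}

#' @export
print.summary.risk_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\n")
  print(m$joint)
  cat("\n")
  print(m$conditional)
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) {
  c(h1 = object$kde$bandwidth[1L], h2 = object$kde$bandwidth[2L],
    acceptance_rate = acceptance_rate(object$chain))
}

#' Kernel density of a fitted risk model at new score pairs
#'
#' @param object A `risk_model`.
#' @param newdata Length-2 vector or `m x 2` matrix of (factor, ideation)
#'   scores; defaults to the fitted score pairs.
#' @param ... Unused.
#' @return Density values.
#' @export
predict.risk_model <- function(object, newdata = object$kde$points, ...) {
  kde_density(object$kde, newdata)
}

#' Draw fresh samples from a fitted risk model
#'
#' Continues sampling the fitted kernel density with a new Metropolis-
#' Hastings chain started at the original chain's final state (already in a
#' high-probability region, so no additional burn-in is applied).
#'
#' @param object A `risk_model`.
#' @param nsim Number of samples to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return `nsim x 2` matrix of sampled score pairs.
#' @export
simulate.risk_model <- function(object, nsim = 1000L, seed = NULL, ...) {
  last <- object$chain$states[nrow(object$chain$states), ]
  chain <- run_chain(object$kde, iterations = nsim, burnin = 0L,
                     proposal_scale = object$chain$proposal_scale,
                     init = last, seed = seed)
  chain$states[-1L, , drop = FALSE]
}

#' Residual-style diagnostic: joint table minus its analytic reference
#'
#' Difference between the chain-estimated joint table and the exact cell
#' masses of the fitted kernel density ([kde_cell_mass()]); entries near zero
#' indicate the chain has resolved the density at the grid's resolution.
#'
#' @param object A `risk_model`.
#' @param ... Unused.
#' @return Matrix of cell-probability differences.
#' @export
residuals.risk_model <- function(object, ...) {
  object$joint$probs - kde_cell_mass(object$kde, object$joint$grid)$probs
}

#' Plot a fitted risk model
#'
#' Three base-graphics panels: the kernel density contour with the observed
#' score pairs, the chain trace (burn-in in red), and an image of the joint
#' probability table.
#'
#' @param x A `risk_model`.
#' @param which Subset of `1:3` selecting panels.
#' @param ... Passed to [graphics::contour()].
#' @export
plot.risk_model <- function(x, which = 1:3, ...) {
  if (length(which) > 1L) {
    old <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(old))
  }
  lab <- x$pair
  if (1L %in% which) {
    g <- kde_grid(x$kde)
    graphics::contour(g$x, g$y, g$z, xlab = lab[["factor"]],
                      ylab = lab[["pansi"]], main = "Joint density", ...)
    graphics::points(x$kde$points, pch = 16, cex = 0.4,
                     col = grDevices::adjustcolor("grey40", 0.5))
  }
  if (2L %in% which) {
    st <- x$chain$states
    burn <- seq_len(x$chain$burnin)
    graphics::plot(st, type = "p", pch = 16, cex = 0.3,
                   col = "black", xlab = lab[["factor"]],
                   ylab = lab[["pansi"]], main = "MH chain")
    if (length(burn)) {
      graphics::points(st[burn, , drop = FALSE], pch = 16, cex = 0.3,
                       col = "red")
    }
  }
  if (3L %in% which) {
    p <- x$joint$probs
    graphics::image(seq_len(nrow(p)), seq_len(ncol(p)), p,
                    xlab = lab[["factor"]], ylab = lab[["pansi"]],
                    main = "Joint probabilities", axes = FALSE)
    graphics::axis(1, seq_len(nrow(p)), rownames(p))
    graphics::axis(2, seq_len(ncol(p)), colnames(p))
  }
  invisible(x)
}
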