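#' Construct a two-axis bin grid
#'
#' A grid of closed integer score intervals per axis, used to bin chain
#' samples into a joint probability table. Intervals within an axis must be
#' disjoint and ascending and, for the built-in grids, cover the sub-scale's
#' full score range.
#'
#' @param axis1,axis2 Data frames with integer columns `lo`, `hi`.
#' @param labels Character length-2 axis labels.
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(axis1, axis2, labels = c("axis1", "axis2")) {
  check_axis <- function(ax, nm) {
    ax <- as.data.frame(ax)
    stopifnot(all(c("lo", "hi") %in% names(ax)))
    if (any(ax$lo > ax$hi)) stop(sprintf("%s: interval with lo > hi", nm))
    if (nrow(ax) > 1L && any(ax$lo[-1L] <= ax$hi[-nrow(ax)])) {
      stop(sprintf("%s: intervals must be disjoint and ascending", nm))
    }
    ax
  }
  structure(list(axis1 = check_axis(axis1, labels[1L]),
                 axis2 = check_axis(axis2, labels[2L]),
                 labels = labels),
            class = "bin_grid")
}

interval_labels <- function(ax) sprintf("(%d,%d)", ax$lo, ax$hi)

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("Bin grid: %s x %s\n", x$labels[1L], x$labels[2L]))
  cat(sprintf("  %s: %s\n", x$labels[1L],
              paste(interval_labels(x$axis1), collapse = " ")))
  cat(sprintf("  %s: %s\n", x$labels[2L],
              paste(interval_labels(x$axis2), collapse = " ")))
  invisible(x)
}

builtin_bins <- function() {
  list(
    PANSI_NSI = data.frame(lo = c(8L, 20L, 30L), hi = c(19L, 29L, 40L)),
    PANSI_PI  = data.frame(lo = c(6L, 15L, 23L), hi = c(14L, 22L, 30L)),
    BSSA_SP   = data.frame(lo = c(3L, 9L, 14L),  hi = c(8L, 13L, 18L)),
    BSSA_AE   = data.frame(lo = c(2L, 6L, 10L),  hi = c(5L, 9L, 12L)),
    BSSA_IP   = data.frame(lo = c(5L, 14L, 22L), hi = c(13L, 21L, 30L)),
    BQREB_BP  = data.frame(lo = c(4L, 9L, 13L),  hi = c(8L, 12L, 16L)),
    BQREB_CM  = data.frame(lo = c(3L, 7L, 10L),  hi = c(6L, 9L, 12L)),
    BQREB_R   = data.frame(lo = c(3L, 7L, 10L),  hi = c(6L, 9L, 12L)),
    APGAR     = data.frame(lo = c(0L, 4L, 8L),   hi = c(3L, 7L, 10L))
  )
}

#' Built-in score-interval grid for a (factor, ideation) pair
#'
#' Returns the published three-interval split of each sub-scale's score
#' range: e.g. PANSI-NSI (8,19), (20,29), (30,40) and BSSA-10 SP (3,8),
#' (9,13), (14,18). Axis 1 is the risk/protective factor, axis 2 the PANSI
#' sub-scale.
#'
#' @param factor One of `"BSSA_SP"`, `"BSSA_AE"`, `"BSSA_IP"`, `"BQREB_BP"`,
#'   `"BQREB_CM"`, `"BQREB_R"`, `"APGAR"` (a PANSI name is also accepted so
#'   any sub-scale pair can be gridded).
#' @param pansi `"PANSI_NSI"` or `"PANSI_PI"`.
#' @return A [bin_grid()].
#' @export
builtin_grid <- function(factor, pansi = "PANSI_NSI") {
  bins <- builtin_bins()
  for (nm in c(factor, pansi)) {
    if (!nm %in% names(bins)) {
      stop(sprintf("unknown sub-scale '%s'; known: %s", nm,
                   paste(names(bins), collapse = ", ")))
    }
  }
  bin_grid(bins[[factor]], bins[[pansi]], labels = c(factor, pansi))
}

axis_breaks <- function(ax) {
  k <- nrow(ax)
  if (k == 1L) return(c(-Inf, Inf))
  # midpoint cuts between adjacent intervals; outer bins extend to infinity
  c(-Inf, (ax$hi[-k] + ax$lo[-1L]) / 2, Inf)
}

#' Bin samples into grid cells
#'
#' Each (real-valued) sample is assigned to exactly one cell: boundaries
#' between adjacent integer intervals are placed at their midpoints (e.g.
#' 8.5 between (3,8) and (9,13)) and the outermost bins extend to infinity,
#' so kernel-density mass outside the valid score rectangle is clamped to the
#' nearest bin and counts always sum to the sample size.
#'
#' @param samples Numeric `m x 2` matrix of samples (e.g. retained chain
#'   states).
#' @param grid A [bin_grid()].
#' @return Integer count matrix, rows = axis-1 intervals, columns = axis-2
#'   intervals.
#' @export
bin_samples <- function(samples, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 2L)
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("at least one sample is required")
  i1 <- findInterval(samples[, 1L], axis_breaks(grid$axis1))
  i2 <- findInterval(samples[, 2L], axis_breaks(grid$axis2))
  k1 <- nrow(grid$axis1)
  k2 <- nrow(grid$axis2)
  counts <- matrix(0L, k1, k2,
                   dimnames = list(interval_labels(grid$axis1),
                                   interval_labels(grid$axis2)))
  tab <- table(factor(i1, levels = seq_len(k1)),
               factor(i2, levels = seq_len(k2)))
  counts[] <- as.integer(tab)
  counts
}

new_prob_table <- function(probs, grid, n_samples, kind) {
  dimnames(probs) <- list(interval_labels(grid$axis1),
                          interval_labels(grid$axis2))
  structure(list(probs = probs, grid = grid, n_samples = n_samples,
                 kind = kind),
            class = "prob_table")
}

#' Joint probability table from bin counts
#'
#' @param counts Integer count matrix from [bin_samples()].
#' @param grid The [bin_grid()] the counts were computed on.
#' @return A `prob_table` of kind `"joint"`; cell probabilities are
#'   `count / m` and sum to 1.
#' @export
joint_probabilities <- function(counts, grid) {
  m <- sum(counts)
  if (m < 1) stop("no samples to estimate probabilities from")
  new_prob_table(counts / m, grid, n_samples = m, kind = "joint")
}

#' Conditional probability table given the factor (axis 1)
#'
#' Divides each row of a joint table by its row mass, giving
#' `P(ideation interval | factor interval)`. Rows with zero mass are emitted
#' as `NA` and flagged.
#'
#' @param table A joint `prob_table` (a conditional table passes through
#'   unchanged: conditioning is idempotent).
#' @return A `prob_table` of kind `"conditional"`; each non-empty row sums
#'   to 1. Zero-mass rows are listed in the `empty_rows` field.
#' @export
conditional_probabilities <- function(table) {
  stopifnot(inherits(table, "prob_table"))
  probs <- table$probs
  row_mass <- rowSums(probs, na.rm = TRUE)
  out <- probs
  empty <- integer(0)
  for (i in seq_len(nrow(probs))) {
    if (isTRUE(row_mass[i] > 0)) {
      out[i, ] <- probs[i, ] / row_mass[i]
    } else if (table$kind == "conditional" && !anyNA(probs[i, ])) {
      out[i, ] <- probs[i, ]
    } else {
      out[i, ] <- NA_real_
      empty <- c(empty, i)
    }
  }
  res <- new_prob_table(out, table$grid, table$n_samples, "conditional")
  res$empty_rows <- empty
  res
}

#' @export
print.prob_table <- function(x, digits = 3L, ...) {
  cat(sprintf("%s probability table (%s x %s), %d samples\n",
              if (x$kind == "joint") "Joint" else "Conditional",
              x$grid$labels[1L], x$grid$labels[2L], x$n_samples))
  print(round(x$probs, digits))
  invisible(x)
}

#' @export
as.data.frame.prob_table <- function(x, ...) {
  g <- expand.grid(axis1 = interval_labels(x$grid$axis1),
                   axis2 = interval_labels(x$grid$axis2),
                   stringsAsFactors = FALSE)
  names(g) <- x$grid$labels
  g$prob <- as.vector(x$probs)
  g
}

#' Headline risk summary from a probability table
#'
#' A documented summary convention (the published study does not define its
#' own reduction): the maximum, over a designated set of adverse factor
#' intervals, of the conditional probability mass falling in the designated
#' adverse ideation intervals. Reads as "an adolescent in the worst factor
#' band has up to this probability of an adverse ideation score".
#'
#' @param table A `prob_table`; joint tables are conditioned on the factor
#'   axis first.
#' @param adverse_factor_bins Integer indices (or `"(lo,hi)"` labels) of the
#'   adverse axis-1 intervals.
#' @param adverse_pansi_bins Indices or labels of the adverse axis-2
#'   intervals.
#' @return A single probability in `[0, 1]`.
#' @export
headline_risk <- function(table, adverse_factor_bins, adverse_pansi_bins) {
  stopifnot(inherits(table, "prob_table"))
  if (length(adverse_factor_bins) == 0L || length(adverse_pansi_bins) == 0L) {
    stop("adverse bin sets must be non-empty")
  }
  resolve <- function(bins, ax, nm) {
    if (is.character(bins)) bins <- match(bins, interval_labels(ax))
    if (anyNA(bins) || any(bins < 1L | bins > nrow(ax))) {
      stop(sprintf("unknown %s bin", nm))
    }
    as.integer(bins)
  }
  rows <- resolve(adverse_factor_bins, table$grid$axis1, "factor")
  cols <- resolve(adverse_pansi_bins, table$grid$axis2, "ideation")
  cond <- if (table$kind == "conditional") table else {
    conditional_probabilities(table)
  }
  masses <- rowSums(cond$probs[rows, cols, drop = FALSE])
  masses <- masses[!is.na(masses)]
  # a factor band with no sampled mass contributes no observed risk
  if (length(masses) == 0L) return(0)
  max(masses)
}

#' Exact cell masses of a kernel density over a bin grid
#'
#' For the product-Gaussian kernel the integral of the fitted density over a
#' rectangle factorises into normal CDF differences, so cell masses are
#' available in closed form:
#' `(1/n) * sum_i [Phi((b1 - p_i1)/h1) - Phi((a1 - p_i1)/h1)] *
#' [Phi((b2 - p_i2)/h2) - Phi((a2 - p_i2)/h2)]`.
#' Cell edges use the same midpoint/infinite-outer convention as
#' [bin_samples()], so the resulting joint table is the exact distribution
#' the binned chain samples estimate — an analytic reference for
#' Monte-Carlo error.
#'
#' @param model A [fit_kde()] model.
#' @param grid A [bin_grid()].
#' @return A `prob_table` of kind `"joint"` whose cells sum to 1 exactly
#'   (up to floating point).
#' @export
kde_cell_mass <- function(model, grid) {
  stopifnot(inherits(model, "score_kde"), inherits(grid, "bin_grid"))
  h <- model$bandwidth
  b1 <- axis_breaks(grid$axis1)
  b2 <- axis_breaks(grid$axis2)
  cdf_band <- function(breaks, p, h) {
    # rows: points; cols: bins
    cdf <- vapply(breaks, function(b) stats::pnorm((b - p) / h),
                  numeric(length(p)))
    cdf[, -1L, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  }
  m1 <- cdf_band(b1, model$points[, 1L], h[1L])
  m2 <- cdf_band(b2, model$points[, 2L], h[2L])
  probs <- crossprod(m1, m2) / model$n
  new_prob_table(probs, grid, n_samples = model$n, kind = "joint")
}

#' Total-variation distance between two probability tables
#'
#' Half the sum of absolute cell differences.
#'
#' @param a,b `prob_table`s on the same grid shape.
#' @return A number in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  stopifnot(inherits(a, "prob_table"), inherits(b, "prob_table"),
            all(dim(a$probs) == dim(b$probs)))
  0.5 * sum(abs(a$probs - b$probs))
}

#' Write a probability table to CSV
#'
#' Mirrors the published table layout: rows = factor intervals, columns =
#' ideation intervals. Values are written at 2 decimals, with a companion
#' `*_full.csv` at full precision.
#'
#' @param table A `prob_table`.
#' @param path Output CSV path.
#' @export
write_prob_table <- function(table, path) {
  stopifnot(inherits(table, "prob_table"))
  rounded <- as.data.frame(format(round(table$probs, 2L), nsmall = 2L))
  rounded <- cbind(RANGE = rownames(table$probs), rounded)
  utils::write.csv(rounded, path, row.names = FALSE)
  full <- cbind(RANGE = rownames(table$probs),
                as.data.frame(table$probs))
  utils::write.csv(full, sub("\\.csv$", "_full.csv", path),
                   row.names = FALSE)
  invisible(path)
}
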