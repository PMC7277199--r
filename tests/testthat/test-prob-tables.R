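test_that("built-in grids reproduce the published interval splits", {
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  expect_equal(g$axis1$lo, c(3L, 9L, 14L))
  expect_equal(g$axis1$hi, c(8L, 13L, 18L))
  expect_equal(g$axis2$lo, c(8L, 20L, 30L))
  expect_equal(g$axis2$hi, c(19L, 29L, 40L))
  ga <- builtin_grid("APGAR", "PANSI_PI")
  expect_equal(ga$axis1$lo, c(0L, 4L, 8L))
  expect_equal(ga$axis2$lo, c(6L, 15L, 23L))
  expect_error(builtin_grid("NOPE", "PANSI_NSI"), "unknown sub-scale")
})

test_that("every built-in grid covers its sub-scale's score range", {
  specs <- builtin_instruments()
  cols <- subscale_columns()
  for (i in seq_len(nrow(cols))) {
    ax <- builtin_grid(cols$column[i], "PANSI_NSI")$axis1
    rng <- subscale_range(specs[[cols$instrument[i]]], cols$subscale[i])
    expect_equal(ax$lo[1], rng[1])
    expect_equal(ax$hi[nrow(ax)], rng[2])
    # no integer gaps between adjacent intervals
    if (nrow(ax) > 1) expect_equal(ax$lo[-1], ax$hi[-nrow(ax)] + 1L)
  }
})

test_that("samples are binned by midpoint cuts with clamped outer bins", {
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  cnt <- bin_samples(rbind(c(10.2, 25.0)), g)
  expect_equal(cnt["(9,13)", "(20,29)"], 1L)
  expect_equal(sum(cnt), 1L)
  # out-of-rectangle samples fall in the nearest outer bin
  cnt2 <- bin_samples(rbind(c(-4.0, 90.0)), g)
  expect_equal(cnt2["(3,8)", "(30,40)"], 1L)
  # boundary: 8.5 is the cut between (3,8) and (9,13); 8.49 stays low
  expect_equal(bin_samples(rbind(c(8.49, 10)), g)["(3,8)", "(8,19)"], 1L)
  expect_equal(bin_samples(rbind(c(8.51, 10)), g)["(9,13)", "(8,19)"], 1L)

  set.seed(14)
  samples <- cbind(runif(500, -5, 25), runif(500, 0, 50))
  expect_equal(sum(bin_samples(samples, g)), 500L)
})

test_that("joint and conditional tables satisfy their normalizations", {
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  one_cell <- bin_samples(rbind(c(10, 25), c(10, 25)), g)
  jt <- joint_probabilities(one_cell, g)
  expect_equal(jt$probs["(9,13)", "(20,29)"], 1)
  expect_equal(sum(jt$probs), 1)

  counts <- matrix(5L, 3, 3)
  ju <- joint_probabilities(counts, g)
  expect_equal(unname(ju$probs), matrix(1 / 9, 3, 3))
  expect_error(joint_probabilities(matrix(0L, 3, 3), g), "no samples")

  joint <- ju
  joint$probs[] <- c(0.1, 0, 0.05, 0.2, 0, 0.15, 0.1, 0, 0.4)
  cond <- conditional_probabilities(joint)
  expect_equal(unname(cond$probs[1, ]),
               c(0.1, 0.2, 0.1) / 0.4)
  expect_equal(cond$empty_rows, 2L)
  expect_true(all(is.na(cond$probs[2, ])))
  expect_equal(unname(rowSums(cond$probs)[c(1, 3)]), c(1, 1))
  # conditioning is idempotent
  cond2 <- conditional_probabilities(cond)
  expect_equal(cond2$probs, cond$probs)
})

test_that("headline risk equals a brute-force enumeration over cells", {
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  probs <- matrix(c(0.10, 0.02, 0.08,
                    0.05, 0.20, 0.15,
                    0.10, 0.10, 0.20), 3, 3, byrow = TRUE)
  jt <- joint_probabilities(round(probs * 100), g)
  adverse_rows <- c(1L, 2L)
  adverse_cols <- c(2L, 3L)
  # enumeration oracle: conditional mass per adverse row, maximised
  best <- -Inf
  for (r in adverse_rows) {
    mass <- 0
    for (cc in adverse_cols) mass <- mass + probs[r, cc] / sum(probs[r, ])
    best <- max(best, mass)
  }
  expect_equal(headline_risk(jt, adverse_rows, adverse_cols), best)
  expect_equal(headline_risk(jt, "(3,8)", c("(20,29)", "(30,40)")),
               sum(probs[1, 2:3]) / sum(probs[1, ]))

  # degenerate tables
  one <- matrix(0L, 3, 3); one[1, 3] <- 10L
  expect_equal(headline_risk(joint_probabilities(one, g), 1L, 3L), 1)
  # zero mass on the adverse ideation intervals
  expect_equal(headline_risk(joint_probabilities(one, g), 1L, 1:2), 0)
  # factor bands with no mass at all contribute no observed risk
  expect_equal(headline_risk(joint_probabilities(one, g), 2:3, 1:2), 0)
  expect_error(headline_risk(jt, integer(0), 1L), "non-empty")
  expect_error(headline_risk(jt, 5L, 1L), "unknown")
})

test_that("analytic cell masses agree with numeric quadrature", {
  set.seed(31)
  pts <- cbind(rnorm(40, 10, 3), rnorm(40, 24, 6))
  m <- fit_kde(pts)
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  tab <- kde_cell_mass(m, g)
  expect_equal(sum(tab$probs), 1, tolerance = 1e-12)
  # independent midpoint-rule quadrature of the density over one cell
  cell_mass_quad <- function(x1, x2, y1, y2, n = 400) {
    dx <- (x2 - x1) / n; dy <- (y2 - y1) / n
    xs <- x1 + (seq_len(n) - 0.5) * dx
    ys <- y1 + (seq_len(n) - 0.5) * dy
    h <- m$bandwidth
    a1 <- outer(xs, pts[, 1], function(x, p) dnorm((x - p) / h[1]))
    a2 <- outer(ys, pts[, 2], function(y, p) dnorm((y - p) / h[2]))
    sum(colSums(a1) * colSums(a2)) / (nrow(pts) * h[1] * h[2]) * dx * dy
  }
  expect_equal(tab$probs["(9,13)", "(20,29)"],
               cell_mass_quad(8.5, 13.5, 19.5, 29.5), tolerance = 1e-5)
})

test_that("longer chains move the estimated table toward the analytic one", {
  set.seed(55)
  pts <- cbind(rnorm(120, 10, 3), rnorm(120, 24, 6))
  m <- fit_kde(pts)
  g <- builtin_grid("BSSA_SP", "PANSI_NSI")
  truth <- kde_cell_mass(m, g)
  tv_at <- function(n_iter, seed) {
    ch <- run_chain(m, iterations = n_iter, burnin = n_iter %/% 10,
                    proposal_scale = c(5, 10), init = c(10, 24), seed = seed)
    tv_distance(joint_probabilities(bin_samples(discard_burnin(ch), g), g),
                truth)
  }
  short <- vapply(1:3, function(s) tv_at(1000, s), numeric(1))
  long <- vapply(1:3, function(s) tv_at(30000, s + 100), numeric(1))
  expect_lt(mean(long), mean(short))
})

test_that("probability tables serialize to the two-decimal CSV layout", {
  g <- builtin_grid("APGAR", "PANSI_PI")
  jt <- joint_probabilities(matrix(c(10L, 0L, 5L, 5L, 40L, 10L, 5L, 20L,
                                     5L), 3, 3), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_prob_table(jt, path)
  rounded <- utils::read.csv(path, check.names = FALSE)
  expect_equal(rounded$RANGE, c("(0,3)", "(4,7)", "(8,10)"))
  full <- utils::read.csv(sub("\\.csv$", "_full.csv", path),
                          check.names = FALSE)
  expect_equal(as.matrix(full[, -1]), jt$probs, ignore_attr = TRUE)
})
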