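scores_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- score_cohort(generate_cohort(cohort_spec(n = 200,
                                                         seed = 101)))
    }
    cache
  }
})

test_that("risk_model wires scoring, KDE, chain and tables together", {
  s <- scores_fixture()
  fit <- risk_model(s, "BSSA_SP", "PANSI_NSI", iterations = 3000, seed = 1)
  expect_s3_class(fit, "risk_model")
  expect_equal(sum(fit$joint$probs), 1, tolerance = 1e-12)
  rs <- rowSums(fit$conditional$probs)
  expect_equal(unname(rs[!is.na(rs)]), rep(1, sum(!is.na(rs))),
               tolerance = 1e-12)
  expect_equal(fit$n_respondents, 200L)
  # chain is on the score scale and starts at a respondent's pair
  start <- fit$chain$states[1, ]
  expect_true(any(s$BSSA_SP == start[1] & s$PANSI_NSI == start[2],
                  na.rm = TRUE))
  # same seed, same fit
  fit2 <- risk_model(s, "BSSA_SP", "PANSI_NSI", iterations = 3000, seed = 1)
  expect_identical(fit$joint$probs, fit2$joint$probs)
  expect_error(risk_model(s, "NOPE"), "not found")
})

test_that("risk_model methods expose the fit coherently", {
  s <- scores_fixture()
  fit <- risk_model(s, "APGAR", "PANSI_PI", iterations = 2000, seed = 3)
  expect_output(print(fit), "APGAR")
  expect_output(print(summary(fit)), "Conditional")
  co <- coef(fit)
  expect_named(co, c("h1", "h2", "acceptance_rate"))
  expect_equal(unname(co[1:2]), fit$kde$bandwidth)

  d <- predict(fit, c(5, 20))
  expect_equal(d, kde_density(fit$kde, c(5, 20)))

  sims <- simulate(fit, nsim = 500, seed = 9)
  expect_equal(dim(sims), c(500L, 2L))
  expect_identical(sims, simulate(fit, nsim = 500, seed = 9))

  res <- residuals(fit)
  expect_equal(dim(res), c(3L, 3L))
  expect_lt(max(abs(res)), 0.25)

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("run_full writes a complete, renormalized artifact set", {
  out <- withr::local_tempdir()
  cfg <- run_config(
    input = cohort_spec(n = 150),
    pairs = data.frame(factor = c("BSSA_SP", "APGAR"),
                       pansi = c("PANSI_NSI", "PANSI_PI")),
    iterations = 1500, seed = 7, output_dir = out
  )
  res <- run_full(cfg, quiet = TRUE)
  expect_length(res$models, 2L)
  for (m in res$models) expect_equal(sum(m$joint$probs), 1,
                                     tolerance = 1e-12)
  files <- list.files(out)
  expect_true(all(c("scores.csv", "correlations.csv", "psychometrics.json",
                    "manifest.json", "config.json",
                    "chain_BSSA_SP__PANSI_NSI.csv",
                    "joint_BSSA_SP__PANSI_NSI.csv",
                    "conditional_APGAR__PANSI_PI.csv") %in% files))
  # psychometrics validated both multi-item instruments
  pj <- jsonlite::read_json(file.path(out, "psychometrics.json"))
  expect_setequal(names(pj), c("BQREB", "BSSA-10"))
  expect_true(pj$BQREB$kmo > 0 && pj$BQREB$kmo < 1)
  # headline summary returns a percentage per fitted pair
  hr <- headline_risks(res$models)
  expect_length(hr, 2L)
  expect_true(all(hr >= 0 & hr <= 100))
})

test_that("a run re-executed from its manifest is bitwise identical", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  cfg <- run_config(
    input = cohort_spec(n = 120),
    pairs = data.frame(factor = c("BSSA_IP", "BQREB_BP"),
                       pansi = c("PANSI_NSI", "PANSI_NSI")),
    iterations = 1000, seed = 17, output_dir = out1
  )
  run_full(cfg, quiet = TRUE)
  cfg2 <- config_from_manifest(file.path(out1, "manifest.json"),
                               output_dir = out2)
  run_full(cfg2, quiet = TRUE)
  for (f in list.files(out1)) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))),
                     label = f)
  }
})

test_that("a failing pair does not abort the remaining pairs", {
  out <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(n = 60, seed = 5))
  path <- file.path(out, "resp.csv")
  utils::write.csv(cohort, path, row.names = FALSE)
  cfg <- run_config(
    input = path,
    pairs = data.frame(factor = c("BSSA_SP", "BSSA_AE"),
                       pansi = c("PANSI_NSI", "PANSI_NSI")),
    iterations = 500, seed = 2,
    output_dir = file.path(out, "run")
  )
  # degrade the first pair: constant SP scores make the KDE degenerate
  cohort2 <- cohort
  cohort2[paste0("BSSA_", c(1, 2, 5))] <- 1L
  utils::write.csv(cohort2, path, row.names = FALSE)
  res <- run_full(cfg, quiet = TRUE)
  expect_length(res$models, 1L)
  expect_named(res$models, "BSSA_AE__PANSI_NSI")
  expect_false(res$manifest$pairs$BSSA_SP__PANSI_NSI$ok)
  expect_match(res$manifest$pairs$BSSA_SP__PANSI_NSI$error, "zero variance")
})

test_that("restricting pairs never changes another pair's chain", {
  s <- NULL
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  pairs2 <- data.frame(factor = c("BSSA_SP", "BQREB_CM"),
                       pansi = c("PANSI_NSI", "PANSI_PI"))
  cfg_all <- run_config(input = cohort_spec(n = 100), pairs = pairs2,
                        iterations = 600, seed = 23, output_dir = out1)
  cfg_one <- run_config(input = cohort_spec(n = 100),
                        pairs = pairs2[1, , drop = FALSE],
                        iterations = 600, seed = 23, output_dir = out2)
  r_all <- run_full(cfg_all, quiet = TRUE)
  r_one <- run_full(cfg_one, quiet = TRUE)
  expect_identical(r_all$models[[1]]$joint$probs,
                   r_one$models[[1]]$joint$probs)
  expect_length(r_one$models, 1L)
})
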