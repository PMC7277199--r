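#' The fourteen analysed score pairs
#'
#' Every factor sub-scale of BSSA-10, BQREB and APGAR crossed with both PANSI
#' sub-scales.
#'
#' @return Data frame with columns `factor` and `pansi`.
#' @export
default_pairs <- function() {
  factors <- c("BSSA_SP", "BSSA_AE", "BSSA_IP", "BQREB_BP", "BQREB_CM",
               "BQREB_R", "APGAR")
  expand.grid(factor = factors, pansi = c("PANSI_NSI", "PANSI_PI"),
              stringsAsFactors = FALSE)
}

#' Adverse score bands used by the headline risk summary
#'
#' For each factor sub-scale, the band of its built-in grid read as adverse:
#' the lowest interval for scales where low scores mean trouble (school
#' performance, academic expectations, integration — all keyed so high means
#' good adjustment — and family function), the highest interval for the
#' eating-behavior factors where high scores mean more risk behavior. For
#' the ideation axis: negative-ideation (NSI) scores of 20 and above
#' (elevated negative ideation, the upper two intervals), and the lowest
#' positive-ideation (PI) interval (little protective positive ideation).
#'
#' @return List with `factor_bins` (named list of interval indices) and
#'   `pansi_bins` (named list for `PANSI_NSI` / `PANSI_PI`).
#' @export
adverse_bins <- function() {
  list(
    factor_bins = list(BSSA_SP = 1L, BSSA_AE = 1L, BSSA_IP = 1L,
                       BQREB_BP = 3L, BQREB_CM = 3L, BQREB_R = 3L,
                       APGAR = 1L),
    pansi_bins = list(PANSI_NSI = c(2L, 3L), PANSI_PI = 1L)
  )
}

#' Configure a full pipeline run
#'
#' @param input Either a [cohort_spec()] (a synthetic cohort is generated)
#'   or a path to a response CSV readable by [read_responses()].
#' @param pairs Data frame of (factor, pansi) column pairs; defaults to the
#'   14 pairs of [default_pairs()].
#' @param iterations,burnin,proposal_scale Chain settings per pair;
#'   `proposal_scale = NULL` (the default) uses [risk_model()]'s
#'   scale-matched proposal.
#' @param seed Master seed; each pair runs on its own derived seed
#'   (`seed + pair index`) so restricting `pairs` never perturbs another
#'   pair's results.
#' @param output_dir Directory for run artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = cohort_spec(), pairs = default_pairs(),
                       iterations = 20000L, burnin = iterations %/% 10L,
                       proposal_scale = NULL, seed = 1L,
                       output_dir = tempfile("mcrisk_run_")) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("factor", "pansi") %in% names(pairs)),
            all(pairs$pansi %in% c("PANSI_NSI", "PANSI_PI")))
  structure(list(input = input, pairs = pairs,
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin),
                 proposal_scale = proposal_scale, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "run_config")
}

config_for_json <- function(config) {
  inp <- config$input
  list(
    input = if (inherits(inp, "cohort_spec")) {
      list(type = "synthetic", n = inp$n, loading = inp$loading,
           ceiling_skew = inp$ceiling_skew, seed = inp$seed,
           latent_correlation = unname(inp$latent_correlation))
    } else {
      list(type = "csv", path = as.character(inp))
    },
    pairs = config$pairs,
    iterations = config$iterations, burnin = config$burnin,
    proposal_scale = if (is.null(config$proposal_scale)) "auto" else
      config$proposal_scale,
    seed = config$seed
  )
}

#' Execute the full pipeline
#'
#' Loads or generates the cohort, scores it, writes the score table and the
#' sub-scale correlation matrix, runs the psychometric validation for the
#' multi-item instruments, and, for every configured score pair, fits a
#' [risk_model()] and writes its chain and its joint and conditional
#' probability tables. A `manifest.json` records the configuration, derived
#' per-pair seeds, acceptance rates and package version, so any run can be
#' reproduced bit for bit from the manifest alone.
#'
#' A failure in one pair aborts only that pair (with the reason recorded in
#' the manifest); remaining pairs still run.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-pair progress messages.
#' @return Invisibly, a list with the scores, fitted models, psychometric
#'   reports and the manifest.
#' @export
run_full <- function(config = run_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  if (inherits(config$input, "cohort_spec")) {
    if (is.null(config$input$seed)) {
      # resolve now so the manifest records the seed actually used
      config$input$seed <- config$seed
    }
    responses <- generate_cohort(config$input)
  } else {
    responses <- read_responses(config$input)
  }
  scores <- score_cohort(responses)
  write_scores(scores, file.path(config$output_dir, "scores.csv"))

  R <- tryCatch(
    correlation_matrix(scores[stats::complete.cases(scores), ]),
    error = function(e) {
      say("correlation matrix skipped: %s", conditionMessage(e))
      NULL
    })
  if (!is.null(R)) {
    utils::write.csv(round(R, 3), file.path(config$output_dir,
                                            "correlations.csv"))
  }

  psych <- list()
  for (inst in c("BQREB", "BSSA-10")) {
    spec <- builtin_instruments()[[inst]]
    psych[[inst]] <- tryCatch(
      factor_report(responses[, item_columns(spec)]),
      error = function(e) {
        say("psychometrics for %s skipped: %s", inst, conditionMessage(e))
        NULL
      })
  }
  psych <- Filter(Negate(is.null), psych)
  jsonlite::write_json(
    lapply(psych, function(r) {
      list(kmo = r$kmo, bartlett = r$bartlett, eigenvalues = r$eigenvalues,
           variance_explained = r$variance_explained,
           n_retained = r$n_retained, loadings = r$loadings, n = r$n)
    }),
    file.path(config$output_dir, "psychometrics.json"),
    auto_unbox = TRUE, digits = NA
  )

  models <- list()
  pair_meta <- list()
  for (i in seq_len(nrow(config$pairs))) {
    fct <- config$pairs$factor[i]
    pni <- config$pairs$pansi[i]
    key <- paste(fct, pni, sep = "__")
    pair_seed <- config$seed + i
    res <- tryCatch({
      fit <- risk_model(scores, fct, pni, iterations = config$iterations,
                        burnin = config$burnin,
                        proposal_scale = config$proposal_scale,
                        seed = pair_seed)
      write_chain(fit$chain,
                  file.path(config$output_dir,
                            sprintf("chain_%s.csv", key)))
      write_prob_table(fit$joint,
                       file.path(config$output_dir,
                                 sprintf("joint_%s.csv", key)))
      write_prob_table(fit$conditional,
                       file.path(config$output_dir,
                                 sprintf("conditional_%s.csv", key)))
      say("pair %s: n = %d, acceptance rate = %.3f", key,
          fit$n_respondents, acceptance_rate(fit$chain))
      fit
    }, error = function(e) {
      say("pair %s FAILED: %s", key, conditionMessage(e))
      e
    })
    ok <- inherits(res, "risk_model")
    pair_meta[[key]] <- list(
      factor = fct, pansi = pni, seed = pair_seed, ok = ok,
      acceptance_rate = if (ok) acceptance_rate(res$chain) else NA,
      initial_state = if (ok) res$chain$states[1L, ] else NULL,
      burnin = config$burnin,
      error = if (!ok) conditionMessage(res) else NULL
    )
    if (ok) models[[key]] <- res
  }

  cfg_json <- jsonlite::toJSON(config_for_json(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(config$output_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "mcrisk",
    version = as.character(utils::packageVersion("mcrisk")),
    config = config_for_json(config),
    config_hash = unname(tools::md5sum(cfg_path)),
    pairs = pair_meta
  )
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scores = scores, models = models, psychometrics = psych,
                 manifest = manifest, correlations = R,
                 output_dir = config$output_dir))
}

#' Rebuild a run configuration from a manifest
#'
#' Inverse of the manifest written by [run_full()]: a run re-executed from
#' its manifest reproduces every output file bit for bit.
#'
#' @param path Path to a `manifest.json`.
#' @param output_dir Directory for the re-run's artifacts.
#' @return A [run_config()].
#' @export
config_from_manifest <- function(path, output_dir = tempfile("mcrisk_run_")) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- m$config
  input <- if (identical(cfg$input$type, "synthetic")) {
    cohort_spec(n = cfg$input$n,
                latent_correlation = cfg$input$latent_correlation,
                loading = cfg$input$loading,
                ceiling_skew = cfg$input$ceiling_skew,
                seed = cfg$input$seed)
  } else {
    cfg$input$path
  }
  run_config(input = input, pairs = cfg$pairs,
             iterations = cfg$iterations, burnin = cfg$burnin,
             proposal_scale = if (identical(cfg$proposal_scale, "auto"))
               NULL else cfg$proposal_scale,
             seed = cfg$seed, output_dir = output_dir)
}

#' Headline risk percentages across all factors
#'
#' Applies [headline_risk()] with the [adverse_bins()] convention to each
#' fitted pair of a [run_full()] result, returning percentages.
#'
#' @param models Named list of `risk_model`s (`run_full()$models`).
#' @return Named numeric vector of percentages.
#' @export
headline_risks <- function(models) {
  adv <- adverse_bins()
  out <- vapply(models, function(m) {
    100 * headline_risk(m$conditional,
                        adv$factor_bins[[m$pair[["factor"]]]],
                        adv$pansi_bins[[m$pair[["pansi"]]]])
  }, numeric(1L))
  names(out) <- names(models)
  out
}
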