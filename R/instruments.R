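#' Declare a psychometric instrument
#'
#' An instrument is a named set of Likert-type items, a partition of (some of)
#' those items into sub-scales with optional reverse coding, and, optionally,
#' ordered score categories (as for the family APGAR dysfunction bands).
#'
#' @param name Instrument name, e.g. `"PANSI"`.
#' @param items Data frame with columns `item_id` (integer, 1-based, matching
#'   the instrument's published item numbering), `min` and `max` (integer
#'   response bounds, `min < max`).
#' @param subscales Named list; each element a data frame with columns
#'   `item_id` and `reversed` (logical). Every `item_id` must appear in
#'   `items`. Reversed items are recoded as `(min + max) - response` before
#'   summation, so that high sub-scale scores keep one direction of meaning.
#' @param categories Optional data frame with columns `lo`, `hi`, `label`
#'   giving disjoint, ascending closed integer score intervals.
#' @param prefix Column-name prefix used in response CSVs (defaults to `name`
#'   with non-alphanumeric characters removed, so `"BSSA-10"` items are read
#'   from columns `BSSA_1` ... `BSSA_10`).
#' @return An object of class `instrument_spec`.
#' @seealso [builtin_instruments()] for the four instruments used in the
#'   adolescent suicide-risk screening battery.
#' @export
instrument_spec <- function(name, items, subscales, categories = NULL,
                            prefix = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  items <- as.data.frame(items)
  stopifnot(all(c("item_id", "min", "max") %in% names(items)))
  if (anyDuplicated(items$item_id)) {
    stop("duplicated item_id in 'items'")
  }
  if (!all(items$min < items$max)) {
    stop("every item must satisfy min < max")
  }
  stopifnot(is.list(subscales), length(names(subscales)) == length(subscales))
  for (sub in names(subscales)) {
    ss <- as.data.frame(subscales[[sub]])
    stopifnot(all(c("item_id", "reversed") %in% names(ss)))
    missing_items <- setdiff(ss$item_id, items$item_id)
    if (length(missing_items)) {
      stop(sprintf("sub-scale '%s' refers to unknown item(s): %s",
                   sub, paste(missing_items, collapse = ", ")))
    }
    subscales[[sub]] <- ss
  }
  if (!is.null(categories)) {
    categories <- as.data.frame(categories)
    stopifnot(all(c("lo", "hi", "label") %in% names(categories)))
    if (nrow(categories) > 1L) {
      if (any(diff(categories$lo) <= 0) ||
          any(categories$lo[-1L] <= categories$hi[-nrow(categories)])) {
        stop("category intervals must be disjoint and ascending")
      }
    }
  }
  if (is.null(prefix)) prefix <- gsub("[^A-Za-z0-9]", "", name)
  structure(
    list(name = name, items = items, subscales = subscales,
         categories = categories, prefix = prefix),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("Instrument '%s': %d items (responses %s)\n", x$name,
              nrow(x$items),
              paste(unique(sprintf("%d-%d", x$items$min, x$items$max)),
                    collapse = ", ")))
  for (sub in names(x$subscales)) {
    ss <- x$subscales[[sub]]
    rng <- subscale_range(x, sub)
    cat(sprintf("  %-6s items {%s}%s, score range %d-%d\n", sub,
                paste(ss$item_id, collapse = ","),
                if (any(ss$reversed)) " (reversed)" else "",
                rng[1L], rng[2L]))
  }
  invisible(x)
}

#' Built-in instrument battery
#'
#' Returns the four instruments of the screening battery:
#' \describe{
#'   \item{PANSI}{14 items rated 1-5; sub-scales NSI (negative suicide
#'     ideation, 8 items, scores 8-40) and PI (positive ideation, 6 items,
#'     scores 6-30). The published scale does not bind item numbers to
#'     sub-scales in this battery's description, so the assignment follows the
#'     original instrument keying (PI = items 2, 6, 8, 12, 13, 14) and can be
#'     overridden via `pansi_pi_items`.}
#'   \item{APGAR}{Family APGAR: 5 items rated 0-2, total 0-10, with
#'     dysfunction categories (see [classify_apgar()]).}
#'   \item{BSSA-10}{School adjustment: 10 items rated 1-6; SP = items
#'     \{1,2,5\}, AE = \{3,4\}, IP = \{6..10\} all reverse-keyed (recoded
#'     7 - response), so high scores uniformly mean good adjustment.}
#'   \item{BQREB}{Risk eating behaviors: 10 items rated 1-4; factors BP
#'     (binge-purge, 4 items), CM (compensatory measures, 3 items), R
#'     (restriction, 3 items). The published description gives only the item
#'     counts; the default assignment is BP = 1-4, CM = 5-7, R = 8-10,
#'     overridable via `bqreb_items`.}
#' }
#'
#' @param pansi_pi_items Integer vector of the 6 PANSI items forming the PI
#'   sub-scale; the remaining 8 form NSI.
#' @param bqreb_items Named list with integer vectors `BP`, `CM`, `R`
#'   partitioning items 1-10.
#' @return Named list of [instrument_spec()] objects.
#' @export
builtin_instruments <- function(pansi_pi_items = c(2L, 6L, 8L, 12L, 13L, 14L),
                                bqreb_items = list(BP = 1:4, CM = 5:7,
                                                   R = 8:10)) {
  stopifnot(length(pansi_pi_items) == 6L, all(pansi_pi_items %in% 1:14))
  stopifnot(setequal(unlist(bqreb_items), 1:10),
            setequal(names(bqreb_items), c("BP", "CM", "R")))
  plain <- function(ids) data.frame(item_id = as.integer(ids),
                                    reversed = FALSE)
  pansi <- instrument_spec(
    "PANSI",
    items = data.frame(item_id = 1:14, min = 1L, max = 5L),
    subscales = list(NSI = plain(setdiff(1:14, pansi_pi_items)),
                     PI = plain(pansi_pi_items))
  )
  apgar <- instrument_spec(
    "APGAR",
    items = data.frame(item_id = 1:5, min = 0L, max = 2L),
    subscales = list(total = plain(1:5)),
    categories = data.frame(
      lo = c(0L, 4L, 7L), hi = c(3L, 6L, 10L),
      label = c("severe dysfunction", "moderate dysfunction",
                "mild dysfunction")
    )
  )
  bssa <- instrument_spec(
    "BSSA-10",
    items = data.frame(item_id = 1:10, min = 1L, max = 6L),
    subscales = list(
      SP = plain(c(1L, 2L, 5L)),
      AE = plain(c(3L, 4L)),
      IP = data.frame(item_id = 6:10, reversed = TRUE)
    ),
    prefix = "BSSA"
  )
  bqreb <- instrument_spec(
    "BQREB",
    items = data.frame(item_id = 1:10, min = 1L, max = 4L),
    subscales = lapply(bqreb_items, plain)
  )
  list(PANSI = pansi, APGAR = apgar, `BSSA-10` = bssa, BQREB = bqreb)
}

#' Attainable score range of a sub-scale
#'
#' Minimum and maximum sum score after reverse coding. Reversal maps an item's
#' response range onto itself, so the bounds are simply the sums of item
#' minima and maxima.
#'
#' @param spec An [instrument_spec()].
#' @param subscale Sub-scale name.
#' @return Integer vector `c(min, max)`.
#' @export
subscale_range <- function(spec, subscale) {
  ss <- spec$subscales[[subscale]]
  if (is.null(ss)) stop(sprintf("unknown sub-scale '%s'", subscale))
  it <- spec$items[match(ss$item_id, spec$items$item_id), ]
  c(sum(it$min), sum(it$max))
}

item_columns <- function(spec) paste0(spec$prefix, "_", spec$items$item_id)

#' Score one sub-scale from item-level responses
#'
#' Sums item responses over the sub-scale's items, after recoding reversed
#' items as `(min + max) - response`. Respondents missing any item of the
#' sub-scale are excluded listwise and receive `NA` (a sum over a partial item
#' set is not comparable to a complete one).
#'
#' @param responses Data frame of item responses, columns named
#'   `<PREFIX>_<item>` (e.g. `PANSI_1`); one respondent per row; `NA` =
#'   missing.
#' @param spec An [instrument_spec()].
#' @param subscale Sub-scale name within `spec`.
#' @return Integer vector, one element per respondent, `NA` where excluded.
#' @export
score_subscale <- function(responses, spec, subscale) {
  ss <- spec$subscales[[subscale]]
  if (is.null(ss)) stop(sprintf("unknown sub-scale '%s'", subscale))
  cols <- paste0(spec$prefix, "_", ss$item_id)
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols)) {
    stop(sprintf("response columns missing: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  it <- spec$items[match(ss$item_id, spec$items$item_id), ]
  x <- as.matrix(responses[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  rev_idx <- which(ss$reversed)
  for (j in rev_idx) {
    x[, j] <- (it$min[j] + it$max[j]) - x[, j]
  }
  out <- as.integer(round(rowSums(x)))
  if (all(is.na(out)) && nrow(responses) > 0L) {
    warning(sprintf("all respondents excluded listwise for sub-scale '%s'",
                    subscale))
  }
  out
}

#' Canonical sub-scale columns of the battery
#'
#' Maps short score-column names to (instrument, sub-scale) pairs, in the
#' order used throughout the package's score tables and correlation matrices.
#'
#' @return Data frame with columns `column`, `instrument`, `subscale`.
#' @export
subscale_columns <- function() {
  data.frame(
    column = c("BSSA_SP", "BSSA_AE", "BSSA_IP", "BQREB_BP", "BQREB_CM",
               "BQREB_R", "APGAR", "PANSI_NSI", "PANSI_PI"),
    instrument = c("BSSA-10", "BSSA-10", "BSSA-10", "BQREB", "BQREB",
                   "BQREB", "APGAR", "PANSI", "PANSI"),
    subscale = c("SP", "AE", "IP", "BP", "CM", "R", "total", "NSI", "PI"),
    stringsAsFactors = FALSE
  )
}

#' Score a full cohort on all nine sub-scales
#'
#' @param responses Data frame of item responses (39 columns `PANSI_1` ...
#'   `BQREB_10`); one respondent per row.
#' @param instruments Named list of specs, defaulting to
#'   [builtin_instruments()].
#' @return Data frame of integer scores with columns `BSSA_SP`, `BSSA_AE`,
#'   `BSSA_IP`, `BQREB_BP`, `BQREB_CM`, `BQREB_R`, `APGAR`, `PANSI_NSI`,
#'   `PANSI_PI`; `NA` where a respondent was excluded listwise for a
#'   sub-scale.
#' @export
score_cohort <- function(responses, instruments = builtin_instruments()) {
  cols <- subscale_columns()
  out <- lapply(seq_len(nrow(cols)), function(i) {
    score_subscale(responses, instruments[[cols$instrument[i]]],
                   cols$subscale[i])
  })
  names(out) <- cols$column
  as.data.frame(out)
}

#' Classify a family APGAR total score
#'
#' Scores 0-3 indicate severe family dysfunction, 4-6 moderate dysfunction
#' and 7-10 mild dysfunction. (The published category list also names a
#' "functional" band, but the three dysfunction intervals already cover the
#' whole 0-10 range, leaving it unreachable; scores 7-10 are therefore
#' labelled mild dysfunction.)
#'
#' @param score Integer vector of APGAR totals in 0-10.
#' @return Character vector of category labels.
#' @export
classify_apgar <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 10)) {
    stop("APGAR scores must lie in 0-10")
  }
  cut(score, breaks = c(-0.5, 3.5, 6.5, 10.5),
      labels = c("severe dysfunction", "moderate dysfunction",
                 "mild dysfunction")) |> as.character()
}

#' Validate item-level responses against an instrument
#'
#' Reports, without modifying the input: cells outside their item's response
#' range, missing cells, and the respondents each sub-scale would exclude
#' listwise.
#'
#' @inheritParams score_subscale
#' @return List with components `out_of_range` (data frame `row`, `column`,
#'   `value`), `missing` (data frame `row`, `column`) and `excluded` (named
#'   list of row indices per sub-scale).
#' @export
validate_responses <- function(responses, spec) {
  cols <- item_columns(spec)
  missing_cols <- setdiff(cols, names(responses))
  if (length(missing_cols)) {
    stop(sprintf("response columns missing: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as.matrix(responses[, cols, drop = FALSE])
  storage.mode(x) <- "double"
  oor <- data.frame(row = integer(), column = character(), value = numeric())
  miss <- data.frame(row = integer(), column = character())
  for (j in seq_along(cols)) {
    v <- x[, j]
    bad <- which(!is.na(v) & (v < spec$items$min[j] | v > spec$items$max[j] |
                                v != round(v)))
    if (length(bad)) {
      oor <- rbind(oor, data.frame(row = bad, column = cols[j],
                                   value = v[bad]))
    }
    na_rows <- which(is.na(v))
    if (length(na_rows)) {
      miss <- rbind(miss, data.frame(row = na_rows, column = cols[j]))
    }
  }
  excluded <- lapply(names(spec$subscales), function(sub) {
    sc <- paste0(spec$prefix, "_", spec$subscales[[sub]]$item_id)
    which(rowSums(is.na(x[, sc, drop = FALSE])) > 0L)
  })
  names(excluded) <- names(spec$subscales)
  list(out_of_range = oor, missing = miss, excluded = excluded)
}

#' Read item-level responses from CSV
#'
#' Expects a header row with columns `<PREFIX>_<item>` (`PANSI_1` ...
#' `PANSI_14`, `APGAR_1` ... `APGAR_5`, `BSSA_1` ... `BSSA_10`, `BQREB_1` ...
#' `BQREB_10`); one respondent per row; empty cells are missing.
#'
#' @param path CSV file path.
#' @return Data frame of integer responses with `NA` for missing cells.
#' @export
read_responses <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write a score table to CSV
#'
#' @param scores Data frame as returned by [score_cohort()].
#' @param path Output CSV path.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
}
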