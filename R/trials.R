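#' Read and write trial tables
#'
#' Trial tables are CSV files (comma-separated, header row, UTF-8, `.`
#' decimal) with one row per retrieval-practice trial and columns
#' `participant`, `session`, `item`, `presentation` (1-based count of
#' this item's presentations), `correct` (logical or 0/1) and `rt`
#' (seconds).  `col_map` renames nonstandard headers, e.g.
#' `c(participant = "subj_id", rt = "latency")`.
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping standard column
#'   names to the names used in the file.
#' @return A tibble with the standard columns; `correct` is logical.
#' @export
read_trials <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(x))
        stop("column `", col_map[[std]], "` not found in ", path,
             call. = FALSE)
      names(x)[names(x) == col_map[[std]]] <- std
    }
  }
  validate_trial_table(x)
}

#' @rdname read_trials
#' @param trials A trial table.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

validate_trial_table <- function(x) {
  needed <- c("participant", "session", "item", "presentation",
              "correct", "rt")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("trial table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  x$correct <- as.logical(x$correct)
  if (anyNA(x$correct)) stop("`correct` must be logical or 0/1",
                             call. = FALSE)
  if (any(x$rt <= 0)) stop("`rt` must be > 0", call. = FALSE)
  if (any(x$presentation < 1))
    stop("`presentation` must be >= 1", call. = FALSE)
  key <- paste(x$participant, x$session, x$item, x$presentation)
  if (anyDuplicated(key))
    stop("(participant, session, item, presentation) must be unique",
         call. = FALSE)
  tibble::as_tibble(x)
}

#' Apply the retrieval-practice preprocessing rules to a trial table
#'
#' Filters a raw trial table in a fixed order: (1) drop the first
#' presentation of every item (the answer is shown on screen, so there
#' is no retrieval); (2) drop trials slower than 30 s (no response
#' within the deadline); (3) drop trials faster than 300 ms (anticipatory
#' responses); then (4) drop every (participant, session) cell left with
#' fewer than 50 trials and (5) drop every remaining cell with fewer
#' than 5 error responses, since with almost no errors the error-response
#' distribution cannot constrain a fit.  The RT rules use strict
#' inequalities, so boundary values 0.3 and 30 s are retained.  The
#' output is independent of the row order of the input.
#'
#' @param trials A trial table (see [read_trials()] for the columns).
#' @return The filtered tibble, with an exclusion report attached as the
#'   `"exclusions"` attribute: a tibble of rows removed per rule, in
#'   application order.  Retrieve it with [exclusion_report()].  An empty
#'   result is returned (with a warning), not an error.
#' @examples
#' trials <- tibble::tibble(
#'   participant = 1, session = 1, item = 1:4, presentation = 2,
#'   correct = c(TRUE, TRUE, FALSE, TRUE), rt = c(0.2, 1, 31, 2))
#' filtered <- filter_trials(trials)
#' exclusion_report(filtered)
#' @export
filter_trials <- function(trials) {
  trials <- validate_trial_table(trials)
  n0 <- nrow(trials)
  counts <- integer(5)

  keep <- trials$presentation > 1
  counts[1] <- sum(!keep)
  trials <- trials[keep, ]

  keep <- trials$rt <= 30
  counts[2] <- sum(!keep)
  trials <- trials[keep, ]

  keep <- trials$rt >= 0.3
  counts[3] <- sum(!keep)
  trials <- trials[keep, ]

  cells <- trials |>
    dplyr::group_by(.data$participant, .data$session) |>
    dplyr::summarise(n = dplyr::n(), n_errors = sum(!.data$correct),
                     .groups = "drop")
  small <- cells[cells$n < 50, c("participant", "session")]
  in_small <- paste(trials$participant, trials$session) %in%
    paste(small$participant, small$session)
  counts[4] <- sum(in_small)
  trials <- trials[!in_small, ]

  few_err <- cells[cells$n >= 50 & cells$n_errors < 5,
                   c("participant", "session")]
  in_few <- paste(trials$participant, trials$session) %in%
    paste(few_err$participant, few_err$session)
  counts[5] <- sum(in_few)
  trials <- trials[!in_few, ]

  report <- tibble::tibble(
    rule = c("first_presentation", "rt_above_30s", "rt_below_300ms",
             "cell_under_50_trials", "cell_under_5_errors"),
    rows_removed = counts)
  stopifnot(sum(counts) == n0 - nrow(trials))
  if (nrow(trials) == 0)
    warning("no trials survive the filters", call. = FALSE)
  attr(trials, "exclusions") <- report
  trials
}

#' @rdname filter_trials
#' @export
exclusion_report <- function(trials) {
  rep <- attr(trials, "exclusions")
  if (is.null(rep))
    stop("no exclusion report attached; run filter_trials() first",
         call. = FALSE)
  rep
}

#' Fit the race model independently to every participant-session cell
#'
#' Runs [fit_mle()] on each (participant, session) cell of an (already
#' filtered) trial table and returns a long table of ACT-R parameter
#' estimates.  Cells are fitted independently with the same seed, so
#' results do not depend on cell order and cells with identical data
#' yield identical estimates.  A cell whose fit fails is recorded in
#' the `"failed_cells"` attribute and skipped.
#'
#' @param trials A filtered trial table.
#' @param control A [fit_control()] object.
#' @param seed Integer seed for the per-cell restart schedules.
#' @return A long tibble with columns `participant`, `session`,
#'   `n_trials`, `nll`, `n_converged`, `term`, `estimate` (seven rows
#'   per cell, one per ACT-R parameter).
#' @export
fit_sessions <- function(trials, control = fit_control(), seed = 1) {
  trials <- validate_trial_table(trials)
  if (nrow(trials) == 0) stop("`trials` must be nonempty", call. = FALSE)
  cells <- dplyr::distinct(trials, .data$participant, .data$session) |>
    dplyr::arrange(.data$participant, .data$session)
  failed <- list()
  rows <- purrr::map(seq_len(nrow(cells)), function(i) {
    cell <- trials[trials$participant == cells$participant[i] &
                     trials$session == cells$session[i], ]
    fit <- tryCatch(
      fit_mle(tibble::tibble(response = cell$correct, rt = cell$rt),
              control, seed = seed),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failed[[length(failed) + 1L]] <<- tibble::tibble(
        participant = cells$participant[i], session = cells$session[i],
        message = conditionMessage(fit))
      return(NULL)
    }
    est <- tidy(fit)
    tibble::tibble(participant = cells$participant[i],
                   session = cells$session[i],
                   n_trials = nrow(cell), nll = fit$nll,
                   n_converged = fit$n_converged,
                   term = est$term, estimate = est$estimate)
  })
  out <- dplyr::bind_rows(rows)
  failed <- dplyr::bind_rows(failed)
  if (nrow(failed))
    warning(nrow(failed), " cell(s) failed to fit and were skipped",
            call. = FALSE)
  attr(out, "failed_cells") <- failed
  out
}
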