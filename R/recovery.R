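#' Run a parameter-recovery simulation study
#'
#' Samples simulated participants from the population distributions of
#' [sample_participant_params()], simulates each at every dataset size in
#' `trial_counts` with the ACT-R shared-distance race, fits each dataset
#' by multi-start maximum likelihood ([fit_mle()]), maps the estimates
#' back to ACT-R parameters, and records per-cell recovery errors.
#'
#' All randomness derives from `seed`: a table of per-cell simulation and
#' fitting seeds is drawn once from the master seed, so results are
#' independent of evaluation order and the study is exactly
#' reproducible.  Cells whose fit fails are flagged and excluded from
#' summaries.
#'
#' The default grid (10 participants, 100/250/1000 trials, 50 restarts)
#' is a desk-scale study that runs in minutes; pass larger values (e.g.
#' 25 participants, up to 50,000 trials, 250 restarts) for a full-scale
#' study.
#'
#' @param n_participants Number of simulated participants (>= 2; at
#'   least 10 recommended for stable correlations).
#' @param trial_counts Integer vector of dataset sizes (trials per
#'   participant).
#' @param control A [fit_control()] object used for every cell.
#' @param seed Master seed.
#' @return An object of class `recovery_result`: a list with `cells` (a
#'   long tibble: `participant`, `n_trials`, `term`, `true`, `estimate`,
#'   `abs_error`), `params` (the sampled participant parameters),
#'   `failures` (tibble of failed cells), and the study configuration.
#' @seealso [summarize_recovery()], [autoplot.recovery_result()]
#' @export
run_recovery <- function(n_participants = 10,
                         trial_counts = c(100, 250, 1000),
                         control = fit_control(n_restarts = 50),
                         seed = 1) {
  if (n_participants < 2)
    stop("`n_participants` must be >= 2 (correlations need >= 2 points)",
         call. = FALSE)
  if (any(trial_counts < 1))
    stop("all `trial_counts` must be >= 1", call. = FALSE)
  trial_counts <- sort(unique(as.integer(trial_counts)))
  n_cells <- n_participants * length(trial_counts)
  seeds <- withr::with_seed(as.integer(seed),
    sample.int(.Machine$integer.max - 1L, 1L + 2L * n_cells))
  params <- sample_participant_params(n_participants, seed = seeds[1])
  grid <- tidyr::expand_grid(participant = seq_len(n_participants),
                             n_trials = trial_counts)

  failures <- list()
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    pid <- grid$participant[i]
    nt <- grid$n_trials[i]
    truth <- as_actr_params(params[params$participant == pid, -1])
    trials <- simulate_trials(truth, nt, seed = seeds[2 * i])
    fit <- tryCatch(
      suppressWarnings(fit_mle(trials, control, seed = seeds[2 * i + 1])),
      error = function(e) e)
    if (inherits(fit, "error")) {
      failures[[length(failures) + 1L]] <<- tibble::tibble(
        participant = pid, n_trials = nt,
        message = conditionMessage(fit))
      return(NULL)
    }
    truth_td <- tidy(truth)
    est_td <- tidy(fit)
    tibble::tibble(participant = pid, n_trials = nt,
                   term = truth_td$term, true = truth_td$estimate,
                   estimate = est_td$estimate[match(truth_td$term,
                                                    est_td$term)]) |>
      dplyr::mutate(abs_error = abs(.data$estimate - .data$true))
  })
  failures <- dplyr::bind_rows(failures)
  if (nrow(failures))
    message(nrow(failures), " recovery cell(s) failed to fit; ",
            "excluded from summaries")
  structure(list(cells = dplyr::bind_rows(rows), params = params,
                 failures = failures, n_participants = n_participants,
                 trial_counts = trial_counts, control = control,
                 seed = seed),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Parameter-recovery study: ", x$n_participants, " participants x {",
      paste(x$trial_counts, collapse = ", "), "} trials, ",
      x$control$n_restarts, " restarts\n", sep = "")
  if (nrow(x$failures)) cat("  failed cells:", nrow(x$failures), "\n")
  print(summarize_recovery(x)$summary, n = 20)
  invisible(x)
}

#' Tidy the per-cell recovery results
#'
#' @param x A `recovery_result` object.
#' @param ... Unused.
#' @return The long per-cell tibble (`participant`, `n_trials`, `term`,
#'   `true`, `estimate`, `abs_error`).
#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) x$cells

#' Summarize a recovery study
#'
#' Aggregates the per-cell recovery results into a tidy long table of
#' per-parameter mean absolute error and Pearson correlation between the
#' original and recovered values at each dataset size, appends
#' mean-across-parameters rows (`term = "(mean)"`), and computes the
#' correlation matrix between pairs of recovered parameters at the
#' largest dataset size (diagnosing parameter trade-offs).  Correlations
#' are computed on the raw parameter scales.  Parameters held fixed
#' during fitting (`sigma_c`) have no variance, so their recovery
#' correlation is `NA` and they are excluded from the `"(mean)"` rows
#' and from the trade-off matrix.
#'
#' @param result A `recovery_result` from [run_recovery()].
#' @param out_dir Optional directory; when given, writes
#'   `params_original.csv`, `params_recovered.csv`, `summary.csv` and
#'   `correlations.csv` there.
#' @return A list of class `recovery_summary` with `summary` (tibble:
#'   `term`, `n_trials`, `mean_abs_error`, `pearson_r`) and
#'   `correlations` (named matrix of recovered-parameter correlations at
#'   the largest dataset size).
#' @export
summarize_recovery <- function(result, out_dir = NULL) {
  stopifnot(inherits(result, "recovery_result"))
  cells <- result$cells
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }
  per_term <- cells |>
    dplyr::group_by(.data$term, .data$n_trials) |>
    dplyr::summarise(mean_abs_error = mean(.data$abs_error),
                     pearson_r = safe_cor(.data$true, .data$estimate),
                     .groups = "drop")
  overall <- per_term |>
    dplyr::filter(.data$term != "sigma_c") |>
    dplyr::group_by(.data$n_trials) |>
    dplyr::summarise(mean_abs_error = mean(.data$mean_abs_error),
                     pearson_r = mean(.data$pearson_r, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(term = "(mean)", .before = 1)
  summary <- dplyr::bind_rows(per_term, overall) |>
    dplyr::arrange(.data$n_trials, .data$term)

  nt_max <- max(result$trial_counts)
  wide <- cells |>
    dplyr::filter(.data$n_trials == nt_max, .data$term != "sigma_c") |>
    dplyr::select("participant", "term", "estimate") |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
  correlations <- stats::cor(as.matrix(wide[, -1]))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(result$params,
                     file.path(out_dir, "params_original.csv"))
    recovered <- cells |>
      dplyr::select("participant", "n_trials", "term", "estimate") |>
      tidyr::pivot_wider(names_from = "term", values_from = "estimate")
    readr::write_csv(recovered,
                     file.path(out_dir, "params_recovered.csv"))
    readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    cor_df <- tibble::as_tibble(correlations, rownames = "term")
    readr::write_csv(cor_df, file.path(out_dir, "correlations.csv"))
  }
  structure(list(summary = summary, correlations = correlations,
                 largest_n_trials = nt_max),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  print(x$summary, n = Inf)
  cat("\nRecovered-parameter correlations at",
      x$largest_n_trials, "trials:\n")
  print(round(x$correlations, 3))
  invisible(x)
}
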