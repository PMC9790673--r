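#' Simulate retrieval trials from the ACT-R shared-distance race
#'
#' Each trial draws one latency factor `F ~ Uniform[F_mean - F_range/2,
#' F_mean + F_range/2]` that is shared by both chunks, and an independent
#' activation `a_i ~ Normal(mu_i, sigma_i)` per chunk.  Chunk `i` finishes
#' at `F * exp(-a_i) + t_er`; the chunk with the smaller finishing time
#' determines the response and its finishing time is the response time.
#' Exact ties (possible only in deterministic limits such as
#' `sigma_c = sigma_f = 0` with `mu_c = mu_f`) are resolved in favour of
#' the correct chunk.
#'
#' @param p An [actr_params()] object.  `sigma = 0` and `F_range = 0` are
#'   allowed as deterministic limits.
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer seed.  When given, the simulation is run
#'   with its own RNG stream and the caller's RNG state is untouched;
#'   identical seeds give identical output.
#' @param trace If `TRUE`, include the latent draws (`F_j`, `a_c`, `a_f`)
#'   as extra columns.
#' @param participant,session Identifier columns copied into the output.
#'
#' @return A tibble with columns `participant`, `session`, `trial`
#'   (0-based), `response` (`"correct"`/`"incorrect"`), `rt` (seconds),
#'   plus latent columns when `trace = TRUE`.
#' @examples
#' p <- actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1.5,
#'                  F_mean = 1, F_range = 0.1, t_er = 0.75)
#' simulate_trials(p, 5, seed = 1)
#' @export
simulate_trials <- function(p, n_trials, seed = NULL, trace = FALSE,
                            participant = "p1", session = 1L) {
  stopifnot(inherits(p, "actr_params"))
  validate_actr_params(p)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  n <- as.integer(n_trials)
  draw <- function() {
    aF <- p$F_mean - p$F_range / 2
    bF <- p$F_mean + p$F_range / 2
    Fj <- stats::runif(n, aF, bF)
    a_c <- stats::rnorm(n, p$mu_c, p$sigma_c)
    a_f <- stats::rnorm(n, p$mu_f, p$sigma_f)
    rt_c <- Fj * exp(-a_c) + p$t_er
    rt_f <- Fj * exp(-a_f) + p$t_er
    correct_wins <- rt_c <= rt_f   # ties go to the correct chunk
    out <- tibble::tibble(
      participant = participant,
      session = as.integer(session),
      trial = seq_len(n) - 1L,
      response = ifelse(correct_wins, "correct", "incorrect"),
      rt = ifelse(correct_wins, rt_c, rt_f))
    if (trace) {
      out$F_j <- Fj
      out$a_c <- a_c
      out$a_f <- a_f
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate trials from the standard independent-start LBA
#'
#' The standard LBA race: each accumulator draws its own start point
#' `k_i ~ Uniform[0, A]` and a drift `v_i` from its lognormal distribution,
#' finishing at `(d - k_i) / v_i + t0`.  The winner is the accumulator
#' with the minimal finishing time; ties go to the accumulator labelled
#' `"correct"` if present, otherwise to the first accumulator.
#'
#' With `A = 0` this coincides in law with [simulate_trials()] at
#' `F_range = 0`: both collapse to the lognormal race.
#'
#' @param q An [lba_params()] object (any number of accumulators).
#' @inheritParams simulate_trials
#' @return A tibble with columns `participant`, `session`, `trial`,
#'   `response`, `rt`.
#' @export
simulate_lba_trials <- function(q, n_trials, seed = NULL,
                                participant = "p1", session = 1L) {
  stopifnot(inherits(q, "lba_params"))
  validate_lba_params(q)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  n <- as.integer(n_trials)
  n_acc <- length(q$labels)
  # put the correct-labelled accumulator first so which.min tie-breaks to it
  ord <- order(q$labels != "correct")
  draw <- function() {
    t_fin <- matrix(NA_real_, n, n_acc)
    for (j in seq_len(n_acc)) {
      i <- ord[j]
      k <- stats::runif(n, 0, q$A)
      v <- stats::rlnorm(n, q$drift_logmean[i], q$drift_logsd[i])
      t_fin[, j] <- (q$d - k) / v + q$t0
    }
    win <- max.col(-t_fin, ties.method = "first")
    tibble::tibble(
      participant = participant,
      session = as.integer(session),
      trial = seq_len(n) - 1L,
      response = q$labels[ord][win],
      rt = t_fin[cbind(seq_len(n), win)])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rtruncnorm_sign <- function(n, mean, sd, positive) {
  # rejection sampling; acceptance probability >= 0.5 for the
  # distributions used here, so the loop terminates quickly
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    keep <- if (positive) x > 0 else x < 0
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}

#' Sample plausible simulated-participant parameter sets
#'
#' Draws ACT-R memory parameters from the truncated-normal population
#' distributions used in the recovery study: `mu_c ~ N(-0.5, 0.5)` and
#' `mu_f ~ N(-1.5, 0.5)` truncated to negative values; `sigma_f ~
#' N(1.5, 0.5)`, `F_mean ~ N(1, 0.5)`, `F_range ~ N(0.1, 0.05)` and
#' `t_er ~ N(0.75, 0.5)` truncated to positive values; `sigma_c` is
#' identically 1 (the scale convention).  Draws violating
#' `F_mean - F_range/2 > 0` are redrawn.  Truncation uses rejection
#' sampling, which is exact.
#'
#' @param n Number of participants to sample.
#' @param seed Optional integer seed (caller's RNG state is preserved).
#' @return A tibble with `n` rows and columns `participant`, `mu_c`,
#'   `mu_f`, `sigma_c`, `sigma_f`, `F_mean`, `F_range`, `t_er`.  Use
#'   [as_actr_params()] on a row to obtain an [actr_params()] object.
#' @examples
#' sample_participant_params(3, seed = 42)
#' @export
sample_participant_params <- function(n = 1, seed = NULL) {
  draw <- function() {
    mu_c <- rtruncnorm_sign(n, -0.5, 0.5, positive = FALSE)
    mu_f <- rtruncnorm_sign(n, -1.5, 0.5, positive = FALSE)
    sigma_f <- rtruncnorm_sign(n, 1.5, 0.5, positive = TRUE)
    F_mean <- rtruncnorm_sign(n, 1, 0.5, positive = TRUE)
    F_range <- rtruncnorm_sign(n, 0.1, 0.05, positive = TRUE)
    t_er <- rtruncnorm_sign(n, 0.75, 0.5, positive = TRUE)
    bad <- which(F_mean - F_range / 2 <= 0)
    while (length(bad)) {
      F_mean[bad] <- rtruncnorm_sign(length(bad), 1, 0.5, positive = TRUE)
      F_range[bad] <- rtruncnorm_sign(length(bad), 0.1, 0.05,
                                      positive = TRUE)
      bad <- bad[F_mean[bad] - F_range[bad] / 2 <= 0]
    }
    tibble::tibble(participant = seq_len(n),
                   mu_c = mu_c, mu_f = mu_f,
                   sigma_c = 1, sigma_f = sigma_f,
                   F_mean = F_mean, F_range = F_range, t_er = t_er)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
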