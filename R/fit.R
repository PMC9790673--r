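#' Control settings for maximum-likelihood fitting
#'
#' @param n_restarts Number of random restarts of the local optimizer;
#'   the fit keeps the restart with the lowest negative log-likelihood.
#' @param variant Race density used as the objective.  The default is the
#'   standard independent-start LBA density; the shared-distance density
#'   is also available.
#' @param seed Optional integer seed making the whole fit (start values
#'   included) reproducible.
#' @param floor Density floor inside the likelihood (see
#'   [neg_log_likelihood()]).
#' @param iter_max,eval_max,rel_tol Iteration / evaluation caps and
#'   relative convergence tolerance passed to [stats::nlminb()].
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_restarts = 250,
                        variant = c("independent_start", "shared_distance"),
                        seed = NULL, floor = 1e-10,
                        iter_max = 400, eval_max = 1000, rel_tol = 1e-10) {
  variant <- match.arg(variant)
  if (n_restarts < 1) stop("`n_restarts` must be >= 1", call. = FALSE)
  if (floor <= 0 || iter_max < 1 || eval_max < 1 || rel_tol <= 0)
    stop("tolerances and caps must be positive", call. = FALSE)
  structure(list(n_restarts = as.integer(n_restarts), variant = variant,
                 seed = seed, floor = floor,
                 iter_max = as.integer(iter_max),
                 eval_max = as.integer(eval_max), rel_tol = rel_tol),
            class = "fit_control")
}

#' Draw a random starting point for the optimizer
#'
#' Start values are drawn from wide uniform ranges that bracket the
#' plausible parameter region by a comfortable margin: `t0 ~ Uniform(0,
#' 0.9 * min(rt))`, start range `A ~ Uniform(0.01, 1)`, boundary gap
#' `d - A ~ Uniform(0.2, 3)`, drift log-means `~ Uniform(-3, 1)`,
#' `sigma_f ~ Uniform(0.25, 3)`; `sigma_c` is fixed at 1.  Every draw
#' satisfies the [lba_params()] invariants.  Uses the caller's RNG
#' stream ([fit_mle()] seeds it once for the whole restart schedule).
#'
#' @param data Trial table with an `rt` column (used to cap `t0`).
#' @return An [lba_params()] object.
#' @export
generate_start <- function(data) {
  if (nrow(data) == 0) stop("`data` must be nonempty", call. = FALSE)
  min_rt <- min(data$rt)
  A <- stats::runif(1, 0.01, 1)
  lba_params(d = A + stats::runif(1, 0.2, 3), A = A,
             drift_logmean = stats::runif(2, -3, 1),
             drift_logsd = c(1, stats::runif(1, 0.25, 3)),
             t0 = stats::runif(1, 0, 0.9 * min_rt),
             labels = c("correct", "incorrect"))
}

# unconstrained <-> natural parameter transforms.  theta is
# (qlogis(t0/cap), log A, log(d - A), mu_c, mu_f, log sigma_f); the
# transform keeps every optimizer iterate inside 0 < A < d, t0 < cap.
.theta_from_lba <- function(q, cap) {
  t0 <- min(q$t0, 0.9999 * cap)
  c(stats::qlogis(max(t0 / cap, 1e-8)), log(q$A), log(q$d - q$A),
    q$drift_logmean[1], q$drift_logmean[2], log(q$drift_logsd[2]))
}

.lba_from_theta <- function(theta, cap) {
  A <- exp(theta[2])
  lba_params(d = A + exp(theta[3]), A = A,
             drift_logmean = theta[4:5],
             drift_logsd = c(1, exp(theta[6])),
             t0 = cap * stats::plogis(theta[1]),
             labels = c("correct", "incorrect"))
}

.theta_lower <- c(-15, log(1e-5), log(1e-3), -10, -10, log(0.05))
.theta_upper <- c(15, log(10), log(50), 5, 5, log(10))

#' Fit the lognormal-drift LBA to choice/RT data by maximum likelihood
#'
#' Minimizes the negative log-likelihood of the race density with
#' [stats::nlminb()] (a quasi-Newton box-constrained method with
#' numerical derivatives) from `n_restarts` random starting points and
#' keeps the restart with the best likelihood.  Optimization runs on a
#' transformed scale that enforces `0 < A < d` and
#' `0 < t0 < 0.999 * min(rt)` by construction; beyond the `t0` cap the
#' density of the fastest response is zero (floored), a flat region local
#' optimizers handle poorly.  The activation-noise SD of the correct
#' accumulator is fixed at 1 — with it free, multiplying all log-scale
#' parameters by a constant leaves the likelihood unchanged, so the
#' model is identified only up to scale.
#'
#' Restarts that do not report convergence still compete on likelihood;
#' only the best objective value is kept.  The fitted parameters are
#' mapped back to ACT-R memory parameters via [lba_to_actr()].
#'
#' @param data Trial table with columns `response`
#'   (`"correct"`/`"incorrect"`, logical, or 0/1 correctness) and `rt`
#'   (seconds).
#' @param control A [fit_control()] object.
#' @param seed Integer seed for the restart schedule; overrides
#'   `control$seed`.  With a seed the fit is fully reproducible.
#' @return An object of class `actrlba_fit` with elements `lba`
#'   ([lba_params()] estimate), `actr` (mapped [actr_params()]), `nll`,
#'   `n_trials`, `restarts` (per-restart tibble of objective values and
#'   convergence codes), `n_converged`, `best_start_index`,
#'   `single_response` (flag: only one response label observed, so the
#'   error-response distribution is unconstrained), `variant`, and the
#'   (normalized) `data`.
#' @seealso [tidy.actrlba_fit()], [glance.actrlba_fit()],
#'   [autoplot.actrlba_fit()]
#' @examples
#' p <- actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1.5,
#'                  F_mean = 1, F_range = 0.1, t_er = 0.75)
#' trials <- simulate_trials(p, 300, seed = 1)
#' fit <- fit_mle(trials, fit_control(n_restarts = 10), seed = 2)
#' tidy(fit)
#' @export
fit_mle <- function(data, control = fit_control(), seed = control$seed) {
  stopifnot(inherits(control, "fit_control"))
  data <- normalize_trials(data, c("correct", "incorrect"))
  if (nrow(data) == 0) stop("`data` must be nonempty", call. = FALSE)
  single_response <- length(unique(data$response)) < 2
  if (single_response)
    warning("only one response label present; the other accumulator's ",
            "parameters are unconstrained by the data", call. = FALSE)

  cap <- 0.999 * min(data$rt)
  rt_c <- data$rt[data$response == "correct"]
  rt_f <- data$rt[data$response == "incorrect"]
  variant <- control$variant
  floor <- control$floor

  objective <- function(theta) {
    t0 <- cap * stats::plogis(theta[1])
    A <- exp(theta[2])
    d <- A + exp(theta[3])
    ml <- theta[4:5]
    sl <- c(1, exp(theta[6]))
    nll <- 0
    if (length(rt_c))
      nll <- nll - sum(log(pmax(.race_density(rt_c, 1L, d, A, t0, ml, sl,
                                              variant), floor)))
    if (length(rt_f))
      nll <- nll - sum(log(pmax(.race_density(rt_f, 2L, d, A, t0, ml, sl,
                                              variant), floor)))
    if (!is.finite(nll)) 1e10 else nll
  }

  starts <- if (is.null(seed)) {
    replicate(control$n_restarts, generate_start(data), simplify = FALSE)
  } else {
    withr::with_seed(as.integer(seed),
      replicate(control$n_restarts, generate_start(data), simplify = FALSE))
  }

  runs <- purrr::map(starts, function(s0) {
    opt <- stats::nlminb(.theta_from_lba(s0, cap), objective,
                         lower = .theta_lower, upper = .theta_upper,
                         control = list(iter.max = control$iter_max,
                                        eval.max = control$eval_max,
                                        rel.tol = control$rel_tol))
    list(theta = opt$par, nll = opt$objective,
         converged = opt$convergence == 0)
  })

  trace <- tibble::tibble(
    start_index = seq_along(runs),
    nll = purrr::map_dbl(runs, "nll"),
    converged = purrr::map_lgl(runs, "converged"))
  if (all(!is.finite(trace$nll)))
    stop("optimization failed from every starting point", call. = FALSE)
  best <- which.min(trace$nll)
  lba <- .lba_from_theta(runs[[best]]$theta, cap)

  structure(list(
    lba = lba,
    actr = lba_to_actr(lba),
    nll = trace$nll[best],
    n_trials = nrow(data),
    restarts = trace,
    n_converged = sum(trace$converged),
    best_start_index = best,
    single_response = single_response,
    variant = variant,
    control = control,
    data = data), class = "actrlba_fit")
}

#' Extract the ACT-R parameters from a fit
#'
#' Pure relabelling: applies [lba_to_actr()] to the maximum-likelihood
#' LBA estimate.
#'
#' @param fit An `actrlba_fit` object.
#' @return An [actr_params()] object.
#' @export
fit_to_actr <- function(fit) {
  stopifnot(inherits(fit, "actrlba_fit"))
  lba_to_actr(fit$lba)
}

#' @export
print.actrlba_fit <- function(x, ...) {
  cat("Lognormal-drift LBA fit (", x$variant, " density)\n", sep = "")
  cat("  trials: ", x$n_trials, ",  NLL: ", format(x$nll, digits = 8),
      ",  restarts converged: ", x$n_converged, "/",
      nrow(x$restarts), "\n", sep = "")
  if (x$single_response)
    cat("  ! only one response label observed\n")
  cat("ACT-R parameters:\n")
  print(x$actr)
  invisible(x)
}

#' Tidy and one-line summaries of a fit
#'
#' `tidy()` returns the parameter estimates, on the ACT-R scale by
#' default or the LBA scale; `glance()` returns a one-row tibble of fit
#' metadata.
#'
#' @param x An `actrlba_fit` object.
#' @param space `"actr"` or `"lba"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy actrlba_fit
#' @export
tidy.actrlba_fit <- function(x, space = c("actr", "lba"), ...) {
  space <- match.arg(space)
  if (space == "actr") tidy(x$actr) else tidy(x$lba)
}

#' @rdname tidy.actrlba_fit
#' @method glance actrlba_fit
#' @export
glance.actrlba_fit <- function(x, ...) {
  tibble::tibble(nll = x$nll, n_trials = x$n_trials,
                 n_restarts = nrow(x$restarts),
                 n_converged = x$n_converged,
                 best_start_index = x$best_start_index,
                 variant = x$variant,
                 single_response = x$single_response)
}
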