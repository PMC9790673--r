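#' Partial expectation of a lognormal variable
#'
#' Computes `E[v * 1{lo <= v <= hi}]` for `v ~ Lognormal(meanlog, sdlog)`:
#' `exp(meanlog + sdlog^2/2) * (pnorm((log(hi) - meanlog - sdlog^2)/sdlog)
#' - pnorm((log(lo) - meanlog - sdlog^2)/sdlog))`, with `log(0) = -Inf`
#' and `log(Inf) = Inf`.  This is the building block of the closed-form
#' accumulator densities: conditional on a drift `v`, the finishing time
#' is uniform with height proportional to `v`, so marginalizing the drift
#' reduces to truncated first moments.
#'
#' @param lo,hi Truncation bounds, `0 <= lo <= hi` (`Inf` allowed).
#'   Vectors are recycled against each other.
#' @param meanlog,sdlog Log-scale location and spread, `sdlog > 0`.
#' @return Nonnegative numeric vector.
#' @examples
#' lnorm_partial_expectation(0, Inf, 0.3, 1)  # full mean exp(0.3 + 1/2)
#' @export
lnorm_partial_expectation <- function(lo, hi, meanlog, sdlog) {
  if (any(lo < 0, na.rm = TRUE)) stop("`lo` must be >= 0", call. = FALSE)
  if (any(lo > hi, na.rm = TRUE)) stop("`lo` must be <= `hi`", call. = FALSE)
  exp(meanlog + sdlog^2 / 2) *
    (stats::pnorm((log(hi) - meanlog - sdlog^2) / sdlog) -
       stats::pnorm((log(lo) - meanlog - sdlog^2) / sdlog))
}

# threshold below which the exact lognormal-race (A -> 0) limit replaces
# the 1/A closed forms, avoiding a 0/0 form
.A_EPS <- 1e-6

# Gauss-Legendre nodes/weights on [0, 1], cached per order (the
# quadrature sits on the likelihood hot path)
.gl_env <- new.env(parent = emptyenv())
.gl_unit <- function(order) {
  key <- as.character(order)
  if (is.null(.gl_env[[key]])) {
    gl <- pracma::gaussLegendre(order, 0, 1)
    .gl_env[[key]] <- list(x = gl$x, w = gl$w)
  }
  .gl_env[[key]]
}

.acc_pdf <- function(t, d, A, t0, meanlog, sdlog) {
  s <- t - t0
  out <- numeric(length(s))
  pos <- which(s > 0)
  if (!length(pos)) return(out)
  sp <- s[pos]
  if (A < .A_EPS) {
    out[pos] <- stats::dlnorm(sp, log(d) - meanlog, sdlog)
  } else {
    out[pos] <- lnorm_partial_expectation((d - A) / sp, d / sp,
                                          meanlog, sdlog) / A
  }
  out
}

.acc_cdf <- function(t, d, A, t0, meanlog, sdlog) {
  s <- t - t0
  out <- numeric(length(s))
  pos <- which(s > 0)
  if (!length(pos)) return(out)
  sp <- s[pos]
  if (A < .A_EPS) {
    out[pos] <- stats::plnorm(sp, log(d) - meanlog, sdlog)
  } else {
    zU <- (log(d / sp) - meanlog) / sdlog
    zL <- (log((d - A) / sp) - meanlog) / sdlog
    pe <- lnorm_partial_expectation((d - A) / sp, d / sp, meanlog, sdlog)
    out[pos] <- (sp * pe -
                   (d - A) * (stats::pnorm(zU) - stats::pnorm(zL))) / A +
      stats::pnorm(zU, lower.tail = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

#' Single-accumulator finishing-time density and distribution
#'
#' Closed forms for the first-passage time `T = (d - k)/v + t0` of one
#' lognormal-drift linear ballistic accumulator, with start point
#' `k ~ Uniform[0, A]` and drift `v ~ Lognormal(meanlog, sdlog)`.
#' Conditional on `v`, `T - t0` is uniform on `[(d-A)/v, d/v]` with
#' density `v/A`, so for `s = t - t0 > 0` the density is `(1/A) * E[v *
#' 1{(d-A)/s <= v <= d/s}]` and the distribution function follows from
#' one further truncated moment.  Both are 0 for `t <= t0`; the
#' distribution tends to 1 as `t` grows because lognormal drifts are
#' strictly positive.  For `A` below `1e-6` the exact lognormal-race
#' limit is used (`log(T - t0) ~ Normal(log(d) - meanlog, sdlog)`).
#'
#' @param t Vector of response times (seconds).
#' @param q An [lba_params()] object; `drift_logsd` must be positive for
#'   the selected accumulator.
#' @param acc Accumulator selector: an index or a label in `q$labels`.
#' @return `dlba_acc()` the density (per second); `plba_acc()` the
#'   distribution function.
#' @examples
#' q <- lba_params(d = 1.05, A = 0.1, drift_logmean = c(-0.5, -1.5),
#'                 drift_logsd = c(1, 1.5), t0 = 0.75)
#' dlba_acc(c(1, 2, 4), q, "correct")
#' @export
dlba_acc <- function(t, q, acc = 1) {
  stopifnot(inherits(q, "lba_params"))
  i <- .acc_index(q, acc)
  if (q$drift_logsd[i] <= 0)
    stop("`drift_logsd` must be > 0 for density evaluation", call. = FALSE)
  .acc_pdf(t, q$d, q$A, q$t0, q$drift_logmean[i], q$drift_logsd[i])
}

#' @rdname dlba_acc
#' @export
plba_acc <- function(t, q, acc = 1) {
  stopifnot(inherits(q, "lba_params"))
  i <- .acc_index(q, acc)
  if (q$drift_logsd[i] <= 0)
    stop("`drift_logsd` must be > 0 for density evaluation", call. = FALSE)
  .acc_cdf(t, q$d, q$A, q$t0, q$drift_logmean[i], q$drift_logsd[i])
}

.acc_index <- function(q, acc) {
  if (is.character(acc)) {
    i <- match(acc, q$labels)
    if (is.na(i)) stop("unknown accumulator label: ", acc, call. = FALSE)
    i
  } else {
    if (acc < 1 || acc > length(q$labels))
      stop("accumulator index out of range", call. = FALSE)
    as.integer(acc)
  }
}

# Defective race density on raw numeric parameters (hot path of the
# likelihood; `widx` is the winning accumulator's index).
# variant: "independent_start" or "shared_distance".
.race_density <- function(t, widx, d, A, t0, meanlog, sdlog, variant,
                          gl_order = 64L) {
  n_acc <- length(meanlog)
  others <- setdiff(seq_len(n_acc), widx)
  if (variant == "independent_start") {
    # f_w(t) * prod_j S_j(t); survivals computed in log space so products
    # of many small survivals do not underflow prematurely
    logf <- log(.acc_pdf(t, d, A, t0, meanlog[widx], sdlog[widx]))
    for (j in others) {
      logf <- logf +
        log1p(-.acc_cdf(t, d, A, t0, meanlog[j], sdlog[j]))
    }
    out <- exp(logf)
    out[!is.finite(out)] <- 0
    out
  } else if (variant == "shared_distance") {
    s <- t - t0
    out <- numeric(length(s))
    pos <- which(s > 0)
    if (!length(pos)) return(out)
    sp <- s[pos]
    cond_density <- function(u) {
      g <- stats::dlnorm(sp, log(u) - meanlog[widx], sdlog[widx])
      for (j in others) {
        g <- g * stats::plnorm(sp, log(u) - meanlog[j], sdlog[j],
                               lower.tail = FALSE)
      }
      g
    }
    if (A < .A_EPS) {
      out[pos] <- cond_density(d)
    } else {
      gl <- .gl_unit(gl_order)
      u <- (d - A) + A * gl$x   # weights absorb the 1/A average
      acc <- numeric(length(sp))
      for (k in seq_len(gl_order)) {
        acc <- acc + gl$w[k] * cond_density(u[k])
      }
      out[pos] <- acc
    }
    out
  } else {
    stop("unknown variant: ", variant, call. = FALSE)
  }
}

#' Defective race density of the lognormal-drift LBA
#'
#' Joint density that the accumulator labelled `choice` finishes at time
#' `t` *and* finishes before every other accumulator.  Two race variants
#' are available:
#'
#' * `"independent_start"` — the standard LBA: each accumulator draws its
#'   own start point, so the defective density is the winning
#'   accumulator's density times the product of the others' survival
#'   functions.
#' * `"shared_distance"` — the ACT-R retrieval race: one distance draw
#'   `u ~ Uniform[d - A, d]` is shared by all accumulators, so finishing
#'   times are conditionally independent shifted lognormals given `u`
#'   (`log(T_i - t0) ~ Normal(log(u) - meanlog_i, sdlog_i)`); the
#'   conditional race density is averaged over `u` with 64-point
#'   Gauss-Legendre quadrature.
#'
#' Summed over choices and integrated over `t`, both variants integrate
#' to 1.  For `A` below `1e-6` both collapse to the same lognormal race.
#'
#' @inheritParams dlba_acc
#' @param choice Label (or index) of the responding accumulator.
#' @param variant `"independent_start"` or `"shared_distance"`.
#' @return Numeric vector of defective densities at `t`.
#' @examples
#' q <- lba_params(d = 1.05, A = 0.1, drift_logmean = c(-0.5, -1.5),
#'                 drift_logsd = c(1, 1.5), t0 = 0.75)
#' drace(c(1, 2, 4), "correct", q)
#' drace(c(1, 2, 4), "correct", q, variant = "shared_distance")
#' @export
drace <- function(t, choice, q,
                  variant = c("independent_start", "shared_distance")) {
  stopifnot(inherits(q, "lba_params"))
  validate_lba_params(q)
  variant <- match.arg(variant)
  if (any(q$drift_logsd <= 0))
    stop("`drift_logsd` must be > 0 for density evaluation", call. = FALSE)
  widx <- .acc_index(q, choice)
  .race_density(t, widx, q$d, q$A, q$t0, q$drift_logmean, q$drift_logsd,
                variant)
}

#' Negative log-likelihood of a trial table under the race model
#'
#' Sums `-log(max(drace(rt_i, response_i), floor))` over trials.  The
#' density floor keeps the objective finite everywhere during
#' optimization (e.g. when a candidate `t0` exceeds an observed RT); it
#' is far below any density value attained near an optimum.
#'
#' @param data A data frame with columns `response` (labels matching
#'   `q$labels`, or logical/0-1 correctness for a two-accumulator model)
#'   and `rt` (seconds).
#' @inheritParams drace
#' @param floor Density floor, default `1e-10`.
#' @return A single number, the negative log-likelihood.
#' @export
neg_log_likelihood <- function(data, q,
                               variant = c("independent_start",
                                           "shared_distance"),
                               floor = 1e-10) {
  stopifnot(inherits(q, "lba_params"))
  validate_lba_params(q)
  variant <- match.arg(variant)
  if (any(q$drift_logsd <= 0))
    stop("`drift_logsd` must be > 0 in a likelihood evaluation",
         call. = FALSE)
  data <- normalize_trials(data, q$labels)
  if (nrow(data) == 0) stop("`data` must be nonempty", call. = FALSE)
  nll <- 0
  for (lab in unique(data$response)) {
    idx <- data$response == lab
    dens <- .race_density(data$rt[idx], .acc_index(q, lab),
                          q$d, q$A, q$t0, q$drift_logmean, q$drift_logsd,
                          variant)
    nll <- nll - sum(log(pmax(dens, floor)))
  }
  nll
}

# Coerce a response column to the model's labels.  Accepts labels already
# in `labels`, or (two-accumulator case) logical / 0-1 correctness.
normalize_trials <- function(data, labels) {
  if (!all(c("response", "rt") %in% names(data)))
    stop("`data` needs columns `response` and `rt`", call. = FALSE)
  r <- data$response
  if (is.logical(r) || all(r %in% c(0, 1))) {
    if (length(labels) != 2)
      stop("0/1 responses require a two-accumulator model", call. = FALSE)
    corr <- labels[labels == "correct"]
    inc <- labels[labels != "correct"]
    r <- ifelse(as.logical(r), corr, inc)
  }
  r <- as.character(r)
  if (!all(r %in% labels))
    stop("unknown response label(s): ",
         paste(unique(setdiff(r, labels)), collapse = ", "), call. = FALSE)
  tibble::tibble(response = r, rt = as.numeric(data$rt))
}

#' Model-implied RT distribution on a time grid
#'
#' Evaluates the defective density of every response on a log-spaced time
#' grid covering essentially all the probability mass, and accumulates it
#' with the trapezoidal rule.  The resulting table supports plotting,
#' normalization checks and distributional comparisons against simulated
#' data (see [ks_distance()]).
#'
#' @inheritParams drace
#' @param n Number of grid points per response.
#' @param p_tail Marginal tail probability used to set the grid
#'   endpoints.
#' @return A tibble with columns `response`, `t`, `density` and
#'   `cum_prob` (defective cumulative probability, tending to that
#'   response's choice probability).
#' @export
race_distribution <- function(q, variant = c("independent_start",
                                             "shared_distance"),
                              n = 4096, p_tail = 1e-9) {
  stopifnot(inherits(q, "lba_params"))
  variant <- match.arg(variant)
  s_lo <- min(stats::qlnorm(p_tail, log(max(q$d - q$A, q$d * 1e-9)) -
                              q$drift_logmean, q$drift_logsd))
  s_hi <- max(stats::qlnorm(1 - p_tail, log(q$d) - q$drift_logmean,
                            q$drift_logsd))
  s <- exp(seq(log(s_lo), log(s_hi), length.out = n))
  t_grid <- q$t0 + s
  purrr::map_dfr(q$labels, function(lab) {
    dens <- drace(t_grid, lab, q, variant)
    cum <- c(0, cumsum(diff(t_grid) * (dens[-1] + dens[-n]) / 2))
    tibble::tibble(response = lab, t = t_grid, density = dens,
                   cum_prob = cum)
  })
}

#' Kolmogorov-Smirnov distance between observed RTs and the model
#'
#' For each response label, compares the empirical distribution of the
#' observed RTs with the model-implied RT distribution, on one of two
#' scales:
#'
#' * `"conditional"` — the RT distribution given the response (the
#'   defective cumulative normalized by the choice probability), with
#'   the empirical CDF normalized by the response's own count.  The
#'   classic per-response goodness-of-fit view; its sampling noise
#'   scales with the (possibly much smaller) per-response count.
#' * `"defective"` — the joint (choice, RT) law: the empirical
#'   defective CDF (jumps of `1/n` over *all* trials) against the model
#'   defective cumulative.  This is the distribution-equality statement
#'   "both processes generate the same response-time distributions"
#'   with error responses folded into one defective distribution, and
#'   its noise scales with the full sample size.
#'
#' Useful as an absolute goodness-of-fit diagnostic and to verify that a
#' simulator and a density describe the same process.
#'
#' @param data Trial table with `response` and `rt` columns.
#' @inheritParams drace
#' @param scale `"conditional"` or `"defective"` (see above).
#' @param n_grid Grid resolution for the implied distribution.
#' @return A tibble with columns `response`, `n` (trials with that
#'   response), `p_choice` (model choice probability) and `ks`.
#' @export
ks_distance <- function(data, q, variant = c("independent_start",
                                             "shared_distance"),
                        scale = c("conditional", "defective"),
                        n_grid = 8192) {
  stopifnot(inherits(q, "lba_params"))
  variant <- match.arg(variant)
  scale <- match.arg(scale)
  data <- normalize_trials(data, q$labels)
  n_all <- nrow(data)
  dist <- race_distribution(q, variant, n = n_grid)
  purrr::map_dfr(unique(data$response), function(lab) {
    g <- dist[dist$response == lab, ]
    p_choice <- g$cum_prob[nrow(g)]
    rts <- sort(data$rt[data$response == lab])
    n <- length(rts)
    if (scale == "conditional") {
      Fi <- stats::approx(g$t, g$cum_prob / p_choice, xout = rts,
                          yleft = 0, yright = 1, rule = 2)$y
      ks <- max(seq_len(n) / n - Fi, Fi - (seq_len(n) - 1) / n)
    } else {
      Fi <- stats::approx(g$t, g$cum_prob, xout = rts,
                          yleft = 0, yright = p_choice, rule = 2)$y
      ks <- max(seq_len(n) / n_all - Fi, Fi - (seq_len(n) - 1) / n_all,
                abs(n / n_all - p_choice))
    }
    tibble::tibble(response = lab, n = n, p_choice = p_choice, ks = ks)
  })
}
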