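#' ACT-R declarative memory parameters
#'
#' Bundle of the seven quantities that govern a two-chunk memory retrieval
#' race in ACT-R: the mean and standard deviation of the activation of the
#' correct and the incorrect chunk, the mean and range of the trial-varying
#' latency factor, and the non-retrieval time.
#'
#' Activation is on a log-odds scale; retrieval time scales as
#' `F * exp(-activation)`, where the latency factor `F` is drawn anew each
#' trial from a uniform distribution on
#' `[F_mean - F_range / 2, F_mean + F_range / 2]`.  By convention the
#' activation noise of the correct chunk is fixed at 1, which pins down the
#' scale of the activation axis; `sigma_c` is therefore 1 by default.
#'
#' Zero values of `sigma_c`, `sigma_f` and `F_range` are accepted: they are
#' useful deterministic limits for simulation.  They are rejected at fit
#' time, where the likelihood degenerates.
#'
#' @param mu_c Mean activation of the correct chunk (log-odds units).
#' @param mu_f Mean activation of the incorrect chunk.
#' @param sigma_c SD of the correct chunk's activation; fixed to 1 by the
#'   scale convention.
#' @param sigma_f SD of the incorrect chunk's activation.
#' @param F_mean Mean latency factor (seconds per unit drift).
#' @param F_range Range of the latency factor (same units);
#'   `F_mean - F_range / 2` must stay positive.
#' @param t_er Non-retrieval time in seconds (perceptual/motor processes).
#'
#' @return An object of class `actr_params`: a named list with the seven
#'   fields above.
#' @seealso [lba_params()], [actr_to_lba()], [expected_rt()]
#' @examples
#' p <- actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1.5,
#'                  F_mean = 1, F_range = 0.1, t_er = 0.75)
#' actr_to_lba(p)
#' @export
actr_params <- function(mu_c, mu_f, sigma_c = 1, sigma_f,
                        F_mean, F_range, t_er) {
  p <- list(mu_c = as.numeric(mu_c), mu_f = as.numeric(mu_f),
            sigma_c = as.numeric(sigma_c), sigma_f = as.numeric(sigma_f),
            F_mean = as.numeric(F_mean), F_range = as.numeric(F_range),
            t_er = as.numeric(t_er))
  validate_actr_params(p)
  structure(p, class = "actr_params")
}

validate_actr_params <- function(p) {
  check_scalar <- function(x, nm) {
    if (length(p[[x]]) != 1 || !is.finite(p[[x]]))
      stop("`", x, "` must be a single finite number", call. = FALSE)
  }
  for (nm in names(p)) check_scalar(nm, nm)
  if (p$sigma_c < 0) stop("`sigma_c` must be >= 0", call. = FALSE)
  if (p$sigma_f < 0) stop("`sigma_f` must be >= 0", call. = FALSE)
  if (p$F_mean <= 0) stop("`F_mean` must be > 0", call. = FALSE)
  if (p$F_range < 0) stop("`F_range` must be >= 0", call. = FALSE)
  if (p$F_mean - p$F_range / 2 <= 0)
    stop("`F_range` too large: F_mean - F_range/2 must be > 0 ",
         "(the lower endpoint of the latency-factor distribution)",
         call. = FALSE)
  if (p$t_er < 0) stop("`t_er` must be >= 0", call. = FALSE)
  invisible(p)
}

#' Linear ballistic accumulator parameters with lognormal drift rates
#'
#' Parameters of an LBA race in which each accumulator starts at
#' `k ~ Uniform[0, A]`, travels at a drift rate drawn once per trial from a
#' lognormal distribution, and finishes when it covers the remaining
#' distance `d - k`.  The first accumulator to reach the boundary `d`
#' determines the response; the non-decision time `t0` is added to every
#' response time.
#'
#' Distances (`d`, `A`) are expressed in seconds times unit drift, so that
#' distance divided by drift is a time in seconds.  The drift rate of
#' accumulator `i` is `exp(a)` with `a ~ Normal(drift_logmean[i],
#' drift_logsd[i])`; drifts are therefore strictly positive and every
#' accumulator finishes in finite time.
#'
#' @param d Decision boundary (distance from zero evidence).
#' @param A Start-point range; starting evidence is uniform on `[0, A]`,
#'   with `0 <= A < d`.
#' @param drift_logmean Numeric vector, log-scale location of each
#'   accumulator's drift distribution.
#' @param drift_logsd Numeric vector, log-scale spread of each
#'   accumulator's drift distribution (zero allowed for deterministic
#'   simulation limits; rejected at fit time).
#' @param t0 Non-decision time in seconds.
#' @param labels Character vector of response labels, one per accumulator.
#'   Defaults to `c("correct", "incorrect", ...)`.
#'
#' @return An object of class `lba_params`.
#' @seealso [actr_params()], [lba_to_actr()], [drace()]
#' @examples
#' q <- lba_params(d = 1.05, A = 0.1, drift_logmean = c(-0.5, -1.5),
#'                 drift_logsd = c(1, 1.5), t0 = 0.75)
#' lba_to_actr(q)
#' @export
lba_params <- function(d, A, drift_logmean, drift_logsd, t0,
                       labels = NULL) {
  n_acc <- length(drift_logmean)
  if (is.null(labels)) {
    if (n_acc == 2) labels <- c("correct", "incorrect")
    else labels <- c("correct", paste0("incorrect_", seq_len(n_acc - 1)))
  }
  q <- list(d = as.numeric(d), A = as.numeric(A),
            drift_logmean = as.numeric(drift_logmean),
            drift_logsd = as.numeric(drift_logsd),
            t0 = as.numeric(t0), labels = as.character(labels))
  validate_lba_params(q)
  structure(q, class = "lba_params")
}

validate_lba_params <- function(q) {
  for (nm in c("d", "A", "t0")) {
    if (length(q[[nm]]) != 1 || !is.finite(q[[nm]]))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  n_acc <- length(q$drift_logmean)
  if (n_acc < 2) stop("at least 2 accumulators are required", call. = FALSE)
  if (length(q$drift_logsd) != n_acc || length(q$labels) != n_acc)
    stop("`drift_logmean`, `drift_logsd` and `labels` must have equal length",
         call. = FALSE)
  if (anyDuplicated(q$labels))
    stop("`labels` must be unique", call. = FALSE)
  if (!all(is.finite(q$drift_logmean)) || !all(is.finite(q$drift_logsd)))
    stop("`drift_logmean` and `drift_logsd` must be finite", call. = FALSE)
  if (any(q$drift_logsd < 0))
    stop("`drift_logsd` must be >= 0", call. = FALSE)
  if (q$A < 0) stop("`A` must be >= 0", call. = FALSE)
  if (q$A >= q$d)
    stop("`A` must be < `d` (a start point cannot lie beyond the boundary)",
         call. = FALSE)
  if (q$t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  invisible(q)
}

#' @export
print.actr_params <- function(x, ...) {
  cat("<actr_params>\n")
  v <- unlist(x)
  cat(sprintf("  %-8s %s\n", names(v), format(v, digits = 6)), sep = "")
  invisible(x)
}

#' @export
print.lba_params <- function(x, ...) {
  cat("<lba_params>  d =", format(x$d, digits = 6),
      " A =", format(x$A, digits = 6),
      " t0 =", format(x$t0, digits = 6), "\n")
  for (i in seq_along(x$labels)) {
    cat(sprintf("  %-12s drift_logmean = %s, drift_logsd = %s\n",
                x$labels[i], format(x$drift_logmean[i], digits = 6),
                format(x$drift_logsd[i], digits = 6)))
  }
  invisible(x)
}

#' Map ACT-R memory parameters to LBA parameters
#'
#' The trial-varying latency factor `F ~ Uniform[aF, bF]` plays the role of
#' the boundary-to-start distance of the LBA: setting `A = F_range` and
#' `d = F_mean + A / 2` makes the per-trial distance `d - k` uniform on
#' `[aF, bF]`.  Activations map to drift rates on the log scale
#' (`drift_logmean = mu`, `drift_logsd = sigma`, so the drift is
#' `exp(activation)` and `exp(mu)` is the median drift), and the
#' non-retrieval time carries over unchanged as `t0`.  Under this mapping
#' the two generative processes produce identical response-time
#' distributions up to the correlation induced by sharing one distance
#' draw across accumulators.
#'
#' @param p An [actr_params()] object.
#' @return An [lba_params()] object with accumulators labelled
#'   `"correct"` and `"incorrect"`.
#' @seealso [lba_to_actr()] for the inverse.
#' @export
actr_to_lba <- function(p) {
  stopifnot(inherits(p, "actr_params"))
  validate_actr_params(p)
  lba_params(d = p$F_mean + p$F_range / 2, A = p$F_range,
             drift_logmean = c(p$mu_c, p$mu_f),
             drift_logsd = c(p$sigma_c, p$sigma_f),
             t0 = p$t_er,
             labels = c("correct", "incorrect"))
}

#' Map LBA parameters back to ACT-R memory parameters
#'
#' Inverse of [actr_to_lba()]: `F_mean = d - A / 2`, `F_range = A`,
#' activation means and SDs are read off the drift log-scale parameters,
#' and `t_er = t0`.  Requires exactly two accumulators, one of which is
#' labelled `"correct"`.
#'
#' @param q An [lba_params()] object with two accumulators.
#' @return An [actr_params()] object.
#' @export
lba_to_actr <- function(q) {
  stopifnot(inherits(q, "lba_params"))
  validate_lba_params(q)
  if (length(q$labels) != 2)
    stop("lba_to_actr() needs exactly 2 accumulators ",
         "(errors pooled into one incorrect accumulator)", call. = FALSE)
  ic <- match("correct", q$labels)
  if (is.na(ic))
    stop("one accumulator must be labelled \"correct\"", call. = FALSE)
  ifo <- setdiff(1:2, ic)
  actr_params(mu_c = q$drift_logmean[ic], mu_f = q$drift_logmean[ifo],
              sigma_c = q$drift_logsd[ic], sigma_f = q$drift_logsd[ifo],
              F_mean = q$d - q$A / 2, F_range = q$A, t_er = q$t0)
}

#' Expected response time at the mean activation
#'
#' Retrieval time with the activation plugged in at its mean:
#' `F_mean * exp(-mu) + t_er`.  Note this is the finishing time of the
#' mean-activation trajectory, not the expectation over activation noise
#' (which is `F_mean * exp(-mu + sigma^2 / 2) + t_er` because
#' `exp(-activation)` is lognormal); the two coincide as `sigma -> 0`.
#'
#' @param p An [actr_params()] object.
#' @param chunk `"correct"` or `"incorrect"`.
#' @return Expected response time in seconds.
#' @examples
#' p <- actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1.5,
#'                  F_mean = 1, F_range = 0.1, t_er = 0.75)
#' expected_rt(p, "correct")
#' @export
expected_rt <- function(p, chunk = c("correct", "incorrect")) {
  stopifnot(inherits(p, "actr_params"))
  validate_actr_params(p)
  chunk <- match.arg(chunk)
  mu <- if (chunk == "correct") p$mu_c else p$mu_f
  p$F_mean * exp(-mu) + p$t_er
}

#' Analytic choice probability of the shared-distance race
#'
#' Because both chunks race over the same per-trial distance, the winner is
#' simply the chunk with the larger activation draw, so the probability of
#' a correct response is `pnorm((mu_c - mu_f) / sqrt(sigma_c^2 +
#' sigma_f^2))`, independent of the latency factor and the non-retrieval
#' time.
#'
#' @param p An [actr_params()] object.
#' @return Probability of a correct response.
#' @export
choice_probability <- function(p) {
  stopifnot(inherits(p, "actr_params"))
  s <- sqrt(p$sigma_c^2 + p$sigma_f^2)
  if (s == 0) return(as.numeric(p$mu_c >= p$mu_f))
  stats::pnorm((p$mu_c - p$mu_f) / s)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a parameter set into a one-row-per-term tibble
#'
#' @param x An `actr_params` or `lba_params` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @method tidy actr_params
#' @export
tidy.actr_params <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)),
                 estimate = unlist(x, use.names = FALSE))
}

#' @rdname tidy.actr_params
#' @method tidy lba_params
#' @export
tidy.lba_params <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = c("d", "A", "t0"),
                   estimate = c(x$d, x$A, x$t0)),
    tibble::tibble(term = c(paste0("drift_logmean_", x$labels),
                            paste0("drift_logsd_", x$labels)),
                   estimate = c(x$drift_logmean, x$drift_logsd)))
}

#' Coerce a named list or one-row data frame to ACT-R parameters
#'
#' Convenience for working with tabular parameter sets, e.g. rows of
#' [sample_participant_params()].
#'
#' @param x A named list, one-row data frame, or `actr_params` object with
#'   fields `mu_c`, `mu_f`, `sigma_c`, `sigma_f`, `F_mean`, `F_range`,
#'   `t_er`.
#' @return An [actr_params()] object.
#' @export
as_actr_params <- function(x) {
  if (inherits(x, "actr_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) stop("`x` must have exactly one row", call. = FALSE)
    x <- as.list(x)
  }
  fields <- c("mu_c", "mu_f", "sigma_c", "sigma_f",
              "F_mean", "F_range", "t_er")
  missing <- setdiff(fields, names(x))
  if (length(missing))
    stop("missing fields: ", paste(missing, collapse = ", "), call. = FALSE)
  do.call(actr_params, x[fields])
}

#' Read and write parameter sets as flat YAML or JSON
#'
#' Parameter sets serialize to a flat key-value mapping using the field
#' names of [actr_params()] / [lba_params()]; the file extension selects
#' the format (`.yaml`/`.yml` or `.json`).  Decimal values round-trip
#' exactly (JSON is written at full precision).
#'
#' @param p An `actr_params` or `lba_params` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns the parameter object.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "actr_params") || inherits(p, "lba_params"))
  x <- unclass(p)
  x$.class <- class(p)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 17)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported extension: ", ext, call. = FALSE)
  cls <- x$.class
  x$.class <- NULL
  if (identical(cls, "lba_params")) do.call(lba_params, x)
  else do.call(actr_params, x)
}
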