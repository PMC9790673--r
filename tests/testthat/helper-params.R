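# Reference parameter set: the means of the simulated-participant
# population distributions.
table_means_params <- function() {
  actr_params(mu_c = -0.5, mu_f = -1.5, sigma_c = 1, sigma_f = 1.5,
              F_mean = 1, F_range = 0.1, t_er = 0.75)
}

# A deterministic batch of valid random LBA parameter sets for
# property-style tests.
random_lba_params <- function(n, seed = 99) {
  withr::with_seed(seed, replicate(n, {
    A <- runif(1, 0.01, 1.5)
    lba_params(d = A + runif(1, 0.1, 3), A = A,
               drift_logmean = runif(2, -2.5, 1),
               drift_logsd = runif(2, 0.3, 2),
               t0 = runif(1, 0, 1.5))
  }, simplify = FALSE))
}

# Independent oracle: single-accumulator finishing-time density by
# direct integration over the drift, f(s) = int v/A * dlnorm(v) dv over
# drifts that land the finishing time in [s, s+ds].
oracle_acc_pdf <- function(t, q, acc) {
  s <- t - q$t0
  if (s <= 0) return(0)
  ml <- q$drift_logmean[acc]
  sl <- q$drift_logsd[acc]
  stats::integrate(function(v) v / q$A * stats::dlnorm(v, ml, sl),
                   (q$d - q$A) / s, q$d / s,
                   rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Independent oracle: P(T <= t) by integrating over the start point.
oracle_acc_cdf <- function(t, q, acc) {
  s <- t - q$t0
  if (s <= 0) return(0)
  ml <- q$drift_logmean[acc]
  sl <- q$drift_logsd[acc]
  stats::integrate(function(k) {
    stats::plnorm((q$d - k) / s, ml, sl, lower.tail = FALSE) / q$A
  }, 0, q$A, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Total probability of a race variant by adaptive integration of the
# defective densities over both responses.
total_probability <- function(q, variant) {
  sum(vapply(q$labels, function(ch) {
    stats::integrate(function(t) drace(t, ch, q, variant),
                     q$t0, Inf, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }, numeric(1)))
}
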