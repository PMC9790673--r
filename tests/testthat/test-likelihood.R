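test_that("lognormal partial expectation matches quadrature", {
  expect_equal(lnorm_partial_expectation(0, Inf, 0.3, 0.8),
               exp(0.3 + 0.8^2 / 2), tolerance = 1e-12)
  expect_equal(lnorm_partial_expectation(2, 2, 0, 1), 0)
  expect_error(lnorm_partial_expectation(2, 1, 0, 1), "<=")
  withr::with_seed(31, {
    for (i in 1:50) {
      ml <- runif(1, -2, 1); sl <- runif(1, 0.2, 2)
      lo <- runif(1, 0, 2); hi <- lo + rexp(1)
      oracle <- integrate(function(v) v * dlnorm(v, ml, sl), lo, hi,
                          rel.tol = 1e-12, abs.tol = 1e-14)$value
      # mixed tolerance: far in the tails the oracle itself bottoms out
      # at its absolute-error floor
      expect_lt(abs(lnorm_partial_expectation(lo, hi, ml, sl) - oracle),
                1e-10 * max(1, abs(oracle)))
    }
  })
})

test_that("single-accumulator pdf/cdf agree with brute-force oracles", {
  qs <- random_lba_params(10, seed = 41)
  withr::with_seed(42, {
    for (q in qs) {
      for (acc in 1:2) {
        t <- q$t0 + rexp(2, 1 / exp(log(q$d) - q$drift_logmean[acc]))
        for (ti in t) {
          expect_lt(abs(dlba_acc(ti, q, acc) - oracle_acc_pdf(ti, q, acc)),
                    1e-8 * max(1, oracle_acc_pdf(ti, q, acc)))
          expect_lt(abs(plba_acc(ti, q, acc) - oracle_acc_cdf(ti, q, acc)),
                    1e-9)
        }
      }
    }
  })
})

test_that("cdf is a proper distribution function with derivative = pdf", {
  q <- lba_params(d = 1.2, A = 0.4, drift_logmean = c(-0.4, -1.2),
                  drift_logsd = c(1, 1.4), t0 = 0.6)
  grid <- seq(0.65, 12, length.out = 80)
  for (acc in 1:2) {
    Fg <- plba_acc(grid, q, acc)
    expect_true(all(diff(Fg) >= 0))
    expect_true(all(Fg >= 0 & Fg <= 1))
    expect_equal(plba_acc(c(0, q$t0), q, acc), c(0, 0))
    expect_equal(plba_acc(1e6, q, acc), 1, tolerance = 1e-9)
    h <- 1e-5
    num_deriv <- (plba_acc(grid + h, q, acc) -
                    plba_acc(grid - h, q, acc)) / (2 * h)
    expect_equal(num_deriv, dlba_acc(grid, q, acc), tolerance = 1e-6)
  }
})

test_that("defective densities integrate to one and recover the analytic
           choice probability", {
  qs <- random_lba_params(8, seed = 51)
  for (q in qs) {
    expect_equal(total_probability(q, "independent_start"), 1,
                 tolerance = 1e-6)
    expect_equal(total_probability(q, "shared_distance"), 1,
                 tolerance = 1e-6)
  }
  # shared-distance choice probability depends only on the activations
  for (q in qs[1:4]) {
    p_c <- integrate(function(t) drace(t, q$labels[1], q,
                                       "shared_distance"),
                     q$t0, Inf, rel.tol = 1e-10)$value
    p_ana <- pnorm((q$drift_logmean[1] - q$drift_logmean[2]) /
                     sqrt(sum(q$drift_logsd^2)))
    expect_equal(p_c, p_ana, tolerance = 1e-4)
  }
})

test_that("both variants collapse to the lognormal race as A -> 0", {
  p <- table_means_params()
  q <- actr_to_lba(p)
  q_small <- lba_params(d = q$d, A = 1e-6, drift_logmean = q$drift_logmean,
                        drift_logsd = q$drift_logsd, t0 = q$t0)
  t_grid <- seq(q$t0 + 0.01, 15, length.out = 200)
  for (ch in c("correct", "incorrect")) {
    i <- match(ch, q$labels)
    j <- setdiff(1:2, i)
    lnr <- dlnorm(t_grid - q$t0, log(q_small$d) - q$drift_logmean[i],
                  q$drift_logsd[i]) *
      plnorm(t_grid - q$t0, log(q_small$d) - q$drift_logmean[j],
             q$drift_logsd[j], lower.tail = FALSE)
    expect_equal(drace(t_grid, ch, q_small, "independent_start"), lnr,
                 tolerance = 1e-5)
    expect_equal(drace(t_grid, ch, q_small, "shared_distance"), lnr,
                 tolerance = 1e-5)
  }
})

test_that("negative log-likelihood is floored, additive and consistent", {
  q <- actr_to_lba(table_means_params())
  # a trial before t0 has zero density: contributes -log(floor)
  one <- tibble::tibble(response = "correct", rt = 0.1)
  expect_equal(neg_log_likelihood(one, q), -log(1e-10))
  # duplicating a trial adds exactly its own -log density
  tr <- simulate_trials(table_means_params(), 100, seed = 61)
  nll <- neg_log_likelihood(tr, q)
  dup <- dplyr::bind_rows(tr, tr[7, ])
  d7 <- drace(tr$rt[7], tr$response[7], q)
  expect_equal(neg_log_likelihood(dup, q), nll - log(d7),
               tolerance = 1e-10)
  # generating parameters beat a perturbed set on average
  perturbed <- lba_params(d = q$d * 1.4, A = q$A, t0 = q$t0 * 0.7,
                          drift_logmean = q$drift_logmean + 0.4,
                          drift_logsd = q$drift_logsd * 1.3)
  diffs <- vapply(1:20, function(i) {
    dat <- simulate_trials(table_means_params(), 5000, seed = 100 + i)
    neg_log_likelihood(dat, perturbed) - neg_log_likelihood(dat, q)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
  # contract violations
  expect_error(neg_log_likelihood(tr[0, ], q), "nonempty")
  expect_error(drace(1, "nope", q), "label")
  q0 <- lba_params(d = 1, A = 0.2, drift_logmean = c(0, 0),
                   drift_logsd = c(1, 0), t0 = 0)
  expect_error(neg_log_likelihood(tr, q0), "drift_logsd")
})

test_that("simulated RTs match the implied conditional distributions", {
  p <- table_means_params()
  q <- actr_to_lba(p)
  n <- 4e4
  ks_sh <- ks_distance(simulate_trials(p, n, seed = 71), q,
                       "shared_distance")
  expect_true(all(ks_sh$ks < 0.012))
  ks_in <- ks_distance(simulate_lba_trials(q, n, seed = 72), q,
                       "independent_start")
  expect_true(all(ks_in$ks < 0.012))
  # cross-check: the independent-start density should NOT drift far from
  # shared data either at this small A, but the two variants do differ
  t_grid <- seq(q$t0 + 0.05, 6, length.out = 50)
  expect_false(isTRUE(all.equal(
    drace(t_grid, "correct", q, "independent_start"),
    drace(t_grid, "correct", q, "shared_distance"),
    tolerance = 1e-8)))
})
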