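test_that("ACT-R -> LBA mapping follows the latency-factor algebra", {
  p <- actr_params(mu_c = -0.5, mu_f = -1.5, sigma_c = 1, sigma_f = 1.5,
                   F_mean = 1, F_range = 0.1, t_er = 0.75)
  q <- actr_to_lba(p)
  expect_equal(q$d, 1.05)
  expect_equal(q$A, 0.1)
  expect_equal(q$t0, 0.75)
  expect_equal(q$drift_logmean, c(-0.5, -1.5))
  expect_equal(q$drift_logsd, c(1, 1.5))
  expect_equal(q$labels, c("correct", "incorrect"))

  # degenerate uniform latency factor
  p0 <- actr_params(mu_c = -0.2, mu_f = -1, sigma_f = 1,
                    F_mean = 2, F_range = 0, t_er = 0.5)
  q0 <- actr_to_lba(p0)
  expect_equal(q0$A, 0)
  expect_equal(q0$d, 2)
})

test_that("LBA -> ACT-R inverts the mapping", {
  q <- lba_params(d = 1.05, A = 0.1, drift_logmean = c(-0.5, -1.5),
                  drift_logsd = c(1, 1.5), t0 = 0.75)
  p <- lba_to_actr(q)
  expect_equal(p$F_mean, 1)
  expect_equal(p$F_range, 0.1)
  expect_equal(p$t_er, 0.75)
  expect_equal(p$mu_c, -0.5)
  expect_equal(p$sigma_f, 1.5)

  q0 <- lba_params(d = 2, A = 0, drift_logmean = c(0, -1),
                   drift_logsd = c(1, 1), t0 = 0.3)
  p0 <- lba_to_actr(q0)
  expect_equal(p0$F_mean, 2)
  expect_equal(p0$F_range, 0)
})

test_that("round trips are identities to 1e-12 on sampled parameter sets", {
  draws <- sample_participant_params(100, seed = 7)
  for (i in seq_len(nrow(draws))) {
    p <- as_actr_params(draws[i, -1])
    back <- lba_to_actr(actr_to_lba(p))
    expect_equal(unlist(unclass(back)), unlist(unclass(p)),
                 tolerance = 1e-12)
  }
  # reverse direction on random valid LBA parameter sets
  for (q in random_lba_params(50)) {
    back <- actr_to_lba(lba_to_actr(q))
    expect_equal(back$d, q$d, tolerance = 1e-12)
    expect_equal(back$A, q$A, tolerance = 1e-12)
    expect_equal(back$drift_logmean, q$drift_logmean, tolerance = 1e-12)
    expect_equal(back$drift_logsd, q$drift_logsd, tolerance = 1e-12)
    expect_equal(back$t0, q$t0, tolerance = 1e-12)
  }
})

test_that("invariant violations are rejected naming the offending field", {
  expect_error(actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = -1,
                           F_mean = 1, F_range = 0.1, t_er = 0.75),
               "sigma_f")
  expect_error(actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1,
                           F_mean = 0, F_range = 0, t_er = 0.75),
               "F_mean")
  expect_error(actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1,
                           F_mean = 1, F_range = 2.5, t_er = 0.75),
               "F_range")
  expect_error(actr_params(mu_c = -0.5, mu_f = -1.5, sigma_f = 1,
                           F_mean = 1, F_range = 0.1, t_er = -1),
               "t_er")
  # a start range reaching the boundary implies a non-positive minimum
  # latency factor
  expect_error(lba_params(d = 1, A = 1, drift_logmean = c(0, 0),
                          drift_logsd = c(1, 1), t0 = 0), "A")
  expect_error(lba_params(d = 1, A = 0.1, drift_logmean = 0,
                          drift_logsd = 1, t0 = 0), "2 accumulators")
  q <- lba_params(d = 1, A = 0.1, drift_logmean = c(0, 0),
                  drift_logsd = c(1, 1), t0 = 0, labels = c("a", "b"))
  expect_error(lba_to_actr(q), "correct")
})

test_that("expected_rt evaluates the mean-activation finishing time", {
  p1 <- actr_params(mu_c = 0, mu_f = -1, sigma_f = 1,
                    F_mean = 1, F_range = 0, t_er = 0)
  expect_equal(expected_rt(p1, "correct"), 1)
  p2 <- table_means_params()
  expect_equal(expected_rt(p2, "correct"), exp(0.5) + 0.75,
               tolerance = 1e-12)
  # strictly decreasing in the chunk's mean activation
  mus <- seq(-2, 2, by = 0.25)
  rts <- vapply(mus, function(m) {
    expected_rt(actr_params(mu_c = m, mu_f = -1, sigma_f = 1,
                            F_mean = 1.3, F_range = 0.2, t_er = 0.4),
                "correct")
  }, numeric(1))
  expect_true(all(diff(rts) < 0))
  expect_true(all(rts - 0.4 > 0))
})

test_that("parameter sets serialize round-trip through YAML and JSON", {
  p <- actr_params(mu_c = -0.37, mu_f = -1.21, sigma_f = 1.55,
                   F_mean = 0.93, F_range = 0.12, t_er = 0.81)
  q <- actr_to_lba(p)
  for (ext in c("yaml", "json")) {
    fp <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(p, fp)
    expect_identical(unclass(read_params(fp)), unclass(p))
    fq <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params(q, fq)
    expect_identical(unclass(read_params(fq)), unclass(q))
  }
})
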