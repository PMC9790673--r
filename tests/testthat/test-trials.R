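# a clean cell that passes every inclusion rule: >= 50 usable trials,
# >= 5 errors, all presentations >= 2, all RTs inside (0.3, 30)
clean_cell <- function(participant, session, n = 60, n_err = 8,
                       rt = NULL) {
  tibble::tibble(
    participant = participant, session = session, item = seq_len(n),
    presentation = 2L,
    correct = rep(c(FALSE, TRUE), c(n_err, n - n_err)),
    rt = if (is.null(rt)) seq(0.5, 3, length.out = n) else rt)
}

test_that("RT bounds drop exactly the out-of-range trials", {
  tr <- tibble::tibble(
    participant = 1, session = 1, item = 1:6, presentation = 2L,
    correct = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    rt = c(0.2, 0.5, 31.0, 1.0, 2.0, 0.31))
  # the emptied table is flagged with a warning, not an error
  expect_warning(out <- filter_trials(tr), "no trials survive")
  rep <- exclusion_report(out)
  expect_equal(rep$rows_removed[rep$rule == "rt_above_30s"], 1L)
  expect_equal(rep$rows_removed[rep$rule == "rt_below_300ms"], 1L)
  # the boundary-adjacent 0.31 s trial survives the row filters
  expect_false(0.2 %in% out$rt || 31 %in% out$rt)
  # (the 4 remaining rows then fall to the 50-trial cell rule)
  expect_equal(rep$rows_removed[rep$rule == "cell_under_50_trials"], 4L)
  expect_equal(sum(rep$rows_removed), nrow(tr) - nrow(out))
})

test_that("strict inequalities retain the boundary RTs 0.3 and 30 s", {
  tr <- clean_cell(1, 1, n = 60)
  tr$rt[1:2] <- c(0.3, 30)
  out <- filter_trials(tr)
  expect_equal(nrow(out), 60)
  expect_true(all(c(0.3, 30) %in% out$rt))
})

test_that("cell-level rules remove whole sessions", {
  tr <- dplyr::bind_rows(
    clean_cell(1, 1),                      # survives
    clean_cell(1, 2, n = 60, n_err = 4),   # enough trials, 4 errors
    clean_cell(2, 1, n = 49))              # one trial short
  out <- filter_trials(tr)
  rep <- exclusion_report(out)
  expect_equal(rep$rows_removed[rep$rule == "cell_under_50_trials"], 49L)
  expect_equal(rep$rows_removed[rep$rule == "cell_under_5_errors"], 60L)
  expect_equal(unique(paste(out$participant, out$session)), "1 1")
})

test_that("a conforming table passes unchanged with an all-zero report", {
  tr <- clean_cell(1, 1)
  out <- filter_trials(tr)
  expect_equal(nrow(out), nrow(tr))
  expect_true(all(exclusion_report(out)$rows_removed == 0))
  # filtering is idempotent
  out2 <- filter_trials(out)
  expect_equal(as.data.frame(out2), as.data.frame(out))
})

test_that("filtering is invariant to input row order", {
  tr <- dplyr::bind_rows(
    clean_cell(1, 1),
    clean_cell(2, 1, n = 30),
    tibble::tibble(participant = 1, session = 1, item = 100:104,
                   presentation = 1L, correct = TRUE, rt = 1))
  shuffled <- withr::with_seed(9, tr[sample(nrow(tr)), ])
  a <- filter_trials(tr)
  b <- filter_trials(shuffled)
  key <- function(x) sort(paste(x$participant, x$session, x$item,
                                x$presentation))
  expect_identical(key(a), key(b))
  expect_identical(exclusion_report(a), exclusion_report(b))
  expect_equal(exclusion_report(a)$rows_removed,
               c(5L, 0L, 0L, 30L, 0L))
})

test_that("trial tables survive a CSV round trip, with header mapping", {
  tr <- clean_cell(3, 2)
  fp <- withr::local_tempfile(fileext = ".csv")
  write_trials(tr, fp)
  back <- read_trials(fp)
  expect_equal(as.data.frame(back), as.data.frame(tr))
  # alternative headers via col_map
  alt <- dplyr::rename(tr, subj = "participant", latency = "rt")
  fp2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(alt, fp2)
  back2 <- read_trials(fp2, col_map = c(participant = "subj",
                                        rt = "latency"))
  expect_setequal(names(back2), names(tr))
  expect_error(read_trials(fp2), "missing column")
})

test_that("malformed trial tables are rejected", {
  tr <- clean_cell(1, 1)
  bad_rt <- tr; bad_rt$rt[1] <- -1
  expect_error(filter_trials(bad_rt), "rt")
  bad_dup <- dplyr::bind_rows(tr, tr[1, ])
  expect_error(filter_trials(bad_dup), "unique")
  bad_pres <- tr; bad_pres$presentation[1] <- 0L
  expect_error(filter_trials(bad_pres), "presentation")
})

test_that("per-session fits recover a session effect in t_er", {
  p_base <- table_means_params()
  sessions <- purrr::map(1:3, function(s) {
    t_er_s <- c(1.0, 1.0, 0.8)[s]
    p <- actr_params(mu_c = p_base$mu_c, mu_f = p_base$mu_f,
                     sigma_f = p_base$sigma_f, F_mean = p_base$F_mean,
                     F_range = p_base$F_range, t_er = t_er_s)
    tr <- simulate_trials(p, 1000, seed = 200 + s, session = s)
    tibble::tibble(participant = "p1", session = s,
                   item = seq_len(nrow(tr)), presentation = 2L,
                   correct = tr$response == "correct", rt = tr$rt)
  }) |> dplyr::bind_rows()
  est <- fit_sessions(sessions, fit_control(n_restarts = 10), seed = 33)
  expect_equal(nrow(est), 3 * 7)
  t_er_hat <- est$estimate[est$term == "t_er"]  # cells sorted by session
  expect_lt(t_er_hat[3], min(t_er_hat[1:2]))
  expect_true(all(est$n_trials == 1000))

  # identical cells with the same seed yield identical estimates
  two <- dplyr::bind_rows(
    sessions[sessions$session == 1, ],
    dplyr::mutate(sessions[sessions$session == 1, ],
                  participant = "p2"))
  est2 <- fit_sessions(two, fit_control(n_restarts = 4), seed = 44)
  e1 <- est2$estimate[est2$participant == "p1"]
  e2 <- est2$estimate[est2$participant == "p2"]
  expect_identical(e1, e2)
})
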