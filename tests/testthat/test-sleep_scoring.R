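test_that("bin_minutes sums displacement per minute and thresholds activity", {
  # 10 min at 5 Hz, 0.02 mm per frame = 6 mm/min: every minute active
  trace <- tibble::tibble(
    fly_id = "f1",
    t = seq(0, 600 - 0.2, by = 0.2),
    d = 0.02
  )
  ms <- bin_minutes(trace)
  expect_equal(nrow(ms), 10)
  expect_equal(ms$dist_mm, rep(6, 10), tolerance = 1e-12)
  expect_true(all(ms$active))

  # boundary: exactly 3.6 mm is active; just below is not; zero is zero
  tr <- trace_from_minute_sums(c(3.6, 3.5999999, 0))
  ms <- bin_minutes(tr)
  expect_equal(ms$active, c(TRUE, FALSE, FALSE))
  expect_equal(ms$dist_mm[3], 0)

  # the threshold is configurable
  expect_false(bin_minutes(tr, threshold_mm = 3.7)$active[1])
})

test_that("bin_minutes validates input and drops the incomplete trailing bin", {
  expect_error(bin_minutes(tibble::tibble(fly_id = character(),
                                          t = numeric(), d = numeric())),
               "empty")
  bad <- tibble::tibble(fly_id = "f1", t = c(0, 2, 1), d = 0)
  expect_error(bin_minutes(bad), "increasing")
  expect_error(bin_minutes(tibble::tibble(fly_id = "f1", t = 0:10,
                                          d = -1)), ">= 0")

  # recording stops 30 s into minute 3: that bin is dropped
  tr <- tibble::tibble(fly_id = "f1", t = seq(0, 149.8, by = 0.2), d = 0.1)
  expect_equal(nrow(bin_minutes(tr)), 2)
})

test_that("sparse minutes are invalid and absent minutes fill the grid", {
  # minute 1 full, minute 2 only 20 frames (< 50% of 300), minute 3 full
  t <- c(seq(0, 59.8, 0.2), seq(60, 63.8, 0.2), seq(120, 179.8, 0.2))
  tr <- tibble::tibble(fly_id = "f1", t = t, d = 0.1)
  ms <- bin_minutes(tr)
  expect_equal(ms$valid, c(TRUE, FALSE, TRUE))
  expect_true(is.na(ms$active[2]))

  # a wholly missing minute appears as an invalid grid row
  t2 <- c(seq(0, 59.8, 0.2), seq(120, 179.8, 0.2))
  ms2 <- bin_minutes(tibble::tibble(fly_id = "f1", t = t2, d = 0.1))
  expect_equal(ms2$minute_start, c(0, 60, 120))
  expect_false(ms2$valid[2])
})

test_that("score_sleep applies the 5-minute rule on maximal inactive runs", {
  A <- TRUE; I <- FALSE
  cases <- list(
    list(states = rep(I, 5), asleep = rep(TRUE, 5)),        # run of 5
    list(states = c(A, rep(I, 4), A), asleep = rep(FALSE, 6)), # run of 4
    # A IIIII A IIII A: only the 5-run sleeps
    list(states = c(A, rep(I, 5), A, rep(I, 4), A),
         asleep = c(FALSE, rep(TRUE, 5), rep(FALSE, 6))),
    # boundary-truncated run of 4 does not count
    list(states = c(rep(I, 4), A), asleep = rep(FALSE, 5)),
    # boundary run of exactly 5 counts
    list(states = c(rep(I, 5), A), asleep = c(rep(TRUE, 5), FALSE))
  )
  for (cs in cases) {
    scored <- score_sleep(ms_from_states(cs$states))
    expect_equal(scored$asleep, cs$asleep)
  }
})

test_that("invalid minutes break sleep runs and gaps are rejected", {
  ms <- ms_from_states(rep(FALSE, 10))
  ms$valid[6] <- FALSE
  ms$active[6] <- NA
  scored <- score_sleep(ms)
  expect_equal(scored$asleep, c(rep(TRUE, 5), FALSE, rep(FALSE, 4)))

  gap <- ms_from_states(rep(FALSE, 6))[-3, ]
  expect_error(score_sleep(gap), "gap")
})

test_that("score_sleep matches the brute-force scanner and asleep implies inactive", {
  withr::with_seed(42, {
    for (i in 1:50) {
      states <- runif(120) < 0.7
      scored <- score_sleep(ms_from_states(states))
      expect_identical(scored$asleep, oracle_sleep_runs(!states))
      expect_true(all(!scored$active[scored$asleep]))
    }
  })
})

test_that("raising the activity threshold never decreases sleep", {
  withr::with_seed(7, {
    tr <- sim_locomotion(n_flies = 3, hours = 1, sample_rate = 5)$data
    total_sleep <- vapply(c(1, 3.6, 8, 20), function(th) {
      sum(score_sleep(bin_minutes(tr, threshold_mm = th))$asleep)
    }, numeric(1))
    expect_true(all(diff(total_sleep) >= 0))
  })
})

test_that("pool_sleep counts asleep minutes per 30-min bin", {
  # saturation and fully-awake bins
  ms <- score_sleep(ms_from_states(rep(FALSE, 30)))
  expect_equal(pool_sleep(ms)$sleep_min, 30)
  ms <- score_sleep(ms_from_states(rep(TRUE, 30)))
  expect_equal(pool_sleep(ms)$sleep_min, 0)

  # a 12-min bout over minutes 25..36 splits 5 / 7 across the bin boundary
  states <- rep(TRUE, 60)
  states[26:37] <- FALSE # minute_start 25..36
  bs <- pool_sleep(score_sleep(ms_from_states(states)))
  expect_equal(bs$sleep_min, c(5, 7))

  # conservation over complete bins
  withr::with_seed(11, {
    ms <- score_sleep(ms_from_states(runif(180) < 0.6))
    bs <- pool_sleep(ms)
    expect_equal(sum(bs$sleep_min[bs$complete]), sum(ms$asleep))
  })
})

test_that("delta_sleep subtracts the per-bin control mean", {
  mk <- function(fly, sleep) tibble::tibble(
    fly_id = fly, bin_start = (seq_along(sleep) - 1) * 1800,
    sleep_min = sleep
  )
  exp <- mk("e1", c(25, 25))
  ctrl <- mk("c1", c(10, 10))
  d <- delta_sleep(exp, ctrl)
  expect_equal(d$delta_min, c(15, 15))

  # a fly identical to the control mean has delta 0
  expect_equal(delta_sleep(mk("e", c(10, 10)), ctrl)$delta_min, c(0, 0))

  # self-contrast averages to exactly 0 in every bin
  cohort <- dplyr::bind_rows(mk("a", c(3, 9)), mk("b", c(7, 1)))
  self <- delta_sleep(cohort, cohort)
  means <- tapply(self$delta_min, self$bin_start, mean)
  expect_equal(as.numeric(means), c(0, 0))

  # disjoint grids error
  ctrl2 <- mk("c1", c(10, 10))
  ctrl2$bin_start <- ctrl2$bin_start + 7200
  expect_error(delta_sleep(exp, ctrl2), "overlap")
})

test_that("window_mean averages bins with bin_start inside the half-open window", {
  df <- tibble::tibble(
    fly_id = "f1",
    bin_start = c(0, 1800, 3600, 5400, 7200, 9000, 10800),
    delta_min = c(99, 99, 2, 4, 6, 8, 99)
  )
  # TP1-3 default keeps the bins starting at 60, 90, 120, 150 min
  w <- window_mean(df)
  expect_equal(w$n_bins, 4)
  expect_equal(w$value, 5)
  expect_error(window_mean(df, window = c(2e5, 3e5)), "window")
  expect_error(window_mean(df, window = c(100, 100)), "start < end")

  # constant series returns the constant
  df$delta_min <- 3.3
  expect_equal(window_mean(df)$value, 3.3)
})

test_that("group_tests: exact signed rank, degenerate groups, rank sum ties", {
  df <- tibble::tibble(g = "a", v = rep(5, 10))
  rep1 <- group_tests(df, v, g)
  # all ten values positive: exact two-sided signed-rank p = 2 / 2^10
  expect_equal(rep1$per_group$p_signed_rank, 2 / 1024)

  # all-zero group is flagged with p = 1
  rep2 <- group_tests(tibble::tibble(g = "a", v = rep(0, 8)), v, g)
  expect_true(rep2$per_group$degenerate)
  expect_equal(rep2$per_group$p_signed_rank, 1)

  # identical groups give a maximal rank-sum p
  df3 <- tibble::tibble(g = rep(c("a", "b"), each = 6), v = rep(1:6, 2))
  rep3 <- group_tests(df3, v, g)
  expect_equal(rep3$pairwise$p_rank_sum, 1)
  expect_equal(tidy(rep3, "pairs"), rep3$pairwise)
  expect_error(group_tests(tibble::tibble(g = c("a", "b"), v = 1:2), v, g),
               ">= 2")
})

test_that("signed-rank exact enumeration agrees with wilcox.test when tie-free", {
  withr::with_seed(3, {
    for (i in 1:20) {
      x <- round(rnorm(10), 6)
      expect_equal(plsleep:::signed_rank_p(x),
                   wilcox.test(x, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("activation_delta subtracts the dark-cohort mean", {
  d <- activation_delta(c(35, 20), c(15, 25))
  expect_equal(d$delta_min, c(15, 0))
  expect_error(activation_delta(c(1, 2), numeric()), "empty")

  # a sleep-promoting manipulation planted in the chain yields positive deltas
  withr::with_seed(21, {
    eff <- tibble::tibble(start_min = 60, end_min = 120,
                          p_doze = 0.4, p_wake = 0.1)
    lit <- sim_locomotion(n_flies = 15, hours = 2, effects = eff,
                          sample_rate = 1)
    dark <- sim_locomotion(n_flies = 15, hours = 2, sample_rate = 1)
    hour2 <- function(sim) {
      bin_minutes(sim$data, sample_rate = 1) |>
        score_sleep() |>
        pool_sleep(bin_min = 60) |>
        dplyr::filter(bin_start == 3600) |>
        dplyr::pull(sleep_min)
    }
    delta <- activation_delta(hour2(lit), hour2(dark))
    expect_gt(mean(delta$delta_min), 0)
  })
})
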