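test_that("generators are bitwise reproducible under a seed", {
  a <- sim_locomotion(n_flies = 2, hours = 0.5, seed = 10)
  b <- sim_locomotion(n_flies = 2, hours = 0.5, seed = 10)
  expect_identical(a, b)
  c_ <- sim_locomotion(n_flies = 2, hours = 0.5, seed = 11)
  expect_false(identical(a$data$d, c_$data$d))

  for (f in list(
    function(s) sim_courtship(n_trained = 5, n_naive = 5, seed = s),
    function(s) sim_luminescence(n_per_group = 2, durations = c(0, 6),
                                 seed = s),
    function(s) sim_calcium(n_flies = 2, seed = s),
    function(s) sim_connectome(n_per_type = 2, seed = s)
  )) {
    expect_identical(f(3), f(3))
    expect_false(identical(f(3)$data, f(4)$data))
  }
})

test_that("degenerate transition probabilities pin the chain", {
  # p_doze = 0: a waking fly never dozes
  st <- sim_minute_states(5, 120, p_doze = 0, p_wake = 0.3, seed = 1)
  expect_true(all(st$data$active))
  asleep <- score_sleep(ms_from_states_truth(st$data))$asleep
  expect_equal(sum(asleep), 0)

  # p_wake = 0: the stationary start is inactive and stays so
  st2 <- sim_minute_states(5, 120, p_doze = 0.2, p_wake = 0, seed = 2)
  expect_true(all(!st2$data$active))

  expect_error(sim_minute_states(2, 10, p_doze = 1.4), "\\[0, 1\\]")
})

test_that("long-run inactive fraction matches the stationary distribution", {
  st <- sim_minute_states(30, 2000, p_doze = 0.1, p_wake = 0.3, seed = 3)
  expect_equal(mean(!st$data$active), 0.25, tolerance = 0.05)
})

test_that("locomotion frames respect minute states and distance law", {
  sim <- sim_locomotion(n_flies = 3, hours = 1, sample_rate = 5, seed = 4)
  frames <- dplyr::mutate(sim$data, minute_start = floor(t / 60) * 60)
  per_min <- frames |>
    dplyr::group_by(fly_id, minute_start) |>
    dplyr::summarise(dist = sum(d), n = dplyr::n(), .groups = "drop") |>
    dplyr::inner_join(sim$truth, by = c("fly_id", "minute_start"))
  expect_true(all(per_min$n == 300))
  expect_true(all(per_min$dist[!per_min$active] == 0))
  expect_true(all(per_min$dist[per_min$active] > 0))
  # log-normal distance law: median near 6 mm, rarely below the 3.6 mm
  # activity threshold
  expect_equal(median(per_min$dist[per_min$active]), 6, tolerance = 0.2)
  expect_lt(mean(per_min$dist[per_min$active] < 3.6), 0.2)
})

test_that("courtship generator hits its target medians and SI", {
  sim <- sim_courtship(n_trained = 4000, n_naive = 4000,
                       median_trained = 30, median_naive = 80, seed = 5)
  tr <- sim$data$ci[sim$data$condition == "trained"]
  na <- sim$data$ci[sim$data$condition == "naive"]
  expect_equal(median(tr), 30, tolerance = 0.05)
  expect_equal(median(na), 80, tolerance = 0.05)
  # implied SI: 100 * (1 - 30/80) = 62.5
  expect_lt(abs(suppression_index(tr, na) - 62.5), 3)
  expect_equal(sim$truth$si, 62.5) # recorded as ground truth

  # symmetric Beta(2,2) has median 50
  sym <- sim_courtship(n_trained = 4000, n_naive = 10, median_trained = 50,
                       concentration = 4, seed = 6)
  expect_equal(unname(sim_courtship(2, 2, 50, concentration = 4,
                                    seed = 1)$truth$shapes_trained),
               c(2, 2), tolerance = 1e-12)
  expect_equal(median(sym$data$ci[sym$data$condition == "trained"]), 50,
               tolerance = 1)

  expect_error(sim_courtship(5, 5, median_trained = 0.001,
                             concentration = 0.1), "infeasible")
})

test_that("luminescence amplitude laws follow the configured mode", {
  lin <- sim_luminescence(n_per_group = 2, seed = 7, mode = "linear")
  a <- lin$truth$amplitudes
  expect_equal(unname(a["6h"] / a["1h"]), 6)

  stp <- sim_luminescence(n_per_group = 2, seed = 7, mode = "step")
  a <- stp$truth$amplitudes
  expect_equal(unname(a[c("1h", "2h")]), c(0, 0))
  expect_true(all(a[c("4h", "6h")] > 0))

  pk <- sim_luminescence(n_per_group = 2, seed = 7, mode = "peaked")
  a <- pk$truth$amplitudes
  expect_true(a["2h"] == max(a) && a["2h"] > a["6h"])

  # amp = 0: experienced wells share the naive law (matching window means)
  withr::with_seed(71, {
    z <- sim_luminescence(n_per_group = 25, durations = c(0, 6), amp = 0)
    nl <- subtract_background(z$data) |> normalize_luminescence()
    wc <- window_contrast(nl)
    expect_lt(abs(wc$tests$difference), 0.1)
  })
})

test_that("calcium kernel scales linearly and drives downstream calls", {
  k1 <- sim_calcium(n_flies = 1, amplitude = 0.3, noise_sd = 0, seed = 8)
  k2 <- sim_calcium(n_flies = 1, amplitude = 0.6, noise_sd = 0, seed = 8)
  r1 <- k1$data$f / k1$truth$f0 - 1
  r2 <- k2$data$f / k2$truth$f0 - 1
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
  # kernel area scales with amplitude
  expect_equal(sum(r2), 2 * sum(r1), tolerance = 1e-10)

  # an inhibitory amplitude produces an inhibitory call end to end
  inh <- sim_calcium(n_flies = 7, amplitude = -0.4, noise_sd = 1, seed = 9)
  ss <- stim_summary(compute_dff(inh$data))
  call <- connectivity_call(ss$baseline_mean, ss$stim_mean)
  expect_equal(call$direction, "inhibitory")

  # zero amplitude: dff hovers near zero, typically no call
  z <- sim_calcium(n_flies = 7, amplitude = 0, noise_sd = 1, seed = 10)
  ssz <- stim_summary(compute_dff(z$data))
  expect_lt(abs(mean(ssz$effect)), 0.02)
})

test_that("connectome generator plants recoverable edges", {
  cn <- sim_connectome(seed = 12)
  kept <- filter_pairs(cn$data)
  truth <- cn$truth
  planted_keys <- truth[truth$planted, c("pre_id", "post_id")]
  tp <- nrow(dplyr::inner_join(kept, planted_keys,
                               by = c("pre_id", "post_id")))
  precision <- tp / nrow(kept)
  recall <- tp / nrow(planted_keys)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  # Poisson tail controls the retention fraction
  none <- tibble::tibble(pre_type = character(), post_type = character())
  pois <- sim_connectome(planted = none, lambda_noise = 9, n_per_type = 8,
                         seed = 13)
  frac <- mean(pois$truth$weight >= 9)
  expect_equal(frac, 1 - ppois(8, 9), tolerance = 0.06)

  # with only weak background, nothing survives a high threshold
  weak <- sim_connectome(planted = none, lambda_noise = 1, seed = 14)
  expect_equal(nrow(filter_pairs(weak$data, min_syn = 9)), 0)
})
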