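# Independent brute-force oracles, deliberately written as explicit scans so
# they share no code path with the package implementation.

# Mark sleep minutes by scanning runs of inactive minutes one by one.
oracle_sleep_runs <- function(inactive, min_run = 5) {
  n <- length(inactive)
  asleep <- logical(n)
  i <- 1
  while (i <= n) {
    if (inactive[i]) {
      j <- i
      while (j < n && inactive[j + 1]) j <- j + 1
      if (j - i + 1 >= min_run) asleep[i:j] <- TRUE
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  asleep
}

# Per-minute displacement sums by explicit looping over frames.
oracle_minute_sums <- function(t, d) {
  starts <- sort(unique(floor(t / 60) * 60))
  vapply(starts, function(s) sum(d[t >= s & t < s + 60]), numeric(1))
}

# Build a minute-state tibble straight from a logical activity vector
# (TRUE = active), bypassing bin_minutes. Active minutes move 6 mm.
ms_from_states <- function(active, fly_id = "f1", valid = TRUE,
                           t0_min = 0) {
  tibble::tibble(
    fly_id = fly_id,
    minute_start = (t0_min + seq_along(active) - 1) * 60,
    dist_mm = ifelse(active, 6, 0),
    active = active,
    valid = valid
  )
}

# Turn the ground-truth state table of sim_minute_states() into the
# minute-series shape the analysis verbs consume.
ms_from_states_truth <- function(truth) {
  tibble::tibble(
    fly_id = truth$fly_id,
    minute_start = truth$minute_start,
    dist_mm = ifelse(truth$active, 6, 0),
    active = truth$active,
    valid = TRUE
  )
}

# A frame-level trace whose minute displacement sums are given exactly:
# one frame carries the whole minute's distance, the rest are zero.
trace_from_minute_sums <- function(sums, sample_rate = 5, fly_id = "f1") {
  m <- round(60 * sample_rate)
  d <- as.vector(vapply(sums, function(s) c(s, rep(0, m - 1)), numeric(m)))
  tibble::tibble(
    fly_id = fly_id,
    t = (seq_along(d) - 1) / sample_rate,
    d = d
  )
}
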