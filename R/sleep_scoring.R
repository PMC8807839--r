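#' Pool locomotion into per-minute activity states
#'
#' Sums video-tracked displacement into 60-s bins anchored at `t = 0` (the end
#' of training) and flags each minute as active when its total displacement
#' reaches `threshold_mm`. The boundary value is assigned to *active*
#' (`dist_mm >= threshold_mm`), so that "no locomotion" is strictly
#' sub-threshold; set `threshold_mm` differently to explore the convention.
#'
#' Minutes with fewer than `min_frac` of the expected samples are marked
#' invalid (`valid = FALSE`, `dist_mm`/`active` are `NA`); minutes with no
#' samples at all are inserted as invalid rows so the per-fly minute grid is
#' contiguous. Invalid minutes later break sleep runs, which is conservative:
#' missing data can never fabricate sleep. An incomplete trailing minute
#' (recording stopped mid-bin) is dropped.
#'
#' @param trace A data frame with columns `fly_id`, `t` (seconds relative to
#'   the end of training; strictly increasing within fly), `d` (displacement in
#'   mm per video frame, non-negative). An optional `condition` column is
#'   carried through.
#' @param threshold_mm Activity threshold on total displacement per minute
#'   (mm); default 3.6.
#' @param sample_rate Nominal video frame rate in Hz; default 5.
#' @param min_frac Minimum fraction of expected frames for a minute to be
#'   valid; default 0.5.
#'
#' @return A tibble with one row per fly and complete minute: `fly_id`,
#'   (`condition`,) `minute_start` (s), `dist_mm`, `active`, `valid`.
#' @examples
#' trace <- tibble::tibble(
#'   fly_id = "f1",
#'   t = seq(0, 120 - 0.2, by = 0.2),
#'   d = rep(c(0.02, 0), each = 300)
#' )
#' bin_minutes(trace) # minute 1 active (6 mm), minute 2 not (0 mm)
#' @export
bin_minutes <- function(trace, threshold_mm = 3.6, sample_rate = 5,
                        min_frac = 0.5) {
  check_nonempty(trace, "`trace`")
  check_cols(trace, c("fly_id", "t", "d"), "`trace`")
  if (threshold_mm <= 0) abort("`threshold_mm` must be > 0")
  if (sample_rate <= 0) abort("`sample_rate` must be > 0")
  if (any(trace$d < 0, na.rm = TRUE)) abort("displacement `d` must be >= 0")

  bad_t <- trace %>%
    group_by(.data$fly_id) %>%
    summarise(ok = all(diff(.data$t) > 0), .groups = "drop")
  if (!all(bad_t$ok)) {
    abort("`t` must be strictly increasing within each fly")
  }

  has_condition <- "condition" %in% names(trace)
  expected <- round(60 * sample_rate)
  dt <- 1 / sample_rate

  ms <- trace %>%
    mutate(minute_start = floor(.data$t / 60) * 60) %>%
    group_by(.data$fly_id, .data$minute_start) %>%
    summarise(
      condition = if (has_condition) .data$condition[1] else NA_character_,
      dist_mm = sum(.data$d),
      n_samples = dplyr::n(),
      t_max = max(.data$t),
      .groups = "drop"
    )

  # drop a trailing bin whose recording stops before the last expected frame
  ms <- ms %>%
    group_by(.data$fly_id) %>%
    filter(!(.data$minute_start == max(.data$minute_start) &
               .data$t_max < .data$minute_start + 60 - dt - 1e-9)) %>%
    ungroup()
  check_nonempty(ms, "binned minute series")

  # complete the minute grid so gaps become explicit invalid minutes
  ms <- ms %>%
    group_by(.data$fly_id) %>%
    tidyr::complete(
      minute_start = seq(min(.data$minute_start), max(.data$minute_start), 60)
    ) %>%
    mutate(condition = .data$condition[!is.na(.data$condition)][1]) %>%
    ungroup() %>%
    mutate(
      n_samples = tidyr::replace_na(.data$n_samples, 0L),
      valid = .data$n_samples >= ceiling(min_frac * expected),
      dist_mm = ifelse(.data$valid, .data$dist_mm, NA_real_),
      active = ifelse(.data$valid, .data$dist_mm >= threshold_mm, NA)
    ) %>%
    arrange(.data$fly_id, .data$minute_start)

  out <- ms %>% select(dplyr::any_of(c(
    "fly_id", "condition", "minute_start", "dist_mm", "active", "valid"
  )))
  if (!has_condition) out$condition <- NULL
  out
}

#' Call sleep minutes with the 5-minute immobility rule
#'
#' Marks a minute as asleep exactly when it lies inside a maximal run of at
#' least `min_run` consecutive inactive minutes. Invalid minutes break runs,
#' and a run truncated by the recording boundary counts only if its observed
#' length already reaches `min_run` (unobserved immobility is never assumed).
#'
#' @param ms A minute-state tibble from [bin_minutes()] (columns `fly_id`,
#'   `minute_start`, `active`, `valid`).
#' @param min_run Minimum run length, in minutes, of immobility that counts as
#'   sleep; default 5.
#' @return `ms` with an added logical `asleep` column.
#' @export
score_sleep <- function(ms, min_run = 5) {
  check_nonempty(ms, "`ms`")
  check_cols(ms, c("fly_id", "minute_start", "active", "valid"), "`ms`")
  if (min_run < 1) abort("`min_run` must be >= 1")

  ms %>%
    arrange(.data$fly_id, .data$minute_start) %>%
    group_by(.data$fly_id) %>%
    mutate(asleep = {
      if (any(diff(.data$minute_start) != 60)) {
        abort("minute grid has gaps; run bin_minutes() first")
      }
      inactive <- .data$valid & !is.na(.data$active) & !.data$active
      runs <- rle(inactive)
      rep(runs$values & runs$lengths >= min_run, runs$lengths)
    }) %>%
    ungroup()
}

#' Pool sleep minutes into fixed bins
#'
#' Counts asleep minutes in consecutive half-open bins of `bin_min` minutes
#' anchored at `t = 0`. Bins containing any invalid minute are flagged;
#' `complete` marks bins covered by a full `bin_min` minutes of recording.
#'
#' @param ms A scored minute series from [score_sleep()].
#' @param bin_min Bin width in minutes; default 30.
#' @return A tibble `fly_id`, (`condition`,) `bin_start` (s), `sleep_min`,
#'   `n_min`, `any_invalid`, `complete`.
#' @export
pool_sleep <- function(ms, bin_min = 30) {
  check_nonempty(ms, "`ms`")
  check_cols(ms, c("fly_id", "minute_start", "asleep"), "`ms`")
  width <- bin_min * 60
  has_condition <- "condition" %in% names(ms)

  ms %>%
    mutate(bin_start = floor(.data$minute_start / width) * width) %>%
    group_by(.data$fly_id, .data$bin_start) %>%
    summarise(
      condition = if (has_condition) .data$condition[1] else NULL,
      sleep_min = sum(.data$asleep),
      n_min = dplyr::n(),
      any_invalid = any(!.data$valid),
      .groups = "drop"
    ) %>%
    mutate(complete = .data$n_min == bin_min) %>%
    arrange(.data$fly_id, .data$bin_start)
}

#' Per-fly sleep change relative to a control cohort
#'
#' For each experimental fly and bin, subtracts the mean control-cohort sleep
#' in that bin: `delta_min(f, b) = sleep_min(f, b) - mean(ctrl sleep at b)`.
#' Only bins present in both cohorts are kept; an empty overlap is an error.
#'
#' @param exp,ctrl Binned sleep tibbles from [pool_sleep()] for the
#'   experimental and control cohorts (shared bin grid).
#' @return A tibble `fly_id`, `bin_start`, `sleep_min`, `ctrl_mean`,
#'   `delta_min`.
#' @export
delta_sleep <- function(exp, ctrl) {
  check_nonempty(exp, "`exp`")
  check_nonempty(ctrl, "`ctrl`")
  check_cols(exp, c("fly_id", "bin_start", "sleep_min"), "`exp`")
  check_cols(ctrl, c("fly_id", "bin_start", "sleep_min"), "`ctrl`")

  ctrl_means <- ctrl %>%
    group_by(.data$bin_start) %>%
    summarise(ctrl_mean = mean(.data$sleep_min), n_ctrl = dplyr::n(),
              .groups = "drop")

  out <- exp %>%
    inner_join(ctrl_means, by = "bin_start") %>%
    mutate(delta_min = .data$sleep_min - .data$ctrl_mean) %>%
    arrange(.data$fly_id, .data$bin_start)
  if (nrow(out) == 0) {
    abort("experimental and control bin grids do not overlap")
  }
  out %>% select(dplyr::any_of(c(
    "fly_id", "condition", "bin_start", "sleep_min", "ctrl_mean",
    "n_ctrl", "delta_min"
  )))
}

#' Per-fly mean of a binned series over a time window
#'
#' Averages a per-bin quantity over bins whose `bin_start` falls in the
#' half-open window `[start, end)`. With the defaults of the pipeline, the
#' 1-3 h post-training window (TP1-3) contains the 30-min bins starting at
#' 60, 90, 120 and 150 min.
#'
#' @param data A per-fly binned tibble (e.g. from [delta_sleep()] or
#'   [pool_sleep()]).
#' @param window `c(start, end)` in seconds.
#' @param value Column to average (tidy-eval); default `delta_min`.
#' @param time Time column; default `bin_start`.
#' @return A tibble `fly_id`, `window_start`, `window_end`, `n_bins`, `value`.
#' @export
window_mean <- function(data, window = c(3600, 10800), value = delta_min,
                        time = bin_start) {
  check_nonempty(data, "`data`")
  check_window(window)
  value <- enquo(value)
  time <- enquo(time)

  out <- data %>%
    filter(in_window(!!time, window)) %>%
    group_by(.data$fly_id) %>%
    summarise(
      window_start = window[1], window_end = window[2],
      n_bins = dplyr::n(),
      value = mean(!!value),
      .groups = "drop"
    )
  if (nrow(out) == 0) abort("no bins fall inside `window`")
  out
}

#' Wilcoxon tests on per-fly summary values by group
#'
#' For each group, a two-sided Wilcoxon signed-rank test of H0: the median
#' equals zero; for each pair of groups, a two-sided Wilcoxon rank-sum test.
#' This is the test battery used on per-fly delta-sleep, delta-P(doze) and
#' delta-P(wake) window means.
#'
#' For small groups (n <= 15 non-zero values) the signed-rank p-value is
#' computed by exact enumeration of sign assignments on midranks, which stays
#' exact under ties; larger groups use the normal approximation with
#' continuity correction. A group whose values are all zero has an undefined
#' signed-rank statistic and is flagged with `p = 1`.
#'
#' @param data A data frame of per-fly values.
#' @param value Value column (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return An object of class `group_test_report` with components
#'   `per_group` (group, n, median, p_signed_rank, degenerate) and
#'   `pairwise` (group1, group2, p_rank_sum).
#' @export
group_tests <- function(data, value, group) {
  check_nonempty(data, "`data`")
  value <- enquo(value)
  group <- enquo(group)

  df <- tibble(
    group = as.character(dplyr::pull(data, !!group)),
    value = dplyr::pull(data, !!value)
  ) %>% filter(!is.na(.data$value))

  sizes <- table(df$group)
  if (any(sizes < 2)) abort("every group needs >= 2 observations")

  per_group <- df %>%
    group_by(.data$group) %>%
    summarise(
      n = dplyr::n(),
      median = median(.data$value),
      p_signed_rank = signed_rank_p(.data$value),
      degenerate = all(.data$value == 0),
      .groups = "drop"
    )

  groups <- sort(unique(df$group))
  pairs <- if (length(groups) >= 2) {
    combs <- utils::combn(groups, 2)
    purrr::map_dfr(seq_len(ncol(combs)), function(i) {
      g1 <- combs[1, i]; g2 <- combs[2, i]
      p <- suppressWarnings(wilcox.test(
        df$value[df$group == g1], df$value[df$group == g2],
        alternative = "two.sided", exact = FALSE, correct = TRUE
      )$p.value)
      tibble(group1 = g1, group2 = g2, p_rank_sum = p)
    })
  } else {
    tibble(group1 = character(), group2 = character(),
           p_rank_sum = numeric())
  }

  structure(list(per_group = per_group, pairwise = pairs),
            class = "group_test_report")
}

# Two-sided signed-rank p for H0: symmetric around 0.
# Exact sign-flip enumeration on midranks for n <= max_exact (valid under
# ties); normal approximation via wilcox.test otherwise.
signed_rank_p <- function(x, max_exact = 15) {
  x <- x[x != 0]
  n <- length(x)
  if (n == 0) return(1)
  if (n <= max_exact) {
    r <- rank(abs(x))
    w_obs <- sum(r[x > 0])
    mu <- sum(r) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.vector(signs %*% r)
    mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
  } else {
    suppressWarnings(wilcox.test(
      x, alternative = "two.sided", exact = FALSE, correct = TRUE
    )$p.value)
  }
}

#' @export
print.group_test_report <- function(x, ...) {
  cat("Group tests (two-sided Wilcoxon)\n")
  cat("Per-group signed-rank vs 0:\n")
  print(x$per_group)
  if (nrow(x$pairwise) > 0) {
    cat("Pairwise rank-sum:\n")
    print(x$pairwise)
  }
  invisible(x)
}

#' @rdname group_tests
#' @param x A `group_test_report`.
#' @param which `"groups"` (signed-rank vs 0) or `"pairs"` (rank-sum).
#' @param ... Unused.
#' @export
tidy.group_test_report <- function(x, which = c("groups", "pairs"), ...) {
  which <- match.arg(which)
  if (which == "groups") x$per_group else x$pairwise
}

#' Sleep change caused by acute optogenetic activation
#'
#' Subtracts the mean hour-2 sleep of the non-illuminated cohort from each
#' illuminated fly's hour-2 sleep, yielding one delta per illuminated fly.
#'
#' @param illuminated Numeric vector (or single-column data frame) of per-fly
#'   sleep minutes in the illuminated hour.
#' @param dark Same for the never-illuminated cohort.
#' @return A tibble `fly`, `sleep_min`, `dark_mean`, `delta_min`.
#' @export
activation_delta <- function(illuminated, dark) {
  illuminated <- as.numeric(unlist(illuminated))
  dark <- as.numeric(unlist(dark))
  if (length(dark) == 0) abort("`dark` cohort is empty")
  if (length(illuminated) == 0) abort("`illuminated` cohort is empty")
  tibble(
    fly = seq_along(illuminated),
    sleep_min = illuminated,
    dark_mean = mean(dark),
    delta_min = illuminated - mean(dark)
  )
}
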