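#' Per-window sleep-depth transition probabilities P(doze) and P(wake)
#'
#' Estimates, in consecutive windows of `window_min` minutes, the per-minute
#' probability of transitioning from the active to the non-active state
#' (P(doze)) and from non-active to active (P(wake)). Each probability is the
#' number of observed transitions divided by the number of source minutes of
#' the corresponding state that have an observed successor minute, so both
#' always lie in `[0, 1]`. The successor of a window's last minute is taken
#' from the following window when data are available there (transitions are
#' counted on the undivided series, then attributed to the window of their
#' source minute), so summing window counts reproduces the whole-series
#' counts exactly.
#'
#' Two state bases are offered. The default, `"activity"`, calls a minute
#' active iff its locomotion is greater than zero. `"sleep_state"` instead
#' uses the 5-minute-rule sleep/wake states from [score_sleep()] (wake =
#' not asleep). Windows with no source minutes of a kind get a missing
#' probability (`NA`), never zero, and invalid minutes contribute neither as
#' source nor as successor.
#'
#' @param ms A minute-state tibble from [bin_minutes()] (for
#'   `state_basis = "sleep_state"` it must already carry `asleep` from
#'   [score_sleep()]).
#' @param window_min Window width in minutes; default 30.
#' @param state_basis `"activity"` (locomotion > 0) or `"sleep_state"`.
#' @return A tibble per fly and window: `fly_id`, `window_start` (s),
#'   `n_active_src`, `n_inactive_src`, `n_doze`, `n_wake`, `p_doze`, `p_wake`.
#' @export
transition_probs <- function(ms, window_min = 30,
                             state_basis = c("activity", "sleep_state")) {
  state_basis <- match.arg(state_basis)
  check_nonempty(ms, "`ms`")
  check_cols(ms, c("fly_id", "minute_start", "valid"), "`ms`")
  if (state_basis == "activity") {
    check_cols(ms, "dist_mm", "`ms`")
  } else {
    check_cols(ms, "asleep", "`ms`")
  }
  width <- window_min * 60

  ms %>%
    arrange(.data$fly_id, .data$minute_start) %>%
    group_by(.data$fly_id) %>%
    mutate(
      state = if (state_basis == "activity") {
        ifelse(.data$valid, .data$dist_mm > 0, NA)
      } else {
        ifelse(.data$valid, !.data$asleep, NA)
      },
      succ = lead(.data$state),
      contiguous = lead(.data$minute_start) - .data$minute_start == 60
    ) %>%
    ungroup() %>%
    mutate(
      observed = !is.na(.data$state) & !is.na(.data$succ) &
        !is.na(.data$contiguous) & .data$contiguous,
      window_start = floor(.data$minute_start / width) * width
    ) %>%
    group_by(.data$fly_id, .data$window_start) %>%
    summarise(
      n_active_src = sum(.data$observed & .data$state),
      n_inactive_src = sum(.data$observed & !.data$state),
      n_doze = sum(.data$observed & .data$state & !.data$succ),
      n_wake = sum(.data$observed & !.data$state & .data$succ),
      .groups = "drop"
    ) %>%
    mutate(
      p_doze = ifelse(.data$n_active_src > 0,
                      .data$n_doze / .data$n_active_src, NA_real_),
      p_wake = ifelse(.data$n_inactive_src > 0,
                      .data$n_wake / .data$n_inactive_src, NA_real_)
    )
}

#' Per-fly transition-probability change relative to a control cohort
#'
#' Subtracts the control cohort's mean P(doze) and P(wake) trace, window by
#' window, from each experimental fly's trace. Windows where either side is
#' missing are skipped (delta is `NA`), and missingness is never treated as
#' zero.
#'
#' @param exp,ctrl Window tibbles from [transition_probs()] (shared window
#'   grid).
#' @return A tibble `fly_id`, `window_start`, `p_doze`, `p_wake`,
#'   `ctrl_p_doze`, `ctrl_p_wake`, `delta_p_doze`, `delta_p_wake`.
#' @export
delta_transition <- function(exp, ctrl) {
  check_nonempty(exp, "`exp`")
  check_nonempty(ctrl, "`ctrl`")
  check_cols(exp, c("fly_id", "window_start", "p_doze", "p_wake"), "`exp`")
  check_cols(ctrl, c("fly_id", "window_start", "p_doze", "p_wake"), "`ctrl`")

  ctrl_means <- ctrl %>%
    group_by(.data$window_start) %>%
    summarise(
      ctrl_p_doze = if (all(is.na(.data$p_doze))) NA_real_ else
        mean(.data$p_doze, na.rm = TRUE),
      ctrl_p_wake = if (all(is.na(.data$p_wake))) NA_real_ else
        mean(.data$p_wake, na.rm = TRUE),
      .groups = "drop"
    )

  out <- exp %>%
    inner_join(ctrl_means, by = "window_start") %>%
    mutate(
      delta_p_doze = .data$p_doze - .data$ctrl_p_doze,
      delta_p_wake = .data$p_wake - .data$ctrl_p_wake
    ) %>%
    arrange(.data$fly_id, .data$window_start)

  if (nrow(out) == 0 ||
      (all(is.na(out$delta_p_doze)) && all(is.na(out$delta_p_wake)))) {
    abort("no overlapping windows with defined probabilities")
  }
  out %>% select(
    "fly_id", "window_start", "p_doze", "p_wake",
    "ctrl_p_doze", "ctrl_p_wake", "delta_p_doze", "delta_p_wake"
  )
}
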