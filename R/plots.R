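# ggplot2 views of the main result types. Each returns a ggplot object so
# callers can restyle freely.

mean_sem <- function(x) {
  tibble(mean = mean(x, na.rm = TRUE),
         sem = sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
}

#' Mean delta-sleep trace with SEM ribbon
#'
#' @param delta Output of [delta_sleep()], optionally with a `condition`
#'   column to facet the cohorts by colour.
#' @return A ggplot object: mean `delta_min` per 30-min bin, ribbon = SEM.
#' @export
plot_delta_sleep <- function(delta) {
  check_cols(delta, c("bin_start", "delta_min"), "`delta`")
  grp <- if ("condition" %in% names(delta)) "condition" else NULL
  summ <- delta %>%
    group_by(dplyr::across(dplyr::all_of(c(grp, "bin_start")))) %>%
    summarise(mean_sem(.data$delta_min), .groups = "drop")
  aes_col <- if (is.null(grp)) NULL else ggplot2::aes(
    colour = .data$condition, fill = .data$condition
  )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$bin_start / 3600,
                                     y = .data$mean)) +
    aes_col +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after training (h)",
                  y = expression(Delta * "Sleep (min / 30 min)"))
}

#' Mean P(doze)/P(wake) traces per window
#'
#' @param windows Output of [transition_probs()] (possibly several flies).
#' @return A ggplot object with one panel per probability.
#' @export
plot_transition_probs <- function(windows) {
  check_cols(windows, c("window_start", "p_doze", "p_wake"), "`windows`")
  long <- windows %>%
    tidyr::pivot_longer(c("p_doze", "p_wake"), names_to = "prob",
                        values_to = "p") %>%
    filter(!is.na(.data$p)) %>%
    group_by(.data$prob, .data$window_start) %>%
    summarise(mean_sem(.data$p), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window_start / 3600,
                                     y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~prob, scales = "free_y") +
    ggplot2::labs(x = "Time after training (h)", y = "Probability / min")
}

#' Permutation null distribution of an SI test
#'
#' @param object An `si_test` from [perm_test_si_zero()] or
#'   [perm_test_si_equal()].
#' @param ... Unused.
#' @return A ggplot histogram of the permutation statistics with the
#'   observed value marked.
#' @export
autoplot.si_test <- function(object, ...) {
  df <- tibble(stat = object$perm)
  lab <- if (object$null_type == "si_zero") "Permuted SI (%)" else
    "Permuted SI difference (%)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = NA) +
    ggplot2::geom_vline(xintercept = object$si_obs, colour = "red") +
    ggplot2::labs(x = lab, y = "Permutations",
                  subtitle = sprintf("observed = %.1f%%, p = %.4g",
                                     object$si_obs, object$p))
}

#' Mean normalized luminescence traces by cohort
#'
#' @param nlum Output of [normalize_luminescence()].
#' @return A ggplot object: mean `nlum` over wells per cohort, ribbon = SEM.
#' @export
plot_luminescence <- function(nlum) {
  check_cols(nlum, c("training_h", "t", "nlum"), "`nlum`")
  summ <- nlum %>%
    group_by(.data$training_h, .data$t) %>%
    summarise(mean_sem(.data$nlum), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(
    x = .data$t / 60, y = .data$mean,
    colour = factor(.data$training_h), fill = factor(.data$training_h)
  )) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time after training (h)", y = "N. Luminescence",
                  colour = "Training (h)", fill = "Training (h)")
}

#' Stimulus-locked mean response
#'
#' @param epoch Output of [epoch_average()].
#' @param pulse_s Pulse duration to shade (s); default 5.
#' @return A ggplot object of the onset-aligned mean dF/F.
#' @export
plot_epoch_response <- function(epoch, pulse_s = 5) {
  check_cols(epoch, c("t_rel", "dff"), "`epoch`")
  ggplot2::ggplot(epoch, ggplot2::aes(x = .data$t_rel, y = .data$dff)) +
    ggplot2::annotate("rect", xmin = 0, xmax = pulse_s, ymin = -Inf,
                      ymax = Inf, alpha = 0.15, fill = "red") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time from pulse onset (s)",
                  y = expression(Delta * "F/F"))
}

#' Cell-type connectivity matrix
#'
#' @param type_conn Output of [aggregate_types()].
#' @return A ggplot tile map of total synapse counts between cell types.
#' @export
plot_type_connectivity <- function(type_conn) {
  check_cols(type_conn, c("pre_type", "post_type", "total_weight"),
             "`type_conn`")
  ggplot2::ggplot(type_conn, ggplot2::aes(
    x = .data$post_type, y = .data$pre_type, fill = .data$total_weight
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$total_weight),
                       colour = "white") +
    ggplot2::labs(x = "Postsynaptic type", y = "Presynaptic type",
                  fill = "Synapses")
}
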