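#' Photostimulation protocol descriptor
#'
#' The standard functional-connectivity session: six 5-s light pulses with a
#' 10-s latency to the first pulse and 30-s intervals between pulse onsets,
#' making a 200-s session.
#'
#' @param n_pulses,pulse_s,first_onset_s,onset_interval_s,session_s Protocol
#'   parameters in seconds (counts for `n_pulses`).
#' @return A `stim_protocol` list with an `onsets` vector.
#' @export
stim_protocol <- function(n_pulses = 6, pulse_s = 5, first_onset_s = 10,
                          onset_interval_s = 30, session_s = 200) {
  onsets <- first_onset_s + (seq_len(n_pulses) - 1) * onset_interval_s
  if (any(onsets + pulse_s > session_s)) {
    abort("pulses do not fit within the session")
  }
  structure(
    list(n_pulses = n_pulses, pulse_s = pulse_s,
         first_onset_s = first_onset_s, onset_interval_s = onset_interval_s,
         session_s = session_s, onsets = onsets),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("%d pulses of %g s; onsets at %s s (session %g s)\n",
              x$n_pulses, x$pulse_s, paste(x$onsets, collapse = ", "),
              x$session_s))
  invisible(x)
}

#' Fractional fluorescence change dF/F
#'
#' `dff(t) = (f(t) - F0) / F0` with `F0` the mean raw fluorescence over the
#' first `baseline_s` seconds of the session (before the first light pulse).
#' The baseline-window mean of `dff` is therefore 0 by construction, and
#' `dff` is invariant to multiplicative gain on `f`.
#'
#' @param trace A data frame with columns `t` (seconds from session start)
#'   and `f` (raw fluorescence, a.u.), one ROI of one fly; grouping columns
#'   such as `fly_id`/`roi` are carried through (the baseline is computed per
#'   fly/roi group when present).
#' @param baseline_s Baseline span in seconds (half-open `[0, baseline_s)`);
#'   default 10.
#' @return The input with `f0` and `dff` columns added.
#' @export
compute_dff <- function(trace, baseline_s = 10) {
  check_nonempty(trace, "`trace`")
  check_cols(trace, c("t", "f"), "`trace`")
  keys <- intersect(c("fly_id", "roi"), names(trace))

  trace %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    mutate(f0 = {
      base <- .data$f[in_window(.data$t, c(0, baseline_s))]
      if (length(base) < 2) {
        abort("need >= 2 samples in the baseline window")
      }
      f0 <- mean(base)
      if (f0 <= 0) abort("baseline F0 <= 0: dF/F undefined")
      f0
    }) %>%
    mutate(dff = (.data$f - .data$f0) / .data$f0) %>%
    ungroup()
}

#' Stimulus-locked average response
#'
#' Cuts the dF/F trace into one epoch per light pulse, aligns each epoch to
#' its pulse onset on a common relative-time grid (nearest recorded sample),
#' and averages the epochs pointwise. With identical responses the average
#' equals a single response; with independent zero-mean noise the averaged
#' amplitude shrinks by about `sqrt(n_pulses)`.
#'
#' @param dff_trace Output of [compute_dff()] for one ROI of one fly.
#' @param proto A [stim_protocol()].
#' @param pre_s,post_s Seconds before/after onset to include; defaults 10/20.
#' @param grid_hz Sampling rate of the relative grid; default the median
#'   sampling rate of the trace.
#' @return A tibble `t_rel` (s, 0 = pulse onset), `dff` (mean across epochs),
#'   `n_epochs`.
#' @export
epoch_average <- function(dff_trace, proto = stim_protocol(), pre_s = 10,
                          post_s = 20, grid_hz = NULL) {
  check_nonempty(dff_trace, "`dff_trace`")
  check_cols(dff_trace, c("t", "dff"), "`dff_trace`")
  t <- dff_trace$t
  if (any(proto$onsets - pre_s < min(t) - 1e-9) ||
      any(proto$onsets + post_s > max(t) + 1e-9)) {
    abort("a stimulation epoch falls outside the recording")
  }
  if (is.null(grid_hz)) grid_hz <- 1 / median(diff(t))
  t_rel <- seq(-pre_s, post_s, by = 1 / grid_hz)

  segs <- vapply(proto$onsets, function(on) {
    idx <- vapply(on + t_rel, function(tt) which.min(abs(t - tt)), integer(1))
    dff_trace$dff[idx]
  }, numeric(length(t_rel)))

  tibble(t_rel = t_rel, dff = rowMeans(segs), n_epochs = proto$n_pulses)
}

#' Functional-connectivity call from baseline and stimulated activity
#'
#' Compares each fly's mean dF/F during the 10-s pre-stimulation baseline
#' against its mean dF/F during the stimulation pulses, across flies. If the
#' comparison is significant at `alpha`, the connection is called excitatory
#' (positive mean effect) or inhibitory (negative); otherwise no connectivity
#' is called. Negating the responses flips excitatory and inhibitory with an
#' identical p-value.
#'
#' By default the comparison is paired within fly (baseline and stimulated
#' values come from the same animal); `paired = FALSE` gives the unpaired
#' two-sample version. `test = "auto"` picks Student's t-test when a Shapiro
#' normality check (at 0.05) does not reject, and the corresponding Wilcoxon
#' test otherwise; `"t"` and `"wilcoxon"` force the choice.
#'
#' @param baseline,stim Numeric vectors of per-fly mean dF/F (same order;
#'   length >= 3).
#' @param alpha Significance level for calling connectivity; default 0.05.
#' @param test `"auto"`, `"t"` or `"wilcoxon"`.
#' @param paired Compare within fly (default) or as independent groups.
#' @return An object of class `connectivity_call`: `direction`
#'   (`"excitatory"`, `"inhibitory"` or `"none"`), `p`, `effect` (mean
#'   stimulated-minus-baseline dF/F), `n_flies`, `test_used`.
#' @export
connectivity_call <- function(baseline, stim, alpha = 0.05,
                              test = c("auto", "t", "wilcoxon"),
                              paired = TRUE) {
  test <- match.arg(test)
  baseline <- as.numeric(baseline)
  stim <- as.numeric(stim)
  if (length(baseline) < 3 || (paired && length(stim) != length(baseline)) ||
      length(stim) < 3) {
    abort("need >= 3 flies (and equal lengths when paired)")
  }
  effect <- mean(stim) - mean(baseline)

  degenerate <- if (paired) all(stim - baseline == 0) else
    sd(c(baseline, stim)) == 0
  if (degenerate) {
    p <- 1
    test_used <- "none (degenerate)"
  } else {
    if (test == "auto") {
      norm_p <- tryCatch({
        if (paired) shapiro.test(stim - baseline)$p.value
        else min(shapiro.test(baseline)$p.value, shapiro.test(stim)$p.value)
      }, error = function(e) 0)
      test <- if (norm_p >= 0.05) "t" else "wilcoxon"
    }
    if (test == "t") {
      p <- t.test(stim, baseline, paired = paired,
                  alternative = "two.sided")$p.value
      test_used <- if (paired) "paired t" else "Student t"
    } else {
      # exact distribution when tie-free (crucial at typical n of 5-9;
      # the normal approximation is anticonservative there)
      p <- suppressWarnings(wilcox.test(
        stim, baseline, paired = paired, alternative = "two.sided"
      )$p.value)
      test_used <- if (paired) "Wilcoxon signed rank" else "Wilcoxon rank sum"
    }
  }

  direction <- if (p < alpha && effect > 0) "excitatory"
  else if (p < alpha && effect < 0) "inhibitory"
  else "none"
  structure(
    list(direction = direction, p = p, effect = effect,
         n_flies = length(baseline), alpha = alpha, test_used = test_used),
    class = "connectivity_call"
  )
}

#' @export
print.connectivity_call <- function(x, ...) {
  cat(sprintf(
    "Connectivity: %s (effect = %.4g dF/F, p = %.4g, %s, n = %d flies)\n",
    x$direction, x$effect, x$p, x$test_used, x$n_flies
  ))
  invisible(x)
}

#' @rdname connectivity_call
#' @param x A `connectivity_call`.
#' @param ... Unused.
#' @export
tidy.connectivity_call <- function(x, ...) {
  tibble(direction = x$direction, effect = x$effect, p.value = x$p,
         n_flies = x$n_flies, test = x$test_used)
}

#' Per-fly baseline and stimulated dF/F means
#'
#' Convenience summary feeding [connectivity_call()]: for each fly/ROI, the
#' mean dF/F over the 10-s pre-stimulation baseline and over the union of the
#' stimulation pulse intervals (`[onset, onset + pulse_s)` for each pulse).
#'
#' @param dff_traces Output of [compute_dff()], possibly many flies.
#' @param proto A [stim_protocol()].
#' @param baseline_s Baseline span in seconds; default 10.
#' @return A tibble per fly(/roi): `baseline_mean`, `stim_mean`, `effect`.
#' @export
stim_summary <- function(dff_traces, proto = stim_protocol(),
                         baseline_s = 10) {
  check_nonempty(dff_traces, "`dff_traces`")
  check_cols(dff_traces, c("t", "dff"), "`dff_traces`")
  keys <- intersect(c("fly_id", "roi"), names(dff_traces))

  in_pulse <- function(t) {
    Reduce(`|`, lapply(proto$onsets, function(on) {
      in_window(t, c(on, on + proto$pulse_s))
    }))
  }
  dff_traces %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(
      baseline_mean = mean(.data$dff[in_window(.data$t, c(0, baseline_s))]),
      stim_mean = mean(.data$dff[in_pulse(.data$t)]),
      .groups = "drop"
    ) %>%
    mutate(effect = .data$stim_mean - .data$baseline_mean)
}

#' Spontaneous activity of a neuron
#'
#' The mean raw calcium intensity over a recording span (60 s by default),
#' the summary used for resting-state comparisons across flies. The value is
#' a property of the underlying signal, not of the sampling rate.
#'
#' @param trace A data frame with `t` (s) and `f` (a.u.) for one ROI;
#'   grouping columns `fly_id`/`roi` are honoured.
#' @param span_s Averaging span `[0, span_s)` in seconds; default 60.
#' @return A tibble with one `spont` value per fly/roi group.
#' @export
spontaneous_activity <- function(trace, span_s = 60) {
  check_nonempty(trace, "`trace`")
  check_cols(trace, c("t", "f"), "`trace`")
  keys <- intersect(c("fly_id", "roi"), names(trace))

  kept <- trace %>% filter(in_window(.data$t, c(0, span_s)))
  if (nrow(kept) == 0) abort("no samples inside the span")
  out <- kept %>%
    group_by(dplyr::across(dplyr::all_of(keys))) %>%
    summarise(spont = mean(.data$f), n_samples = dplyr::n(),
              .groups = "drop")
  if (nrow(out) == 0) abort("no samples inside the span")
  out
}
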