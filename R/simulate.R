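# Synthetic-data generators. Each generator returns list(data, truth): `data`
# in the exact shape the analysis functions consume, `truth` the generating
# parameters/states, so recovery tests need no external data. All generators
# are bitwise reproducible under `seed`.

#' Simulate per-minute wake/inactive states from a two-state Markov chain
#'
#' Each fly follows a two-state chain over minutes: an active minute becomes
#' inactive with probability `p_doze`, an inactive minute becomes active with
#' probability `p_wake`. Windows listed in `effects` override both
#' probabilities (by source minute), which is how condition-dependent sleep
#' deepening (e.g. restricted to the 1-3 h post-training window) is planted.
#' Initial states are drawn from the stationary distribution of the first
#' minute's probabilities, `P(inactive) = p_doze / (p_doze + p_wake)`.
#'
#' @param n_flies Number of flies.
#' @param n_minutes Session length in minutes.
#' @param p_doze,p_wake Baseline per-minute transition probabilities.
#' @param effects Optional data frame `start_min`, `end_min`, `p_doze`,
#'   `p_wake`: override windows in minutes post-training (half-open).
#' @param t0_min Start of the session in minutes relative to end of training.
#' @param condition Condition label attached to every fly.
#' @param fly_prefix Prefix for fly ids.
#' @param seed Optional seed.
#' @return `list(data, truth)`; `data` is a tibble `fly_id`, `condition`,
#'   `minute_start` (s), `active` (true state), `truth` records the
#'   per-minute probability vectors.
#' @export
sim_minute_states <- function(n_flies, n_minutes, p_doze = 0.1, p_wake = 0.3,
                              effects = NULL, t0_min = 0,
                              condition = "naive", fly_prefix = "fly",
                              seed = NULL) {
  check_prob(p_doze, "p_doze")
  check_prob(p_wake, "p_wake")
  minutes <- t0_min + seq_len(n_minutes) - 1
  pd <- rep(p_doze, n_minutes)
  pw <- rep(p_wake, n_minutes)
  if (!is.null(effects)) {
    check_cols(effects, c("start_min", "end_min", "p_doze", "p_wake"),
               "`effects`")
    check_prob(effects$p_doze, "effects$p_doze")
    check_prob(effects$p_wake, "effects$p_wake")
    for (i in seq_len(nrow(effects))) {
      sel <- minutes >= effects$start_min[i] & minutes < effects$end_min[i]
      pd[sel] <- effects$p_doze[i]
      pw[sel] <- effects$p_wake[i]
    }
  }

  states <- with_optional_seed(seed, {
    m <- matrix(NA, n_flies, n_minutes)
    p_inact0 <- if (pd[1] + pw[1] > 0) pd[1] / (pd[1] + pw[1]) else 0
    m[, 1] <- runif(n_flies) >= p_inact0 # TRUE = active
    for (j in seq_len(n_minutes - 1)) {
      u <- runif(n_flies)
      m[, j + 1] <- ifelse(m[, j], u >= pd[j], u < pw[j])
    }
    m
  })

  data <- tibble(
    fly_id = rep(sprintf("%s%03d", fly_prefix, seq_len(n_flies)),
                 each = n_minutes),
    condition = condition,
    minute_start = rep(minutes * 60, n_flies),
    active = as.vector(t(states))
  )
  list(data = data,
       truth = list(p_doze = pd, p_wake = pw, minute_start = minutes * 60))
}

#' Simulate video-tracked locomotion traces
#'
#' Wraps [sim_minute_states()] and emits frame-level displacements: an active
#' minute's total distance is drawn from a log-normal (median
#' `exp(dist_meanlog)`, 6 mm by default, well above the 3.6 mm activity
#' threshold) and spread over the minute's frames with random exponential
#' weights; inactive minutes emit zeros.
#'
#' @inheritParams sim_minute_states
#' @param hours Session length in hours.
#' @param sample_rate Frame rate in Hz; default 5.
#' @param dist_meanlog,dist_sdlog Log-normal parameters of per-minute
#'   distance in active minutes.
#' @return `list(data, truth)`: `data` a tibble `fly_id`, `condition`, `t`
#'   (s), `d` (mm/frame); `truth` the minute-state tibble of
#'   [sim_minute_states()].
#' @export
sim_locomotion <- function(n_flies = 45, hours = 12, p_doze = 0.1,
                           p_wake = 0.3, effects = NULL, t0_min = 0,
                           condition = "naive", fly_prefix = "fly",
                           sample_rate = 5, dist_meanlog = log(6),
                           dist_sdlog = 0.4, seed = NULL) {
  with_optional_seed(seed, {
    n_minutes <- round(hours * 60)
    st <- sim_minute_states(n_flies, n_minutes, p_doze, p_wake, effects,
                            t0_min, condition, fly_prefix, seed = NULL)
    m <- round(60 * sample_rate)
    active <- st$data$active
    k_active <- sum(active)

    d_mat <- matrix(0, m, length(active))
    if (k_active > 0) {
      totals <- rlnorm(k_active, dist_meanlog, dist_sdlog)
      w <- matrix(rexp(m * k_active), m, k_active)
      d_mat[, active] <- sweep(w, 2, totals / colSums(w), `*`)
    }

    frame_offsets <- (seq_len(m) - 1) / sample_rate
    data <- tibble(
      fly_id = rep(st$data$fly_id, each = m),
      condition = condition,
      t = rep(st$data$minute_start, each = m) + rep(frame_offsets,
                                                    length(active)),
      d = as.vector(d_mat)
    )
    list(data = data, truth = st$data)
  })
}

#' Simulate a full post-training sleep study
#'
#' One shared naive control cohort plus one trained cohort per training
#' duration, all recorded from the end of training. Cohorts whose duration is
#' in `effective_durations` get deeper sleep planted in the effect window
#' (1-3 h post-training by default): a raised P(doze) and a lowered P(wake).
#' Short-training cohorts are statistically identical to the naive controls.
#'
#' @param durations Training durations in hours (labels only; one cohort
#'   each).
#' @param n_trained Flies per trained cohort.
#' @param n_naive Flies in the shared naive control cohort. The default
#'   oversizes the control relative to each trained cohort: every cohort's
#'   per-fly delta-sleep subtracts the same control mean, so control-mean
#'   noise shifts all of a cohort's deltas together and inflates the
#'   per-fly signed-rank test's false-positive rate by about
#'   `sqrt(1 + n_trained / n_naive)`. The default 12:1 ratio keeps that
#'   factor at ~1.04.
#' @param hours Recording length (hours post-training).
#' @param effective_durations Durations (h) that receive the planted effect.
#' @param effect_window_min Effect window `c(start, end)` in minutes
#'   post-training.
#' @param effect_p_doze,effect_p_wake Transition probabilities inside the
#'   effect window for effective cohorts.
#' @inheritParams sim_locomotion
#' @return `list(data, truth)`: `data` a frame-level locomotion tibble with
#'   `condition` in `"naive"`, `"1h"`, ...; `truth` the per-cohort minute
#'   states plus the planted parameters.
#' @export
sim_trained_study <- function(durations = c(1, 2, 4, 6), n_trained = 12,
                              n_naive = 144, hours = 3,
                              p_doze = 0.1, p_wake = 0.3,
                              effective_durations = c(4, 6),
                              effect_window_min = c(60, 180),
                              effect_p_doze = 0.3, effect_p_wake = 0.15,
                              sample_rate = 1, dist_meanlog = log(6),
                              dist_sdlog = 0.4, seed = NULL) {
  with_optional_seed(seed, {
    cohorts <- list(sim_locomotion(
      n_flies = n_naive, hours = hours, p_doze = p_doze, p_wake = p_wake,
      condition = "naive", fly_prefix = "nai", sample_rate = sample_rate,
      dist_meanlog = dist_meanlog, dist_sdlog = dist_sdlog
    ))
    for (h in durations) {
      eff <- if (h %in% effective_durations) {
        tibble(start_min = effect_window_min[1],
               end_min = effect_window_min[2],
               p_doze = effect_p_doze, p_wake = effect_p_wake)
      } else {
        NULL
      }
      cohorts <- c(cohorts, list(sim_locomotion(
        n_flies = n_trained, hours = hours, p_doze = p_doze, p_wake = p_wake,
        effects = eff, condition = paste0(h, "h"),
        fly_prefix = sprintf("t%gh_", h), sample_rate = sample_rate,
        dist_meanlog = dist_meanlog, dist_sdlog = dist_sdlog
      )))
    }
    list(
      data = bind_rows(lapply(cohorts, `[[`, "data")),
      truth = list(
        states = bind_rows(lapply(cohorts, `[[`, "truth")),
        effective_durations = effective_durations,
        effect_window_min = effect_window_min,
        effect_p_doze = effect_p_doze, effect_p_wake = effect_p_wake,
        baseline = c(p_doze = p_doze, p_wake = p_wake)
      )
    )
  })
}

# Beta shapes whose median approximates `median01` at total concentration k,
# via the (a - 1/3) / (a + b - 2/3) median approximation.
beta_shapes_for_median <- function(median01, concentration = 6) {
  a <- median01 * (concentration - 2 / 3) + 1 / 3
  b <- concentration - a
  if (a <= 0 || b <= 0) abort("infeasible Beta shapes for requested median")
  c(shape1 = a, shape2 = b)
}

#' Simulate courtship-index populations
#'
#' Courtship indices are Beta draws scaled to `[0, 100]`, with shapes chosen
#' so the group medians converge to the configured targets as n grows. With
#' the defaults (trained median 30%, naive median 70%) the population
#' suppression index is `100 * (1 - 30/70) = 57.1%`, in the range of robust
#' long-term courtship memory.
#'
#' @param n_trained,n_naive Group sizes.
#' @param median_trained,median_naive Target median CIs in percent.
#' @param concentration Beta concentration (shape1 + shape2); larger is less
#'   dispersed.
#' @param arm Arm label (`"exp"`/`"ctrl"`).
#' @param seed Optional seed.
#' @return `list(data, truth)`: `data` a tibble `fly_id`, `arm`, `condition`
#'   (`"trained"`/`"naive"`), `ci`; `truth` the target medians, shapes and
#'   implied SI.
#' @export
sim_courtship <- function(n_trained = 60, n_naive = 60, median_trained = 30,
                          median_naive = 70, concentration = 6, arm = "exp",
                          seed = NULL) {
  st <- beta_shapes_for_median(median_trained / 100, concentration)
  sn <- beta_shapes_for_median(median_naive / 100, concentration)
  data <- with_optional_seed(seed, tibble(
    fly_id = sprintf("%s_%s%03d", arm,
                     rep(c("t", "n"), c(n_trained, n_naive)),
                     c(seq_len(n_trained), seq_len(n_naive))),
    arm = arm,
    condition = rep(c("trained", "naive"), c(n_trained, n_naive)),
    ci = 100 * c(rbeta(n_trained, st[1], st[2]),
                 rbeta(n_naive, sn[1], sn[2]))
  ))
  list(data = data, truth = list(
    median_trained = median_trained, median_naive = median_naive,
    shapes_trained = st, shapes_naive = sn,
    si = 100 * (1 - median_trained / median_naive)
  ))
}

#' Simulate a luminescence reporter plate
#'
#' Every well carries an AR(1) background around a common level plus white
#' noise; fly wells add a baseline reporter signal and a Gaussian activity
#' bump in the post-training window whose amplitude depends on training
#' duration according to `mode`:
#' * `"linear"` - amplitude grows linearly with training duration
#'   (reporter of a neuron whose activity tracks training length);
#' * `"peaked"` - amplitude is maximal after 2 h of training and falls off
#'   for longer training (Gaussian in duration);
#' * `"step"` - amplitude is zero for short (< 4 h) and constant for long
#'   training (reporter of a long-training detector).
#'
#' @param n_per_group Fly wells per training-duration cohort.
#' @param n_empty Empty (background) wells; default 3.
#' @param durations Training durations in hours; 0 is the naive cohort.
#' @param hours Recording length in hours; samples every `dt_min` minutes.
#' @param dt_min Sampling interval in minutes; default 15.
#' @param background Mean background luminescence (a.u.).
#' @param ar_phi,ar_sd AR(1) coefficient and innovation SD of the slow
#'   background drift.
#' @param base_signal Reporter baseline above background in fly wells (a.u.).
#' @param amp Amplitude parameter; meaning depends on `mode` (linear: a.u.
#'   per hour of training, default 8; peaked/step: plateau amplitude,
#'   default 40).
#' @param bump_center_min,bump_sd_min Center and SD (minutes post-training)
#'   of the Gaussian activity bump.
#' @param noise_sd White measurement noise SD (a.u.).
#' @param mode Amplitude-versus-duration law, see above.
#' @param seed Optional seed.
#' @return `list(data, truth)`: `data` a tibble `well_id`, `role`,
#'   `training_h`, `t` (min), `lum`; `truth` the per-duration bump
#'   amplitudes and the noiseless signal parameters.
#' @export
sim_luminescence <- function(n_per_group = 35, n_empty = 3,
                             durations = c(0, 1, 2, 4, 6), hours = 10,
                             dt_min = 15, background = 100, ar_phi = 0.8,
                             ar_sd = 2, base_signal = 50, amp = NULL,
                             bump_center_min = 120, bump_sd_min = 45,
                             noise_sd = 5,
                             mode = c("linear", "peaked", "step"),
                             seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(amp)) amp <- if (mode == "linear") 8 else 40
  if (!0 %in% durations) abort("`durations` must include 0 (naive cohort)")
  t_grid <- seq(0, hours * 60 - dt_min, by = dt_min)
  nt <- length(t_grid)

  amp_of <- function(h) {
    switch(mode,
      linear = amp * h,
      peaked = amp * exp(-(h - 2)^2 / 2),
      step = amp * (h >= 4)
    )
  }
  bump <- exp(-(t_grid - bump_center_min)^2 / (2 * bump_sd_min^2))

  with_optional_seed(seed, {
    one_well <- function(well_id, role, training_h) {
      drift <- as.numeric(stats::filter(rnorm(nt, 0, ar_sd), ar_phi,
                                        method = "recursive"))
      signal <- if (role == "empty") 0 else
        base_signal + amp_of(training_h) * bump
      tibble(
        well_id = well_id, role = role, training_h = training_h,
        t = t_grid,
        lum = background + drift + signal + rnorm(nt, 0, noise_sd)
      )
    }
    wells <- list()
    for (i in seq_len(n_empty)) {
      wells <- c(wells, list(one_well(sprintf("empty%02d", i), "empty", NA)))
    }
    for (h in durations) {
      role <- if (h == 0) "naive" else "experienced"
      for (i in seq_len(n_per_group)) {
        wells <- c(wells, list(
          one_well(sprintf("w%gh_%02d", h, i), role, h)
        ))
      }
    }
    list(
      data = bind_rows(wells),
      truth = list(
        mode = mode,
        amplitudes = stats::setNames(vapply(durations, amp_of, numeric(1)),
                                     paste0(durations, "h")),
        background = background, base_signal = base_signal,
        bump_center_min = bump_center_min, bump_sd_min = bump_sd_min
      )
    )
  })
}

#' Simulate stimulus-locked calcium imaging traces
#'
#' Raw fluorescence is `f0 * (1 + amplitude * r(t))` plus Gaussian noise,
#' where `r(t)` is a pulse-locked response kernel: a saturating exponential
#' rise (time constant `tau_rise`) during each light pulse and an exponential
#' decay (`tau_decay`) after it, summed over the six pulses. A negative
#' `amplitude` plants an inhibitory response; `amplitude = 0` gives pure
#' noise around baseline. The kernel's integral scales linearly with
#' `amplitude`.
#'
#' @param n_flies Number of flies; default 7.
#' @param proto A [stim_protocol()].
#' @param amplitude Peak fractional response (dF/F units, signed).
#' @param f0 Baseline fluorescence (a.u.).
#' @param tau_rise,tau_decay Kernel time constants (s).
#' @param noise_sd Noise SD on raw fluorescence (a.u.).
#' @param volume_rate Imaging rate in Hz; default 1 (volumetric scanning).
#' @param roi ROI label.
#' @param seed Optional seed.
#' @return `list(data, truth)`: `data` a tibble `fly_id`, `roi`, `t`, `f`;
#'   `truth` holds `amplitude` and the noiseless kernel `r(t)`.
#' @export
sim_calcium <- function(n_flies = 7, proto = stim_protocol(),
                        amplitude = 0.5, f0 = 100, tau_rise = 1,
                        tau_decay = 4, noise_sd = 2, volume_rate = 1,
                        roi = "roi1", seed = NULL) {
  t_grid <- seq(0, proto$session_s - 1 / volume_rate, by = 1 / volume_rate)
  r <- rep(0, length(t_grid))
  for (on in proto$onsets) {
    s <- t_grid - on
    during <- s >= 0 & s < proto$pulse_s
    after <- s >= proto$pulse_s
    r[during] <- r[during] + (1 - exp(-s[during] / tau_rise))
    peak <- 1 - exp(-proto$pulse_s / tau_rise)
    r[after] <- r[after] + peak * exp(-(s[after] - proto$pulse_s) / tau_decay)
  }

  data <- with_optional_seed(seed, {
    purrr::map_dfr(seq_len(n_flies), function(i) {
      tibble(
        fly_id = sprintf("fly%03d", i), roi = roi, t = t_grid,
        f = f0 * (1 + amplitude * r) +
          rnorm(length(t_grid), 0, noise_sd)
      )
    })
  })
  list(data = data,
       truth = list(amplitude = amplitude, kernel = r, t = t_grid, f0 = f0))
}

#' Simulate a synapse-count edge table with planted type-level edges
#'
#' Generates all directed neuron pairs between the given cell types. Pairs
#' belonging to a planted type-level edge draw their synapse count from
#' Poisson(`lambda_planted`); all other pairs from Poisson(`lambda_noise`).
#' Pairs with zero synapses are omitted, mirroring a connectome export that
#' lists only observed connections.
#'
#' @param types Cell-type labels. The default four types mirror a
#'   feed-forward sleep circuit (two opposing mushroom-body outputs, an
#'   integrating interneuron class, and the sleep-promoting target).
#' @param planted Data frame `pre_type`, `post_type` of type-level edges to
#'   plant; the default plants the two MBON inputs onto the interneuron and
#'   the interneuron onto the target.
#' @param n_per_type Neurons per type.
#' @param lambda_planted,lambda_noise Poisson means of planted and background
#'   pair weights.
#' @param seed Optional seed.
#' @return `list(data, truth)`: `data` a tibble `pre_id`, `post_id`,
#'   `pre_type`, `post_type`, `weight`; `truth` the same rows with a
#'   `planted` flag (zero-weight pairs included).
#' @export
sim_connectome <- function(types = c("MBON-a", "MBON-b", "SFS", "vFB"),
                           planted = tibble(
                             pre_type = c("MBON-a", "MBON-b", "SFS"),
                             post_type = c("SFS", "SFS", "vFB")
                           ),
                           n_per_type = 4, lambda_planted = 20,
                           lambda_noise = 2, seed = NULL) {
  ids <- purrr::map(stats::setNames(types, types), function(ty) {
    sprintf("%s_%02d", ty, seq_len(n_per_type))
  })
  pairs <- tidyr::expand_grid(pre_type = types, post_type = types) %>%
    purrr::pmap_dfr(function(pre_type, post_type) {
      tidyr::expand_grid(pre_id = ids[[pre_type]],
                         post_id = ids[[post_type]]) %>%
        mutate(pre_type = pre_type, post_type = post_type)
    }) %>%
    filter(.data$pre_id != .data$post_id) %>%
    left_join(mutate(planted, planted = TRUE),
              by = c("pre_type", "post_type")) %>%
    mutate(planted = !is.na(.data$planted))

  pairs <- with_optional_seed(seed, mutate(
    pairs,
    weight = rpois(dplyr::n(),
                   ifelse(.data$planted, lambda_planted, lambda_noise))
  ))
  list(
    data = pairs %>% filter(.data$weight > 0) %>%
      select("pre_id", "post_id", "pre_type", "post_type", "weight"),
    truth = pairs %>%
      select("pre_id", "post_id", "pre_type", "post_type", "weight",
             "planted")
  )
}
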