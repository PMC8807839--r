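#' Subtract empty-well background from a luminescence plate
#'
#' Estimates background at each sampling time as the mean luminescence of the
#' plate's empty (fly-free) wells and subtracts it from every fly well.
#' Negative corrected values are permitted. At least one empty well is
#' required; fewer than three raises a warning, since plates are normally run
#' with three or more background wells.
#'
#' @param plate A data frame with columns `well_id`, `role` (one of `"empty"`,
#'   `"naive"`, `"experienced"`), `t` (minutes post-training, shared grid),
#'   `lum` (raw luminescence, a.u.). Optional columns (e.g. `training_h`) are
#'   carried through.
#' @return A tibble of the fly wells only, with `lum_corr` added.
#' @export
subtract_background <- function(plate) {
  check_nonempty(plate, "`plate`")
  check_cols(plate, c("well_id", "role", "t", "lum"), "`plate`")
  empties <- plate %>% filter(.data$role == "empty")
  n_empty <- dplyr::n_distinct(empties$well_id)
  if (n_empty == 0) abort("no empty wells: background cannot be estimated")
  if (n_empty < 3) {
    warn(sprintf("only %d empty well(s); plates normally carry >= 3", n_empty))
  }

  bg <- empties %>%
    group_by(.data$t) %>%
    summarise(bg = mean(.data$lum), .groups = "drop")

  out <- plate %>%
    filter(.data$role != "empty") %>%
    left_join(bg, by = "t")
  if (any(is.na(out$bg))) {
    abort("empty wells do not cover every sampling time of the plate")
  }
  out %>%
    mutate(lum_corr = .data$lum - .data$bg) %>%
    select(-"bg")
}

#' Normalize corrected luminescence to the naive-group mean
#'
#' Divides every background-corrected sample by a single scalar: the time
#' average of the pointwise mean trace of the naive wells over the averaging
#' window (the full session by default). By construction the grand mean of
#' the naive wells' normalized luminescence equals 1 exactly, and the result
#' is invariant to plate-wide additive background (already removed) and to
#' plate-wide multiplicative gain.
#'
#' @param corrected Output of [subtract_background()].
#' @param norm_window Optional `c(start, end)` (minutes, half-open) to
#'   restrict the averaging span of the normalization scalar; `NULL` (default)
#'   uses the full recorded session.
#' @return The input with an `nlum` column (dimensionless) added.
#' @export
normalize_luminescence <- function(corrected, norm_window = NULL) {
  check_nonempty(corrected, "`corrected`")
  check_cols(corrected, c("well_id", "role", "t", "lum_corr"), "`corrected`")
  naive <- corrected %>% filter(.data$role == "naive")
  if (nrow(naive) == 0) abort("no naive wells: normalization undefined")
  if (!is.null(norm_window)) {
    check_window(norm_window)
    naive <- naive %>% filter(in_window(.data$t, norm_window))
    if (nrow(naive) == 0) abort("`norm_window` contains no samples")
  }
  s <- naive %>%
    group_by(.data$t) %>%
    summarise(m = mean(.data$lum_corr), .groups = "drop") %>%
    pull("m") %>%
    mean()
  if (s <= 0) {
    abort("naive-group mean luminescence is <= 0 (signal below background)")
  }
  corrected %>% mutate(nlum = .data$lum_corr / s)
}

#' Window means of normalized luminescence and cohort contrasts
#'
#' Averages each well's normalized luminescence over samples with
#' `t` in `[window[1], window[2])` (the 1-3 h post-training window by
#' default, which holds exactly 8 samples on the 15-min grid) and compares
#' each training-duration cohort against the naive cohort with a two-sided
#' Student t-test (equal variances).
#'
#' @param nlum Output of [normalize_luminescence()]; needs a `training_h`
#'   column (0 for naive).
#' @param window `c(start, end)` in minutes; default `c(60, 180)`.
#' @return An object of class `lum_contrast`: `$well_means` (per-well window
#'   means) and `$tests` (each duration vs naive: group means, difference,
#'   `p`).
#' @export
window_contrast <- function(nlum, window = c(60, 180)) {
  check_nonempty(nlum, "`nlum`")
  check_cols(nlum, c("well_id", "role", "training_h", "t", "nlum"), "`nlum`")
  check_window(window)

  well_means <- nlum %>%
    filter(in_window(.data$t, window)) %>%
    group_by(.data$well_id, .data$role, .data$training_h) %>%
    summarise(n_samples = dplyr::n(), mean_nlum = mean(.data$nlum),
              .groups = "drop")
  if (nrow(well_means) == 0) abort("`window` contains no samples")

  naive_vals <- well_means %>% filter(.data$training_h == 0) %>%
    pull("mean_nlum")
  durations <- sort(setdiff(unique(well_means$training_h), 0))
  tests <- purrr::map_dfr(durations, function(h) {
    vals <- well_means %>% filter(.data$training_h == h) %>% pull("mean_nlum")
    tt <- t.test(vals, naive_vals, var.equal = TRUE,
                 alternative = "two.sided")
    tibble(
      training_h = h, n_exp = length(vals), n_naive = length(naive_vals),
      mean_exp = mean(vals), mean_naive = mean(naive_vals),
      difference = mean(vals) - mean(naive_vals), p = tt$p.value
    )
  })

  structure(list(well_means = well_means, tests = tests, window = window),
            class = "lum_contrast")
}

#' @export
print.lum_contrast <- function(x, ...) {
  cat(sprintf("Normalized luminescence, window [%g, %g) min\n",
              x$window[1], x$window[2]))
  print(x$tests)
  invisible(x)
}

#' @rdname window_contrast
#' @param x A `lum_contrast` object.
#' @param which `"tests"` or `"wells"`.
#' @param ... Unused.
#' @export
tidy.lum_contrast <- function(x, which = c("tests", "wells"), ...) {
  which <- match.arg(which)
  if (which == "tests") x$tests else x$well_means
}
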