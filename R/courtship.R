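#' Courtship suppression index
#'
#' The memory readout of courtship conditioning:
#' `SI = 100 * (1 - median(CI+) / median(CI-))`, the relative reduction of the
#' median courtship index of trained males (CI+) versus naive males (CI-),
#' in percent. Equal medians give 0; complete suppression gives 100. SI is
#' invariant to rescaling both groups by the same positive constant.
#'
#' @param trained_ci,naive_ci Numeric vectors of courtship indices in
#'   `[0, 100]` (percent of the 10-min test spent courting).
#' @return The suppression index in percent (a single number).
#' @examples
#' suppression_index(c(20, 30, 40), c(60, 80, 100)) # 62.5
#' @export
suppression_index <- function(trained_ci, naive_ci) {
  check_ci(trained_ci, "trained_ci")
  check_ci(naive_ci, "naive_ci")
  med_n <- median(naive_ci)
  if (med_n == 0) {
    abort("median naive CI is 0: suppression index is undefined")
  }
  100 * (1 - median(trained_ci) / med_n)
}

check_ci <- function(ci, name) {
  if (length(ci) == 0) abort(sprintf("`%s` is empty", name))
  if (!is.numeric(ci) || any(!is.finite(ci)) || any(ci < 0) || any(ci > 100)) {
    abort(sprintf("`%s` must be numeric courtship indices in [0, 100]", name))
  }
  invisible(ci)
}

#' Permutation test of H0: SI = 0
#'
#' Pools the trained and naive courtship indices, randomly reassigns them to
#' simulated trained and naive groups of the original sizes, and recomputes
#' the suppression index for each of `n_perm` permuted data sets. The
#' two-sided p-value compares `|SI|` of the permutations against the observed
#' value, with the add-one correction
#' `p = (1 + #{|SI_perm| >= |SI_obs|}) / (n_perm + 1)`, so p is never exactly
#' zero. A permuted naive group with median 0 (SI undefined) is assigned the
#' maximal-suppression sentinel `|SI| = 100` rather than discarded, keeping
#' `n_perm` fixed.
#'
#' The pooled values are sorted before permuting, so the p-value depends only
#' on the data as multisets (and the seed), not on input order. Given the same
#' seed and inputs the result is bitwise reproducible.
#'
#' @param trained_ci,naive_ci Courtship-index vectors (each of length >= 2).
#' @param n_perm Number of permutations; default 100000.
#' @param seed Optional integer seed for an isolated RNG stream.
#' @return An object of class `si_test`: `si_obs`, `p`, `n_perm`, `seed`,
#'   `null_type = "si_zero"`, group sizes, and the permutation statistics in
#'   `$perm` (for plotting).
#' @export
perm_test_si_zero <- function(trained_ci, naive_ci, n_perm = 100000,
                              seed = NULL) {
  check_ci(trained_ci, "trained_ci")
  check_ci(naive_ci, "naive_ci")
  if (length(trained_ci) < 2 || length(naive_ci) < 2) {
    abort("both groups need >= 2 courtship indices")
  }
  si_obs <- suppression_index(trained_ci, naive_ci)
  pool <- sort(c(trained_ci, naive_ci))
  perm <- with_optional_seed(seed,
    perm_si_pool(pool, length(trained_ci), as.integer(n_perm))
  )
  p <- (1 + sum(abs(perm) >= abs(si_obs) - 1e-12)) / (n_perm + 1)
  new_si_test(si_obs, p, n_perm, seed, "si_zero", perm,
              n = c(trained = length(trained_ci), naive = length(naive_ci)))
}

#' Permutation test of H0: SI_exp = SI_ctrl
#'
#' Tests whether the experimental and control arms learn equally well. The
#' statistic is `SI_exp - SI_ctrl`. The null distribution is built by
#' permuting arm labels (experimental/control) independently within the pooled
#' trained flies and within the pooled naive flies, preserving group sizes;
#' the trained/naive structure itself is not under test and is never
#' shuffled. Two-sided p with add-one correction, and the same zero-median
#' sentinel rule as [perm_test_si_zero()].
#'
#' @param exp_trained,exp_naive,ctrl_trained,ctrl_naive Courtship-index
#'   vectors for the four groups.
#' @inheritParams perm_test_si_zero
#' @return An `si_test` object with `null_type = "si_equal"`; `si_obs` is the
#'   observed difference `SI_exp - SI_ctrl` (components in `$si_exp`,
#'   `$si_ctrl`).
#' @export
perm_test_si_equal <- function(exp_trained, exp_naive, ctrl_trained,
                               ctrl_naive, n_perm = 100000, seed = NULL) {
  for (nm in c("exp_trained", "exp_naive", "ctrl_trained", "ctrl_naive")) {
    check_ci(get(nm), nm)
  }
  si_exp <- suppression_index(exp_trained, exp_naive)
  si_ctrl <- suppression_index(ctrl_trained, ctrl_naive)
  stat_obs <- si_exp - si_ctrl
  trained_pool <- sort(c(exp_trained, ctrl_trained))
  naive_pool <- sort(c(exp_naive, ctrl_naive))
  perm <- with_optional_seed(seed,
    perm_si_diff(trained_pool, length(exp_trained),
                 naive_pool, length(exp_naive), as.integer(n_perm))
  )
  p <- (1 + sum(abs(perm) >= abs(stat_obs) - 1e-12)) / (n_perm + 1)
  out <- new_si_test(stat_obs, p, n_perm, seed, "si_equal", perm,
                     n = c(exp_trained = length(exp_trained),
                           exp_naive = length(exp_naive),
                           ctrl_trained = length(ctrl_trained),
                           ctrl_naive = length(ctrl_naive)))
  out$si_exp <- si_exp
  out$si_ctrl <- si_ctrl
  out
}

new_si_test <- function(si_obs, p, n_perm, seed, null_type, perm, n) {
  structure(
    list(si_obs = si_obs, p = p, n_perm = n_perm,
         seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
         null_type = null_type, n = n, perm = perm),
    class = "si_test"
  )
}

#' @export
print.si_test <- function(x, ...) {
  lab <- if (x$null_type == "si_zero") "H0: SI = 0" else "H0: SI_exp = SI_ctrl"
  stat <- if (x$null_type == "si_zero") "SI" else "SI_exp - SI_ctrl"
  cat(sprintf("Permutation test, %s\n", lab))
  cat(sprintf("  %s = %.2f%%, p = %.5g (%d permutations)\n",
              stat, x$si_obs, x$p, x$n_perm))
  invisible(x)
}

#' @rdname perm_test_si_zero
#' @param x An `si_test` object.
#' @param ... Unused.
#' @export
tidy.si_test <- function(x, ...) {
  tibble(
    null_type = x$null_type,
    estimate = x$si_obs,
    p.value = x$p,
    n_perm = x$n_perm,
    seed = x$seed
  )
}

#' @rdname perm_test_si_zero
#' @export
glance.si_test <- function(x, ...) {
  tidy(x) %>% mutate(n_total = sum(x$n))
}
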