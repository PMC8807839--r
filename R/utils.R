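# Shared input checks and small helpers. All windows in the package are
# half-open [start, end): a bin or sample belongs to the window iff
# start <= x < end, so adjacent windows never double count.

in_window <- function(x, window) {
  x >= window[1] & x < window[2]
}

check_cols <- function(data, cols, what) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s must contain column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

check_nonempty <- function(data, what) {
  if (is.null(data) || nrow(as.data.frame(data)) == 0) {
    abort(sprintf("%s is empty", what))
  }
  invisible(data)
}

check_window <- function(window) {
  if (length(window) != 2 || !is.numeric(window) || window[1] >= window[2]) {
    abort("`window` must be a numeric vector c(start, end) with start < end")
  }
  invisible(window)
}

check_prob <- function(p, name) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(p)
}

# Run a block under a fixed seed when one is given, leaving the global RNG
# stream untouched; otherwise consume the current stream.
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), force(code))
  }
}
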