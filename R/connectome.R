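#' Threshold single-neuron synapse-count edges
#'
#' Retains directed neuron-to-neuron edges whose synapse count reaches
#' `min_syn`. The threshold is inclusive: an edge with exactly `min_syn`
#' synapses is kept (a "threshold of 9" reads as the minimum retained count).
#' Direction is preserved; reciprocal connections are never merged.
#'
#' @param edges A data frame with columns `pre_id`, `post_id`, `pre_type`,
#'   `post_type`, `weight` (non-negative integer synapse count), one row per
#'   directed neuron pair.
#' @param min_syn Minimum synapse count retained; default 9. `min_syn = 0` is
#'   the identity.
#' @return The retained rows, as a tibble.
#' @export
filter_pairs <- function(edges, min_syn = 9) {
  check_nonempty(edges, "`edges`")
  check_cols(edges, c("pre_id", "post_id", "weight"), "`edges`")
  w <- edges$weight
  if (!is.numeric(w) || any(!is.finite(w)) || any(w < 0) ||
      any(w %% 1 != 0)) {
    abort("`weight` must be non-negative integer synapse counts")
  }
  if (anyDuplicated(edges[c("pre_id", "post_id")]) > 0) {
    abort("duplicate (pre_id, post_id) rows: one row per directed pair")
  }
  as_tibble(edges) %>% filter(.data$weight >= min_syn)
}

#' Aggregate retained edges to cell-type connectivity
#'
#' Groups retained single-neuron edges by their directed (pre-type,
#' post-type) pair, summing synapse counts and counting the neuron pairs that
#' survive the threshold. Type pairs with no retained pair are absent (never
#' reported as zero). Rows lacking a type label are excluded with a warning.
#' Aggregation conserves weight exactly:
#' the totals sum to the summed weights of the retained rows.
#'
#' @param filtered Output of [filter_pairs()] (columns `pre_type`,
#'   `post_type`, `weight`).
#' @return A tibble `pre_type`, `post_type`, `total_weight`,
#'   `n_pairs_retained`.
#' @export
aggregate_types <- function(filtered) {
  check_nonempty(filtered, "`filtered`")
  check_cols(filtered, c("pre_type", "post_type", "weight"), "`filtered`")
  labelled <- !is.na(filtered$pre_type) & !is.na(filtered$post_type) &
    filtered$pre_type != "" & filtered$post_type != ""
  if (any(!labelled)) {
    warn(sprintf("%d row(s) without type labels excluded", sum(!labelled)))
  }
  filtered[labelled, ] %>%
    group_by(.data$pre_type, .data$post_type) %>%
    summarise(
      total_weight = sum(.data$weight),
      n_pairs_retained = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$pre_type, .data$post_type)
}
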