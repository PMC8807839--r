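# Readers for the tidy CSV dialects the pipeline consumes. Each reader
# validates the header and returns a tibble ready for the corresponding
# analysis verbs.

#' Read pipeline input tables
#'
#' Thin [readr::read_csv()] wrappers with column validation for the five
#' input kinds: locomotion traces (`fly_id,condition,t_s,d_mm`), courtship
#' index tables (`fly_id,arm,condition,ci`), luminescence plates
#' (`well_id,role,training_h,t_min,lum`), ROI fluorescence traces
#' (`fly_id,roi,t_s,f`) and synapse edge tables
#' (`pre_id,post_id,pre_type,post_type,weight`). Columns are renamed to the
#' unit-free names used across the package (`t`, `d`, `f`).
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble in the shape the matching analysis function expects.
#' @name read_inputs
NULL

read_checked <- function(path, required, renames = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_cols(df, required, path)
  if (!is.null(renames)) df <- rename(df, !!!renames)
  df
}

#' @rdname read_inputs
#' @export
read_locomotion <- function(path) {
  read_checked(path, c("fly_id", "condition", "t_s", "d_mm"),
               c(t = "t_s", d = "d_mm"))
}

#' @rdname read_inputs
#' @export
read_courtship <- function(path) {
  df <- read_checked(path, c("fly_id", "arm", "condition", "ci"))
  check_ci(df$ci, "ci")
  df
}

#' @rdname read_inputs
#' @export
read_plate <- function(path) {
  read_checked(path, c("well_id", "role", "training_h", "t_min", "lum"),
               c(t = "t_min"))
}

#' @rdname read_inputs
#' @export
read_roi_traces <- function(path) {
  read_checked(path, c("fly_id", "roi", "t_s", "f"), c(t = "t_s"))
}

#' @rdname read_inputs
#' @export
read_edges <- function(path) {
  read_checked(path, c("pre_id", "post_id", "pre_type", "post_type",
                       "weight"))
}
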