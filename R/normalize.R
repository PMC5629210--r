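#' Normalize measurements to same-experiment controls
#'
#' Per-experiment normalization used throughout the package: the mean value
#' of each experimental condition is divided by the mean value of the
#' control condition of the same experiment, so controls average to 1 and
#' experiment-level multiplicative offsets cancel before conditions are
#' compared across experiments.
#'
#' @param df data.frame with at least `experiment`, `condition` and the
#'   value column.
#' @param value_col name of the numeric column to normalize.
#' @param control_label condition label of the control.
#' @param out_col name of the normalized column (default `<value_col>_norm`).
#' @return `df` with the normalized column appended.
#' @export
normalize_to_control <- function(df, value_col, control_label = "control",
                                 out_col = paste0(value_col, "_norm")) {
  assert_that(all(c("experiment", "condition", value_col) %in% names(df)),
              "df must have columns experiment, condition and the value column")
  out <- df
  out[[out_col]] <- NA_real_
  for (ex in unique(df$experiment)) {
    in_ex <- df$experiment == ex
    ctrl <- in_ex & df$condition == control_label
    if (!any(ctrl))
      stopf("experiment '%s' has no control condition '%s'", ex, control_label)
    ref <- mean(df[[value_col]][ctrl])
    if (!is.finite(ref) || ref == 0)
      stopf("experiment '%s': control mean is zero or non-finite", ex)
    out[[out_col]][in_ex] <- df[[value_col]][in_ex] / ref
  }
  out
}
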