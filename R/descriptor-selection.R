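#' Autoscale descriptor columns
#'
#' Centres each descriptor on its mean and scales it to unit sample
#' standard deviation (n - 1 denominator), so every descriptor carries
#' equal weight regardless of its native units. The centring and scaling
#' constants are returned for the inverse transform.
#'
#' @param table A compound tibble.
#' @param columns Columns to scale (default: all descriptor columns).
#' @return A list with `scaled` (tibble of scaled columns), `center` and
#'   `scale` (named numeric vectors).
#' @examples
#' sc <- autoscale(a2a_training())
#' colMeans(sc$scaled) # all ~0
#' @export
autoscale <- function(table, columns = descriptor_names(table)) {
  if (nrow(table) < 2) abort("autoscaling needs at least 2 rows")
  x <- table[columns]
  if (anyNA(x)) abort("autoscaling requires complete columns (no missing cells)")
  center <- vapply(x, mean, numeric(1))
  scale <- vapply(x, sd, numeric(1))
  zero <- names(scale)[scale == 0]
  if (length(zero)) {
    abort(paste0("zero-variance column cannot be autoscaled: ",
                 paste(zero, collapse = ", ")))
  }
  scaled <- as_tibble(purrr::map2(x, seq_along(x),
                                  ~ (.x - center[.y]) / scale[.y]))
  names(scaled) <- columns
  list(scaled = scaled, center = center, scale = scale)
}

#' Pearson correlation of each descriptor with activity
#'
#' Computes the Pearson correlation coefficient between every descriptor
#' column and the activity column, the screening step that decides which
#' descriptors enter the regression models. Correlation is scale-free, so
#' the result is identical on raw and autoscaled descriptors.
#'
#' @param table A compound tibble with activity present for all rows.
#' @param activity Name of the activity column (default `"pec50"`).
#' @param descriptors Descriptor columns to correlate (default: all).
#' @param cutoff Absolute-correlation selection threshold recorded in the
#'   report (default 0.5).
#' @return A tibble with columns `descriptor`, `r`, `abs_r`, `selected`
#'   (TRUE where `|r| >= cutoff`), ordered as the input columns, with the
#'   cutoff stored in the `"cutoff"` attribute. Constant descriptors get
#'   `r = NA` and are flagged unselected with a warning.
#' @examples
#' correlate_activity(a2a_training())
#' @export
correlate_activity <- function(table, activity = "pec50",
                               descriptors = descriptor_names(table),
                               cutoff = 0.5) {
  if (!activity %in% names(table)) {
    abort(paste0("activity column '", activity, "' not found"))
  }
  y <- table[[activity]]
  if (anyNA(y)) abort("activity must be present for all rows")
  r <- vapply(descriptors, function(d) {
    x <- table[[d]]
    if (sd(x) == 0) NA_real_ else cor(x, y)
  }, numeric(1))
  if (anyNA(r)) {
    warn(paste0("constant descriptor(s) excluded from selection: ",
                paste(descriptors[is.na(r)], collapse = ", ")))
  }
  out <- tibble(descriptor = descriptors, r = unname(r),
                abs_r = abs(unname(r)),
                selected = !is.na(r) & abs(r) >= cutoff)
  attr(out, "cutoff") <- cutoff
  out
}

#' Select descriptors by absolute correlation
#'
#' Returns the descriptors whose absolute Pearson correlation with the
#' activity meets the cutoff. The cutoff applies to `|r|`: descriptors
#' that track potency inversely (such as polarizability here) are as
#' informative as positively correlated ones.
#'
#' @param report A correlation report from [correlate_activity()].
#' @param cutoff Absolute-correlation threshold (default: the report's
#'   recorded cutoff, itself defaulting to 0.5).
#' @return Character vector of selected descriptor names, input order
#'   preserved.
#' @examples
#' a2a_training() %>% correlate_activity() %>% select_descriptors()
#' @export
select_descriptors <- function(report, cutoff = attr(report, "cutoff") %||% 0.5) {
  report %>%
    filter(!is.na(.data$r), .data$abs_r >= cutoff) %>%
    pull("descriptor")
}
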