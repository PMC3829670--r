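#' Compare methods of averaging score ratios
#'
#' Ratios between successive scores can be summarised in several ways: the
#' ratio of the mean scores, the plain mean of the per-item ratios, the mean
#' base-10 log-ratio, and the mean Contrast. The ratio of means is dominated
#' by whichever item has the largest baseline, and the plain mean of ratios
#' lacks a symmetric zero point (factors \eqn{k} and \eqn{1/k} do not cancel).
#' Log-ratios and Contrasts both have a zero point at which an equivalent
#' relative increase and decrease cancel exactly, which is why TDC averages
#' Contrasts; unlike the log-ratio, the Contrast stays finite when a score
#' reaches zero.
#'
#' @param pairs A data frame with columns `s1` (baseline scores, strictly
#'   positive so all ratios are defined) and `s2` (later scores).
#' @return A one-row tibble with `ratio_of_means`, `mean_of_ratios`,
#'   `mean_log_ratio` (base 10), `mean_contrast`, and `n`.
#' @export
#' @examples
#' # three items with baselines 20, 40, 60 and factors 2, 1, 0.5
#' compare_averaging_methods(data.frame(s1 = c(20, 40, 60), s2 = c(40, 40, 30)))
compare_averaging_methods <- function(pairs) {
  if (!is.data.frame(pairs) || !all(c("s1", "s2") %in% names(pairs))) {
    abort("`pairs` must be a data frame with columns `s1` and `s2`.",
          class = "tdcontrol_error_input")
  }
  if (nrow(pairs) == 0L) {
    abort("`pairs` is empty.", class = "tdcontrol_error_input")
  }
  s1 <- pairs$s1
  s2 <- pairs$s2
  check_scores(s2, "s2")
  if (!is.numeric(s1) || any(!is.finite(s1)) || any(s1 <= 0)) {
    abort("All baseline scores `s1` must be strictly positive for ratios to be defined.",
          class = "tdcontrol_error_input")
  }
  r <- s2 / s1
  tibble::tibble(
    ratio_of_means = mean(s2) / mean(s1),
    mean_of_ratios = mean(r),
    mean_log_ratio = mean(log10(r)),
    mean_contrast  = mean(contrast(s1, s2)),
    n              = length(r)
  )
}
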