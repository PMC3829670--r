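#' Contrast between a reference score and a later score
#'
#' The Contrast is the normalized difference \eqn{C = (S_2 - S_1)/(S_2 + S_1)}
#' between a later score \eqn{S_2} and a reference score \eqn{S_1}. It is a
#' symmetric transform of the multiplication factor \eqn{R = S_2/S_1}: an
#' increase and a decrease by the same factor give Contrasts of equal size and
#' opposite sign, which makes Contrasts suitable for averaging relative change
#' across items (see [compare_averaging_methods()]). The value is bounded in
#' \eqn{[-1, +1]}: \eqn{-1} means the sign has fully resolved (\eqn{S_2 = 0}),
#' \eqn{0} no change, \eqn{+1} a sign that appeared from zero.
#'
#' When both scores are zero the Contrast is defined as 0 (no change in an
#' absent sign), continuous with the no-change case.
#'
#' @param s1 Reference score(s), non-negative and finite.
#' @param s2 Later score(s), non-negative and finite. Recycled against `s1`.
#' @return Numeric vector of Contrast values in \eqn{[-1, +1]}.
#' @seealso [tdc()], [contrast_to_factor()], [complement_contrast()]
#' @export
#' @examples
#' contrast(4, 2)    # a score halves: -0.333
#' contrast(20, 3)   # VAS pain 20 mm -> 3 mm: -0.739
#' contrast(5, 0)    # sign fully resolved: -1
contrast <- function(s1, s2) {
  check_scores(s1, "s1")
  check_scores(s2, "s2")
  xy <- recycle2(s1, s2, "s1", "s2")
  s1 <- xy[[1]]; s2 <- xy[[2]]
  total <- s1 + s2
  out <- numeric(length(total))
  pos <- total > 0
  out[pos] <- (s2[pos] - s1[pos]) / total[pos]
  out
}

#' Treatment Duration Control index: mean of Contrast values
#'
#' TDC at an evaluation occasion is the arithmetic mean of the Contrast values
#' of all reference items, \eqn{TDC = \sum_i C_i / n}. Items are equally
#' weighted: every reference item reflects pain or pain-related impairment, so
#' no item has a privileged scale.
#'
#' @param contrasts Numeric vector of Contrast values in \eqn{[-1, +1]}.
#' @return A single TDC value in \eqn{[-1, +1]}.
#' @export
#' @examples
#' tdc(contrast(c(20, 3, 3, 3), c(3, 1, 1, 0)))  # anamnestic subset: -0.685
tdc <- function(contrasts) {
  if (length(contrasts) == 0L) {
    abort("No reference items contribute at this occasion; TDC is undefined.",
          class = "tdcontrol_error_input")
  }
  if (!is.numeric(contrasts) || any(!is.finite(contrasts))) {
    abort("`contrasts` must be finite numeric Contrast values.",
          class = "tdcontrol_error_input")
  }
  if (any(contrasts < -1 - 1e-12 | contrasts > 1 + 1e-12)) {
    abort("Contrast values must lie in [-1, +1].", class = "tdcontrol_error_input")
  }
  mean(contrasts)
}

#' Convert between Contrast values and multiplication factors
#'
#' A Contrast \eqn{C} corresponds to the multiplication factor
#' \eqn{R = (1 + C)/(1 - C)} between the later and the reference score;
#' conversely \eqn{C = (R - 1)/(R + 1)}. The cut-off \eqn{TDC = -0.378}
#' derived from the maximal-severity calibration profile corresponds to an
#' overall factor \eqn{1/T = 0.451}, i.e. a treatment factor \eqn{T = 2.22}.
#'
#' @param c Contrast value(s) strictly inside \eqn{(-1, +1)}.
#' @param r Multiplication factor(s), strictly positive.
#' @return `contrast_to_factor()` returns factors; `factor_to_contrast()`
#'   returns Contrast values.
#' @export
#' @examples
#' contrast_to_factor(-0.378)  # 0.451: scores drop to 45% of the reference
#' factor_to_contrast(0.65)    # -0.212: a 35% decrease
contrast_to_factor <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c))) {
    abort("`c` must be finite numeric.", class = "tdcontrol_error_input")
  }
  if (any(c <= -1 | c >= 1)) {
    abort("The factor is undefined (zero or infinite) at Contrast = -1 or +1.",
          class = "tdcontrol_error_input")
  }
  (1 + c) / (1 - c)
}

#' @rdname contrast_to_factor
#' @export
factor_to_contrast <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    abort("`r` must be finite numeric.", class = "tdcontrol_error_input")
  }
  if (any(r <= 0)) {
    abort("Multiplication factors must be strictly positive.",
          class = "tdcontrol_error_input")
  }
  (r - 1) / (r + 1)
}

#' Contrast for scales with a reversed meaning
#'
#' On instruments where a larger score means better status (e.g. a 0-100
#' health VAS), scores are first transformed to their complements
#' \eqn{S' = S_{max} - S} so that \eqn{C = -1} keeps its meaning of "no
#' impairment left". The Contrast is then computed on the complementary pair.
#'
#' @param s1,s2 First and later score on the reversed scale, in
#'   \eqn{[0, s_{max}]}.
#' @param s_max Maximum value of the scale.
#' @return Numeric Contrast value(s).
#' @export
#' @examples
#' complement_contrast(40, 80, 100)  # health VAS rising 40 -> 80: -0.500
complement_contrast <- function(s1, s2, s_max) {
  check_scores(s1, "s1")
  check_scores(s2, "s2")
  check_scores(s_max, "s_max")
  if (any(s1 > s_max) || any(s2 > s_max)) {
    abort("Scores exceed the scale maximum `s_max`.",
          class = "tdcontrol_error_input")
  }
  contrast(s_max - s1, s_max - s2)
}

#' Contrast when the unimpaired scale maximum is unknown
#'
#' For items such as maximal mouth opening the unimpaired value of an
#' individual patient is a priori unknown. The lower 95% confidence limit of
#' normal values (`s_cl_normal`) is initially taken as the effective scale
#' maximum for the complementary transform; if a later score exceeds it, that
#' score replaces the maximum from then on. `unknown_max_contrast()` is the
#' stateless single-visit form; [unknown_max_timeline()] applies the
#' persisting-maximum update along a patient's sequence of visits.
#'
#' @param s1 Score at the reference visit.
#' @param s2 Score at the later visit.
#' @param s_cl_normal Lower 95% confidence limit of normal (healthy) values,
#'   positive.
#' @return Numeric Contrast value(s).
#' @export
#' @examples
#' unknown_max_contrast(20, 30, 35)  # mouth opening 20 -> 30 mm: -0.500
#' unknown_max_contrast(20, 43, 35)  # 43 mm exceeds the limit: -1
unknown_max_contrast <- function(s1, s2, s_cl_normal) {
  check_scores(s1, "s1")
  check_scores(s2, "s2")
  if (!is.numeric(s_cl_normal) || any(!is.finite(s_cl_normal)) || any(s_cl_normal <= 0)) {
    abort("`s_cl_normal` must be a positive finite number.",
          class = "tdcontrol_error_input")
  }
  eff_max <- pmax(s_cl_normal, s2)
  if (any(s1 > eff_max)) {
    abort("`s1` exceeds the effective scale maximum.",
          class = "tdcontrol_error_input")
  }
  complement_contrast(s1, s2, eff_max)
}

#' @rdname unknown_max_contrast
#' @param s2_seq Scores at successive later visits (chronological).
#' @export
unknown_max_timeline <- function(s1, s2_seq, s_cl_normal) {
  check_scores(s1, "s1")
  check_scores(s2_seq, "s2_seq")
  if (length(s1) != 1L) {
    abort("`s1` must be a single reference score.", class = "tdcontrol_error_input")
  }
  # once a score exceeds the running maximum, the update persists
  eff_max <- pmax(s_cl_normal, cummax(s2_seq))
  if (any(s1 > eff_max)) {
    abort("`s1` exceeds the effective scale maximum.",
          class = "tdcontrol_error_input")
  }
  contrast(eff_max - s1, eff_max - s2_seq)
}

#' Deviation of a Contrast from its base-10 log-ratio approximation
#'
#' Contrast values are numerically similar to \eqn{\log_{10} R} of the
#' corresponding factor over a wide band around zero: for
#' \eqn{|\log_{10} R| \le 0.80} the deviation relative to the mean of the two
#' values stays below 15%. This diagnostic returns that relative deviation,
#' \eqn{|C - \log_{10}R| / |(C + \log_{10}R)/2|}, defined as 0 at \eqn{C = 0}.
#'
#' @param c Contrast value(s) strictly inside \eqn{(-1, +1)}.
#' @return Numeric vector of relative deviations (dimensionless).
#' @export
#' @examples
#' log_ratio_deviation(contrast(4, 2))  # C = -0.333 vs log10(0.5) = -0.301
log_ratio_deviation <- function(c) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c <= -1 | c >= 1)) {
    abort("`c` must lie strictly inside (-1, +1).", class = "tdcontrol_error_input")
  }
  lr <- log10((1 + c) / (1 - c))
  m <- (c + lr) / 2
  out <- numeric(length(c))
  nz <- c != 0
  out[nz] <- abs(c[nz] - lr[nz]) / abs(m[nz])
  out
}
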