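# Input checks shared by the arithmetic layer. All user-facing errors carry the
# class "tdcontrol_error_input" so callers (and the CLI) can map them to exit codes.

check_scores <- function(x, arg) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", arg), class = "tdcontrol_error_input")
  }
  if (any(!is.finite(x))) {
    abort(sprintf("`%s` contains missing or non-finite values.", arg),
          class = "tdcontrol_error_input")
  }
  if (any(x < 0)) {
    abort(sprintf("`%s` contains negative scores; scores are magnitudes >= 0.", arg),
          class = "tdcontrol_error_input")
  }
  invisible(x)
}

recycle2 <- function(a, b, arg_a, arg_b) {
  na <- length(a); nb <- length(b)
  if (na == nb) return(list(a, b))
  if (na == 1L) return(list(rep(a, nb), b))
  if (nb == 1L) return(list(a, rep(b, na)))
  abort(sprintf("`%s` and `%s` must have equal length (or length 1).", arg_a, arg_b),
        class = "tdcontrol_error_input")
}

#' Round a Contrast or TDC value for reporting
#'
#' Reported Contrast and TDC values use three decimals, enough that rounding
#' error is negligible when values are transformed back to multiplication
#' factors. Rounding uses base [round()], i.e. round-half-to-even on the
#' binary representation, which is the spreadsheet convention the reference
#' tables were produced with; internal arithmetic is always full precision.
#'
#' @param x Numeric vector.
#' @param digits Number of decimals (default 3).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_tdc(-0.673913)
round_tdc <- function(x, digits = 3) {
  round(x, digits)
}
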