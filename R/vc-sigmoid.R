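#' Percent loss of hydraulic conductivity
#'
#' PLC relative to the maximum conductivity of the segment:
#' `100 * (1 - K / K_max)`. Values from noisy measurements with
#' `K > K_max` come out negative and are deliberately kept raw —
#' clamping at zero would bias curve fits near the 0 % loss plateau.
#'
#' @param K measured hydraulic conductivity (same units as `K_max`,
#'   typically m^2 MPa^-1 s^-1). Must be non-negative. Vectorised.
#' @param K_max reference (maximum) conductivity, strictly positive.
#' @return PLC in percent. Never exceeds 100 for `K >= 0`.
#' @examples
#' plc(0, 2e-4)      # 100: total loss
#' plc(1e-4, 2e-4)   # 50
#' @export
plc <- function(K, K_max) {
  if (!is.numeric(K_max) || any(!is.finite(K_max)) || any(K_max <= 0)) {
    stop("`K_max` must be a finite, strictly positive conductivity", call. = FALSE)
  }
  if (any(!is.finite(K)) || any(K < 0)) {
    stop("`K` must be finite and non-negative", call. = FALSE)
  }
  100 * (1 - K / K_max)
}

#' Sigmoid vulnerability curve model
#'
#' The two-parameter sigmoid used to describe vulnerability curves:
#' `PLC(P) = 100 / (1 + exp((S / 25) * (P - P50)))`,
#' where `P50` is the xylem pressure inducing 50 % loss of conductivity
#' and `S` is the slope of the curve at its inflexion point
#' (equal to |dPLC/dP| at `P = P50`), in % MPa^-1.
#'
#' @param P xylem pressure in MPa (negative under tension). Vectorised.
#' @param P50 pressure of 50 % conductivity loss, MPa.
#' @param S slope at the inflexion point, % MPa^-1; must be positive.
#' @return PLC in percent, strictly between 0 and 100 and strictly
#'   decreasing in `P`.
#' @examples
#' sigmoid_plc(-3.07, P50 = -3.07, S = 62)  # exactly 50
#' @export
sigmoid_plc <- function(P, P50, S) {
  if (!is.numeric(S) || length(S) != 1L || !is.finite(S) || S <= 0) {
    stop("`S` must be a single positive slope (% MPa^-1)", call. = FALSE)
  }
  100 / (1 + exp((S / 25) * (P - P50)))
}

#' Pressure inducing a given percent loss of conductivity
#'
#' Inverts the sigmoid vulnerability model in closed form:
#' `P_x = P50 + (25 / S) * log((100 - x) / x)`.
#' `x = 12` gives the air-entry point P12, `x = 88` gives P88; the
#' three are symmetric, `P12 - P50 = P50 - P88 = (25/S) * log(88/12)`.
#'
#' @param P50,S sigmoid parameters (see [sigmoid_plc()]).
#' @param x target percent loss, strictly between 0 and 100. Vectorised.
#' @return pressure in MPa; monotone decreasing in `x`.
#' @examples
#' pressure_at_loss(-3.07, 62, 88)  # about -3.873 MPa
#' @export
pressure_at_loss <- function(P50, S, x) {
  if (!is.numeric(S) || any(S <= 0)) {
    stop("`S` must be positive", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= 100)) {
    stop("`x` must lie strictly between 0 and 100 percent", call. = FALSE)
  }
  P50 + (25 / S) * log((100 - x) / x)
}
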