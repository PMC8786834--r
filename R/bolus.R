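#' Arterial input (bolus) function
#'
#' Gamma-variate bolus model for the hyperpolarised pyruvate arriving in the
#' imaging plane. The function is zero before `arrival` and non-negative
#' everywhere; the peak value equals `amplitude`.
#'
#' @param form Functional form; only `"gamma"` (gamma-variate) is provided.
#' @param arrival Arrival time in seconds.
#' @param shape Dimensionless shape parameter of the gamma-variate.
#' @param scale Time scale of the rise/decay in seconds.
#' @param amplitude Peak amplitude in arbitrary signal units.
#' @return An object of class `"bolus_input"`; call it on a time vector via
#'   [bolus_signal()].
#' @export
bolus_input <- function(form = "gamma", arrival = 8, shape = 2.5, scale = 4,
                        amplitude = 1) {
  if (form != "gamma") stop("unsupported bolus form: ", form)
  if (arrival < 0 || shape <= 0 || scale <= 0 || amplitude < 0)
    stop("invalid bolus parameters")
  structure(list(form = form, arrival = arrival, shape = shape,
                 scale = scale, amplitude = amplitude),
            class = "bolus_input")
}

#' Evaluate a bolus input on a time grid
#'
#' @param bolus A [bolus_input()].
#' @param t Numeric vector of times in seconds.
#' @return Non-negative signal values; zero for `t < arrival`.
#' @export
bolus_signal <- function(bolus, t) {
  tt <- t - bolus$arrival
  out <- numeric(length(t))
  pos <- tt > 0
  # normalised so the peak (at tt = shape*scale) equals `amplitude`
  out[pos] <- bolus$amplitude *
    (tt[pos] / (bolus$shape * bolus$scale))^bolus$shape *
    exp(bolus$shape - tt[pos] / bolus$scale)
  out
}
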