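#' Metaplasticity parameters
#'
#' Parameters of the synaptic-drive metaplasticity model. Each plastic
#' synapse contributes a *resistance* value computed by
#' [weight_resistance()] from its current weight and derivative; the
#' per-neuron modification threshold is the tanh-limited, inertia-scaled
#' mean of those values ([modification_threshold()]), and it modulates the
#' STDP amplitudes through [modulate_amplitudes()].
#'
#' @param r Resistance (overall amplitude of the weighting function), >= 0.
#' @param p Precision (curvature of the exponential terms), >= 0.
#' @param inertia Sensitivity of the modification threshold to the mean
#'   resistance, > 0.
#' @param soft_min,soft_max Soft weight limits in mV (uncapped; the hard
#'   clip is separate). Network runs use 0 and 10; the single-synapse
#'   demonstration scales `soft_max` to its 15 mV cap.
#' @return A list of class `meta_params`.
#' @export
meta_params <- function(r = 0.1, p = 0.5, inertia = 0.2, soft_min = 0,
                        soft_max = 10) {
  stopifnot(r >= 0, p >= 0, inertia > 0, soft_min < soft_max)
  structure(list(r = r, p = p, inertia = inertia, soft_min = soft_min,
                 soft_max = soft_max),
            class = "meta_params")
}

#' Map a synaptic derivative into the 0-10 range
#'
#' Affine map of the normal derivative range (-10 to +10) onto 0-10,
#' clipping values outside it: `clip(0.5 * (x + 10), 0, 10)`.
#'
#' @param x Synaptic derivative value(s); must be finite.
#' @export
map_derivative <- function(x) {
  if (any(!is.finite(x))) abort("derivative values must be finite")
  pmin(pmax(0.5 * (x + 10), 0), 10)
}

#' Synaptic weighting function: resistance to weight change
#'
#' For derivative `d` and weight `w` (mV) the weighting function is
#' \deqn{f(d, w) = r e^{p \, m(d)} (w - min) - r e^{p (10 - m(d))} (max - w)}
#' with `m` the [map_derivative()] map. The surface is close to zero over
#' most of the (d, w) plane and rises (falls) exponentially in the corner
#' where drive and weight are both high (both low): positive output opposes
#' further potentiation, negative output opposes further depression.
#'
#' @param d Synaptic derivative(s).
#' @param w Synaptic weight(s), mV.
#' @param params A [meta_params()] list.
#' @export
weight_resistance <- function(d, w, params = meta_params()) {
  if (any(!is.finite(w))) abort("weights must be finite")
  m <- map_derivative(d)
  params$r * exp(params$p * m) * (w - params$soft_min) -
    params$r * exp(params$p * (10 - m)) * (params$soft_max - w)
}

#' Metaplastic modification threshold of a neuron
#'
#' The tanh-limited, inertia-scaled mean of the afferent resistance values:
#' `theta = tanh(inertia * mean(resistances))`, always in (-1, 1). Positive
#' values make subsequent LTP harder and LTD easier; negative values do the
#' opposite.
#'
#' @param resistances Resistance values of the neuron's plastic afferent
#'   synapses; must be non-empty (a neuron without plastic afferents has no
#'   modification threshold).
#' @param inertia Inertia parameter, > 0.
#' @export
modification_threshold <- function(resistances, inertia = 0.2) {
  if (length(resistances) == 0) {
    abort("a neuron with no plastic afferent synapses has no modification threshold")
  }
  tanh(inertia * mean(resistances))
}

#' Modulated LTP/LTD amplitudes
#'
#' Symmetric modulation of the baseline STDP amplitudes by the modification
#' threshold: `A_ltp = A_ltp0 * (1 - theta)`, `A_ltd = A_ltd0 * (1 +
#' theta)`. Both amplitudes stay in 0-2 times their baselines, and the sum
#' of their baseline-relative values is exactly 2.
#'
#' @param theta Modification threshold value(s) in (-1, 1).
#' @param A_ltp0,A_ltd0 Baseline amplitudes.
#' @return A tibble with columns `A_ltp` and `A_ltd`.
#' @examples
#' modulate_amplitudes(c(0, -0.5, 0.9))
#' @export
modulate_amplitudes <- function(theta, A_ltp0 = 0.1, A_ltd0 = 0.12) {
  stopifnot(all(theta > -1), all(theta < 1))
  tibble(theta = theta,
         A_ltp = A_ltp0 - A_ltp0 * theta,
         A_ltd = A_ltd0 + A_ltd0 * theta)
}
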