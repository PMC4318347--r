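#' STDP parameters
#'
#' Temporally asymmetric spike-timing-dependent plasticity with exponential
#' traces and nearest-event (trace reset) semantics. A pre-synaptic spike
#' *arrival* (spike time plus conduction delay) followed by a post-synaptic
#' spike potentiates; a post-synaptic spike followed by a pre-synaptic
#' arrival depresses. Pending changes accumulate in a per-synapse
#' derivative (the synaptic-drive proxy) and are applied to the weights once
#' per `update_interval`:
#' `w <- clip(w + drift + derivative, 0, w_max)`, after which the
#' derivative is retained with factor `decay`.
#'
#' @param A_plus Baseline LTP amplitude (default 0.1).
#' @param A_minus Baseline LTD amplitude (default 0.12).
#' @param tau_plus,tau_minus Trace time constants in ms.
#' @param drift Additive constant applied at every weight update.
#' @param decay Derivative retention factor per update, in (0, 1).
#' @param update_interval Weight-update interval in ms.
#' @return A list of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.1, A_minus = 0.12, tau_plus = 20,
                        tau_minus = 20, drift = 0.01, decay = 0.9,
                        update_interval = 1000) {
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0,
            decay > 0, decay < 1, update_interval >= 1)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, drift = drift, decay = decay,
                 update_interval = update_interval),
            class = "stdp_params")
}

#' Derivative increment for a pre-before-post pairing
#'
#' The increment applied to a synapse's derivative when its post-synaptic
#' neuron fires `dt` ms after the most recent pre-synaptic arrival:
#' `A_ltp * exp(-dt / tau_plus)`.
#'
#' @param dt Time from pre-synaptic arrival to post-synaptic spike (ms,
#'   non-negative).
#' @param A_ltp Current (possibly metaplastically modulated) LTP amplitude.
#' @param tau_plus Trace time constant (ms).
#' @export
stdp_ltp_increment <- function(dt, A_ltp = 0.1, tau_plus = 20) {
  stopifnot(all(dt >= 0))
  A_ltp * exp(-dt / tau_plus)
}

#' Derivative decrement for a post-before-pre pairing
#'
#' The decrement applied when a pre-synaptic spike arrives `dt` ms after the
#' most recent post-synaptic spike: `A_ltd * exp(-dt / tau_minus)`. Zero
#' when the post-synaptic neuron has never fired (`dt = Inf`).
#'
#' @param dt Time from post-synaptic spike to pre-synaptic arrival (ms).
#' @param A_ltd Current LTD amplitude.
#' @param tau_minus Trace time constant (ms).
#' @export
stdp_ltd_decrement <- function(dt, A_ltd = 0.12, tau_minus = 20) {
  stopifnot(all(dt >= 0))
  A_ltd * exp(-dt / tau_minus)
}

#' Apply one weight update to a connection table
#'
#' For every plastic connection the pending derivative (plus the additive
#' drift) is folded into the weight, the result is clipped to `[0, w_max]`,
#' and the derivative is decayed. Non-plastic connections are untouched.
#'
#' @param connections A connection tibble with columns `weight`,
#'   `derivative` and `plastic`.
#' @param params An [stdp_params()] list.
#' @param w_max Hard upper weight limit (mV).
#' @return The updated connection tibble.
#' @examples
#' con <- tibble::tibble(weight = c(5, 9.99, 0.005), derivative = c(0, 5, -5),
#'                       plastic = TRUE)
#' update_weights(con, stdp_params(), w_max = 10)
#' @export
update_weights <- function(connections, params = stdp_params(), w_max = 10) {
  connections %>%
    mutate(
      weight = ifelse(.data$plastic,
                      pmin(pmax(.data$weight + params$drift + .data$derivative, 0), w_max),
                      .data$weight),
      derivative = ifelse(.data$plastic, params$decay * .data$derivative,
                          .data$derivative))
}
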