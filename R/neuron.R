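#' Izhikevich neuron parameter presets
#'
#' Parameters of the two-variable Izhikevich model
#' \deqn{v' = 0.04 v^2 + 5 v + 140 - u + I, \qquad u' = a (b v - u),}
#' with a spike cutoff at \eqn{v \ge 30} mV followed by the reset
#' \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}. Two presets are provided:
#' regular-spiking (RS) excitatory cells (`a = 0.02, b = 0.2, c = -65,
#' d = 8`) and fast-spiking (FS) inhibitory cells (`a = 0.1, b = 0.2,
#' c = -65, d = 2`).
#'
#' @param type `"RS"` (regular spiking, excitatory) or `"FS"` (fast
#'   spiking, inhibitory).
#' @return A list with fields `a` (recovery time scale, 1/ms), `b`
#'   (recovery sensitivity), `c` (reset potential, mV), and `d` (recovery
#'   reset increment).
#' @examples
#' neuron_params("RS")
#' @export
neuron_params <- function(type = c("RS", "FS")) {
  type <- match.arg(type)
  if (type == "RS") {
    list(type = "RS", a = 0.02, b = 0.2, c = -65, d = 8)
  } else {
    list(type = "FS", a = 0.1, b = 0.2, c = -65, d = 2)
  }
}

#' Initial membrane state for a neuron
#'
#' The default potential is the exact resting fixed point of the dynamics,
#' `v = -70` mV with `u = b * v` (both presets share `b = 0.2`, for which
#' \eqn{0.04 v^2 + (5 - b) v + 140 = 0} has the stable root \eqn{v = -70}).
#'
#' @param params A parameter list from [neuron_params()].
#' @param v Initial membrane potential in mV.
#' @return A list with fields `v` (mV) and `u`.
#' @export
neuron_state <- function(params = neuron_params("RS"), v = -70) {
  list(v = v, u = params$b * v)
}

#' Advance a single neuron by one 1 ms tick
#'
#' Integrates the Izhikevich dynamics with two 0.5 ms forward-Euler substeps
#' for `v` and one 1 ms step for `u`. The input current is applied for the
#' whole tick; the 30 mV cutoff is checked (and `v` clamped) after each
#' substep, and the spike reset is applied within the tick, so the returned
#' `v` never exceeds the cutoff.
#'
#' @param state A state list from [neuron_state()].
#' @param params A parameter list from [neuron_params()].
#' @param input Summed synaptic plus external input for this tick, in mV.
#' @return A list with `state` (the advanced state) and `fired` (`TRUE` iff
#'   `v` reached 30 mV during the tick).
#' @examples
#' st <- neuron_state()
#' step_neuron(st, neuron_params("RS"), input = 0)
#' @export
step_neuron <- function(state, params, input) {
  v <- state$v
  u <- state$u
  if (!is.finite(v) || !is.finite(u)) {
    abort(sprintf("non-finite neuron state (v = %s, u = %s)", v, u))
  }
  if (!is.finite(input)) abort("non-finite input current")
  fired <- FALSE
  for (sub in 1:2) {
    v <- v + 0.5 * (0.04 * v * v + 5 * v + 140 - u + input)
    if (v >= 30) {
      v <- 30
      fired <- TRUE
      break
    }
  }
  u <- u + params$a * (params$b * v - u)
  if (fired) {
    v <- params$c
    u <- u + params$d
  }
  if (!is.finite(v) || !is.finite(u)) {
    abort(sprintf("neuron state blew up (v = %s, u = %s)", v, u))
  }
  list(state = list(v = v, u = u), fired = fired)
}

#' Spike-latency curve of a fan-in circuit
#'
#' Three input neurons fire simultaneously at frame start; their spikes
#' reach a single RS output cell after the given conduction delays. The
#' combined synaptic weight is swept and the output's firing time (measured
#' from the input firing, so conduction delays are included) is recorded at
#' each sweep value. Near threshold the integrator dynamics produce a long
#' spike latency which shrinks monotonically as the combined weight grows.
#'
#' The combined weight is split across the three inputs proportionally to
#' `base_weights`. The defaults place the firing threshold just below
#' 17 mV so the near-threshold latency effect is visible over the default
#' sweep; pass `seed` to draw the delays uniformly from `delay_range`
#' instead.
#'
#' @param sweep Combined-weight values (mV) to evaluate. Must be non-empty.
#' @param delays Integer conduction delays (ms) for the three inputs.
#' @param base_weights Relative weights used to split the combined weight.
#' @param frame_ms Frame length per sweep value.
#' @param seed If non-`NULL`, delays are drawn uniformly from `delay_range`.
#' @param delay_range Range used when `seed` is given.
#' @return A tibble with `combined_weight` and `firing_time` (ms, `NA` when
#'   the output never fires).
#' @examples
#' spike_latency_curve(sweep = c(17, 30))
#' @export
spike_latency_curve <- function(sweep = 17:30, delays = c(10, 10, 11),
                                base_weights = c(8, 8, 2), frame_ms = 100,
                                seed = NULL, delay_range = c(1, 20)) {
  if (length(sweep) == 0) abort("`sweep` must contain at least one combined weight")
  if (length(delays) != 3 || length(base_weights) != 3) {
    abort("`delays` and `base_weights` must each have length 3")
  }
  if (!is.null(seed)) {
    delays <- withr::with_seed(seed, sample(delay_range[1]:delay_range[2], 3, replace = TRUE))
  }
  split <- base_weights / sum(base_weights)
  rs <- neuron_params("RS")
  firing_time <- vapply(sweep, function(w) {
    ft <- run_frames_cpp(
      pre = 1:3, post = rep(4L, 3), delay = as.integer(delays),
      weight = w * split,
      pa = rep(rs$a, 4), pb = rep(rs$b, 4), pc = rep(rs$c, 4), pd = rep(rs$d, 4),
      force_off = rep(0L, 3), force_neuron = 1:3,
      cur_off = integer(), cur_neuron = integer(), cur_amp = numeric(),
      trial_idx = integer(), trial_off = integer(), trial_neuron = integer(),
      trial_amp = numeric(),
      frame_ms = as.integer(frame_ms), n_trials = 1L, target = 4L)
    if (ft[1] < 0) NA_real_ else as.numeric(ft[1])
  }, numeric(1))
  tibble(combined_weight = as.numeric(sweep), firing_time = firing_time)
}
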