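#' Toy circuit presets
#'
#' Mechanistic workbench circuits, all built from RS cells:
#'
#' * `single_synapse_circuit()`: two neurons joined by one plastic synapse
#'   (delay 1 ms, initial weight 6 mV, hard cap 15 mV) — the single-synapse
#'   regulation demonstration.
#' * `fan_in_circuit()`: three input neurons converging on one output
#'   (delays 10/10/15 ms, weights 8/8/6 mV, cap 10 mV) — the synaptic-drive
#'   reversal demonstration.
#' * `png_chain_circuit()`: six neurons; inputs 1-3 converge on neuron 4 as
#'   in `fan_in_circuit()`, neuron 4 projects to neuron 6 (the `chain`
#'   connection, variable delay) and neuron 5 projects to neuron 6 with a
#'   1 ms delay — the input-space workbench. All weights default to the
#'   10 mV cap, so neuron 4 needs at least two near-coincident inputs to
#'   fire.
#'
#' @param delay,weight,w_max Single-synapse circuit parameters.
#' @return A `spiking_network`.
#' @export
single_synapse_circuit <- function(delay = 1, weight = 6, w_max = 15) {
  make_circuit(2, tibble(pre = 1L, post = 2L, delay = delay, weight = weight),
               w_max = w_max)
}

#' @rdname single_synapse_circuit
#' @param delays,weights Per-connection delays (ms) and initial weights
#'   (mV) for the three input connections.
#' @export
fan_in_circuit <- function(delays = c(10, 10, 15), weights = c(8, 8, 6),
                           w_max = 10) {
  make_circuit(4, tibble(pre = 1:3, post = 4L, delay = delays, weight = weights),
               w_max = w_max)
}

#' @rdname single_synapse_circuit
#' @param input_delays,input_weights Parameters of the three input
#'   connections onto neuron 4.
#' @param chain_delay Conduction delay of the 4-to-6 connection (ms).
#' @param chain_weight,lateral_weight Weights of the 4-to-6 and 5-to-6
#'   connections (mV).
#' @param lateral_delay Conduction delay of the 5-to-6 connection (ms).
#' @export
png_chain_circuit <- function(input_delays = c(10, 10, 15),
                              input_weights = c(10, 10, 10),
                              chain_delay = 2, chain_weight = 10,
                              lateral_delay = 1, lateral_weight = 10,
                              w_max = 10) {
  make_circuit(6, tibble(
    pre = c(1:3, 4L, 5L), post = c(rep(4L, 3), 6L, 6L),
    delay = c(input_delays, chain_delay, lateral_delay),
    weight = c(input_weights, chain_weight, lateral_weight)),
    w_max = w_max)
}

burst_schedule <- function(duration_s, bursts_per_s = 2, pulses_per_burst = 6,
                           intra_burst_ms = 12, pre_lead_ms = 5) {
  burst_starts <- seq(0, by = 1000 / bursts_per_s, length.out = bursts_per_s)
  pulse_off <- seq(0, by = intra_burst_ms, length.out = pulses_per_burst)
  within_s <- as.vector(outer(pulse_off, burst_starts, `+`))
  pre_t <- as.vector(outer(within_s, (seq_len(duration_s) - 1) * 1000, `+`))
  tibble(
    time = as.integer(c(pre_t, pre_t + pre_lead_ms)),
    neuron = rep(c(1L, 2L), each = length(pre_t)),
    amplitude = NA_real_, kind = "spike") %>%
    arrange(.data$time, .data$neuron)
}

#' Single-synapse regulation demonstration
#'
#' Two RS neurons joined by one plastic synapse are both driven directly:
#' in every second, `bursts_per_s` evenly spaced bursts of
#' `pulses_per_burst` pulses are delivered, with each pre-synaptic pulse
#' leading the post-synaptic pulse by `pre_lead_ms` ms — a sustained
#' positive synaptic drive. Without metaplasticity the additive STDP rule
#' pushes the weight to the hard cap and keeps it there; with
#' metaplasticity the rising modification threshold throttles LTP and
#' boosts LTD so the weight settles below the cap.
#'
#' @param duration_s Run length in seconds.
#' @param metaplasticity Enable the metaplastic modulation.
#' @param meta A [meta_params()] list; the demonstration defaults use
#'   `r = 0.1, p = 0.05` with soft limits matching the 15 mV cap.
#' @param stdp An [stdp_params()] list.
#' @param circuit The two-neuron circuit.
#' @param bursts_per_s,pulses_per_burst,intra_burst_ms,pre_lead_ms Drive
#'   schedule knobs (see Details in the vignette).
#' @return A `synapse_demo` tibble with per-second `derivative`, `theta`
#'   and `weight` (the t = 0 row holds the initial state).
#' @export
run_single_synapse_demo <- function(duration_s = 100, metaplasticity = TRUE,
                                    meta = meta_params(r = 0.1, p = 0.05,
                                                       soft_min = 0, soft_max = 15),
                                    stdp = stdp_params(),
                                    circuit = single_synapse_circuit(),
                                    bursts_per_s = 2, pulses_per_burst = 6,
                                    intra_burst_ms = 12, pre_lead_ms = 5) {
  sched <- burst_schedule(duration_s, bursts_per_s, pulses_per_burst,
                          intra_burst_ms, pre_lead_ms)
  run <- run_network(circuit, duration_s * 1000, inputs = sched,
                     plasticity = TRUE, metaplasticity = metaplasticity,
                     stdp = stdp, meta = meta, guard_hz = 0,
                     record_series = TRUE)
  out <- run$series$connections %>%
    filter(.data$connection == 1) %>%
    select("second", "derivative", "weight") %>%
    left_join(filter(run$series$neurons, .data$neuron == 2) %>%
                select("second", "theta"),
              by = "second") %>%
    select("second", "derivative", "theta", "weight")
  out <- bind_rows(
    tibble(second = 0, derivative = 0, theta = 0,
           weight = circuit$connections$weight[1]),
    out)
  structure(out, metaplasticity = metaplasticity, w_max = circuit$w_max,
            class = c("synapse_demo", class(out)))
}

#' Synaptic-drive reversal demonstration
#'
#' The three inputs of a [fan_in_circuit()] are fired together at
#' `rate_hz` while STDP adapts the three convergent connections. With the
#' default delays (10, 10, 15 ms) and weights (8, 8, 6 mV) the output
#' initially fires *after* the late arrival on connection C, so C
#' potentiates along with A and B; as A and B approach saturation the
#' output's spike latency shrinks, its firing time migrates backwards past
#' C's arrival, the drive on C reverses sign, and C's weight falls — an
#' interior maximum in its weight series.
#'
#' @param duration_s Training length in seconds.
#' @param rate_hz Stimulation rate of the three inputs (Hz).
#' @param circuit A [fan_in_circuit()].
#' @param plasticity Enable STDP (disable to verify the frozen contract).
#' @param metaplasticity Enable metaplastic modulation (off by default;
#'   the reversal is a pure STDP + spike-latency effect).
#' @param stdp,meta Parameter lists.
#' @return A `reversal_demo` tibble with per-second `weight` for
#'   connections `A`, `B`, `C` (t = 0 rows hold the initial weights).
#' @export
run_weight_reversal_demo <- function(duration_s = 60, rate_hz = 5,
                                     circuit = fan_in_circuit(),
                                     plasticity = TRUE, metaplasticity = FALSE,
                                     stdp = stdp_params(),
                                     meta = meta_params()) {
  period <- 1000 / rate_hz
  n_frames <- duration_s * rate_hz
  t0 <- rep((seq_len(n_frames) - 1) * period, each = 3)
  ev <- tibble(time = as.integer(t0), neuron = rep(1:3, n_frames),
               amplitude = NA_real_, kind = "spike") %>%
    arrange(.data$time, .data$neuron)
  run <- run_network(circuit, duration_s * 1000, inputs = ev,
                     plasticity = plasticity, metaplasticity = metaplasticity,
                     stdp = stdp, meta = meta, guard_hz = 0,
                     record_series = TRUE)
  labels <- c("A", "B", "C")
  out <- run$series$connections %>%
    mutate(connection = labels[.data$connection]) %>%
    select("second", "connection", "weight")
  out <- bind_rows(
    tibble(second = 0, connection = labels,
           weight = circuit$connections$weight),
    out) %>%
    arrange(.data$second, .data$connection)
  structure(out, class = c("reversal_demo", class(out)))
}

isr_grid <- function(timing_range) {
  lo <- min(timing_range)
  hi <- max(timing_range)
  grid <- tidyr::expand_grid(dt12 = (lo - hi):(hi - lo),
                             dt23 = (lo - hi):(hi - lo))
  grid %>%
    mutate(t2 = pmax(lo, lo - .data$dt12, lo + .data$dt23),
           t1 = .data$t2 + .data$dt12,
           t3 = .data$t2 - .data$dt23) %>%
    filter(.data$t1 <= hi, .data$t2 <= hi, .data$t3 <= hi)
}

eval_frames <- function(circuit, forced, n_trials, frame_ms, target,
                        noise = NULL) {
  nn <- circuit$neurons
  con <- circuit$connections
  if (is.null(noise)) {
    # deterministic frames: every trial is the same pure function of the
    # schedule, so one frame stands for all of them
    ft <- run_frames_cpp(
      pre = as.integer(con$pre), post = as.integer(con$post),
      delay = as.integer(con$delay), weight = con$weight,
      pa = nn$a, pb = nn$b, pc = nn$c, pd = nn$d,
      force_off = as.integer(forced$offset), force_neuron = as.integer(forced$neuron),
      cur_off = integer(), cur_neuron = integer(), cur_amp = numeric(),
      trial_idx = integer(), trial_off = integer(), trial_neuron = integer(),
      trial_amp = numeric(),
      frame_ms = as.integer(frame_ms), n_trials = 1L, target = as.integer(target))
    rep(ft, n_trials)
  } else {
    run_frames_cpp(
      pre = as.integer(con$pre), post = as.integer(con$post),
      delay = as.integer(con$delay), weight = con$weight,
      pa = nn$a, pb = nn$b, pc = nn$c, pd = nn$d,
      force_off = as.integer(forced$offset), force_neuron = as.integer(forced$neuron),
      cur_off = integer(), cur_neuron = integer(), cur_amp = numeric(),
      trial_idx = as.integer(noise$trial), trial_off = as.integer(noise$offset),
      trial_neuron = as.integer(noise$neuron), trial_amp = noise$amplitude,
      frame_ms = as.integer(frame_ms), n_trials = as.integer(n_trials),
      target = as.integer(target))
  }
}

isr_noise <- function(noise_rate_hz, n_neurons, n_trials, frame_ms, seed) {
  if (noise_rate_hz <= 0) return(NULL)
  withr::with_seed(seed, {
    counts <- rpois(n_trials * n_neurons, noise_rate_hz * frame_ms / 1000)
    idx <- rep(seq_len(n_trials * n_neurons), counts)
    tibble(trial = (idx - 1) %/% n_neurons + 1,
           neuron = (idx - 1) %% n_neurons + 1,
           offset = floor(runif(sum(counts)) * frame_ms),
           amplitude = 20)
  })
}

#' Input-space response of a target neuron
#'
#' Varies the firing times of three input neurons over `timing_range` and
#' records, for every timing combination, whether the target fires
#' consistently (in at least `hit_min` of `n_trials` independent test
#' frames; each trial starts from the resting state). Because shifting all
#' three firing times by a constant leaves the spatio-temporal pattern --
#' and hence the response -- unchanged, the three-dimensional timing cube
#' is reported in difference coordinates `dt12 = t1 - t2` and
#' `dt23 = t2 - t3`; each grid cell is evaluated at its earliest
#' realization within the range.
#'
#' @param circuit A `spiking_network`, e.g. [png_chain_circuit()].
#' @param target Target neuron id.
#' @param inputs Ids of the three varied input neurons.
#' @param timing_range Allowed firing times (ms), default 0-20.
#' @param n_trials Test frames per timing combination.
#' @param frame_ms Frame length (ms).
#' @param hit_min Minimum number of firing frames for a cell to count as
#'   active.
#' @param extra_forced Optional tibble (`offset`, `neuron`) of additional
#'   forced firings applied in every frame (e.g. a helper neuron at a
#'   fixed offset).
#' @param noise_rate_hz Optional per-neuron Poisson background rate inside
#'   each frame (adds trial-to-trial variability; 0 = deterministic
#'   frames).
#' @param seed Seed for the frame noise.
#' @return An `isr` tibble: `dt12`, `dt23`, the realized `t1`, `t2`, `t3`,
#'   `n_fired` and `active`.
#' @export
input_space_response <- function(circuit, target = 4, inputs = c(1, 2, 3),
                                 timing_range = 0:20, n_trials = 400,
                                 frame_ms = 250, hit_min = 100,
                                 extra_forced = NULL, noise_rate_hz = 0,
                                 seed = 1) {
  if (length(unique(range(timing_range))) < 2) {
    abort("degenerate `timing_range`: need at least two distinct timings")
  }
  if (length(inputs) != 3) abort("exactly three varied inputs are required")
  grid <- isr_grid(timing_range)
  noise <- isr_noise(noise_rate_hz, nrow(circuit$neurons), n_trials, frame_ms, seed)
  n_fired <- vapply(seq_len(nrow(grid)), function(k) {
    forced <- tibble(offset = c(grid$t1[k], grid$t2[k], grid$t3[k]),
                     neuron = inputs)
    if (!is.null(extra_forced)) forced <- bind_rows(forced, extra_forced)
    ft <- eval_frames(circuit, forced, n_trials, frame_ms, target, noise)
    sum(ft >= 0)
  }, numeric(1))
  out <- grid %>%
    mutate(n_fired = as.integer(n_fired), active = n_fired >= hit_min)
  structure(out, target = target, n_trials = n_trials, hit_min = hit_min,
            frame_ms = frame_ms,
            class = c("isr", class(out)))
}

#' Latency optimization of the input space
#'
#' For each chain delay, computes the input space of the chain target
#' (neuron 6 of [png_chain_circuit()]) twice: once at the default weights
#' (non-optimized) and once allowing the weight of the first input
#' connection (1-to-4) to be re-chosen per timing combination from
#' `weight_steps` (optimized) — shifting neuron 4's firing time through
#' its spike latency until it is congruent with the chain and lateral
#' delays. A cell is active in the optimized map iff *any* step (or the
#' default weight) yields consistent firing, so the optimized active set
#' is a superset of the non-optimized one by construction. Neuron 5 is
#' fired at a fixed offset in every frame.
#'
#' @param chain_delays Conduction delays (ms) of the 4-to-6 connection to
#'   evaluate.
#' @param weight_steps Candidate weights (mV) for the 1-to-4 connection;
#'   ten steps at 1 mV spacing by default. Empty = no optimization.
#' @param target Target neuron id.
#' @param inputs The three varied input neurons.
#' @param helper_offset,helper_neuron Fixed forced firing applied in every
#'   frame.
#' @param timing_range,n_trials,frame_ms,hit_min,noise_rate_hz,seed As in
#'   [input_space_response()].
#' @param ... Passed to [png_chain_circuit()] (e.g. `input_delays`).
#' @return A `latency_optimization` tibble with one row per (chain delay,
#'   grid cell): `active_default`, `active_optimized`, `best_weight` (the
#'   first step that worked, `NA` if none beyond the default).
#' @export
optimize_latency <- function(chain_delays = c(2, 3, 4, 5),
                             weight_steps = seq(1, 10),
                             target = 6, inputs = c(1, 2, 3),
                             helper_offset = 19, helper_neuron = 5,
                             timing_range = 0:20, n_trials = 400,
                             frame_ms = 250, hit_min = 100,
                             noise_rate_hz = 0, seed = 1, ...) {
  helper <- tibble(offset = helper_offset, neuron = as.integer(helper_neuron))
  out <- lapply(chain_delays, function(cd) {
    circuit <- png_chain_circuit(chain_delay = cd, ...)
    base <- input_space_response(circuit, target = target, inputs = inputs,
                                 timing_range = timing_range, n_trials = n_trials,
                                 frame_ms = frame_ms, hit_min = hit_min,
                                 extra_forced = helper,
                                 noise_rate_hz = noise_rate_hz, seed = seed)
    noise <- isr_noise(noise_rate_hz, nrow(circuit$neurons), n_trials, frame_ms, seed)
    w14 <- which(circuit$connections$pre == inputs[1] &
                   circuit$connections$post == 4)
    best <- rep(NA_real_, nrow(base))
    opt <- base$active
    for (k in seq_len(nrow(base))) {
      if (opt[k]) next
      forced <- bind_rows(
        tibble(offset = c(base$t1[k], base$t2[k], base$t3[k]), neuron = inputs),
        helper)
      for (w in weight_steps) {
        c2 <- circuit
        c2$connections$weight[w14] <- w
        ft <- eval_frames(c2, forced, n_trials, frame_ms, target, noise)
        if (sum(ft >= 0) >= hit_min) {
          opt[k] <- TRUE
          best[k] <- w
          break
        }
      }
    }
    base %>%
      mutate(chain_delay = cd, .before = 1) %>%
      dplyr::rename(active_default = "active") %>%
      mutate(active_optimized = opt, best_weight = best) %>%
      select(-"n_fired")
  })
  out <- bind_rows(out)
  structure(out, class = c("latency_optimization", class(out)))
}
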