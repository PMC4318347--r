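#' Poisson background input
#'
#' Independent Poisson event trains, one per neuron. Each event is a
#' super-threshold 20 mV current pulse at its tick (an RS cell at rest
#' fires a few ms after such a pulse).
#'
#' @param rate_hz Event rate per neuron (Hz), >= 0.
#' @param n_neurons Number of neurons (events target ids `1:n_neurons`).
#' @param duration_ms Duration covered (ms).
#' @param seed Integer seed; the stream is reproducible from it.
#' @param amplitude Pulse amplitude (mV).
#' @param t_start Absolute start time (ms) of the covered window.
#' @return An event tibble (`time`, `neuron`, `amplitude`,
#'   `kind = "current"`) sorted by time.
#' @export
poisson_background <- function(rate_hz, n_neurons, duration_ms, seed,
                               amplitude = 20, t_start = 0) {
  stopifnot(rate_hz >= 0, n_neurons >= 1, duration_ms >= 1)
  if (rate_hz == 0) {
    return(tibble(time = integer(), neuron = integer(),
                  amplitude = numeric(), kind = character()))
  }
  withr::with_seed(seed, {
    counts <- rpois(n_neurons, rate_hz * duration_ms / 1000)
    neuron <- rep(seq_len(n_neurons), counts)
    time <- t_start + floor(runif(sum(counts)) * duration_ms)
    tibble(time = as.integer(time), neuron = neuron,
           amplitude = amplitude, kind = "current") %>%
      arrange(.data$time, .data$neuron)
  })
}

#' The ascending stimulus pattern
#'
#' A spatio-temporal pattern of forty firing events in the first 40 ms of
#' each stimulus frame: event `k` fires `neuron_ids[k]` at offset `k` ms,
#' so both offsets and neuron ids ascend strictly.
#'
#' @param neuron_ids Exactly 40 distinct neuron ids (sorted ascending
#'   internally). Defaults to the 40 lowest excitatory ids.
#' @param frame_period Frame period in ms (200 for a 5 Hz stimulus, 250
#'   for 4 Hz, 1000 for 1 Hz).
#' @return A `stimulus_pattern`: an events tibble (`offset`, `neuron`)
#'   with a `frame_period` attribute.
#' @examples
#' ascending_pattern(frame_period = 250)
#' @export
ascending_pattern <- function(neuron_ids = 1:40, frame_period = 200) {
  if (length(neuron_ids) != 40 || anyDuplicated(neuron_ids) > 0) {
    abort("`neuron_ids` must be exactly 40 distinct ids")
  }
  if (frame_period <= 40) abort("`frame_period` must exceed the 40 ms pattern span")
  events <- tibble(offset = 1:40, neuron = as.integer(sort(neuron_ids)))
  structure(events, frame_period = frame_period,
            class = c("stimulus_pattern", class(events)))
}

#' Tile a stimulus pattern into an absolute event stream
#'
#' Repeats the pattern's events every frame for the requested number of
#' frames, as forced-spike events (the stimulated neurons emit a spike at
#' exactly their offset in every frame).
#'
#' @param pattern A [ascending_pattern()] (or compatible) pattern.
#' @param n_frames Number of frames to tile.
#' @param t_start Absolute time (ms) of the first frame's start.
#' @return An event tibble (`time`, `neuron`, `amplitude`, `kind =
#'   "spike"`).
#' @export
pattern_events <- function(pattern, n_frames, t_start = 0) {
  period <- attr(pattern, "frame_period")
  if (is.null(period)) abort("`pattern` must carry a frame_period attribute")
  stopifnot(n_frames >= 1)
  ev <- as_tibble(pattern)
  tibble(
    time = as.integer(t_start + rep((seq_len(n_frames) - 1) * period, each = nrow(ev)) +
                        rep(ev$offset, n_frames)),
    neuron = rep(ev$neuron, n_frames),
    amplitude = NA_real_,
    kind = "spike")
}

#' Three-phase experimental protocol
#'
#' Runs maturation, training, and probing on one network. Maturation
#' exposes the network to Poisson background only, with STDP on and
#' metaplasticity off. Training superimposes the stimulus pattern at
#' `training_rate_hz` on the background, with metaplasticity switched per
#' the `metaplasticity` argument. Probing presents the pattern at
#' `probing_rate_hz` with background and *all plasticity frozen* (the
#' probe measures responses, it does not learn). Snapshots of the network
#' are taken at each phase boundary.
#'
#' @param network A freshly built `spiking_network`.
#' @param pattern A stimulus pattern whose `frame_period` attribute is
#'   ignored here; the training/probing frame periods are derived from the
#'   rates (1000 / rate).
#' @param maturation_s,training_s,probing_s Phase durations in seconds.
#'   Phases with zero duration are skipped.
#' @param metaplasticity Enable metaplastic modulation during training.
#' @param background_rate_hz Poisson background rate, per neuron, used in
#'   all phases.
#' @param training_rate_hz,probing_rate_hz Stimulus presentation rates.
#' @param stdp,meta Parameter lists.
#' @param seeds List with integer elements `maturation`, `training`,
#'   `probing` seeding the background streams of each phase.
#' @param guard_hz Runaway-firing guard passed to [run_network()].
#' @param record_maturation_raster Keep the (large) maturation raster.
#' @return A list of class `protocol_run` with `snapshots` (networks after
#'   each phase), `rasters`, and `diagnostics` per phase.
#' @export
run_protocol <- function(network, pattern,
                         maturation_s = 1200, training_s = 180, probing_s = 100,
                         metaplasticity = TRUE,
                         background_rate_hz = 1,
                         training_rate_hz = 5, probing_rate_hz = 4,
                         stdp = stdp_params(), meta = meta_params(),
                         seeds = list(maturation = 1, training = 2, probing = 3),
                         guard_hz = 100,
                         record_maturation_raster = FALSE) {
  if ((training_s > 0 || probing_s > 0) && is.null(pattern)) {
    abort("training/probing phases need a stimulus pattern")
  }
  n <- nrow(network$neurons)
  snapshots <- list()
  rasters <- list()
  diagnostics <- list()

  if (maturation_s > 0) {
    bg <- poisson_background(background_rate_hz, n, maturation_s * 1000,
                             seed = seeds$maturation, t_start = network$time)
    run <- run_network(network, maturation_s * 1000, inputs = bg,
                       plasticity = TRUE, metaplasticity = FALSE,
                       stdp = stdp, meta = meta, guard_hz = guard_hz,
                       record_raster = record_maturation_raster)
    network <- run$network
    snapshots$matured <- network
    rasters$maturation <- run$raster
    diagnostics$maturation <- run$diagnostics
  }

  if (training_s > 0) {
    period <- 1000 / training_rate_hz
    n_frames <- training_s * training_rate_hz
    pat <- structure(as_tibble(pattern), frame_period = period)
    ev <- bind_rows(
      pattern_events(pat, n_frames, t_start = network$time),
      poisson_background(background_rate_hz, n, training_s * 1000,
                         seed = seeds$training, t_start = network$time))
    run <- run_network(network, training_s * 1000, inputs = ev,
                       plasticity = TRUE, metaplasticity = metaplasticity,
                       stdp = stdp, meta = meta, guard_hz = guard_hz)
    network <- run$network
    snapshots$trained <- network
    rasters$training <- run$raster
    diagnostics$training <- run$diagnostics
  }

  if (probing_s > 0) {
    period <- 1000 / probing_rate_hz
    n_frames <- probing_s * probing_rate_hz
    pat <- structure(as_tibble(pattern), frame_period = period)
    ev <- bind_rows(
      pattern_events(pat, n_frames, t_start = network$time),
      poisson_background(background_rate_hz, n, probing_s * 1000,
                         seed = seeds$probing, t_start = network$time))
    run <- run_network(network, probing_s * 1000, inputs = ev,
                       plasticity = FALSE, metaplasticity = FALSE,
                       stdp = stdp, meta = meta, guard_hz = guard_hz)
    network <- run$network
    snapshots$probed <- network
    raster <- run$raster
    attr(raster, "t_start") <- network$time - probing_s * 1000
    attr(raster, "frame_period") <- period
    attr(raster, "n_frames") <- n_frames
    rasters$probing <- raster
    diagnostics$probing <- run$diagnostics
  }

  structure(list(snapshots = snapshots, rasters = rasters,
                 diagnostics = diagnostics),
            class = "protocol_run")
}
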