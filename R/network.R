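#' Network configuration
#'
#' Defaults follow the standard 1000-neuron recurrent topology: 800
#' regular-spiking excitatory and 200 fast-spiking inhibitory cells, each
#' with a fan-out of 100 randomly chosen post-synaptic targets. Excitatory
#' connections get integer conduction delays drawn uniformly from
#' `1:delay_max` ms and start at +3.0 mV; inhibitory connections have a
#' 1 ms delay, start at -2.0 mV, target excitatory neurons only, and are
#' non-plastic. Excitatory weights are hard-clipped to `[0, w_max]`.
#'
#' @param n_neurons Total number of neurons.
#' @param n_excitatory Number of excitatory (RS) neurons; ids `1:n_excitatory`.
#' @param fan_out Outgoing connections per neuron.
#' @param delay_max Maximum excitatory conduction delay (ms).
#' @param w_init_exc,w_init_inh Initial weights (mV).
#' @param w_max Hard upper limit for excitatory weights (mV).
#' @param seed Integer seed for the topology RNG.
#' @return A list of class `network_config`.
#' @export
network_config <- function(n_neurons = 1000, n_excitatory = 800,
                           fan_out = 100, delay_max = 20,
                           w_init_exc = 3.0, w_init_inh = -2.0,
                           w_max = 10.0, seed = 1) {
  stopifnot(n_excitatory < n_neurons, fan_out < n_neurons, delay_max >= 1)
  structure(list(n_neurons = n_neurons, n_excitatory = n_excitatory,
                 fan_out = fan_out, delay_max = delay_max,
                 w_init_exc = w_init_exc, w_init_inh = w_init_inh,
                 w_max = w_max, seed = seed),
            class = "network_config")
}

new_network <- function(neurons, connections, w_max, config = NULL) {
  structure(list(
    neurons = neurons,
    connections = connections,
    w_max = w_max,
    config = config,
    time = 0L,
    pending = tibble(synapse = integer(), time = integer())),
    class = "spiking_network")
}

#' @export
print.spiking_network <- function(x, ...) {
  cat(sprintf("<spiking_network> %d neurons (%d excitatory), %d connections, t = %d ms\n",
              nrow(x$neurons), sum(x$neurons$excitatory),
              nrow(x$connections), x$time))
  invisible(x)
}

#' Build a recurrent spiking network
#'
#' Wires the topology described by a [network_config()]: every neuron gets
#' `fan_out` distinct post-synaptic targets (no self-connections, no
#' duplicated (pre, post) pairs; inhibitory neurons target excitatory
#' neurons only). The result is reproducible from the config seed.
#'
#' @param config A [network_config()].
#' @return A `spiking_network` object holding a `neurons` tibble (id, type,
#'   Izhikevich parameters, membrane state, modification threshold) and a
#'   `connections` tibble (id, pre, post, delay, weight, derivative,
#'   plastic).
#' @examples
#' net <- build_network(network_config(n_neurons = 50, n_excitatory = 40,
#'                                     fan_out = 10, seed = 1))
#' net
#' @export
build_network <- function(config = network_config()) {
  n <- config$n_neurons
  ne <- config$n_excitatory
  if (config$fan_out > ne) {
    abort("infeasible fan-out: inhibitory neurons can only target excitatory neurons")
  }
  rs <- neuron_params("RS")
  fs <- neuron_params("FS")
  excitatory <- seq_len(n) <= ne
  neurons <- tibble(
    id = seq_len(n),
    type = ifelse(excitatory, "RS", "FS"),
    excitatory = excitatory,
    a = ifelse(excitatory, rs$a, fs$a),
    b = ifelse(excitatory, rs$b, fs$b),
    c = ifelse(excitatory, rs$c, fs$c),
    d = ifelse(excitatory, rs$d, fs$d),
    v = -65,
    u = ifelse(excitatory, rs$b, fs$b) * -65,
    theta = 0,
    last_fire = -Inf)

  wire <- withr::with_seed(config$seed, {
    lapply(seq_len(n), function(i) {
      candidates <- if (excitatory[i]) setdiff(seq_len(n), i) else setdiff(seq_len(ne), i)
      if (length(candidates) < config$fan_out) {
        abort(sprintf("infeasible fan-out for neuron %d", i))
      }
      targets <- sample(candidates, config$fan_out)
      delays <- if (excitatory[i]) {
        sample(seq_len(config$delay_max), config$fan_out, replace = TRUE)
      } else {
        rep(1L, config$fan_out)
      }
      list(post = targets, delay = as.integer(delays))
    })
  })
  connections <- tibble(
    pre = rep(seq_len(n), each = config$fan_out),
    post = unlist(lapply(wire, `[[`, "post")),
    delay = unlist(lapply(wire, `[[`, "delay")),
    weight = ifelse(rep(excitatory, each = config$fan_out),
                    config$w_init_exc, config$w_init_inh),
    derivative = 0,
    plastic = rep(excitatory, each = config$fan_out),
    last_arrival = -Inf) %>%
    mutate(id = dplyr::row_number(), .before = 1)
  new_network(neurons, connections, config$w_max, config)
}

#' Build a small feed-forward circuit by hand
#'
#' Workbench constructor for toy circuits: all neurons are RS cells unless
#' listed in `inhibitory`, and every connection is taken as given (plastic
#' iff its pre-synaptic neuron is excitatory).
#'
#' @param n_neurons Number of neurons (ids `1:n_neurons`).
#' @param connections A data frame with columns `pre`, `post`, `delay`,
#'   `weight` (one row per connection).
#' @param w_max Hard upper weight limit (mV).
#' @param inhibitory Optional integer ids of FS cells.
#' @return A `spiking_network`.
#' @export
make_circuit <- function(n_neurons, connections, w_max = 10, inhibitory = integer()) {
  rs <- neuron_params("RS")
  fs <- neuron_params("FS")
  excitatory <- !(seq_len(n_neurons) %in% inhibitory)
  neurons <- tibble(
    id = seq_len(n_neurons),
    type = ifelse(excitatory, "RS", "FS"),
    excitatory = excitatory,
    a = ifelse(excitatory, rs$a, fs$a),
    b = ifelse(excitatory, rs$b, fs$b),
    c = ifelse(excitatory, rs$c, fs$c),
    d = ifelse(excitatory, rs$d, fs$d),
    v = -70,
    u = ifelse(excitatory, rs$b, fs$b) * -70,
    theta = 0,
    last_fire = -Inf)
  connections <- as_tibble(connections) %>%
    mutate(id = dplyr::row_number(), .before = 1) %>%
    mutate(delay = as.integer(.data$delay),
           derivative = 0,
           plastic = excitatory[.data$pre],
           last_arrival = -Inf)
  new_network(neurons, connections, w_max)
}

validate_inputs <- function(inputs, n_neurons) {
  if (is.null(inputs)) {
    return(tibble(time = integer(), neuron = integer(),
                  amplitude = numeric(), kind = character()))
  }
  inputs <- as_tibble(inputs)
  if (!all(c("time", "neuron") %in% names(inputs))) {
    abort("inputs need `time` and `neuron` columns")
  }
  if (!"kind" %in% names(inputs)) inputs$kind <- "current"
  if (!"amplitude" %in% names(inputs)) inputs$amplitude <- 20
  bad <- inputs$neuron < 1 | inputs$neuron > n_neurons | is.na(inputs$neuron)
  if (any(bad)) {
    abort(sprintf("unknown neuron id(s) in inputs: %s",
                  paste(unique(inputs$neuron[bad]), collapse = ", ")))
  }
  if (!all(inputs$kind %in% c("current", "spike"))) {
    abort("input `kind` must be \"current\" or \"spike\"")
  }
  arrange(inputs, .data$time, .data$neuron)
}

#' Run a network for a stretch of simulated time
#'
#' Advances the network by `duration` ms at a 1 ms resolution. Spikes
#' propagate along their connections and arrive exactly `delay` ms later;
#' simultaneous arrivals sum linearly. External inputs are events of two
#' kinds: `"current"` events add their `amplitude` (mV) to the target's
#' input for one tick, `"spike"` events force an exact spike emission at
#' their tick. With `plasticity = TRUE` the STDP derivative accumulates and
#' weights are updated once per `stdp$update_interval`;
#' `metaplasticity = TRUE` additionally recomputes each excitatory neuron's
#' modification threshold immediately before every weight update and
#' modulates the STDP amplitudes for the following interval.
#'
#' The run continues from `network$time`; event times are absolute. State
#' (membrane variables, traces, in-flight spikes, thresholds) is carried in
#' the returned network, so consecutive runs compose exactly: running
#' `a` then `b` ms equals one `a + b` ms run, bit for bit.
#'
#' @param network A `spiking_network`.
#' @param duration Duration in ms (>= 1).
#' @param inputs Event tibble with columns `time` (absolute ms), `neuron`,
#'   and optionally `amplitude` (default 20) and `kind` (default
#'   `"current"`).
#' @param plasticity,metaplasticity Enable STDP / metaplastic modulation.
#' @param stdp An [stdp_params()] list.
#' @param meta A [meta_params()] list.
#' @param guard_hz Runaway-firing guard: the run faults if the mean
#'   excitatory rate over any update interval exceeds this (Hz). `0`
#'   disables the guard (toy circuits).
#' @param record_raster Keep the spike raster (disable to save memory on
#'   long maturation runs; diagnostics are always kept).
#' @param record_series Record per-interval weight/derivative/threshold
#'   series (toy circuits only; memory scales with connections x seconds).
#' @return A list of class `network_run` with elements `network` (advanced
#'   state), `raster` (spike tibble with population metadata attributes),
#'   `diagnostics` (per-interval rates and mean threshold) and `series`
#'   (`NULL` unless requested).
#' @export
run_network <- function(network, duration, inputs = NULL,
                        plasticity = TRUE, metaplasticity = FALSE,
                        stdp = stdp_params(), meta = meta_params(),
                        guard_hz = 100, record_raster = TRUE,
                        record_series = FALSE) {
  stopifnot(inherits(network, "spiking_network"), duration >= 1)
  nn <- network$neurons
  con <- network$connections
  inputs <- validate_inputs(inputs, nrow(nn))
  cur <- filter(inputs, .data$kind == "current")
  frc <- filter(inputs, .data$kind == "spike")
  t0 <- network$time

  res <- run_network_cpp(
    pre = as.integer(con$pre), post = as.integer(con$post),
    delay = as.integer(con$delay),
    weight0 = con$weight, deriv0 = con$derivative,
    plastic = con$plastic,
    pa = nn$a, pb = nn$b, pc = nn$c, pd = nn$d,
    excitatory = nn$excitatory,
    v0 = nn$v, u0 = nn$u,
    last_fire0 = ifelse(is.finite(nn$last_fire), nn$last_fire, -1e18),
    last_arrival0 = ifelse(is.finite(con$last_arrival), con$last_arrival, -1e18),
    theta0 = nn$theta,
    pend_syn = as.integer(network$pending$synapse),
    pend_time = as.integer(network$pending$time),
    cur_time = as.integer(cur$time), cur_neuron = as.integer(cur$neuron),
    cur_amp = cur$amplitude,
    force_time = as.integer(frc$time), force_neuron = as.integer(frc$neuron),
    t_start = as.integer(t0), duration = as.integer(duration),
    plasticity_on = plasticity, meta_on = metaplasticity,
    A_plus = stdp$A_plus, A_minus = stdp$A_minus,
    tau_plus = stdp$tau_plus, tau_minus = stdp$tau_minus,
    drift = stdp$drift, decay = stdp$decay,
    update_interval = as.integer(stdp$update_interval),
    w_max = network$w_max,
    meta_r = meta$r, meta_p = meta$p, inertia = meta$inertia,
    soft_min = meta$soft_min, soft_max = meta$soft_max,
    guard_hz = guard_hz, record_raster = record_raster,
    record_series = record_series)

  out <- network
  out$neurons <- mutate(nn, v = res$v, u = res$u, theta = res$theta,
                        last_fire = ifelse(res$last_fire < -1e17, -Inf, res$last_fire))
  out$connections <- mutate(con, weight = res$weight, derivative = res$derivative,
                            last_arrival = ifelse(res$last_arrival < -1e17, -Inf,
                                                  res$last_arrival))
  out$time <- res$time_end
  out$pending <- tibble(synapse = res$pending_synapse, time = res$pending_time)

  raster <- tibble(time = res$spike_time, neuron = res$spike_neuron)
  attr(raster, "n_excitatory") <- sum(nn$excitatory)
  attr(raster, "n_inhibitory") <- sum(!nn$excitatory)
  diagnostics <- as_tibble(res$diagnostics)

  series <- NULL
  if (record_series && !is.null(res$series)) {
    k <- res$series$n_intervals
    sec0 <- t0 / 1000
    secs <- sec0 + seq_len(k) * stdp$update_interval / 1000
    series <- list(
      connections = tibble(
        second = rep(secs, each = nrow(con)),
        connection = rep(con$id, k),
        weight = res$series$weight,
        derivative = res$series$derivative),
      neurons = tibble(
        second = rep(secs, each = nrow(nn)),
        neuron = rep(nn$id, k),
        theta = res$series$theta))
  }
  structure(list(network = out, raster = raster, diagnostics = diagnostics,
                 series = series),
            class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
  cat(sprintf("<network_run> %d spikes recorded, network now at t = %d ms\n",
              nrow(x$raster), x$network$time))
  invisible(x)
}
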