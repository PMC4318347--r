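#' Paired metaplasticity experiment across networks
#'
#' The network-level comparison: for each of `n_networks` independently
#' wired networks, the network is matured once on Poisson background, and
#' then trained twice from the *same* matured snapshot — once with and
#' once without metaplasticity, with identical training/probing input
#' streams — so every measurement is paired. Per network and arm the
#' experiment records PNG size (from a response fingerprint of the probe),
#' the three-way weight census after training, the end-of-training
#' excitatory firing rate, and the PNG connection-activation counts.
#'
#' The scaled default (5 networks, 20 min maturation, 180 s training,
#' 100 s probing) is sized for a desk run; the full-scale protocol uses
#' 20 networks and 2 h maturation.
#'
#' @param n_networks Number of independently wired networks.
#' @param seed Master seed; all per-network and per-phase seeds derive
#'   from it.
#' @param config A [network_config()] (its `seed` field is overridden per
#'   network).
#' @param maturation_s,training_s,probing_s Phase durations (seconds).
#' @param stdp,meta Parameter lists shared by both arms.
#' @param pattern_ids Ids of the 40 stimulated neurons.
#' @param jitter Partition jitter (ms).
#' @param rate_window_s Width of the end-of-training rate window (s).
#' @param consistency_threshold Fingerprint consistency threshold.
#' @param guard_hz Runaway-firing guard (Hz).
#' @param quiet Suppress per-network progress messages.
#' @return A `png_experiment` object; see [tidy.png_experiment()] and
#'   [glance.png_experiment()].
#' @export
run_experiment <- function(n_networks = 5, seed = 1,
                           config = network_config(),
                           maturation_s = 1200, training_s = 180,
                           probing_s = 100,
                           stdp = stdp_params(), meta = meta_params(),
                           pattern_ids = 1:40, jitter = 2,
                           rate_window_s = 10,
                           consistency_threshold = 0.75,
                           guard_hz = 100, quiet = TRUE) {
  stopifnot(n_networks >= 1)
  pattern <- ascending_pattern(pattern_ids, frame_period = 200)
  probe_rate <- 4
  results <- list()
  for (k in seq_len(n_networks)) {
    base <- (seed * 1009L + k * 7919L) %% 2147480000L
    cfg <- config
    cfg$seed <- base
    net <- build_network(cfg)
    if (!quiet) message(sprintf("network %d/%d: maturing %d s", k, n_networks, maturation_s))
    matured <- run_protocol(net, pattern,
                            maturation_s = maturation_s, training_s = 0,
                            probing_s = 0, stdp = stdp, meta = meta,
                            seeds = list(maturation = base + 1),
                            guard_hz = guard_hz)$snapshots$matured

    for (arm in c("disabled", "enabled")) {
      if (!quiet) message(sprintf("network %d/%d: training (metaplasticity %s)", k, n_networks, arm))
      run <- run_protocol(matured, pattern,
                          maturation_s = 0, training_s = training_s,
                          probing_s = probing_s,
                          metaplasticity = (arm == "enabled"),
                          stdp = stdp, meta = meta,
                          seeds = list(training = base + 2, probing = base + 3),
                          guard_hz = guard_hz)
      trained <- run$snapshots$trained
      census <- weight_census(trained$connections, w_max = trained$w_max)
      t_end_s <- trained$time / 1000
      rate <- firing_rate(run$rasters$training,
                          neurons = which(trained$neurons$excitatory),
                          window = c(t_end_s - rate_window_s, t_end_s))
      probe <- run$rasters$probing
      fp <- build_fingerprint(probe,
                              frame_period = attr(probe, "frame_period"),
                              n_frames = attr(probe, "n_frames"),
                              consistency_threshold = consistency_threshold)
      part <- partition_connections(probe, trained$connections, jitter = jitter)
      results[[length(results) + 1]] <- dplyr::bind_cols(
        tibble(network = k, arm = arm, png_size = png_size(fp),
               rate_hz = rate),
        census, partition_summary(part))
    }
  }
  structure(list(
    results = bind_rows(results),
    params = list(n_networks = n_networks, seed = seed,
                  maturation_s = maturation_s, training_s = training_s,
                  probing_s = probing_s, stdp = stdp, meta = meta)),
    class = "png_experiment")
}

#' @export
print.png_experiment <- function(x, ...) {
  cat(sprintf("<png_experiment> %d networks, paired arms (metaplasticity enabled/disabled)\n",
              x$params$n_networks))
  print(glance(x))
  invisible(x)
}

#' Deterministic fixtures for tests and examples
#'
#' Small, seeded inputs exercising the analysis pipeline:
#'
#' * `"planted-png-raster"`: 400 frames (250 ms) in which 10 chain neurons
#'   fire at fixed offsets in every frame, over 1 Hz Poisson noise on 40
#'   neurons — a fingerprint at threshold 0.75 recovers exactly the chain.
#' * `"toy-network"`: a 20-neuron network (16 excitatory, fan-out 5).
#' * `"toy-raster-for-partition"`: a random raster plus a random
#'   connection table for oracle checks of the activation partition.
#' * `"isr-circuit"`: the six-neuron input-space circuit.
#'
#' @param kind Fixture name (see above).
#' @param seed Integer seed.
#' @return Kind-specific list or object.
#' @export
generate_fixtures <- function(kind = c("planted-png-raster", "toy-network",
                                       "toy-raster-for-partition", "isr-circuit"),
                              seed = 1) {
  if (!is.character(kind) || length(kind) != 1 ||
      !kind %in% c("planted-png-raster", "toy-network",
                   "toy-raster-for-partition", "isr-circuit")) {
    abort(sprintf("unknown fixture kind: %s", paste(kind, collapse = ", ")))
  }
  switch(kind,
    "planted-png-raster" = {
      n_frames <- 400
      period <- 250
      n_neurons <- 40
      chain <- tibble(neuron = 2L * (1:10), offset = 5 + 3 * (0:9))
      planted <- tibble(
        time = as.integer(rep((seq_len(n_frames) - 1) * period, each = 10) +
                            rep(chain$offset, n_frames)),
        neuron = rep(chain$neuron, n_frames))
      noise <- poisson_background(1, n_neurons, n_frames * period, seed = seed)
      raster <- bind_rows(planted, select(noise, "time", "neuron")) %>%
        arrange(.data$time, .data$neuron)
      attr(raster, "t_start") <- 0
      attr(raster, "frame_period") <- period
      attr(raster, "n_frames") <- n_frames
      list(raster = raster, planted = chain, frame_period = period,
           n_frames = n_frames)
    },
    "toy-network" = build_network(network_config(
      n_neurons = 20, n_excitatory = 16, fan_out = 5, seed = seed)),
    "toy-raster-for-partition" = {
      withr::with_seed(seed, {
        n <- 20
        raster <- tibble(
          time = sort(as.integer(floor(runif(300) * 500))),
          neuron = sample(n, 300, replace = TRUE))
        connections <- tibble(
          pre = sample(n, 60, replace = TRUE),
          post = sample(n, 60, replace = TRUE),
          delay = sample(20, 60, replace = TRUE),
          weight = 3, derivative = 0,
          plastic = sample(c(TRUE, FALSE), 60, replace = TRUE)) %>%
          filter(.data$pre != .data$post) %>%
          mutate(id = dplyr::row_number(), .before = 1)
        list(raster = raster, connections = connections)
      })
    },
    "isr-circuit" = png_chain_circuit())
}
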