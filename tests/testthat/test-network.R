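test_that("default topology satisfies all wiring invariants", {
  net <- build_network(network_config(seed = 11))
  con <- net$connections
  expect_identical(nrow(con), 100000L)
  expect_identical(sum(con$plastic), 80000L)
  # fan-out exactly 100 everywhere, no self-connections, no duplicate pairs
  expect_true(all(table(con$pre) == 100))
  expect_false(any(con$pre == con$post))
  expect_identical(anyDuplicated(con[, c("pre", "post")]), 0L)
  # delays: excitatory 1..20, inhibitory exactly 1
  exc <- con$pre <= 800
  expect_true(all(con$delay[exc] %in% 1:20))
  expect_true(all(con$delay[!exc] == 1L))
  # inhibitory connections target excitatory neurons only and are non-plastic
  expect_true(all(con$post[!exc] <= 800))
  expect_false(any(con$plastic[!exc]))
  # initial weights
  expect_true(all(con$weight[exc] == 3.0))
  expect_true(all(con$weight[!exc] == -2.0))
})

test_that("the same seed wires the same network; infeasible fan-out faults", {
  a <- build_network(network_config(n_neurons = 100, n_excitatory = 80,
                                    fan_out = 20, seed = 3))
  b <- build_network(network_config(n_neurons = 100, n_excitatory = 80,
                                    fan_out = 20, seed = 3))
  expect_identical(a$connections, b$connections)
  expect_error(
    build_network(network_config(n_neurons = 30, n_excitatory = 10,
                                 fan_out = 15, seed = 1)),
    "fan-out")
})

test_that("a matured-free network with no input is silent", {
  net <- build_network(network_config(seed = 5))
  run <- run_network(net, 1000, plasticity = FALSE)
  expect_identical(nrow(run$raster), 0L)
})

test_that("conduction delays shift post-synaptic firing tick for tick", {
  fire_time <- function(d) {
    circ <- make_circuit(2, tibble::tibble(pre = 1L, post = 2L,
                                           delay = d, weight = 30))
    run <- run_network(circ, 60,
                       inputs = tibble::tibble(time = 10L, neuron = 1L,
                                               amplitude = NA_real_,
                                               kind = "spike"),
                       plasticity = FALSE, guard_hz = 0)
    min(run$raster$time[run$raster$neuron == 2])
  }
  t7 <- fire_time(7L)
  t8 <- fire_time(8L)
  expect_gte(t7, 17)                  # nothing can arrive before t = 10 + 7
  expect_identical(t8 - t7, 1L)       # one extra delay ms, one tick later
})

test_that("with plasticity off a run preserves every weight", {
  net <- build_network(network_config(n_neurons = 100, n_excitatory = 80,
                                      fan_out = 20, seed = 9))
  bg <- poisson_background(5, 100, 3000, seed = 2)
  run <- run_network(net, 3000, inputs = bg, plasticity = FALSE)
  expect_gt(nrow(run$raster), 0)
  expect_identical(run$network$connections$weight, net$connections$weight)
  expect_identical(run$network$connections$derivative, net$connections$derivative)
})

test_that("raster event count equals the sum of per-neuron spike counts", {
  net <- build_network(network_config(n_neurons = 100, n_excitatory = 80,
                                      fan_out = 20, seed = 9))
  run <- run_network(net, 2000, inputs = poisson_background(5, 100, 2000, seed = 4),
                     plasticity = FALSE)
  expect_identical(nrow(run$raster), sum(table(run$raster$neuron)))
  expect_true(all(diff(run$raster$time) >= 0))
})

test_that("engine matches the event-queue oracle on random toy networks", {
  for (seed in c(1, 2)) {
    net <- build_network(network_config(n_neurons = 10, n_excitatory = 8,
                                        fan_out = 3, delay_max = 8,
                                        w_init_exc = 8, seed = seed))
    inputs <- dplyr::bind_rows(
      poisson_background(30, 10, 400, seed = seed + 100),
      tibble::tibble(time = c(13L, 50L, 211L), neuron = c(1L, 2L, 3L),
                     amplitude = NA_real_, kind = "spike"))
    run <- run_network(net, 400, inputs = inputs, plasticity = TRUE,
                       metaplasticity = TRUE, guard_hz = 0)
    ora <- oracle_run(net, 400, inputs = inputs, plasticity = TRUE,
                      metaplasticity = TRUE)
    expect_identical(run$raster$time, as.integer(ora$raster$time))
    expect_identical(run$raster$neuron, as.integer(ora$raster$neuron))
    expect_identical(run$network$connections$weight, ora$weight)
    expect_identical(run$network$connections$derivative, ora$derivative)
    expect_identical(run$network$neurons$v, ora$v)
    expect_identical(run$network$neurons$u, ora$u)
    expect_identical(run$network$neurons$theta, ora$theta)
  }
})

test_that("a run resumed mid-stream reproduces the uninterrupted run bit for bit", {
  net <- build_network(network_config(n_neurons = 50, n_excitatory = 40,
                                      fan_out = 10, w_init_exc = 6, seed = 21))
  inputs <- poisson_background(20, 50, 2500, seed = 8)
  whole <- run_network(net, 2500, inputs = inputs, plasticity = TRUE,
                       metaplasticity = TRUE)
  # split at 1300 ms: inside an update interval, with spikes in flight
  part1 <- run_network(net, 1300, inputs = dplyr::filter(inputs, time < 1300),
                       plasticity = TRUE, metaplasticity = TRUE)
  part2 <- run_network(part1$network, 1200,
                       inputs = dplyr::filter(inputs, time >= 1300),
                       plasticity = TRUE, metaplasticity = TRUE)
  expect_identical(dplyr::bind_rows(part1$raster, part2$raster)$time,
                   whole$raster$time)
  expect_identical(part2$network$connections$weight,
                   whole$network$connections$weight)
  expect_identical(part2$network$neurons$v, whole$network$neurons$v)
  expect_identical(part2$network$connections$derivative,
                   whole$network$connections$derivative)
})

test_that("unknown input neuron ids and runaway firing fault loudly", {
  circ <- single_synapse_circuit()
  expect_error(
    run_network(circ, 10, inputs = tibble::tibble(time = 1L, neuron = 9L)),
    "unknown neuron")
  # 250 forced spikes per second on the (excitatory) pre neuron: a mean
  # excitatory rate of at least 125 Hz over the two-cell population
  storm <- tibble::tibble(time = as.integer(seq(0, 996, by = 4)), neuron = 1L,
                          amplitude = NA_real_, kind = "spike")
  expect_error(
    run_network(circ, 1000, inputs = storm, plasticity = FALSE, guard_hz = 100),
    "runaway")
  expect_no_error(
    run_network(circ, 1000, inputs = storm, plasticity = FALSE, guard_hz = 0))
})
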