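planted_raster <- function(neuron, offset, n_frames = 400, period = 250,
                           every = 1) {
  frames <- seq(0, n_frames - 1, by = every)
  r <- tibble::tibble(time = as.integer(frames * period + offset),
                      neuron = as.integer(neuron))
  attr(r, "t_start") <- 0
  r
}

test_that("a fully consistent planted neuron yields a probability-1 entry", {
  r <- planted_raster(7, 12)
  fp <- build_fingerprint(r, frame_period = 250, n_frames = 400)
  expect_identical(nrow(fp), 1L)
  expect_identical(fp$neuron, 7L)
  expect_true(fp$window_start <= 12 && fp$window_end >= 12)
  expect_identical(fp$probability, 1)
  expect_identical(png_size(fp), 1L)
})

test_that("a neuron firing in only half the frames is excluded at threshold 0.75", {
  r <- planted_raster(7, 12, every = 2)        # 50% of frames
  fp <- build_fingerprint(r, frame_period = 250, n_frames = 400)
  expect_identical(nrow(fp), 0L)
  expect_identical(png_size(fp), 0L)
  # but admitted at a 0.4 threshold
  fp2 <- build_fingerprint(r, frame_period = 250, n_frames = 400,
                           consistency_threshold = 0.4)
  expect_identical(png_size(fp2), 1L)
})

test_that("raising the consistency threshold never grows the PNG", {
  fx <- generate_fixtures("planted-png-raster", seed = 2)
  sizes <- vapply(c(0.3, 0.5, 0.75, 0.9, 1), function(th) {
    png_size(build_fingerprint(fx$raster, fx$frame_period, fx$n_frames,
                               consistency_threshold = th))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("background-only firing produces an empty fingerprint at 0.75", {
  noise <- poisson_background(1, 100, 400 * 250, seed = 6)
  r <- tibble::tibble(time = noise$time, neuron = noise$neuron)
  fp <- build_fingerprint(r, frame_period = 250, n_frames = 400)
  expect_identical(png_size(fp), 0L)
})

test_that("a planted polychronous chain is recovered exactly over noise", {
  for (seed in c(1, 3)) {
    fx <- generate_fixtures("planted-png-raster", seed = seed)
    fp <- build_fingerprint(fx$raster, fx$frame_period, fx$n_frames)
    expect_identical(sort(unique(fp$neuron)), sort(fx$planted$neuron))
    expect_identical(png_size(fp), nrow(fx$planted))
    # each planted neuron's window covers its true offset
    j <- match(fp$neuron, fx$planted$neuron)
    expect_true(all(fp$window_start <= fx$planted$offset[j] &
                      fp$window_end >= fx$planted$offset[j]))
  }
})

test_that("png_size counts distinct neurons, not windows", {
  fp <- tibble::tibble(neuron = c(3L, 5L, 5L, 9L),
                       window_start = c(1, 2, 30, 4),
                       window_end = c(2, 3, 31, 5),
                       probability = 1)
  expect_identical(png_size(fp), 3L)
  expect_identical(png_size(fp[0, ]), 0L)
})

test_that("windows within a neuron are disjoint", {
  # two well-separated consistent offsets for one neuron
  r <- dplyr::bind_rows(planted_raster(4, 10), planted_raster(4, 50))
  attr(r, "t_start") <- 0
  fp <- build_fingerprint(r, frame_period = 250, n_frames = 400)
  expect_identical(nrow(fp), 2L)
  expect_true(fp$window_start[2] > fp$window_end[1])
  expect_identical(png_size(fp), 1L)
})

test_that("the activation rule admits exactly the delay-to-delay+jitter pairs", {
  con <- tibble::tibble(id = 1:2, pre = 1L, post = 2L, delay = 5L,
                        weight = 3, derivative = 0, plastic = TRUE,
                        last_arrival = -Inf)
  r_in <- tibble::tibble(time = c(10L, 16L), neuron = c(1L, 2L))
  p <- partition_connections(r_in, con[1, ], jitter = 2)
  expect_true(p$active)                       # 5 <= 6 <= 7
  r_out <- tibble::tibble(time = c(10L, 18L), neuron = c(1L, 2L))
  expect_false(partition_connections(r_out, con[1, ], jitter = 2)$active)
  # boundary cases: exactly delay and exactly delay + jitter
  expect_true(partition_connections(
    tibble::tibble(time = c(10L, 15L), neuron = c(1L, 2L)), con[1, ], 2)$active)
  expect_true(partition_connections(
    tibble::tibble(time = c(10L, 17L), neuron = c(1L, 2L)), con[1, ], 2)$active)
  expect_false(partition_connections(
    tibble::tibble(time = c(10L, 14L), neuron = c(1L, 2L)), con[1, ], 2)$active)
})

test_that("the partition equals a brute-force double loop over spike pairs", {
  for (seed in c(2, 5)) {
    fx <- generate_fixtures("toy-raster-for-partition", seed = seed)
    part <- partition_connections(fx$raster, fx$connections, jitter = 2)
    brute <- vapply(seq_len(nrow(fx$connections)), function(k) {
      pre_t <- fx$raster$time[fx$raster$neuron == fx$connections$pre[k]]
      post_t <- fx$raster$time[fx$raster$neuron == fx$connections$post[k]]
      d <- fx$connections$delay[k]
      any(outer(post_t, pre_t, `-`) >= d & outer(post_t, pre_t, `-`) <= d + 2)
    }, logical(1))
    expect_identical(part$active, brute)
    s <- partition_summary(part)
    expect_identical(s$active_total, sum(brute))
    expect_identical(s$active_excitatory + s$active_inhibitory, s$active_total)
  }
})

test_that("the weight census is exact and conserves the total", {
  con <- tibble::tibble(weight = c(0, 10, 4.3), plastic = TRUE)
  expect_identical(weight_census(con, w_max = 10),
                   tibble::tibble(pruned = 1L, saturated = 1L, other = 1L))
  net <- build_network(network_config(seed = 30))
  cen <- weight_census(net$connections, w_max = 10)
  expect_identical(cen, tibble::tibble(pruned = 0L, saturated = 0L,
                                       other = 80000L))
  expect_identical(cen$pruned + cen$saturated + cen$other, 80000L)
  expect_error(weight_census(tibble::tibble(weight = 11, plastic = TRUE), 10),
               "clipped")
})

test_that("firing rate is spikes per neuron per second and scales with the window", {
  r <- tibble::tibble(time = as.integer(seq(0, 999, length.out = 4800) * 1),
                      neuron = rep(1:800, 6))
  expect_equal(firing_rate(r, neurons = 1:800, window = c(0, 1)), 6)
  expect_equal(firing_rate(tibble::tibble(time = integer(), neuron = integer()),
                           neurons = 1:10, window = c(0, 1)), 0)
  expect_error(firing_rate(r, neurons = integer(), window = c(0, 1)), "empty")
  # stationary raster: doubling the window leaves the rate unchanged
  r2 <- tibble::tibble(time = rep(0:1999, each = 2),
                       neuron = rep(1:2, 2000))
  expect_equal(firing_rate(r2, 1:2, c(0, 1)), firing_rate(r2, 1:2, c(0, 2)))
})
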