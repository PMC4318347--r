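test_that("single-synapse drive: regulated weight stays in range, unregulated saturates", {
  on <- run_single_synapse_demo(60, metaplasticity = TRUE)
  off <- run_single_synapse_demo(60, metaplasticity = FALSE)
  # series starts at the initial state with zero drive
  expect_identical(on$second[1], 0)
  expect_identical(on$theta[1], 0)
  expect_identical(on$derivative[1], 0)
  expect_identical(on$weight[1], 6)
  expect_lt(max(on$weight), 15)
  expect_identical(max(off$weight), 15)
  # positive synaptic drive early in both runs
  expect_gt(on$derivative[2], 0)
  expect_gt(off$derivative[2], 0)
  # the threshold rises under sustained positive drive
  expect_gt(max(on$theta), 0)
  expect_true(all(off$theta == 0))
})

test_that("connection C's weight rises then falls while A and B saturate", {
  rev <- run_weight_reversal_demo(60)
  wc <- rev$weight[rev$connection == "C"]
  wa <- rev$weight[rev$connection == "A"]
  wb <- rev$weight[rev$connection == "B"]
  peak <- which.max(wc)
  expect_gt(peak, 1)                      # strict interior maximum:
  expect_lt(peak, length(wc))             # rises first ...
  expect_gt(max(wc), wc[1])
  expect_lt(wc[length(wc)], max(wc))      # ... then falls
  expect_identical(max(wa), 10)
  expect_identical(max(wb), 10)
  expect_identical(wa[length(wa)], 10)
})

test_that("with plasticity off the reversal-demo weights are constant", {
  rev <- run_weight_reversal_demo(5, plasticity = FALSE)
  for (cc in c("A", "B", "C")) {
    expect_identical(length(unique(rev$weight[rev$connection == cc])), 1L)
  }
})

test_that("with zero input weights the input space is empty", {
  circ <- png_chain_circuit(input_weights = c(0, 0, 0))
  isr <- input_space_response(circ, target = 4, n_trials = 8, hit_min = 2)
  expect_false(any(isr$active))
})

test_that("saturated weights produce the three two-of-three arms", {
  isr <- input_space_response(png_chain_circuit(), target = 4)
  expect_true(any(isr$active))
  # arrival coincidence lines for delays (10, 10, 15): inputs 1&2 together,
  # 2&3 together (dt23 = 5), 1&3 together (dt12 + dt23 = 5)
  arm12 <- isr$dt12 == 0
  arm23 <- isr$dt23 == 5
  arm13 <- isr$dt12 + isr$dt23 == 5
  expect_true(all(isr$active[arm12]))
  expect_true(all(isr$active[arm23]))
  expect_true(all(isr$active[arm13]))
  # a pattern with all three arrivals far apart does not fire the target
  # (dt12 = 10, dt23 = -10: arrivals separated by 10 and 5 ms)
  expect_false(isr$active[isr$dt12 == 10 & isr$dt23 == -10])
  expect_false(all(isr$active))
})

test_that("the response depends only on firing-time differences (translation invariance)", {
  circ <- png_chain_circuit()
  fire_at <- function(t1, t2, t3) {
    run <- run_network(circ, 250,
                       inputs = tibble::tibble(time = as.integer(c(t1, t2, t3)),
                                               neuron = 1:3,
                                               amplitude = NA_real_,
                                               kind = "spike"),
                       plasticity = FALSE, guard_hz = 0)
    any(run$raster$neuron == 4)
  }
  cases <- list(c(0, 0, 5), c(5, 0, 0), c(3, 7, 1), c(10, 10, 15))
  for (cs in cases) {
    base <- fire_at(cs[1], cs[2], cs[3])
    for (shift in c(4, 30, 117)) {
      expect_identical(fire_at(cs[1] + shift, cs[2] + shift, cs[3] + shift),
                       base)
    }
  }
})

test_that("frame evaluation agrees with a full per-trial simulation", {
  # the ISR fast path evaluates one deterministic frame per cell; the
  # oracle runs all n_trials frames explicitly
  circ <- png_chain_circuit()
  nn <- circ$neurons
  con <- circ$connections
  grid <- expand.grid(t1 = c(0, 4, 9), t2 = c(0, 6), t3 = c(2, 11))
  for (k in seq_len(nrow(grid))) {
    full <- polychron:::run_frames_cpp(
      pre = as.integer(con$pre), post = as.integer(con$post),
      delay = as.integer(con$delay), weight = con$weight,
      pa = nn$a, pb = nn$b, pc = nn$c, pd = nn$d,
      force_off = as.integer(grid[k, ]), force_neuron = 1:3,
      cur_off = integer(), cur_neuron = integer(), cur_amp = numeric(),
      trial_idx = integer(), trial_off = integer(), trial_neuron = integer(),
      trial_amp = numeric(),
      frame_ms = 250L, n_trials = 40L, target = 4L)
    expect_identical(length(unique(full)), 1L)   # frames are true repeats
    one <- polychron:::run_frames_cpp(
      pre = as.integer(con$pre), post = as.integer(con$post),
      delay = as.integer(con$delay), weight = con$weight,
      pa = nn$a, pb = nn$b, pc = nn$c, pd = nn$d,
      force_off = as.integer(grid[k, ]), force_neuron = 1:3,
      cur_off = integer(), cur_neuron = integer(), cur_amp = numeric(),
      trial_idx = integer(), trial_off = integer(), trial_neuron = integer(),
      trial_amp = numeric(),
      frame_ms = 250L, n_trials = 1L, target = 4L)
    expect_identical(full[1], one[1])
  }
})

test_that("latency optimization expands the input space as a strict superset", {
  opt <- optimize_latency()
  expect_identical(sort(unique(opt$chain_delay)), c(2, 3, 4, 5))
  # per-delay superset
  expect_true(all(opt$active_optimized >= opt$active_default))
  by_delay <- dplyr::count(tibble::as_tibble(opt), chain_delay)
  expect_identical(length(unique(by_delay$n)), 1L)
  # strictly more active cells in total
  expect_gt(sum(opt$active_optimized), sum(opt$active_default))
  # a found weight is only reported where optimization changed the outcome
  expect_true(all(is.na(opt$best_weight[opt$active_default])))
})

test_that("with no weight steps the optimized map equals the default map", {
  opt <- optimize_latency(chain_delays = 3, weight_steps = numeric(),
                          n_trials = 4, hit_min = 1)
  expect_identical(opt$active_optimized, opt$active_default)
})

test_that("degenerate timing ranges fault", {
  expect_error(input_space_response(png_chain_circuit(), timing_range = 5),
               "degenerate")
})
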