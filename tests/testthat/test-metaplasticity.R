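test_that("the derivative map is the clipped affine map onto 0-10", {
  expect_identical(map_derivative(0), 5)
  expect_identical(map_derivative(-10), 0)
  expect_identical(map_derivative(10), 10)
  expect_identical(map_derivative(25), 10)      # clipped
  expect_identical(map_derivative(-25), 0)
  expect_error(map_derivative(NaN), "finite")
})

test_that("the weighting function is zero at the symmetric centre and exponential in the corners", {
  mp <- meta_params(r = 0.1, p = 0.5, soft_min = 0, soft_max = 10)
  expect_equal(weight_resistance(0, 5, mp), 0)
  # maximal drive at the upper soft limit: r e^{5p .. } (w - min) = 0.1 e^5 10
  expect_equal(weight_resistance(10, 10, mp), 0.1 * exp(5) * 10)
  expect_equal(weight_resistance(10, 10, mp), 148.4131591, tolerance = 1e-9)
  # antisymmetry under (d, w) -> (-d, mirrored w)
  expect_equal(weight_resistance(-10, 0, mp), -weight_resistance(10, 10, mp))
  for (d in c(-7, -2, 0, 4, 9)) {
    for (w in c(1, 3, 6, 9)) {
      expect_equal(weight_resistance(-d, 10 - w, mp),
                   -weight_resistance(d, w, mp))
    }
  }
})

test_that("the weighting surface rises only in the opposing drive/weight corners", {
  mp <- meta_params(r = 0.1, p = 0.5, soft_min = 0, soft_max = 10)
  corner <- weight_resistance(10, 10, mp)
  expect_gt(corner, 0)                            # opposes further potentiation
  expect_lt(weight_resistance(-10, 0, mp), 0)     # opposes further depression
  # no impediment to migration away from the limits: a large weight under
  # negative drive (and a small weight under positive drive) meets little
  # resistance compared to the active corners
  expect_lt(abs(weight_resistance(10, 0, mp)), corner / 100)
  expect_lt(abs(weight_resistance(-10, 10, mp)), corner / 100)
  # near-zero centre relative to the corners
  grid <- expand.grid(d = seq(-2, 2, by = 0.5), w = seq(4, 6, by = 0.5))
  expect_lt(max(abs(weight_resistance(grid$d, grid$w, mp))), corner / 15)
  # monotonically increasing in w at any fixed drive
  for (d in c(-10, -3, 1, 10)) {
    w <- seq(0, 10, by = 0.25)
    expect_true(all(diff(weight_resistance(d, w, mp)) > 0))
  }
})

test_that("the modification threshold is the tanh of the inertia-scaled mean", {
  expect_identical(modification_threshold(c(0, 0, 0)), tanh(0))
  expect_equal(modification_threshold(5, inertia = 0.2), tanh(1))
  expect_equal(modification_threshold(5, inertia = 0.2), 0.7615942, tolerance = 1e-7)
  expect_error(modification_threshold(numeric()), "no modification threshold")
  set.seed(1)
  for (k in 1:20) {
    th <- modification_threshold(rnorm(5, sd = 20), inertia = 0.2)
    expect_gt(th, -1)
    expect_lt(th, 1)
  }
})

test_that("amplitude modulation is symmetric and conserves the baseline-relative sum", {
  at0 <- modulate_amplitudes(0)
  expect_equal(at0$A_ltp, 0.1)
  expect_equal(at0$A_ltd, 0.12)
  neg <- modulate_amplitudes(-0.5)
  expect_equal(neg$A_ltp, 1.5 * 0.1)
  expect_equal(neg$A_ltd, 0.5 * 0.12)
  # theta -> 1: LTP vanishes, LTD doubles
  lim <- modulate_amplitudes(1 - 1e-12)
  expect_equal(lim$A_ltp, 0, tolerance = 1e-9)
  expect_equal(lim$A_ltd, 2 * 0.12, tolerance = 1e-9)
  set.seed(2)
  theta <- runif(50, -1 + 1e-9, 1 - 1e-9)
  amp <- modulate_amplitudes(theta)
  # the modulation factors sum to 2 exactly; the amplitude ratios recover it
  # to within one rounding step of the two divisions
  expect_identical((1 - theta) + (1 + theta), rep(2, 50))
  expect_equal(amp$A_ltp / 0.1 + amp$A_ltd / 0.12, rep(2, 50),
               tolerance = 1e-15)
})

test_that("one dominating synapse drives the threshold to 1 and shuts LTP off", {
  mp <- meta_params()
  others <- weight_resistance(rep(0, 99), rep(3, 99), mp)
  theta_at <- function(w1) {
    res <- c(weight_resistance(10, w1, mp), others)
    modification_threshold(res, mp$inertia)
  }
  ws <- c(5, 10, 50, 200, 500)
  th <- vapply(ws, theta_at, numeric(1))
  expect_true(all(diff(th) > 0))
  expect_gt(th[length(th)], 0.999)
  expect_lt(modulate_amplitudes(th[length(th)])$A_ltp, 1e-3)
})

test_that("metaplasticity with r = 0 reproduces the disabled trajectory bit for bit", {
  net <- build_network(network_config(n_neurons = 60, n_excitatory = 48,
                                      fan_out = 12, w_init_exc = 6, seed = 13))
  inputs <- poisson_background(15, 60, 3000, seed = 5)
  with_r0 <- run_network(net, 3000, inputs = inputs, plasticity = TRUE,
                         metaplasticity = TRUE, meta = meta_params(r = 0))
  without <- run_network(net, 3000, inputs = inputs, plasticity = TRUE,
                         metaplasticity = FALSE)
  expect_identical(with_r0$raster, without$raster)
  expect_identical(with_r0$network$connections$weight,
                   without$network$connections$weight)
  expect_identical(with_r0$network$neurons$v, without$network$neurons$v)
  expect_identical(with_r0$network$neurons$theta,
                   without$network$neurons$theta)
})

test_that("under sustained positive drive metaplasticity holds a single synapse below the cap", {
  on <- run_single_synapse_demo(100, metaplasticity = TRUE)
  off <- run_single_synapse_demo(100, metaplasticity = FALSE)
  expect_lt(max(on$weight), 15)
  expect_identical(max(off$weight), 15)
  # once capped, the unregulated weight stays there
  reached <- which(off$weight == 15)[1]
  expect_true(all(off$weight[reached:nrow(off)] == 15))
})
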