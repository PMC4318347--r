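# Plain-R reference engine: an independent, event-by-event implementation of
# the tick loop (delay queue, Izhikevich substeps, trace-reset STDP,
# metaplastic updates) used as the brute-force oracle for the compiled
# engine. Deliberately naive: explicit per-tick scans over an arrival list.

oracle_run <- function(network, duration, inputs = NULL,
                       plasticity = TRUE, metaplasticity = FALSE,
                       stdp = stdp_params(), meta = meta_params()) {
  nn <- network$neurons
  con <- network$connections
  n <- nrow(nn)
  ns <- nrow(con)
  v <- nn$v
  u <- nn$u
  theta <- nn$theta
  last_fire <- nn$last_fire
  weight <- con$weight
  deriv <- con$derivative
  last_arr <- con$last_arrival
  a_ltp <- stdp$A_plus * (1 - theta)
  a_ltd <- stdp$A_minus * (1 + theta)
  w_max <- network$w_max

  if (is.null(inputs)) {
    inputs <- tibble::tibble(time = integer(), neuron = integer(),
                             amplitude = numeric(), kind = character())
  }
  # arrival list: (synapse, time); grows as spikes are emitted
  arrivals <- data.frame(synapse = integer(), time = integer())
  spikes <- list()
  t0 <- network$time

  for (t in t0:(t0 + duration - 1)) {
    I <- numeric(n)
    due <- arrivals$synapse[arrivals$time == t]
    for (s in due) {
      j <- con$post[s]
      I[j] <- I[j] + weight[s]
      if (plasticity && con$plastic[s] && is.finite(last_fire[j])) {
        deriv[s] <- deriv[s] - a_ltd[j] * exp(-(t - last_fire[j]) / stdp$tau_minus)
      }
      last_arr[s] <- t
    }
    arrivals <- arrivals[arrivals$time != t, ]
    ev <- inputs[inputs$time == t & inputs$kind == "current", ]
    for (k in seq_len(nrow(ev))) {
      I[ev$neuron[k]] <- I[ev$neuron[k]] + ev$amplitude[k]
    }
    forced <- inputs$neuron[inputs$time == t & inputs$kind == "spike"]

    fired <- logical(n)
    for (j in seq_len(n)) {
      if (j %in% forced) {
        fired[j] <- TRUE
        v[j] <- nn$c[j]
        u[j] <- u[j] + nn$d[j]
        next
      }
      st <- step_neuron(list(v = v[j], u = u[j]),
                        list(a = nn$a[j], b = nn$b[j], c = nn$c[j], d = nn$d[j]),
                        I[j])
      v[j] <- st$state$v
      u[j] <- st$state$u
      fired[j] <- st$fired
    }

    for (j in which(fired)) {
      spikes[[length(spikes) + 1]] <- c(t, j)
      last_fire[j] <- t
      if (plasticity) {
        aff <- which(con$post == j & con$plastic)
        for (s in aff) {
          if (is.finite(last_arr[s])) {
            deriv[s] <- deriv[s] + a_ltp[j] * exp(-(t - last_arr[s]) / stdp$tau_plus)
          }
        }
      }
      out <- which(con$pre == j)
      if (length(out)) {
        arrivals <- rbind(arrivals,
                          data.frame(synapse = out, time = t + con$delay[out]))
      }
    }

    if ((t + 1) %% stdp$update_interval == 0 && plasticity) {
      if (metaplasticity) {
        for (j in which(nn$excitatory)) {
          aff <- which(con$post == j & con$plastic)
          if (length(aff) == 0) next
          res <- weight_resistance(deriv[aff], weight[aff], meta)
          theta[j] <- modification_threshold(res, meta$inertia)
          a_ltp[j] <- stdp$A_plus * (1 - theta[j])
          a_ltd[j] <- stdp$A_minus * (1 + theta[j])
        }
      }
      pl <- con$plastic
      weight[pl] <- pmin(pmax(weight[pl] + stdp$drift + deriv[pl], 0), w_max)
      deriv[pl] <- stdp$decay * deriv[pl]
    }
  }

  raster <- if (length(spikes)) {
    m <- do.call(rbind, spikes)
    tibble::tibble(time = m[, 1], neuron = m[, 2])
  } else {
    tibble::tibble(time = integer(), neuron = integer())
  }
  list(raster = raster, weight = weight, derivative = deriv,
       v = v, u = u, theta = theta)
}

# Direct pair-sum STDP oracle for a single synapse with scripted event times:
# sums the trace-reset contributions over all (arrival, post-spike) pairs.
oracle_pair_sum <- function(arrival_times, post_times, stdp = stdp_params()) {
  d <- 0
  events <- rbind(
    data.frame(t = as.numeric(arrival_times),
               kind = rep("arr", length(arrival_times))),
    data.frame(t = as.numeric(post_times),
               kind = rep("post", length(post_times))))
  events <- events[order(events$t, events$kind), ]
  last_arr <- -Inf
  last_post <- -Inf
  for (k in seq_len(nrow(events))) {
    if (events$kind[k] == "arr") {
      if (is.finite(last_post)) {
        d <- d - stdp$A_minus * exp(-(events$t[k] - last_post) / stdp$tau_minus)
      }
      last_arr <- events$t[k]
    } else {
      if (is.finite(last_arr)) {
        d <- d + stdp$A_plus * exp(-(events$t[k] - last_arr) / stdp$tau_plus)
      }
      last_post <- events$t[k]
    }
  }
  d
}
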