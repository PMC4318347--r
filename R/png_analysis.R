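#' Build a response fingerprint from a probe raster
#'
#' A response fingerprint is a probabilistic signature of polychronous
#' group (PNG) activation: a set of (neuron, time window, probability)
#' entries, where the probability is the fraction of stimulus frames in
#' which the neuron fired at least once inside the window. Per-neuron
#' peri-stimulus histograms at 1 ms bins are scanned for contiguous peak
#' regions (bins whose frame-hit fraction exceeds `floor`; regions
#' separated by at most `merge_gap` low bins are merged) and a region
#' becomes an entry iff its frame-consistency reaches
#' `consistency_threshold`. The distinct-neuron count of the fingerprint
#' is the PNG size.
#'
#' @param raster A spike tibble (`time`, `neuron`) covering `n_frames`
#'   frames of `frame_period` ms starting at `t_start`.
#' @param frame_period Frame period (ms).
#' @param n_frames Number of frames; must be >= 1 and covered by the
#'   raster's span.
#' @param consistency_threshold Final consistency threshold in (0, 1]
#'   (default 0.75).
#' @param floor Per-bin frame-hit fraction above which a bin belongs to a
#'   peak region.
#' @param merge_gap Regions separated by at most this many below-floor
#'   bins are merged before the consistency test.
#' @param t_start Absolute time (ms) of the first frame's start; defaults
#'   to the raster's `t_start` attribute, else 0.
#' @return A `fingerprint` tibble (`neuron`, `window_start`, `window_end`,
#'   `probability`) with threshold/frames/period attributes. Windows are
#'   in ms relative to frame onset; within a neuron they are disjoint.
#' @export
build_fingerprint <- function(raster, frame_period, n_frames,
                              consistency_threshold = 0.75,
                              floor = 0.25, merge_gap = 1, t_start = NULL) {
  if (n_frames < 1) abort("`n_frames` must be at least 1")
  stopifnot(consistency_threshold > 0, consistency_threshold <= 1)
  if (is.null(t_start)) t_start <- attr(raster, "t_start") %||% 0

  span <- c(t_start, t_start + n_frames * frame_period)
  ev <- raster %>%
    filter(.data$time >= span[1], .data$time < span[2]) %>%
    mutate(frame = (.data$time - t_start) %/% frame_period,
           offset = (.data$time - t_start) %% frame_period)

  empty <- tibble(neuron = integer(), window_start = numeric(),
                  window_end = numeric(), probability = numeric())
  if (nrow(ev) == 0) {
    return(structure(empty, consistency_threshold = consistency_threshold,
                     n_frames = n_frames, frame_period = frame_period,
                     class = c("fingerprint", class(empty))))
  }

  # frame-hit fraction per (neuron, offset) bin
  hits <- ev %>%
    distinct(.data$neuron, .data$offset, .data$frame) %>%
    count(.data$neuron, .data$offset, name = "frames_hit")

  per_neuron <- split(hits, hits$neuron)
  entries <- lapply(per_neuron, function(h) {
    frac <- numeric(frame_period)
    frac[h$offset + 1] <- h$frames_hit / n_frames
    high <- frac > floor
    if (!any(high)) return(NULL)
    # maximal runs of high bins, then merge across short gaps
    r <- rle(high)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    regions <- data.frame(start = starts[r$values], end = ends[r$values])
    if (nrow(regions) > 1 && merge_gap > 0) {
      keep <- list(regions[1, ])
      for (k in 2:nrow(regions)) {
        last <- keep[[length(keep)]]
        if (regions$start[k] - last$end - 1 <= merge_gap) {
          keep[[length(keep)]]$end <- regions$end[k]
        } else {
          keep[[length(keep) + 1]] <- regions[k, ]
        }
      }
      regions <- do.call(rbind, keep)
    }
    nid <- h$neuron[1]
    sub <- ev[ev$neuron == nid, ]
    out <- lapply(seq_len(nrow(regions)), function(k) {
      w0 <- regions$start[k] - 1
      w1 <- regions$end[k] - 1
      consistent <- length(unique(sub$frame[sub$offset >= w0 & sub$offset <= w1]))
      prob <- consistent / n_frames
      if (prob >= consistency_threshold) {
        tibble(neuron = nid, window_start = w0, window_end = w1,
               probability = prob)
      } else NULL
    })
    bind_rows(out)
  })
  fp <- bind_rows(entries)
  if (nrow(fp) == 0) fp <- empty
  fp <- arrange(fp, .data$neuron, .data$window_start)
  structure(fp, consistency_threshold = consistency_threshold,
            n_frames = n_frames, frame_period = frame_period,
            class = c("fingerprint", class(fp)))
}

#' PNG size of a fingerprint
#'
#' The number of distinct neurons with at least one fingerprint entry.
#'
#' @param fingerprint A [build_fingerprint()] result.
#' @export
png_size <- function(fingerprint) {
  n_distinct(fingerprint$neuron)
}

#' Partition connections into PNG-active and non-active
#'
#' A connection participates in PNG activation iff some pre-synaptic spike
#' at `t1` and post-synaptic spike at `t2` in the raster satisfy
#' `delay <= t2 - t1 <= delay + jitter`: the pre-synaptic spike then
#' plausibly contributed to the post-synaptic firing.
#'
#' @param raster A spike tibble from repeated presentation of a known
#'   stimulus.
#' @param connections A connection tibble (`pre`, `post`, `delay`, and
#'   `plastic` marking excitatory connections).
#' @param jitter Allowed timing slack in ms (default 2).
#' @return The connection tibble with an `active` column, carrying the
#'   jitter as an attribute; see [partition_summary()] for the counts.
#' @export
partition_connections <- function(raster, connections, jitter = 2) {
  n <- max(c(connections$pre, connections$post, raster$neuron))
  spikes <- vector("list", n)
  byn <- split(raster$time, factor(raster$neuron, levels = seq_len(n)))
  for (j in seq_len(n)) {
    spikes[[j]] <- as.integer(sort(byn[[j]]))
  }
  active <- partition_connections_cpp(
    pre = as.integer(connections$pre), post = as.integer(connections$post),
    delay = as.integer(connections$delay), spikes_by_neuron = spikes,
    jitter = as.integer(jitter))
  out <- mutate(connections, active = active)
  attr(out, "jitter") <- jitter
  class(out) <- c("activation_partition", class(out))
  out
}

#' Active-connection counts of a partition
#'
#' @param partition A [partition_connections()] result.
#' @return A one-row tibble with `active_excitatory`, `active_inhibitory`
#'   and `active_total` counts (excitatory = plastic connections).
#' @export
partition_summary <- function(partition) {
  tibble(
    active_excitatory = sum(partition$active & partition$plastic),
    active_inhibitory = sum(partition$active & !partition$plastic),
    active_total = sum(partition$active))
}

#' Three-way weight census of the plastic connections
#'
#' Counts pruned (weight exactly 0), saturated (weight exactly `w_max`)
#' and other plastic connections. Exact comparison is valid because the
#' weight update clips onto the bounds.
#'
#' @param connections A connection tibble with `weight` and `plastic`.
#' @param w_max Hard upper weight limit (mV).
#' @return A one-row tibble (`pruned`, `saturated`, `other`); the three
#'   counts sum to the number of plastic connections.
#' @export
weight_census <- function(connections, w_max = 10) {
  w <- connections$weight[connections$plastic]
  if (any(w < 0 | w > w_max)) {
    abort("plastic weights outside [0, w_max]; census requires clipped weights")
  }
  tibble(pruned = sum(w == 0), saturated = sum(w == w_max),
         other = sum(w > 0 & w < w_max))
}

#' Mean per-neuron firing rate over a window
#'
#' @param raster A spike tibble (`time` in ms).
#' @param neurons Integer ids of the population to average over.
#' @param window Two-element numeric, window in seconds `[from, to)`.
#' @return Mean spikes per neuron per second (Hz).
#' @examples
#' r <- tibble::tibble(time = rep(0:999, 5), neuron = rep(1:5, each = 1000))
#' firing_rate(r, neurons = 1:5, window = c(0, 1))
#' @export
firing_rate <- function(raster, neurons, window) {
  if (length(neurons) == 0) abort("empty population")
  stopifnot(length(window) == 2, window[2] > window[1])
  n_spk <- sum(raster$neuron %in% neurons &
                 raster$time >= window[1] * 1000 &
                 raster$time < window[2] * 1000)
  n_spk / (length(neurons) * (window[2] - window[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
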