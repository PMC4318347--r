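#' Read and write spike rasters
#'
#' Plain-text raster format: one `time_ms<TAB>neuron_id` event per line,
#' with `#`-prefixed header lines carrying the population metadata
#' (`n_excitatory`, `n_inhibitory`) and, when present, the probe frame
#' metadata (`t_start`, `frame_period`, `n_frames`).
#'
#' @param raster A spike tibble (`time`, `neuron`).
#' @param path File path.
#' @return `read_raster()` returns the raster tibble with its metadata
#'   attributes restored; `write_raster()` returns `path` invisibly.
#' @export
write_raster <- function(raster, path) {
  meta <- c("n_excitatory", "n_inhibitory", "t_start", "frame_period", "n_frames")
  hdr <- character()
  for (m in meta) {
    if (!is.null(attr(raster, m))) {
      hdr <- c(hdr, sprintf("# %s=%s", m, attr(raster, m)))
    }
  }
  body <- sprintf("%d\t%d", raster$time, raster$neuron)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  raster <- if (length(body)) {
    readr::read_tsv(I(body), col_names = c("time", "neuron"),
                    col_types = "ii", progress = FALSE)
  } else {
    tibble(time = integer(), neuron = integer())
  }
  raster <- as_tibble(raster)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2) attr(raster, kv[1]) <- as.numeric(kv[2])
  }
  raster
}

#' Read and write connection (weight snapshot) tables
#'
#' Tabular text with a header row: `pre post delay weight plastic`.
#'
#' @param connections A connection tibble.
#' @param path File path.
#' @export
write_connections <- function(connections, path) {
  readr::write_delim(select(connections, "pre", "post", "delay", "weight", "plastic"),
                     path, delim = " ")
  invisible(path)
}

#' @rdname write_connections
#' @export
read_connections <- function(path) {
  readr::read_delim(path, delim = " ", col_types = "iiidl", progress = FALSE) %>%
    as_tibble() %>%
    mutate(id = dplyr::row_number(), .before = 1) %>%
    mutate(derivative = 0, last_arrival = -Inf)
}

#' Read and write response fingerprints
#'
#' Tabular text `neuron window_start window_end probability` with header
#' metadata (threshold, frames, period) in `#` lines.
#'
#' @param fingerprint A [build_fingerprint()] result.
#' @param path File path.
#' @export
write_fingerprint <- function(fingerprint, path) {
  hdr <- c(
    sprintf("# consistency_threshold=%s", attr(fingerprint, "consistency_threshold")),
    sprintf("# n_frames=%s", attr(fingerprint, "n_frames")),
    sprintf("# frame_period=%s", attr(fingerprint, "frame_period")))
  body <- c("neuron window_start window_end probability",
            sprintf("%d %s %s %s", fingerprint$neuron,
                    fingerprint$window_start, fingerprint$window_end,
                    fingerprint$probability))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_fingerprint
#' @export
read_fingerprint <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  fp <- readr::read_delim(I(body), delim = " ", col_types = "iddd",
                          progress = FALSE) %>%
    as_tibble()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=")[[1]]
    if (length(kv) == 2) attr(fp, kv[1]) <- as.numeric(kv[2])
  }
  class(fp) <- c("fingerprint", class(fp))
  fp
}

#' Read and write stimulus patterns
#'
#' Tabular text `offset_ms neuron_id` with a `# frame_period=` header.
#'
#' @param pattern A stimulus pattern tibble.
#' @param path File path.
#' @export
write_pattern <- function(pattern, path) {
  body <- c("offset neuron",
            sprintf("%d %d", pattern$offset, pattern$neuron))
  writeLines(c(sprintf("# frame_period=%s", attr(pattern, "frame_period")), body),
             path)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  pat <- readr::read_delim(I(body), delim = " ", col_types = "ii",
                           progress = FALSE) %>% as_tibble()
  period <- as.numeric(strsplit(sub("^#\\s*", "", hdr[1]), "=")[[1]][2])
  structure(pat, frame_period = period,
            class = c("stimulus_pattern", class(pat)))
}

#' Write a modification-threshold time series
#'
#' Diagnostic export of the per-neuron threshold series recorded with
#' `record_series = TRUE`: tabular text `time_s neuron theta`.
#'
#' @param series The `neurons` element of a `network_run`'s `series`.
#' @param path File path.
#' @export
write_theta_series <- function(series, path) {
  readr::write_delim(select(series, time_s = "second", "neuron", "theta"),
                     path, delim = " ")
  invisible(path)
}

#' Save and restore a full network snapshot
#'
#' Single-file binary container (RDS) holding the complete simulation
#' state — weights, derivatives, membrane variables, STDP traces,
#' modification thresholds, and in-flight spikes — enabling exact resume:
#' a run continued from a snapshot reproduces the uninterrupted run bit
#' for bit.
#'
#' @param network A `spiking_network`.
#' @param path File path.
#' @export
write_snapshot <- function(network, path) {
  saveRDS(network, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  readRDS(path)
}
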