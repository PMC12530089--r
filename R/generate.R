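#' Configure the synthetic read generator
#'
#' Builds the configuration for [generate_reads()]. Defaults model a
#' realistic run shape without attempting pore physics: read lengths are
#' log-normal with a median of 8,000 samples and sigma(log) = 1, clipped to
#' `[100, 2e6]` samples; signal values follow an integer-rounded Gaussian
#' mixture around two pore current levels, clipped to the signed 16-bit
#' range.
#'
#' @param n_reads Number of reads to generate.
#' @param seed Integer seed; identical configurations generate identical
#'   read sets.
#' @param length_law Named list describing the read-length distribution:
#'   `dist` is `"lognormal"` (fields `meanlog`, `sdlog`), `"uniform"`
#'   (`min`, `max`) or `"fixed"` (`value`), in samples.
#' @param length_bounds Length 2 vector; generated lengths are clipped into
#'   this range (samples).
#' @param signal_law Named list for per-sample values: `dist = "mixture"`
#'   with `means`, `sds` and `weights` of the Gaussian components (ADC
#'   units), or `dist = "uniform"` with `min`, `max`.
#' @param n_channels Number of channels reads cycle over.
#' @param sampling_rate Sampling rate recorded in each read (Hz).
#' @param digitisation ADC levels recorded in each read.
#' @param range Full-scale picoampere range recorded in each read.
#' @return A `gen_config` object.
#' @export
gen_config <- function(n_reads,
                       seed = 1L,
                       length_law = list(dist = "lognormal",
                                         meanlog = log(8000), sdlog = 1),
                       length_bounds = c(100, 2e6),
                       signal_law = list(dist = "mixture",
                                         means = c(480, 760),
                                         sds = c(40, 40),
                                         weights = c(0.5, 0.5)),
                       n_channels = 512L,
                       sampling_rate = 5000,
                       digitisation = 8192,
                       range = 1536) {
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) {
    abort_validation("n_reads must be a positive integer")
  }
  if (length(length_bounds) != 2 || length_bounds[1] > length_bounds[2]) {
    abort_validation("length_bounds must be (min, max) with min <= max")
  }
  if (length_bounds[1] < 0) abort_validation("length_bounds must be non-negative")
  structure(
    list(n_reads = n_reads, seed = as.integer(seed),
         length_law = length_law, length_bounds = as.numeric(length_bounds),
         signal_law = signal_law, n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate, digitisation = digitisation,
         range = range),
    class = "gen_config")
}

#' @export
print.gen_config <- function(x, ...) {
  cat(sprintf("<gen_config> %d reads, seed %d, %s lengths in [%g, %g], %d channels\n",
              x$n_reads, x$seed, x$length_law$dist,
              x$length_bounds[1], x$length_bounds[2], x$n_channels))
  invisible(x)
}

# Draw n read lengths under the configured law (already clipped).
sample_lengths <- function(cfg, n) {
  law <- cfg$length_law
  x <- switch(law$dist,
    lognormal = rlnorm(n, meanlog = law$meanlog, sdlog = law$sdlog),
    uniform = runif(n, law$min, law$max),
    fixed = rep(law$value, n),
    abort_validation(sprintf("unknown length law '%s'", law$dist)))
  pmin(pmax(round(x), cfg$length_bounds[1]), cfg$length_bounds[2])
}

sample_signal <- function(cfg, n_total) {
  law <- cfg$signal_law
  x <- switch(law$dist,
    mixture = {
      comp <- sample.int(length(law$means), n_total, replace = TRUE,
                         prob = law$weights)
      rnorm(n_total, mean = law$means[comp], sd = law$sds[comp])
    },
    uniform = runif(n_total, law$min, law$max),
    abort_validation(sprintf("unknown signal law '%s'", law$dist)))
  as.integer(pmin(pmax(round(x), -32768), 32767))
}

#' Generate a synthetic read set
#'
#' Produces a deterministic, seeded tibble of synthetic nanopore reads: one
#' row per read with calibration fields, auxiliary fields and the raw
#' signal as a list-column. Channel numbers cycle over `1..n_channels` and
#' `start_time` is strictly monotone within each channel.
#'
#' @param cfg A [gen_config()].
#' @return A read tibble with a default [slow5_header()] attached.
#' @export
#' @examples
#' reads <- generate_reads(gen_config(3, seed = 7,
#'   length_law = list(dist = "fixed", value = 50), length_bounds = c(1, 100)))
#' reads$read_id
generate_reads <- function(cfg) {
  if (!inherits(cfg, "gen_config")) abort_validation("cfg must be a gen_config")
  n <- cfg$n_reads
  with_seed(cfg$seed, {
    lens <- sample_lengths(cfg, n)
    tag <- sprintf("%08x", as.integer(floor(runif(n) * 2^31)))
    read_id <- sprintf("%s-%07d", tag, seq_len(n))
    channel_idx <- ((seq_len(n) - 1L) %% cfg$n_channels) + 1L
    gaps <- round(stats::rexp(n, rate = 1 / 1000))
    # per-channel monotone start times: cumulative previous lengths + gaps
    occupied <- lens + gaps
    start_time <- stats::ave(occupied, channel_idx,
                             FUN = function(v) cumsum(v) - v)
    read_number <- stats::ave(seq_len(n), channel_idx,
                              FUN = seq_along) - 1L
    median_before <- rnorm(n, 220, 30)
    median_before[runif(n) < 0.05] <- NA_real_
    offset <- rnorm(n, 15, 4)
    start_mux <- sample.int(4L, n, replace = TRUE)
    sig_all <- sample_signal(cfg, sum(lens))
    signals <- split_by_lengths_cpp(sig_all, as.integer(lens))
    reads <- tibble::tibble(
      read_id = read_id,
      read_group = 0L,
      digitisation = as.numeric(cfg$digitisation),
      offset = offset,
      range = as.numeric(cfg$range),
      sampling_rate = as.numeric(cfg$sampling_rate),
      len_raw_signal = as.integer(lens),
      raw_signal = signals,
      channel_number = as.character(channel_idx),
      median_before = median_before,
      read_number = as.integer(read_number),
      start_mux = as.integer(start_mux),
      start_time = start_time
    )
    header <- slow5_header(
      num_read_groups = 1L,
      attributes = list(run_id = sprintf("synthetic-%08d", cfg$seed),
                        flow_cell_id = "SYN00001",
                        exp_start_time = "1970-01-01T00:00:00Z"))
    set_header(reads, header)
  })
}

#' Read a generator configuration from a flat key=value file
#'
#' Accepts lines of the form `key=value`; unknown keys are rejected. The
#' length and signal laws are flattened as `length_dist`, `length_meanlog`,
#' `length_sdlog`, `length_min`, `length_max`, `length_value`,
#' `signal_dist`, `signal_means`, `signal_sds`, `signal_weights` (comma
#' separated where vector-valued).
#'
#' @param path Path to the config file.
#' @param overrides Named character vector of `key=value` overrides (CLI
#'   flags take precedence over the file).
#' @return A [gen_config()].
#' @export
gen_config_from_file <- function(path = NULL, overrides = character()) {
  kv <- character()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    kv <- lines
  }
  kv <- c(kv, overrides)
  parts <- strsplit(kv, "=", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    abort_validation(sprintf("malformed config entry '%s' (expected key=value)",
                             kv[bad][1]))
  }
  keys <- vapply(parts, `[[`, "", 1)
  vals <- vapply(parts, function(p) paste(p[-1], collapse = "="), "")
  get_num <- function(k, default) {
    if (k %in% keys) as.numeric(vals[match(k, keys)]) else default
  }
  get_vec <- function(k, default) {
    if (k %in% keys) as.numeric(strsplit(vals[match(k, keys)], ",")[[1]]) else default
  }
  known <- c("n_reads", "seed", "n_channels", "sampling_rate", "digitisation",
             "range", "length_dist", "length_meanlog", "length_sdlog",
             "length_min", "length_max", "length_value",
             "length_bound_min", "length_bound_max",
             "signal_dist", "signal_means", "signal_sds", "signal_weights",
             "signal_min", "signal_max")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort_validation(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  length_dist <- if ("length_dist" %in% keys) vals[match("length_dist", keys)] else "lognormal"
  length_law <- switch(length_dist,
    lognormal = list(dist = "lognormal",
                     meanlog = get_num("length_meanlog", log(8000)),
                     sdlog = get_num("length_sdlog", 1)),
    uniform = list(dist = "uniform", min = get_num("length_min", 100),
                   max = get_num("length_max", 10000)),
    fixed = list(dist = "fixed", value = get_num("length_value", 8000)),
    abort_validation(sprintf("unknown length law '%s'", length_dist)))
  signal_dist <- if ("signal_dist" %in% keys) vals[match("signal_dist", keys)] else "mixture"
  signal_law <- switch(signal_dist,
    mixture = list(dist = "mixture",
                   means = get_vec("signal_means", c(480, 760)),
                   sds = get_vec("signal_sds", c(40, 40)),
                   weights = get_vec("signal_weights", c(0.5, 0.5))),
    uniform = list(dist = "uniform", min = get_num("signal_min", -100),
                   max = get_num("signal_max", 100)),
    abort_validation(sprintf("unknown signal law '%s'", signal_dist)))
  gen_config(
    n_reads = get_num("n_reads", 100),
    seed = get_num("seed", 1),
    length_law = length_law,
    length_bounds = c(get_num("length_bound_min", 100),
                      get_num("length_bound_max", 2e6)),
    signal_law = signal_law,
    n_channels = get_num("n_channels", 512),
    sampling_rate = get_num("sampling_rate", 5000),
    digitisation = get_num("digitisation", 8192),
    range = get_num("range", 1536))
}
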