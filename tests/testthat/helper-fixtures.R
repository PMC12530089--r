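# Shared fixture builders: everything is generated in code at test time.

tiny_cfg <- function(n = 20, seed = 1, median_len = 100, sdlog = 1,
                     bounds = c(10, 1000), n_channels = 8) {
  gen_config(n, seed = seed,
             length_law = list(dist = "lognormal",
                               meanlog = log(median_len), sdlog = sdlog),
             length_bounds = bounds, n_channels = n_channels)
}

tiny_reads <- function(n = 20, seed = 1, ...) {
  generate_reads(tiny_cfg(n, seed, ...))
}

# Field-wise equality oracle over every canonical and auxiliary column.
expect_reads_equal <- function(got, want) {
  expect_identical(colnames(got), colnames(want))
  expect_identical(got$read_id, want$read_id)
  expect_identical(got$read_group, want$read_group)
  expect_identical(got$digitisation, want$digitisation)
  expect_identical(got$offset, want$offset)
  expect_identical(got$range, want$range)
  expect_identical(got$sampling_rate, want$sampling_rate)
  expect_identical(got$len_raw_signal, want$len_raw_signal)
  expect_identical(got$raw_signal, want$raw_signal)
  expect_identical(got$channel_number, want$channel_number)
  expect_identical(got$median_before, want$median_before)
  expect_identical(got$read_number, want$read_number)
  expect_identical(got$start_mux, want$start_mux)
  expect_identical(got$start_time, want$start_time)
  for (e in setdiff(colnames(want), c("read_id", "read_group", "digitisation",
                                      "offset", "range", "sampling_rate",
                                      "len_raw_signal", "raw_signal",
                                      "channel_number", "median_before",
                                      "read_number", "start_mux",
                                      "start_time"))) {
    expect_identical(got[[e]], want[[e]])
  }
  invisible(got)
}

# Independent scalar reference for the zigzag-delta transform (wrapping
# 16-bit arithmetic, zigzag as 2d / -2d-1).
naive_zigzag_delta <- function(x) {
  prev <- 0L
  out <- integer(length(x))
  for (i in seq_along(x)) {
    d <- (x[i] - prev) %% 65536L
    if (d >= 32768L) d <- d - 65536L
    out[i] <- if (d >= 0L) 2L * d else -2L * d - 1L
    prev <- x[i]
  }
  out
}

# Independent scalar reference for StreamVByte packing.
naive_svb_encode <- function(values, variant = c("svb16-zd", "svb32-zd")) {
  variant <- match.arg(variant)
  max_bytes <- if (variant == "svb16-zd") 2L else 4L
  per <- if (max_bytes == 2L) 8L else 4L
  n <- length(values)
  count <- integer(8)
  rem <- n
  for (b in 1:8) { count[b] <- rem %% 256L; rem <- rem %/% 256L }
  ctrl <- integer(ceiling(n / per))
  data <- integer(0)
  for (i in seq_along(values)) {
    v <- values[i]
    len <- if (v < 256) 1L else if (v < 65536) 2L else if (v < 2^24) 3L else 4L
    stopifnot(len <= max_bytes)
    slot <- ceiling(i / per)
    if (max_bytes == 2L) {
      if (len == 2L) ctrl[slot] <- ctrl[slot] + 2L^((i - 1L) %% 8L)
    } else {
      ctrl[slot] <- ctrl[slot] + (len - 1L) * 4L^((i - 1L) %% 4L)
    }
    for (b in 0:(len - 1L)) data <- c(data, (v %/% 256^b) %% 256)
  }
  as.raw(c(count, ctrl, data))
}

local_tempfile <- function(ext = "") {
  path <- tempfile(fileext = ext)
  withr::defer(unlink(c(path, paste0(path, ".idx")), force = TRUE),
               envir = parent.frame())
  path
}
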