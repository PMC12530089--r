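test_that("picoampere conversion follows the calibration formula", {
  # raw = -offset forces zero
  r <- list(raw_signal = c(-10L), digitisation = 8192, offset = 10, range = 819.2)
  expect_identical(pa_convert(r), 0)
  # power-of-two digitisation makes the scale exact
  expect_identical(819.2 / 8192, 0.1)
  expect_identical(pa_convert_signal(1L, 8192, 0, 819.2), 0.1)
  # output length equals signal length
  expect_length(pa_convert(list(raw_signal = integer(), digitisation = 1,
                                offset = 0, range = 1)), 0)
})

test_that("picoampere conversion matches an elementwise loop oracle on a fixture", {
  reads <- tiny_reads(100, seed = 11)
  for (i in seq_len(nrow(reads))) {
    got <- pa_convert(reads[i, ])
    want <- vapply(reads$raw_signal[[i]], function(s) {
      (s + reads$offset[i]) * reads$range[i] / reads$digitisation[i]
    }, numeric(1))
    expect_identical(got, want)
  }
})

test_that("picoampere conversion is linear in range and rejects bad calibration", {
  reads <- tiny_reads(3, seed = 2)
  r <- reads[1, ]
  doubled <- r
  doubled$range <- 2 * r$range
  expect_equal(pa_convert(doubled), 2 * pa_convert(r))
  bad <- r
  bad$digitisation <- 0
  expect_error(pa_convert(bad), class = "sigrow_validation_error")
  bad$digitisation <- -5
  expect_error(pa_convert(bad), class = "sigrow_validation_error")
})

test_that("generator is deterministic and honours its bounds", {
  cfg <- tiny_cfg(1, seed = 9)
  one <- generate_reads(cfg)
  expect_identical(nrow(one), 1L)
  expect_true(one$len_raw_signal >= 10 && one$len_raw_signal <= 1000)

  a <- generate_reads(tiny_cfg(50, seed = 4))
  b <- generate_reads(tiny_cfg(50, seed = 4))
  expect_reads_equal(a, b)
  # byte-identical serialized output
  fa <- local_tempfile(".blow5"); fb <- local_tempfile(".blow5")
  write_blow5(a, fa); write_blow5(b, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # a different seed changes the reads
  expect_false(identical(generate_reads(tiny_cfg(50, seed = 5))$read_id,
                         a$read_id))
})

test_that("generator rejects impossible bounds and keeps ids unique", {
  expect_error(gen_config(5, length_bounds = c(100, 10)),
               class = "sigrow_validation_error")
  reads <- tiny_reads(500, seed = 3)
  expect_identical(anyDuplicated(reads$read_id), 0L)
  expect_true(all(reads$len_raw_signal == lengths(reads$raw_signal)))
  expect_true(all(vapply(reads$raw_signal, function(s)
    all(s >= -32768 & s <= 32767), logical(1))))
})

test_that("channel numbers cycle and start times are monotone per channel", {
  reads <- tiny_reads(40, seed = 6, n_channels = 7)
  expect_identical(reads$channel_number,
                   as.character(((seq_len(40) - 1L) %% 7L) + 1L))
  for (ch in unique(reads$channel_number)) {
    st <- reads$start_time[reads$channel_number == ch]
    expect_true(all(diff(st) > 0))
  }
})

test_that("empirical mean read length matches the configured law", {
  # wide bounds so clipping is negligible and the analytic mean applies
  cfg <- gen_config(10000, seed = 21,
                    length_law = list(dist = "lognormal",
                                      meanlog = log(50), sdlog = 0.5),
                    length_bounds = c(1, 1e6), n_channels = 64)
  reads <- generate_reads(cfg)
  lens <- reads$len_raw_signal
  analytic_mean <- exp(log(50) + 0.5^2 / 2)
  se <- stats::sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - analytic_mean), 3 * se)
})
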