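test_that("the consuming workload sums each read's signal", {
  reads <- tiny_reads(1, seed = 1, median_len = 10, bounds = c(3, 3))
  reads$raw_signal[[1]] <- c(1L, 2L, 3L)
  reads$len_raw_signal <- 3L
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  rep <- bench_sequential(f)
  expect_identical(rep$records, 1L)
  expect_identical(sigrow:::sum_signals_cpp(read_blow5(f)$raw_signal), 6)
})

test_that("digests agree across formats, worker counts and batch sizes", {
  reads <- tiny_reads(700, seed = 53, median_len = 30, bounds = c(5, 200))
  fb <- local_tempfile(".blow5")
  fc <- local_tempfile(".colsig")
  write_blow5(reads, fb)
  write_colsig(reads, fc, chunk_size = 64L, interleave = "round_robin")
  reports <- list(
    bench_sequential(fb, n_workers = 1L, batch_size = 1000L),
    bench_sequential(fb, n_workers = 8L, batch_size = 1000L),
    bench_sequential(fb, n_workers = 1L, batch_size = 137L),
    bench_sequential(fc))
  digests <- vapply(reports, function(r) r$checksum, "")
  expect_identical(length(unique(digests)), 1L)
  expect_identical(reports[[1]]$batches, 1L)
  expect_identical(reports[[3]]$batches, 6L)
  expect_true(all(vapply(reports, function(r) r$records, 0L) == 700L))
})

test_that("random-access digest equals the sequential digest on the ID subset", {
  reads <- tiny_reads(300, seed = 59, median_len = 30, bounds = c(5, 200))
  fb <- local_tempfile(".blow5")
  fc <- local_tempfile(".colsig")
  write_blow5(reads, fb)
  build_index(fb)
  write_colsig(reads, fc, chunk_size = 64L)
  ids <- sample_read_ids(fb, 120, seed = 3)
  r_blow <- bench_random(fb, ids)
  r_col <- bench_random(fc, ids)
  expect_identical(r_blow$checksum, r_col$checksum)
  expect_identical(r_blow$seeks, length(ids))
  expect_gt(r_col$seeks, length(ids))
  # recompute the digest from the sequential scan restricted to the IDs
  scan <- read_blow5(fb)
  keep <- scan[match(ids, scan$read_id), ]
  want <- sigrow:::signal_digest(keep$read_id,
                                 sigrow:::sum_signals_cpp(keep$raw_signal))
  expect_identical(r_blow$checksum, want)
})

test_that("narrowing conversions raise conversion errors", {
  reads <- tiny_reads(3, seed = 5)
  reads$sampling_rate <- c(5000, 70000, 5000)  # does not fit uint16
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  expect_error(bench_sequential(f), class = "sigrow_conversion_error")
  reads2 <- tiny_reads(3, seed = 5)
  reads2$channel_number[2] <- "not-a-number"
  f2 <- local_tempfile(".blow5")
  write_blow5(reads2, f2)
  expect_error(bench_sequential(f2), class = "sigrow_conversion_error")
})

test_that("ID sampling is seeded, resolvable, and bounded", {
  reads <- tiny_reads(50, seed = 61, median_len = 20, bounds = c(5, 80))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  build_index(f)
  a <- sample_read_ids(f, 20, seed = 7)
  b <- sample_read_ids(f, 20, seed = 7)
  expect_identical(a, b)
  expect_identical(anyDuplicated(a), 0L)
  got <- fetch_reads(f, a)
  expect_identical(got$read_id, a)
  # k = record count yields a permutation of all IDs
  all_ids <- sample_read_ids(f, 50, seed = 9)
  expect_setequal(all_ids, reads$read_id)
  expect_error(sample_read_ids(f, 51, seed = 1),
               class = "sigrow_validation_error")
})

test_that("bench reports tidy and glance into tibbles", {
  reads <- tiny_reads(10, seed = 2)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  rep <- bench_sequential(f)
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true("phase1_seconds" %in% td$metric)
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$records, 10L)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
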