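test_that("an empty binary file is magic + header + eof and reads back empty", {
  reads <- tiny_reads(2, seed = 1)[0, ]
  f <- local_tempfile(".blow5")
  out <- write_blow5(reads, f)
  expect_identical(out$records, 0L)
  expect_identical(out$bytes, as.integer(file.size(f)))
  back <- read_blow5(f)
  expect_identical(nrow(back), 0L)
  st <- blow5_stats(f)
  expect_identical(st$records, 0L)
})

test_that("fixtures round-trip field-exactly under every codec combination", {
  reads <- tiny_reads(40, seed = 13)
  reads$median_before[3] <- NA_real_
  reads$end_reason <- sample(c("signal_positive", NA), 40, replace = TRUE)
  for (rc in c("none", "zlib", "zstd")) {
    for (sc in c("none", "svb32-zd", "svb16-zd")) {
      f <- local_tempfile(".blow5")
      write_blow5(reads, f, record_codec = rc, signal_codec = sc)
      back <- read_blow5(f)
      expect_reads_equal(back, reads)
      expect_identical(s5_header(back)$record_codec, rc)
      expect_identical(s5_header(back)$signal_codec, sc)
    }
  }
})

test_that("uncompressed signal storage costs two bytes per sample", {
  reads <- tiny_reads(10, seed = 4)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f, record_codec = "none", signal_codec = "none")
  expect_gte(file.size(f), 2 * sum(reads$len_raw_signal))
})

test_that("sequential batches partition the file without altering content", {
  reads <- tiny_reads(2500, seed = 17, median_len = 20, bounds = c(5, 100))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  r <- blow5_reader(f)
  sizes <- integer()
  repeat {
    b <- r$read_batch(1000L)
    if (is.null(b)) break
    sizes <- c(sizes, nrow(b))
  }
  r$close()
  expect_identical(sizes, c(1000L, 1000L, 500L))
  # batch boundaries do not alter the record stream
  expect_reads_equal(read_blow5(f, batch_size = 1L), reads)
  expect_reads_equal(read_blow5(f, batch_size = 997L), reads)
})

test_that("appending to a finalized file is refused", {
  reads <- tiny_reads(3, seed = 2)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  expect_error(blow5_open_append(f), class = "sigrow_validation_error")
})

test_that("a missing eof marker is a truncated-file error", {
  reads <- tiny_reads(5, seed = 3)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  blob <- readBin(f, "raw", file.size(f))
  writeBin(blob[1:(length(blob) - 11)], f)  # cut into the last record
  expect_error(read_blow5(f), class = "sigrow_integrity_error")
})

test_that("a corrupt record is reported with its record number", {
  reads <- tiny_reads(5, seed = 6)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f, record_codec = "zlib")
  build_index(f)
  idx <- load_index(f)
  blob <- readBin(f, "raw", file.size(f))
  # flip bytes inside the third record's compressed body
  at <- idx$offset[3] + 10
  blob[at:(at + 3)] <- as.raw(255 - as.integer(blob[at:(at + 3)]))
  writeBin(blob, f)
  err <- expect_error(read_blow5(f), class = "sigrow_integrity_error")
  expect_match(conditionMessage(err), "record 3")
})

test_that("parallel decode equals sequential decode for any worker count", {
  reads <- tiny_reads(600, seed = 23, median_len = 40, bounds = c(5, 300))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  seq1 <- read_blow5(f)
  for (nw in c(1L, 8L)) {
    par <- parallel_decode(f, n_workers = nw, batch_size = 100L)
    expect_reads_equal(par, seq1)
    expect_identical(sigrow:::sum_signals_cpp(par$raw_signal),
                     sigrow:::sum_signals_cpp(seq1$raw_signal))
  }
})

test_that("low-delta fixtures compress to about one byte per sample", {
  # constructed so the first value and every delta lie in [-64, 63]
  withr::local_seed(31)
  reads <- tiny_reads(5, seed = 31, median_len = 400, bounds = c(200, 800))
  reads$raw_signal <- lapply(reads$len_raw_signal, function(n) {
    as.integer(cumsum(sample(-64:63, n, replace = TRUE)))
  })
  f <- local_tempfile(".blow5")
  write_blow5(reads, f, record_codec = "none", signal_codec = "svb16-zd")
  n_samples <- sum(reads$len_raw_signal)
  # payload bytes = count header + control bytes + 1 data byte per sample
  overhead <- nrow(reads) * (8 + 64 + 128)  # record framing + fields, generous
  expect_lte(file.size(f), n_samples + ceiling(n_samples / 8) +
               overhead + 1000)
  expect_reads_equal(read_blow5(f), reads)
})
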