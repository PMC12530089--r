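test_that("an empty file round-trips header-only", {
  reads <- tiny_reads(3, seed = 1)[0, ]
  f <- local_tempfile(".slow5")
  out <- write_slow5(reads, f)
  expect_identical(out$rows, 0L)
  back <- read_slow5(f)
  expect_identical(nrow(back), 0L)
  expect_identical(s5_header(back)$num_read_groups, 1L)
})

test_that("a small fixture round-trips field-exactly including floats and NA", {
  reads <- tiny_reads(3, seed = 7)
  # exercise full-precision doubles and a missing auxiliary value
  reads$offset[1] <- pi
  reads$range[2] <- 1 / 3
  reads$median_before[2] <- NA_real_
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  expect_reads_equal(read_slow5(f), reads)
})

test_that("header grammar carries version, groups and attributes", {
  reads <- tiny_reads(2, seed = 3)
  hdr <- slow5_header(num_read_groups = 2,
                      attributes = list(run_id = c("a", "b"),
                                        flow_cell_id = c("f1", "f2")))
  reads <- sigrow:::set_header(reads, hdr)
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#slow5_version\t\\d+\\.\\d+\\.\\d+$")
  expect_identical(lines[2], "#num_read_groups\t2")
  expect_identical(lines[3], "@run_id\ta\tb")
  expect_identical(lines[4], "@flow_cell_id\tf1\tf2")
  expect_match(lines[5], "^#read_id\tread_group\t")
  back <- s5_header(read_slow5(f))
  expect_identical(back$num_read_groups, 2L)
  expect_identical(back$attributes$run_id, c("a", "b"))
})

test_that("out-of-range read groups and bad text fields are rejected", {
  reads <- tiny_reads(2, seed = 5)
  reads$read_group <- c(0L, 1L)  # header declares a single group
  f <- local_tempfile(".slow5")
  expect_error(write_slow5(reads, f), class = "sigrow_validation_error")
  reads2 <- tiny_reads(2, seed = 5)
  reads2$channel_number[1] <- "1\t2"
  expect_error(write_slow5(reads2, f), class = "sigrow_validation_error")
})

test_that("a signal length mismatch is an integrity error with a line number", {
  reads <- tiny_reads(2, seed = 8)
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  lines <- readLines(f)
  row <- length(lines)  # corrupt the last data row: claim one fewer sample
  fields <- strsplit(lines[row], "\t", fixed = TRUE)[[1]]
  fields[7] <- as.character(as.integer(fields[7]) - 1L)
  lines[row] <- paste(fields, collapse = "\t")
  writeLines(lines, f)
  err <- expect_error(read_slow5(f), class = "sigrow_integrity_error")
  expect_match(conditionMessage(err), sprintf("line %d", row))
})

test_that("a column-count mismatch is a parse error with a line number", {
  reads <- tiny_reads(2, seed = 8)
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  lines <- readLines(f)
  lines[length(lines)] <- paste0(lines[length(lines)], "\textra")
  writeLines(lines, f)
  err <- expect_error(read_slow5(f), class = "sigrow_integrity_error")
  expect_match(conditionMessage(err), "columns")
})

test_that("unknown extra columns survive as auxiliary text fields", {
  reads <- tiny_reads(4, seed = 9)
  reads$end_reason <- c("signal_positive", "unblock", NA, "signal_positive")
  reads$pore_type <- rep("r10", 4)
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  back <- read_slow5(f)
  expect_identical(back$end_reason, reads$end_reason)
  expect_identical(back$pore_type, reads$pore_type)
  expect_reads_equal(back, reads)
})

test_that("files not starting with a version line are rejected", {
  f <- local_tempfile(".slow5")
  writeLines(c("#not_slow5\t1", "data"), f)
  expect_error(read_slow5(f), class = "sigrow_integrity_error")
})

test_that("zero-length signals use the missing sentinel and round-trip", {
  reads <- tiny_reads(2, seed = 10)
  reads$raw_signal[[1]] <- integer()
  reads$len_raw_signal[1] <- 0L
  f <- local_tempfile(".slow5")
  write_slow5(reads, f)
  expect_reads_equal(read_slow5(f), reads)
})
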