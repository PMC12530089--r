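test_that("index entries cover every record and rebuilds are byte-identical", {
  reads <- tiny_reads(200, seed = 19, median_len = 30, bounds = c(5, 200))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  n <- build_index(f)
  expect_identical(n, 200L)
  idx <- load_index(f)
  expect_identical(idx$read_id, reads$read_id)
  expect_true(all(diff(idx$offset) > 0))           # strictly increasing
  expect_true(all(idx$offset + idx$length <= file.size(f)))
  expect_true(all(head(idx$offset + idx$length, -1) <= tail(idx$offset, -1)))
  first <- readBin(paste0(f, ".idx"), "raw", file.size(paste0(f, ".idx")))
  build_index(f)
  second <- readBin(paste0(f, ".idx"), "raw", file.size(paste0(f, ".idx")))
  expect_identical(first, second)
})

test_that("an empty data file indexes to zero entries", {
  f <- local_tempfile(".blow5")
  write_blow5(tiny_reads(2, seed = 1)[0, ], f)
  expect_identical(build_index(f), 0L)
  expect_identical(nrow(load_index(f)), 0L)
})

test_that("duplicate read IDs cannot be indexed", {
  reads <- tiny_reads(4, seed = 3)
  reads$read_id[2] <- reads$read_id[1]
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  err <- expect_error(build_index(f), class = "sigrow_validation_error")
  expect_match(conditionMessage(err), reads$read_id[1], fixed = TRUE)
})

test_that("fetch returns request order with exactly one seek per read", {
  reads <- tiny_reads(150, seed = 29, median_len = 25, bounds = c(5, 150))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  build_index(f)
  want_ids <- rev(reads$read_id[seq(1, 150, by = 3)])
  got <- fetch_reads(f, want_ids)
  expect_identical(attr(got, "seeks"), length(want_ids))
  expect_identical(got$read_id, want_ids)
  # equals the sequential scan, reordered
  scan <- read_blow5(f)
  expect_reads_equal(got, scan[match(want_ids, scan$read_id), ])
  # duplicates are fetched per occurrence
  dup <- fetch_reads(f, c(want_ids[1], want_ids[1]))
  expect_identical(nrow(dup), 2L)
  expect_identical(dup$raw_signal[[1]], dup$raw_signal[[2]])
})

test_that("fetch unions behave as multisets", {
  reads <- tiny_reads(60, seed = 31, median_len = 20, bounds = c(5, 100))
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  build_index(f)
  ids1 <- reads$read_id[c(3, 9, 27)]
  ids2 <- reads$read_id[c(9, 40)]
  joint <- fetch_reads(f, c(ids1, ids2))
  expect_identical(joint$read_id, c(ids1, ids2))
  split1 <- fetch_reads(f, ids1)
  split2 <- fetch_reads(f, ids2)
  expect_identical(sort(joint$read_id), sort(c(split1$read_id, split2$read_id)))
})

test_that("unknown IDs raise a not-found error naming the ID, or skip on request", {
  reads <- tiny_reads(10, seed = 5)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  build_index(f)
  err <- expect_error(fetch_reads(f, c(reads$read_id[1], "nope")),
                      class = "sigrow_not_found_error")
  expect_match(conditionMessage(err), "nope")
  expect_warning(fetch_reads(f, c(reads$read_id[1], "nope"),
                             on_missing = "skip"))
  got <- suppressWarnings(fetch_reads(f, c(reads$read_id[1], "nope"),
                                      on_missing = "skip"))
  expect_identical(nrow(got), 1L)
})

test_that("a stale index is detected rather than read through", {
  reads <- tiny_reads(10, seed = 7)
  f <- local_tempfile(".blow5")
  write_blow5(reads, f)
  build_index(f)
  write_blow5(tiny_reads(12, seed = 8), f)  # regenerate the data file
  expect_error(load_index(f), class = "sigrow_integrity_error")
  expect_error(fetch_reads(f, reads$read_id[1]),
               class = "sigrow_integrity_error")
})
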