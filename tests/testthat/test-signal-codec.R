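test_that("zigzag-delta matches its stated examples", {
  expect_identical(zigzag_delta(integer()), integer())
  expect_identical(zigzag_delta(c(100L, 102L, 101L)), c(200L, 4L, 1L))
  expect_identical(unzigzag_delta(c(200L, 4L, 1L)), c(100L, 102L, 101L))
})

test_that("zigzag-delta agrees with the scalar reference and inverts exactly", {
  withr::local_seed(101)
  for (rep in 1:200) {
    x <- as.integer(sample(-32768:32767, sample(0:64, 1), replace = TRUE))
    z <- zigzag_delta(x)
    expect_identical(z, naive_zigzag_delta(x))
    expect_true(all(z >= 0 & z <= 65535))
    expect_identical(unzigzag_delta(z), x)
  }
  # extremes wrap losslessly
  x <- c(-32768L, 32767L, -32768L, 0L, 32767L)
  expect_identical(unzigzag_delta(zigzag_delta(x)), x)
})

test_that("svb packing matches its stated examples", {
  expect_identical(svb_encode(integer(), "svb16-zd"),
                   as.raw(c(0, 0, 0, 0, 0, 0, 0, 0)))
  expect_identical(svb_decode(svb_encode(integer(), "svb32-zd"), "svb32-zd"),
                   integer())
  # all values < 256: one zero control byte, one data byte each
  expect_identical(svb_encode(c(200L, 4L, 1L), "svb16-zd"),
                   as.raw(c(3, 0, 0, 0, 0, 0, 0, 0, 0x00, 200, 4, 1)))
  expect_identical(svb_decode(svb_encode(c(0L, 0L, 0L, 0L)), "svb16-zd"),
                   c(0L, 0L, 0L, 0L))
})

test_that("svb round trips match the scalar reference for both variants", {
  withr::local_seed(202)
  for (variant in c("svb16-zd", "svb32-zd")) {
    top <- if (variant == "svb16-zd") 65535 else 2^31 - 1
    for (rep in 1:150) {
      v <- as.integer(floor(runif(sample(0:40, 1), 0, top)))
      v <- c(v, if (length(v) > 0) c(0L, as.integer(top)))  # hit the edges
      payload <- svb_encode(v, variant)
      expect_identical(payload, naive_svb_encode(v, variant))
      expect_identical(svb_decode(payload, variant), v)
    }
  }
})

test_that("svb rejects out-of-range values and malformed payloads", {
  expect_error(svb_encode(70000L, "svb16-zd"), class = "sigrow_validation_error")
  expect_silent(svb_encode(70000L, "svb32-zd"))
  p <- svb_encode(c(5L, 300L, 7L), "svb16-zd")
  expect_error(svb_decode(p[-length(p)], "svb16-zd"),
               class = "sigrow_integrity_error")   # truncated
  expect_error(svb_decode(c(p, as.raw(0)), "svb16-zd"),
               class = "sigrow_integrity_error")   # trailing bytes
  expect_error(svb_decode(p[1:4], "svb16-zd"),
               class = "sigrow_integrity_error")   # truncated count header
  # nonzero pad bits in the final control byte
  bad <- p
  bad[9] <- as.raw(0xF0)
  expect_error(svb_decode(bad, "svb16-zd"), class = "sigrow_integrity_error")
})

test_that("record compression is lossless and none is the identity", {
  withr::local_seed(303)
  blob <- as.raw(sample(0:255, 5000, replace = TRUE))
  expect_identical(record_compress(blob, "none"), blob)
  for (codec in c("zlib", "zstd")) {
    expect_identical(record_decompress(record_compress(blob, codec), codec), blob)
    expect_identical(record_decompress(record_compress(raw(), codec), codec), raw())
  }
  expect_error(record_compress(blob, "lzma"))
})

test_that("the full signal pipeline is the identity for all codec pairs", {
  withr::local_seed(404)
  for (variant in c("svb16-zd", "svb32-zd")) {
    for (codec in c("none", "zlib", "zstd")) {
      for (rep in 1:25) {
        x <- as.integer(sample(-32768:32767, sample(0:300, 1), replace = TRUE))
        wire <- record_compress(svb_encode(zigzag_delta(x), variant), codec)
        back <- unzigzag_delta(svb_decode(record_decompress(wire, codec), variant))
        expect_identical(back, x)
      }
    }
  }
})

test_that("smooth signals pack to one data byte per sample under svb16-zd", {
  withr::local_seed(505)
  for (rep in 1:20) {
    n <- sample(1:500, 1)
    deltas <- sample(-64:63, n, replace = TRUE)
    x <- as.integer(cumsum(deltas))  # first value and deltas all in [-64, 63]
    stopifnot(all(x >= -32768 & x <= 32767))
    payload <- svb_encode(zigzag_delta(x), "svb16-zd")
    expect_identical(length(payload), 8L + as.integer(ceiling(n / 8)) + n)
  }
})
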