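toy_cfg <- function(..., seed = 42) {
  defaults <- list(
    n_positions = 2L, duration_s = 30, channels_per_position = 10L,
    occupancy = 1, chunk_size = 500L, sampling_rate = 5000,
    length_law = list(dist = "lognormal", meanlog = log(400), sdlog = 1),
    length_bounds = c(50, 5000), seed = seed, time_dilation = 10)
  do.call(sim_config, modifyList(defaults, list(...)))
}

test_that("reads at or below the chunk size go direct, longer ones two-pass", {
  expect_identical(classify_read(199999, 200000), "direct")
  expect_identical(classify_read(200000, 200000), "direct")  # boundary
  expect_identical(classify_read(200001, 200000), "two_pass")
  expect_error(classify_read(0, 10), class = "sigrow_validation_error")
})

test_that("the memory budget and chunk-duration arithmetic are exact", {
  gib <- memory_budget_gib(144000, 200000, 2)
  expect_equal(gib, 144000 * 200000 * 2 / 2^30)
  expect_equal(round(gib), 54)            # ~54 GiB worked example
  expect_equal(memory_budget_gib(1, 1, 1), 2^-30)
  expect_equal(memory_budget_gib(2e5, 1000, 2),
               2 * memory_budget_gib(1e5, 1000, 2))  # linear in channels

  expect_equal(chunk_to_bases(200000, 5000, 400), 16000)  # ~16 kbases
  expect_equal(chunk_to_bases(0, 5000, 400), 0)
  expect_equal(chunk_to_bases(200000, 5000, 800),
               2 * chunk_to_bases(200000, 5000, 400))
  expect_error(chunk_to_bases(1, 0, 400), class = "sigrow_validation_error")
})

test_that("position-to-channel structure multiplies out", {
  cfg <- sim_config(n_positions = 39, duration_s = 1)
  expect_identical(cfg$n_positions * cfg$channels_per_position, 117000L)
})

test_that("a toy run conserves samples, stays clean, and leaves no temporaries", {
  outdir <- withr::local_tempdir()
  rep <- run_simulation(toy_cfg(), outdir)
  expect_identical(rep$warnings, 0L)
  expect_identical(rep$temp_files_remaining, 0L)
  expect_identical(rep$samples_written, rep$ledger_samples)
  expect_gt(rep$reads_completed, 0L)

  # conservation re-checked from the files themselves; every read appears in
  # exactly one output, contiguous and complete
  total <- 0
  all_ids <- character()
  for (fpath in c(rep$files$direct, rep$files$merged)) {
    r <- read_blow5(fpath)
    expect_true(all(r$len_raw_signal == lengths(r$raw_signal)))
    total <- total + sum(r$len_raw_signal)
    all_ids <- c(all_ids, r$read_id)
  }
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_identical(total, rep$ledger_samples)
  expect_identical(length(all_ids), rep$reads_completed)

  # direct files hold only chunk-sized-or-shorter reads; merged only longer
  for (p in seq_len(2)) {
    direct <- read_blow5(rep$files$direct[p])
    merged <- read_blow5(rep$files$merged[p])
    expect_true(all(direct$len_raw_signal <= 500))
    expect_true(all(merged$len_raw_signal > 500))
    # two-pass reads land in completion order: per channel, start times rise
    for (ch in unique(merged$channel_number)) {
      expect_true(all(diff(merged$start_time[merged$channel_number == ch]) > 0))
    }
    ends <- merged$start_time + merged$len_raw_signal
    expect_true(all(diff(sort(ends)) >= 0))
  }
})

test_that("a dirty output directory fails loudly instead of double-writing", {
  outdir <- withr::local_tempdir()
  run_simulation(toy_cfg(duration_s = 2), outdir)
  expect_error(run_simulation(toy_cfg(duration_s = 2), outdir),
               class = "sigrow_validation_error")
})

test_that("impossible deadlines always warn", {
  outdir <- withr::local_tempdir()
  rep <- run_simulation(toy_cfg(duration_s = 2, time_dilation = 0), outdir)
  expect_gt(rep$warnings, 0L)
  expect_true(any(rep$latencies$warned))
})

test_that("capacity search returns the throttle's known ceiling", {
  thr <- function(pool, position, tick, n_positions) {
    if (n_positions > 5) Inf else 0
  }
  cfg <- sim_config(n_positions = 1, duration_s = 1,
                    channels_per_position = 3L, occupancy = 1,
                    chunk_size = 500L, sampling_rate = 5000,
                    length_law = list(dist = "fixed", value = 300),
                    length_bounds = c(50, 5000), seed = 1,
                    time_dilation = 50, throttle = thr)
  res1 <- capacity_search(cfg, max_positions = 8, step = 1,
                          outdir = withr::local_tempdir())
  expect_identical(res1$capacity, 5L)
  res3 <- capacity_search(cfg, max_positions = 8, step = 3,
                          outdir = withr::local_tempdir())
  expect_identical(res3$capacity, 5L)   # step-then-refine agrees
  # a throttle that fails immediately reports capacity 0
  cfg0 <- cfg
  cfg0$throttle <- function(pool, position, tick, n_positions) Inf
  res0 <- capacity_search(cfg0, max_positions = 3,
                          outdir = withr::local_tempdir())
  expect_identical(res0$capacity, 0L)
})

test_that("zero-length runs are rejected", {
  expect_error(sim_config(n_positions = 1, duration_s = 0),
               class = "sigrow_validation_error")
})

test_that("sim reports tidy, glance and plot", {
  outdir <- withr::local_tempdir()
  rep <- run_simulation(toy_cfg(duration_s = 2), outdir)
  td <- tidy(rep)
  expect_true(all(c("pool", "position", "tick", "seconds", "warned")
                  %in% colnames(td)))
  expect_setequal(unique(td$pool), c("acquire", "merge", "readback"))
  gl <- glance(rep)
  expect_identical(gl$warnings, 0L)
  expect_s3_class(autoplot(rep), "ggplot")
})
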