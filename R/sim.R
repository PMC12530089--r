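# Acquisition simulator: mimics real-time data acquisition from a
# multi-position nanopore device writing row-format binary files.  Three
# task pools run per position per acquisition tick: acquisition (short
# reads written directly to a per-position file; chunks of long reads
# streamed to one temporary file per read), merge (completed temporary
# files appended whole to a separate per-position file, then deleted) and
# read-back (newly completed records re-read, as live basecalling would).
# A pool task that exceeds its deadline raises a warning counter; capacity
# search increases the position count until warnings appear.

#' Classify a read for direct or two-pass writing
#'
#' Reads no longer than the chunk size fit a single acquisition buffer and
#' are written directly to the output file; longer reads stream through a
#' per-read temporary file and are merged on completion. A read exactly at
#' the boundary goes direct (it fits one chunk buffer).
#'
#' @param length_samples Read length in samples.
#' @param chunk_size Acquisition chunk size in samples.
#' @return `"direct"` or `"two_pass"`.
#' @export
#' @examples
#' classify_read(199999, 200000)  # direct
#' classify_read(200001, 200000)  # two_pass
classify_read <- function(length_samples, chunk_size) {
  if (any(length_samples < 1)) abort_validation("read length must be >= 1")
  ifelse(length_samples <= chunk_size, "direct", "two_pass")
}

#' Acquisition memory budget
#'
#' One chunk buffer per data channel: `n_channels * chunk_size *
#' bytes_per_sample / 2^30` GiB.
#'
#' @param n_channels Total data channels.
#' @param chunk_size Chunk size in samples.
#' @param bytes_per_sample Bytes per signal sample (2 for int16).
#' @return Memory in GiB.
#' @export
#' @examples
#' memory_budget_gib(144000, 200000, 2)  # ~54 GiB
memory_budget_gib <- function(n_channels, chunk_size, bytes_per_sample = 2) {
  if (any(c(n_channels, chunk_size, bytes_per_sample) <= 0)) {
    abort_validation("all memory-budget inputs must be positive")
  }
  n_channels * chunk_size * bytes_per_sample / 2^30
}

#' Bases covered by one signal chunk
#'
#' `chunk_size / sampling_rate * translocation_bps`: the chunk duration in
#' seconds times the translocation speed.
#'
#' @param chunk_size Chunk size in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param translocation_bps Translocation speed in bases per second.
#' @return Number of bases.
#' @export
#' @examples
#' chunk_to_bases(200000, 5000, 400)  # 16000
chunk_to_bases <- function(chunk_size, sampling_rate, translocation_bps) {
  if (sampling_rate <= 0 || translocation_bps <= 0) {
    abort_validation("rates must be positive")
  }
  chunk_size / sampling_rate * translocation_bps
}

#' Configure an acquisition simulation
#'
#' @param n_positions Number of sequencing positions (one flow cell each).
#' @param duration_s Simulated acquisition time in seconds.
#' @param channels_per_position Data channels per position (default 3,000).
#' @param sampling_rate Sampling rate in Hz (default 5,000).
#' @param translocation_bps Translocation speed (default 400 bases/s).
#' @param chunk_size Acquisition chunk size in samples (default 200,000;
#'   at the default rates one chunk spans ~16 kbases).
#' @param bytes_per_sample Bytes per sample (2).
#' @param occupancy Fraction of channels actively sequencing (default
#'   0.45).
#' @param length_law Read-length law as in [gen_config()].
#' @param length_bounds Clipping bounds for read lengths (samples).
#' @param seed Integer seed.
#' @param time_dilation Deadline scale factor: a pool task warns when its
#'   wall time exceeds `chunk_size / sampling_rate * time_dilation`
#'   seconds. 1 reproduces real-time deadlines; larger values relax them
#'   so a desk-scale run can compress a long acquisition into seconds of
#'   wall time while preserving deadline semantics; 0 makes every deadline
#'   impossible.
#' @param record_codec,signal_codec Codecs for the output files.
#' @param throttle Optional function `(pool, position, tick, n_positions)`
#'   returning artificial extra task seconds; used to inject deterministic
#'   deadline misses in capacity experiments.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_positions, duration_s,
                       channels_per_position = 3000L,
                       sampling_rate = 5000,
                       translocation_bps = 400,
                       chunk_size = 200000L,
                       bytes_per_sample = 2L,
                       occupancy = 0.45,
                       length_law = list(dist = "lognormal",
                                         meanlog = log(8000), sdlog = 1),
                       length_bounds = c(100, 2e6),
                       seed = 1L,
                       time_dilation = 1,
                       record_codec = "none",
                       signal_codec = "svb16-zd",
                       throttle = NULL) {
  n_positions <- as.integer(n_positions)
  if (is.na(n_positions) || n_positions < 1L) {
    abort_validation("n_positions must be >= 1")
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort_validation("duration_s must be positive (zero-length runs are not meaningful)")
  }
  if (occupancy <= 0 || occupancy > 1) {
    abort_validation("occupancy must lie in (0, 1]")
  }
  if (time_dilation < 0) abort_validation("time_dilation must be >= 0")
  structure(
    list(n_positions = n_positions, duration_s = duration_s,
         channels_per_position = as.integer(channels_per_position),
         sampling_rate = sampling_rate,
         translocation_bps = translocation_bps,
         chunk_size = as.integer(chunk_size),
         bytes_per_sample = as.integer(bytes_per_sample),
         occupancy = occupancy, length_law = length_law,
         length_bounds = as.numeric(length_bounds),
         seed = as.integer(seed), time_dilation = time_dilation,
         record_codec = record_codec, signal_codec = signal_codec,
         throttle = throttle),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d position(s) x %d channels, %g Hz, chunk %d (%.3fs), %gs run, dilation %g\n",
    x$n_positions, x$channels_per_position, x$sampling_rate, x$chunk_size,
    x$chunk_size / x$sampling_rate, x$duration_s, x$time_dilation))
  invisible(x)
}

# cheap deterministic signal content: the simulator exercises I/O and
# timing, not pore physics
sim_signal <- function(len, channel, phase) {
  as.integer(((seq_len(len) + phase + 13L * channel) %% 701L) - 350L)
}

sim_header <- function(cfg) {
  slow5_header(
    num_read_groups = 1L,
    attributes = list(run_id = sprintf("sim-%08d", cfg$seed)),
    record_codec = cfg$record_codec,
    signal_codec = cfg$signal_codec)
}

#' Run an acquisition simulation
#'
#' Executes the tick loop: each tick, per position, the acquisition task
#' generates up to one chunk of samples per active channel (writing direct
#' reads to `pos<i>.blow5` and streaming long-read chunks to per-read
#' temporary files), the merge task appends completed temporary files to
#' `pos<i>_merged.blow5` and deletes them, and the read-back task re-reads
#' newly completed records. Any task whose wall time exceeds the deadline
#' increments the warning counter.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory; must not contain output from a previous
#'   run (a dirty directory fails loudly rather than double-writing).
#' @return A `sim_report`.
#' @export
run_simulation <- function(cfg, outdir) {
  if (!inherits(cfg, "sim_config")) abort_validation("cfg must be a sim_config")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) abort_io(sprintf("cannot create outdir %s", outdir))
  existing <- list.files(outdir, pattern = "^(pos[0-9]+.*\\.blow5|tmp_pos)")
  if (length(existing) > 0) {
    abort_validation(sprintf(
      "outdir %s contains output from a previous run (%s); refusing to double-write",
      outdir, existing[1]))
  }

  chunk_interval <- cfg$chunk_size / cfg$sampling_rate
  deadline <- chunk_interval * cfg$time_dilation
  n_ticks <- as.integer(ceiling(cfg$duration_s / chunk_interval))
  n_active <- max(1L, as.integer(round(cfg$occupancy * cfg$channels_per_position)))
  header <- sim_header(cfg)
  throttle <- cfg$throttle %||% function(pool, position, tick, n_positions) 0

  warnings_n <- 0L
  reads_completed <- 0L
  samples_written <- 0
  ledger_samples <- 0
  lat_pool <- character(); lat_pos <- integer(); lat_tick <- integer()
  lat_sec <- numeric(); lat_warn <- logical()

  note_task <- function(pool, p, tick, t0) {
    extra <- throttle(pool, p, tick, cfg$n_positions)
    secs <- (proc.time()[["elapsed"]] - t0) + extra
    warned <- secs > deadline
    if (warned) warnings_n <<- warnings_n + 1L
    lat_pool[length(lat_pool) + 1L] <<- pool
    lat_pos[length(lat_pos) + 1L] <<- p
    lat_tick[length(lat_tick) + 1L] <<- tick
    lat_sec[length(lat_sec) + 1L] <<- secs
    lat_warn[length(lat_warn) + 1L] <<- warned
  }

  positions <- vector("list", cfg$n_positions)
  for (p in seq_len(cfg$n_positions)) {
    tmpdir <- file.path(outdir, sprintf("tmp_pos%03d", p))
    dir.create(tmpdir)
    positions[[p]] <- new.env(parent = emptyenv())
    pos <- positions[[p]]
    pos$direct <- blow5_open_write(file.path(outdir, sprintf("pos%03d.blow5", p)), header)
    pos$merged <- blow5_open_write(file.path(outdir, sprintf("pos%03d_merged.blow5", p)), header)
    pos$tmpdir <- tmpdir
    pos$ch_target <- rep(NA_real_, n_active)   # current read length, NA = idle
    pos$ch_done <- rep(0, n_active)
    pos$ch_clock <- rep(0, n_active)           # samples elapsed per channel
    pos$ch_nread <- rep(0L, n_active)
    pos$ch_tmp <- vector("list", n_active)     # open temp connection or NULL
    pos$ch_meta <- vector("list", n_active)    # metadata of the open read
    pos$done_meta <- list()                    # meta keyed by .done path
    pos$rb_offset <- c(direct = 0, merged = 0) # read-back progress (bytes)
    pos$rb_reads <- 0L
  }

  start_read <- function(pos, p, ch) {
    len <- sample_lengths(cfg, 1L)
    pos$ch_nread[ch] <- pos$ch_nread[ch] + 1L
    meta <- list(
      read_id = sprintf("p%02dc%04dr%05d", p, ch, pos$ch_nread[ch]),
      channel_number = as.character(ch),
      read_number = pos$ch_nread[ch] - 1L,
      start_mux = sample.int(4L, 1L),
      start_time = pos$ch_clock[ch],
      median_before = round(rnorm(1, 220, 30), 3),
      offset = round(rnorm(1, 15, 4), 3),
      length = len)
    pos$ch_target[ch] <- len
    pos$ch_done[ch] <- 0
    pos$ch_meta[[ch]] <- meta
    if (len > cfg$chunk_size) {
      tmp <- file.path(pos$tmpdir, paste0(meta$read_id, ".part"))
      pos$ch_tmp[[ch]] <- file(tmp, "wb")
      attr(pos$ch_tmp[[ch]], "path") <- tmp
    }
  }

  meta_to_row <- function(meta, signal, cfg) {
    tibble::tibble(
      read_id = meta$read_id, read_group = 0L,
      digitisation = 8192, offset = meta$offset, range = 1536,
      sampling_rate = cfg$sampling_rate,
      len_raw_signal = length(signal), raw_signal = list(signal),
      channel_number = meta$channel_number,
      median_before = meta$median_before,
      read_number = meta$read_number, start_mux = meta$start_mux,
      start_time = meta$start_time)
  }

  finish_read <- function(pos, p, ch) {
    meta <- pos$ch_meta[[ch]]
    ledger_samples <<- ledger_samples + meta$length
    pos$ch_target[ch] <- NA_real_
    pos$ch_meta[ch] <- list(NULL)
  }

  acquire_tick <- function(pos, p, tick) {
    direct_rows <- list()
    for (ch in seq_len(n_active)) {
      if (is.na(pos$ch_target[ch])) start_read(pos, p, ch)
      meta <- pos$ch_meta[[ch]]
      take <- min(cfg$chunk_size, pos$ch_target[ch] - pos$ch_done[ch])
      sig <- sim_signal(take, ch, pos$ch_done[ch])
      pos$ch_done[ch] <- pos$ch_done[ch] + take
      pos$ch_clock[ch] <- pos$ch_clock[ch] + cfg$chunk_size
      if (meta$length <= cfg$chunk_size) {
        # direct read: completes within this tick
        direct_rows[[length(direct_rows) + 1L]] <- meta_to_row(meta, sig, cfg)
        finish_read(pos, p, ch)
      } else {
        con <- pos$ch_tmp[[ch]]
        writeBin(sig, con, size = 2L, endian = "little")
        if (pos$ch_done[ch] >= meta$length) {
          path <- attr(con, "path")
          close(con)
          pos$ch_tmp[ch] <- list(NULL)
          done_path <- sub("\\.part$", ".done", path)
          file.rename(path, done_path)
          pos$done_meta[[done_path]] <- meta
          finish_read(pos, p, ch)
        }
      }
    }
    if (length(direct_rows) > 0) {
      rows <- dplyr::bind_rows(direct_rows)
      blow5_append(pos$direct, rows)
      flush(pos$direct$con)
      reads_completed <<- reads_completed + nrow(rows)
      samples_written <<- samples_written + sum(rows$len_raw_signal)
    }
  }

  merge_tick <- function(pos, p, tick) {
    done <- names(pos$done_meta) %||% character()
    done <- done[file.exists(done)]
    if (length(done) == 0) return(invisible())
    rows <- vector("list", length(done))
    for (i in seq_along(done)) {
      meta <- pos$done_meta[[done[i]]]
      sig <- readBin(done[i], "integer", n = meta$length, size = 2L,
                     signed = TRUE, endian = "little")
      if (length(sig) != meta$length) {
        abort_integrity(sprintf("temporary file %s is short", done[i]))
      }
      rows[[i]] <- meta_to_row(meta, as.integer(sig), cfg)
    }
    rows <- dplyr::bind_rows(rows)
    blow5_append(pos$merged, rows)
    flush(pos$merged$con)
    file.remove(done)
    for (d in done) pos$done_meta[[d]] <- NULL
    reads_completed <<- reads_completed + nrow(rows)
    samples_written <<- samples_written + sum(rows$len_raw_signal)
  }

  readback_tick <- function(pos, p, tick) {
    for (which_file in c("direct", "merged")) {
      w <- if (which_file == "direct") pos$direct else pos$merged
      from <- pos$rb_offset[[which_file]]
      if (from == 0) from <- w$data_start
      if (w$bytes <= from) next
      con <- file(w$path, "rb")
      seek(con, from, origin = "start")
      blob <- readBin(con, "raw", n = w$bytes - from)
      close(con)
      res <- decode_frames_cpp(blob, 0, .Machine$integer.max, w$rc, w$sc, 0)
      pos$rb_reads <- pos$rb_reads + res$n
      pos$rb_offset[[which_file]] <- from + res$`next`
      # live-basecalling stand-in: consume the decoded signal
      invisible(sum_signals_cpp(res$fields$raw_signal))
    }
  }

  with_seed(cfg$seed, {
    for (tick in seq_len(n_ticks)) {
      for (p in seq_len(cfg$n_positions)) {
        pos <- positions[[p]]
        t0 <- proc.time()[["elapsed"]]
        acquire_tick(pos, p, tick)
        note_task("acquire", p, tick, t0)
        t0 <- proc.time()[["elapsed"]]
        merge_tick(pos, p, tick)
        note_task("merge", p, tick, t0)
        t0 <- proc.time()[["elapsed"]]
        readback_tick(pos, p, tick)
        note_task("readback", p, tick, t0)
      }
    }
    # final merge pass picks up reads completed on the last tick
    for (p in seq_len(cfg$n_positions)) {
      pos <- positions[[p]]
      t0 <- proc.time()[["elapsed"]]
      merge_tick(pos, p, n_ticks + 1L)
      note_task("merge", p, n_ticks + 1L, t0)
      readback_tick(pos, p, n_ticks + 1L)
    }
  })

  bytes_written <- 0
  for (p in seq_len(cfg$n_positions)) {
    pos <- positions[[p]]
    # discard temporaries of reads still in flight at shutdown
    for (ch in seq_len(n_active)) {
      con <- pos$ch_tmp[[ch]]
      if (!is.null(con)) {
        path <- attr(con, "path")
        close(con)
        file.remove(path)
      }
    }
    s1 <- blow5_close(pos$direct)
    s2 <- blow5_close(pos$merged)
    bytes_written <- bytes_written + s1$bytes + s2$bytes
    leftover <- list.files(pos$tmpdir, full.names = TRUE)
    if (length(leftover) > 0) file.remove(leftover)
    unlink(pos$tmpdir, recursive = TRUE)
  }
  temp_left <- length(list.files(outdir, pattern = "^tmp_pos", recursive = TRUE))

  structure(
    list(warnings = warnings_n,
         reads_completed = reads_completed,
         samples_written = samples_written,
         bytes_written = bytes_written,
         ledger_samples = ledger_samples,
         ram_peak_estimate_bytes =
           as.numeric(cfg$n_positions) * n_active * cfg$chunk_size *
           cfg$bytes_per_sample,
         temp_files_remaining = temp_left,
         reads_read_back = sum(vapply(positions, function(pos) pos$rb_reads, 0L)),
         file_size_per_hour_gib =
           bytes_written / cfg$duration_s * 3600 / 2^30,
         latencies = tibble::tibble(pool = lat_pool, position = lat_pos,
                                    tick = lat_tick, seconds = lat_sec,
                                    deadline = deadline, warned = lat_warn),
         files = tibble::tibble(
           position = seq_len(cfg$n_positions),
           direct = file.path(outdir, sprintf("pos%03d.blow5",
                                              seq_len(cfg$n_positions))),
           merged = file.path(outdir, sprintf("pos%03d_merged.blow5",
                                              seq_len(cfg$n_positions)))),
         config = cfg),
    class = "sim_report")
}

#' @export
print.sim_report <- function(x, ...) {
  cat(sprintf(
    "<sim_report> %d reads (%.0f samples) across %d position(s); %d warning(s); %d temp file(s) left\n",
    x$reads_completed, x$samples_written, x$config$n_positions, x$warnings,
    x$temp_files_remaining))
  cat(sprintf("  bytes written %.0f (%.2f GiB/h), RAM estimate %.2f GiB, read back %d reads\n",
              x$bytes_written, x$file_size_per_hour_gib,
              x$ram_peak_estimate_bytes / 2^30, x$reads_read_back))
  invisible(x)
}

#' Find the largest clean position count
#'
#' Runs simulations at increasing position counts until warnings appear;
#' even a single warning marks a count as failed. Returns the largest
#' tested count with zero warnings (0 when one position already warns).
#' With `step > 1`, the last clean window is refined in unit steps.
#'
#' @param base_cfg A [sim_config()]; its `n_positions` is overridden.
#' @param max_positions Largest position count to try.
#' @param step Increment between tested counts.
#' @param outdir Scratch directory for the runs.
#' @return A `capacity_search` object with elements `capacity` and `trace`.
#' @export
capacity_search <- function(base_cfg, max_positions, step = 1L,
                            outdir = tempfile("capacity")) {
  if (!inherits(base_cfg, "sim_config")) {
    abort_validation("base_cfg must be a sim_config")
  }
  step <- as.integer(step)
  if (is.na(step) || step < 1L) abort_validation("step must be >= 1")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  trace_n <- integer(); trace_w <- integer()
  run_at <- function(n) {
    cfg <- base_cfg
    cfg$n_positions <- as.integer(n)
    rep <- run_simulation(cfg, file.path(outdir, sprintf("n%04d", n)))
    trace_n[length(trace_n) + 1L] <<- n
    trace_w[length(trace_w) + 1L] <<- rep$warnings
    rep$warnings
  }
  capacity <- 0L
  tested <- seq(1L, as.integer(max_positions), by = step)
  failed_at <- NA_integer_
  for (n in tested) {
    w <- run_at(n)
    if (w > 0L) { failed_at <- n; break }
    capacity <- n
  }
  if (!is.na(failed_at) && step > 1L && capacity > 0L &&
      failed_at - capacity > 1L) {
    for (n in seq(capacity + 1L, failed_at - 1L)) {
      w <- run_at(n)
      if (w > 0L) break
      capacity <- n
    }
  }
  structure(list(capacity = capacity,
                 trace = tibble::tibble(n_positions = trace_n,
                                        warnings = trace_w)),
            class = "capacity_search")
}

#' @export
print.capacity_search <- function(x, ...) {
  cat(sprintf("<capacity_search> max clean positions: %d (%d run(s))\n",
              x$capacity, nrow(x$trace)))
  invisible(x)
}
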