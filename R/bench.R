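# Benchmark harness: timed sequential and random reads with the
# basecaller-style field-access pattern (fields touched in the order a
# basecalling loader touches them, with its narrowing type conversions),
# signal summation as the consuming workload, and an order-invariant
# per-read digest that must agree across formats, worker counts and batch
# sizes.  Wall-clock numbers are reported, never asserted.

# Field access in basecaller-loader order with conversion penalties:
# id, signal, sampling_rate -> uint16, channel -> uint16, scale =
# range/digitisation, read_number, start_time, mux.
dorado_style_access <- function(reads) {
  ids <- reads$read_id
  sums <- sum_signals_cpp(reads$raw_signal)
  srate <- reads$sampling_rate
  if (any(srate < 0 | srate > 65535)) {
    abort_conversion(sprintf(
      "sampling_rate %g does not fit uint16 for read '%s'",
      srate[which(srate < 0 | srate > 65535)[1]],
      ids[which(srate < 0 | srate > 65535)[1]]))
  }
  srate_u16 <- as.integer(srate)
  chan <- suppressWarnings(as.integer(reads$channel_number))
  bad <- is.na(chan) | chan < 0 | chan > 65535
  if (any(bad)) {
    abort_conversion(sprintf(
      "channel_number '%s' does not fit uint16 for read '%s'",
      reads$channel_number[which(bad)[1]], ids[which(bad)[1]]))
  }
  scale <- reads$range / reads$digitisation
  meta_touch <- sum(srate_u16) + sum(chan) + sum(scale) +
    sum(reads$read_number) + sum(reads$start_time) + sum(reads$start_mux)
  list(ids = ids, sums = sums, meta_touch = meta_touch)
}

# Order-invariant digest over (read_id, signal sum) pairs.
signal_digest <- function(ids, sums) {
  o <- order(ids, method = "radix")
  fnv_digest_cpp(ids[o], sums[o])
}

new_bench_report <- function(phase1_seconds, records, batches, checksum,
                             seeks, config) {
  structure(
    list(phase1_seconds = phase1_seconds, records = records,
         batches = batches, checksum = checksum,
         peak_mem_bytes = peak_rss_bytes(), seeks = seeks, config = config),
    class = "bench_report")
}

#' @export
print.bench_report <- function(x, ...) {
  cat(sprintf(
    "<bench_report> %s %s: %d records in %d batch(es), %.3fs load+parse, %d seeks, digest %s\n",
    x$config$mode, x$config$format, x$records, x$batches,
    x$phase1_seconds, x$seeks, x$checksum))
  invisible(x)
}

#' Timed sequential read benchmark
#'
#' Step 1 loads, decompresses and parses the file batch by batch (timed);
#' step 2 touches the metadata fields in basecaller-loader order, applying
#' the narrowing conversions (sampling rate and channel number to unsigned
#' 16-bit; scale = range/digitisation), and sums each read's signal values;
#' step 3 digests the per-read sums. The digest is independent of format,
#' worker count and batch size; times and memory are hardware-dependent
#' and only reported.
#'
#' @param path Path to a `.blow5` or `.colsig` file.
#' @param format `"blow5"` or `"colsig"`; guessed from the extension when
#'   missing.
#' @param n_workers Decode workers (binary format only).
#' @param batch_size Reads per batch (default 1,000).
#' @return A `bench_report`.
#' @export
bench_sequential <- function(path, format = NULL, n_workers = 1L,
                             batch_size = 1000L) {
  format <- format %||% guess_format(path)
  t0 <- proc.time()[["elapsed"]]
  reads <- switch(format,
    blow5 = if (n_workers > 1L) {
      parallel_decode(path, n_workers = n_workers, batch_size = batch_size)
    } else {
      read_blow5(path, batch_size = batch_size)
    },
    colsig = read_colsig(path),
    abort_validation(sprintf("unknown format '%s'", format)))
  phase1 <- proc.time()[["elapsed"]] - t0
  acc <- dorado_style_access(reads)
  new_bench_report(
    phase1_seconds = phase1,
    records = nrow(reads),
    batches = as.integer(ceiling(nrow(reads) / batch_size)),
    checksum = signal_digest(acc$ids, acc$sums),
    seeks = 0L,
    config = list(mode = "sequential", path = path, format = format,
                  n_workers = n_workers, batch_size = batch_size))
}

#' Timed random-access benchmark
#'
#' Fetches the listed read IDs via the index (binary format) or the walker
#' (columnar format), then applies the same consuming workload and digest
#' as [bench_sequential()]. Seek counts are recorded.
#'
#' @param path Path to a `.blow5` or `.colsig` file.
#' @param read_ids Character vector of IDs, or path to a file with one ID
#'   per line.
#' @param format `"blow5"` or `"colsig"`; guessed from the extension when
#'   missing.
#' @return A `bench_report`.
#' @export
bench_random <- function(path, read_ids, format = NULL) {
  format <- format %||% guess_format(path)
  if (length(read_ids) == 1L && file.exists(read_ids)) {
    read_ids <- readLines(read_ids, warn = FALSE)
    read_ids <- read_ids[nzchar(read_ids)]
  }
  t0 <- proc.time()[["elapsed"]]
  reads <- switch(format,
    blow5 = fetch_reads(path, read_ids),
    colsig = walker_fetch(path, read_ids),
    abort_validation(sprintf("unknown format '%s'", format)))
  phase1 <- proc.time()[["elapsed"]] - t0
  acc <- dorado_style_access(reads)
  new_bench_report(
    phase1_seconds = phase1,
    records = nrow(reads),
    batches = 1L,
    checksum = signal_digest(acc$ids, acc$sums),
    seeks = attr(reads, "seeks") %||% NA_integer_,
    config = list(mode = "random", path = path, format = format,
                  n_ids = length(read_ids)))
}

guess_format <- function(path) {
  if (grepl("\\.blow5$", path)) "blow5"
  else if (grepl("\\.colsig$", path)) "colsig"
  else if (grepl("\\.slow5$", path)) "slow5"
  else abort_validation(sprintf("cannot guess format of '%s'", path))
}

#' Sample read IDs for a random-access workload
#'
#' Draws a uniform sample of read IDs without replacement, deterministically
#' for a given seed, mirroring how a random-access benchmark ID list is
#' prepared.
#'
#' @param path Path to a `.blow5` (uses its index, building it if absent)
#'   or `.colsig` file.
#' @param k Number of IDs to draw; must not exceed the record count.
#' @param seed Integer seed.
#' @param out Optional path; when given, IDs are written one per line.
#' @return Character vector of sampled IDs (invisibly when `out` is given).
#' @export
sample_read_ids <- function(path, k, seed = 1L, out = NULL) {
  ids <- if (guess_format(path) == "blow5") {
    if (!file.exists(index_path_for(path))) build_index(path)
    load_index(path)$read_id
  } else {
    read_colsig(path)$read_id
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(ids)) {
    abort_validation(sprintf("k must be in 1..%d (record count)", length(ids)))
  }
  picked <- with_seed(seed, ids[sample.int(length(ids), k)])
  if (!is.null(out)) {
    writeLines(picked, out)
    return(invisible(picked))
  }
  picked
}
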