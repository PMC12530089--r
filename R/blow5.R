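# Binary dialect (.blow5): magic, version/codec bytes, a record_codec-
# compressed header block, then length-prefixed per-record-compressed rows
# in write order, closed by an end-of-file marker.  All integers are
# little-endian; doubles are 8-byte IEEE-754.

READ_BUFFER_BYTES <- 4L * 1024L * 1024L

#' Open a binary writer
#'
#' Creates a `.blow5` file, writes its header, and returns a handle that
#' accepts successive batches of reads via [blow5_append()] until
#' [blow5_close()] finalizes the file with the end-of-file marker. This is
#' the streaming interface behind [write_blow5()] and the acquisition
#' simulator.
#'
#' @param path Output path.
#' @param header A [slow5_header()]; its codecs decide record and signal
#'   compression.
#' @return A writer handle.
#' @export
blow5_open_write <- function(path, header = slow5_header()) {
  rc <- codec_id(header$record_codec, RECORD_CODECS, "record")
  sc <- codec_id(header$signal_codec, SIGNAL_CODECS, "signal")
  con <- file(path, "wb")
  writeBin(MAGIC_BLOW5, con)
  writeBin(as.raw(c(header$version, rc, sc)), con)
  hblob <- compress_cpp(header_to_blob(header), rc)
  write_u32(con, length(hblob))
  writeBin(hblob, con)
  w <- new.env(parent = emptyenv())
  w$con <- con
  w$path <- path
  w$header <- header
  w$rc <- rc
  w$sc <- sc
  w$n_records <- 0L
  w$data_start <- 8L + 5L + 4L + length(hblob)
  w$bytes <- w$data_start
  w$finalized <- FALSE
  class(w) <- "blow5_writer"
  w
}

#' @rdname blow5_open_write
#' @param w A writer handle.
#' @param reads A read tibble to append.
#' @export
blow5_append <- function(w, reads) {
  if (w$finalized) abort_validation("writer already finalized")
  validate_reads(reads, w$header)
  if (nrow(reads) == 0) return(invisible(w))
  enc <- encode_records_cpp(fields_for_cpp(reads), w$sc, w$rc)
  writeBin(enc$blob, w$con)
  w$n_records <- w$n_records + nrow(reads)
  w$bytes <- w$bytes + length(enc$blob)
  invisible(w)
}

#' @rdname blow5_open_write
#' @export
blow5_close <- function(w) {
  if (!w$finalized) {
    writeBin(EOF_MARKER, w$con)
    w$bytes <- w$bytes + length(EOF_MARKER)
    w$finalized <- TRUE
  }
  close(w$con)
  invisible(list(records = w$n_records, bytes = w$bytes))
}

#' Write reads to the binary dialect
#'
#' @param reads A read tibble.
#' @param path Output path (conventionally `.blow5`).
#' @param header A [slow5_header()]; defaults to the one attached to
#'   `reads`, with codecs overridable below.
#' @param record_codec,signal_codec Optional codec overrides.
#' @return Invisibly, a list with `records` and `bytes` written.
#' @export
write_blow5 <- function(reads, path, header = s5_header(reads),
                        record_codec = NULL, signal_codec = NULL) {
  if (!is.null(record_codec)) header$record_codec <- record_codec
  if (!is.null(signal_codec)) header$signal_codec <- signal_codec
  codec_id(header$record_codec, RECORD_CODECS, "record")
  codec_id(header$signal_codec, SIGNAL_CODECS, "signal")
  w <- blow5_open_write(path, header)
  ok <- FALSE
  on.exit(if (!ok) close(w$con))
  blow5_append(w, reads)
  ok <- TRUE
  on.exit()
  invisible(blow5_close(w))
}

#' Refuse to append to a finalized file
#'
#' A valid binary file ends with the end-of-file marker; reopening one for
#' append without truncating that marker would corrupt the record stream,
#' so this always fails on a finalized file. It exists so callers get a
#' loud, early error rather than a corrupt file.
#'
#' @param path Path to a `.blow5` file.
#' @return Never returns for a finalized file; errors.
#' @export
blow5_open_append <- function(path) {
  f <- aud_open(path)
  on.exit(aud_close(f))
  if (f$size >= length(EOF_MARKER)) {
    aud_seek(f, f$size - length(EOF_MARKER))
    tailb <- aud_read(f, length(EOF_MARKER))
    if (identical(tailb, EOF_MARKER)) {
      abort_validation(sprintf(
        "%s is finalized (ends with the end-of-file marker); appending would corrupt it",
        path))
    }
  }
  abort_integrity(sprintf("%s is not a finalized binary file", path))
}

read_blow5_prelude <- function(con) {
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, MAGIC_BLOW5)) {
    abort_integrity("not a binary signal file (bad magic)")
  }
  meta <- as.integer(readBin(con, "raw", n = 5L))
  version <- meta[1:3]
  rc <- meta[4]
  sc <- meta[5]
  hlen <- read_u32(con)
  hblob <- readBin(con, "raw", n = hlen)
  if (length(hblob) != hlen) abort_integrity("truncated header block")
  header <- header_from_blob(decompress_cpp(hblob, rc),
                             codec_name(rc, RECORD_CODECS),
                             codec_name(sc, SIGNAL_CODECS))
  header$version <- version
  list(header = header, rc = rc, sc = sc, data_start = 8L + 5L + 4L + hlen)
}

#' Open a streaming binary reader
#'
#' Returns a handle with the parsed header and a `read_batch(n)` closure
#' yielding successive batches of at most `n` parsed reads (as tibbles) in
#' file order, or `NULL` at end of file. A missing end-of-file marker
#' raises a truncated-file error.
#'
#' @param path Path to a `.blow5` file.
#' @return A reader handle (environment) with elements `header`,
#'   `read_batch` (parsed tibbles), `read_raw_batch` (undecoded frame blobs
#'   for worker-parallel decoding), and `close`.
#' @export
blow5_reader <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  prelude <- read_blow5_prelude(con)
  r <- new.env(parent = emptyenv())
  r$header <- prelude$header
  r$rc <- prelude$rc
  r$sc <- prelude$sc
  r$buf <- raw()
  r$pos <- 0
  r$base <- prelude$data_start  # file offset of buf[1]
  r$eof <- FALSE
  r$done <- 0
  r$con <- con

  refill <- function() {
    chunk <- readBin(con, "raw", n = READ_BUFFER_BYTES)
    if (length(chunk) == 0) return(FALSE)
    if (r$pos > 0) {
      r$buf <- r$buf[-seq_len(r$pos)]
      r$base <- r$base + r$pos
      r$pos <- 0
    }
    r$buf <- c(r$buf, chunk)
    TRUE
  }

  r$read_batch <- function(n = 1000L) {
    if (r$eof && r$pos >= length(r$buf)) return(NULL)
    pieces <- list()
    offsets <- numeric()
    lengths <- numeric()
    got <- 0L
    repeat {
      res <- reclassify_cpp_error(
        decode_frames_cpp(r$buf, r$pos, n - got, r$rc, r$sc, r$done + got))
      if (res$n > 0) {
        pieces[[length(pieces) + 1L]] <- res$fields
        offsets <- c(offsets, r$base + res$frame_offsets)
        lengths <- c(lengths, res$frame_lengths)
        got <- got + res$n
      }
      r$pos <- res$`next`
      if (res$status == "eof") { r$eof <- TRUE; break }
      if (got >= n) break
      if (!refill()) {
        abort_integrity(sprintf(
          "truncated file: %s has no end-of-file marker", path))
      }
    }
    r$done <- r$done + got
    if (got == 0L) return(NULL)
    fields <- combine_fields(pieces)
    out <- fields_to_tibble(fields)
    attr(out, "frame_offsets") <- offsets
    attr(out, "frame_lengths") <- lengths
    out
  }

  # batch of raw frames: list(blob, offsets, lengths) without decoding
  r$read_raw_batch <- function(n = 1000L) {
    if (r$eof && r$pos >= length(r$buf)) return(NULL)
    frames <- list()
    got <- 0L
    repeat {
      scan <- scan_frames(r, n - got)
      if (scan$n > 0) {
        frames[[length(frames) + 1L]] <- scan$blob
        got <- got + scan$n
      }
      if (r$eof || got >= n) break
      if (!refill()) {
        abort_integrity(sprintf(
          "truncated file: %s has no end-of-file marker", path))
      }
    }
    r$done <- r$done + got
    if (got == 0L) return(NULL)
    list(blob = do.call(c, frames), n = got)
  }

  r$close <- function() close(con)
  r
}

# Scan complete frames at r$pos without decoding; returns the framed bytes.
scan_frames <- function(r, max_records) {
  buf <- r$buf
  pos <- r$pos
  n <- 0L
  start <- pos
  while (n < max_records) {
    if (pos + 4 > length(buf)) break
    len_raw <- buf[(pos + 1):(pos + 4)]
    L <- sum(as.integer(len_raw) * c(1, 256, 65536, 16777216))
    if (L == 4294967295) {
      if (pos + 8 > length(buf)) break
      if (identical(buf[(pos + 5):(pos + 8)], charToRaw("EOF5"))) {
        r$eof <- TRUE
        r$pos <- pos + 8
        return(list(blob = if (pos > start) buf[(start + 1):pos] else raw(),
                    n = n))
      }
      abort_integrity("corrupt frame length")
    }
    if (pos + 4 + L > length(buf)) break
    pos <- pos + 4 + L
    n <- n + 1L
  }
  r$pos <- pos
  list(blob = if (pos > start) buf[(start + 1):pos] else raw(), n = n)
}

#' Read a binary file into a read table
#'
#' @param path Path to a `.blow5` file.
#' @param batch_size Records decoded per internal batch.
#' @return A read tibble with the file header attached.
#' @export
read_blow5 <- function(path, batch_size = 1000L) {
  r <- blow5_reader(path)
  on.exit(r$close())
  batches <- list()
  repeat {
    b <- r$read_batch(batch_size)
    if (is.null(b)) break
    batches[[length(batches) + 1L]] <- b
  }
  out <- if (length(batches) == 0) {
    fields_to_tibble(list(
      read_id = character(), read_group = integer(), digitisation = numeric(),
      offset = numeric(), range = numeric(), sampling_rate = numeric(),
      len_raw_signal = integer(), raw_signal = list(),
      channel_number = character(), median_before = numeric(),
      read_number = integer(), start_mux = integer(), start_time = numeric(),
      extra_names = character(), extras = list()))
  } else {
    dplyr::bind_rows(batches)
  }
  set_header(out, r$header)
}

#' Decode record batches with worker parallelism
#'
#' Reads frames sequentially (one reader), fanning decompression and
#' parsing out over `n_workers` forked workers, batch by batch. Batches are
#' re-emitted in file order with their internal order preserved, so the
#' result is identical for every worker count.
#'
#' @param path Path to a `.blow5` file.
#' @param n_workers Number of decode workers.
#' @param batch_size Records per batch.
#' @return A read tibble with the file header attached.
#' @export
parallel_decode <- function(path, n_workers = 1L, batch_size = 1000L) {
  n_workers <- as.integer(n_workers)
  if (is.na(n_workers) || n_workers < 1L) {
    abort_validation("n_workers must be >= 1")
  }
  r <- blow5_reader(path)
  on.exit(r$close())
  raw_batches <- list()
  repeat {
    b <- r$read_raw_batch(batch_size)
    if (is.null(b)) break
    raw_batches[[length(raw_batches) + 1L]] <- b$blob
  }
  rc <- r$rc
  sc <- r$sc
  decode_one <- function(i) {
    res <- reclassify_cpp_error(
      decode_frames_cpp(raw_batches[[i]], 0, .Machine$integer.max, rc, sc, 0))
    if (res$status == "partial" && res$`next` != length(raw_batches[[i]])) {
      abort_integrity(sprintf("batch %d: truncated frame", i))
    }
    res$fields
  }
  idx <- seq_along(raw_batches)
  fields_list <- if (n_workers == 1L || length(idx) == 0) {
    lapply(idx, decode_one)
  } else {
    res <- parallel::mclapply(idx, decode_one, mc.cores = n_workers,
                              mc.preschedule = TRUE)
    bad <- which(vapply(res, inherits, logical(1), "try-error"))
    if (length(bad) > 0) {
      abort_integrity(sprintf("worker failure while decoding batch %d: %s",
                              bad[1], as.character(res[[bad[1]]])))
    }
    res
  }
  fields <- combine_fields(fields_list)
  out <- if (is.null(fields)) read_blow5(path) else fields_to_tibble(fields)
  set_header(out, r$header)
}

#' Summarize a binary file
#'
#' @param path Path to a `.blow5` file.
#' @return A one-row tibble with version, codecs, read-group and record
#'   counts, and file size.
#' @export
blow5_stats <- function(path) {
  r <- blow5_reader(path)
  on.exit(r$close())
  n <- 0L
  repeat {
    b <- r$read_raw_batch(10000L)
    if (is.null(b)) break
    n <- n + b$n
  }
  tibble::tibble(
    path = path,
    version = paste(r$header$version, collapse = "."),
    record_codec = r$header$record_codec,
    signal_codec = r$header$signal_codec,
    num_read_groups = r$header$num_read_groups,
    records = n,
    bytes = file.size(path))
}
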