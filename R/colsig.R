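# Column-oriented comparator format (.colsig): each metadata attribute is
# stored for all reads contiguously; signal is stored in fixed-size chunks
# tagged (read ordinal, chunk ordinal) that may be interspersed across
# reads; a footer maps every read to its chunk locations and every column
# to its byte region.  Retrieval is index-free: a "walker" first traverses
# the footer into a look-up table, then seeks per chunk and per attribute
# column for each requested read.

COLSIG_TYPES <- c(f64 = 0L, u32 = 1L, u8 = 2L, str = 3L)

colsig_column_plan <- function(reads) {
  extras <- extra_col_names(reads)
  tibble::tibble(
    name = c("read_id", "read_group", "digitisation", "offset", "range",
             "sampling_rate", "len_raw_signal", "channel_number",
             "median_before", "read_number", "start_mux", "start_time",
             extras),
    type = c("str", "u32", "f64", "f64", "f64", "f64", "f64", "str", "f64",
             "u32", "u8", "f64", rep("str", length(extras))))
}

#' Write reads to the columnar comparator format
#'
#' @param reads A read tibble.
#' @param path Output path (conventionally `.colsig`).
#' @param header A [slow5_header()]; codecs are ignored (chunks are stored
#'   raw in this format).
#' @param chunk_size Samples per signal chunk (default 102,400, the
#'   conventional columnar default); every chunk except possibly a read's
#'   last holds exactly this many samples.
#' @param interleave `"contiguous"` keeps each read's chunks adjacent;
#'   `"round_robin"` interleaves chunks of up to `width` concurrently open
#'   reads, emulating parallel acquisition.
#' @param width Concurrency width for `"round_robin"`.
#' @return Invisibly, a list with `records`, `chunks` and `bytes`.
#' @export
write_colsig <- function(reads, path, header = s5_header(reads),
                         chunk_size = 102400L,
                         interleave = c("contiguous", "round_robin"),
                         width = 4L) {
  interleave <- match.arg(interleave)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L) {
    abort_validation("chunk_size must be >= 1")
  }
  validate_reads(reads, header)
  con <- file(path, "wb")
  on.exit(close(con))
  pos <- 0
  put <- function(bytes) {
    writeBin(bytes, con)
    pos <<- pos + length(bytes)
  }
  put(MAGIC_COLSIG)
  put(as.raw(c(s5_header(reads)$version, 0L, 0L)))
  hblob <- header_to_blob(header)
  put(writeBin(length(hblob), raw(), size = 4L, endian = "little"))
  put(hblob)

  enc <- colsig_encode_signal_cpp(reads$raw_signal, chunk_size,
                                  if (interleave == "contiguous") 0L else 1L,
                                  as.integer(width))
  chunk_base <- pos
  put(enc$blob)

  plan <- colsig_column_plan(reads)
  col_offsets <- numeric(nrow(plan))
  col_lengths <- numeric(nrow(plan))
  str_tables <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    col_offsets[k] <- pos
    nm <- plan$name[k]
    v <- reads[[nm]]
    blob <- switch(plan$type[k],
      f64 = writeBin(ifelse(is.na(as.numeric(v)), NaN, as.numeric(v)),
                     raw(), size = 8L, endian = "little"),
      u32 = writeBin(as.integer(v), raw(), size = 4L, endian = "little"),
      u8 = as.raw(as.integer(v)),
      str = {
        packed <- pack_str_col_cpp(as.character(v))
        str_tables[[k]] <- packed$offsets
        packed$blob
      })
    put(blob)
    col_lengths[k] <- pos - col_offsets[k]
  }
  footer <- colsig_footer_encode_cpp(enc$chunk_offsets, enc$chunk_nsamples,
                                     chunk_base, plan$name,
                                     unname(COLSIG_TYPES[plan$type]),
                                     col_offsets, col_lengths, str_tables)
  footer_offset <- pos
  put(footer)
  put(pack_u64_cpp(footer_offset))
  put(MAGIC_COLEND)
  invisible(list(records = nrow(reads),
                 chunks = sum(lengths(enc$chunk_nsamples)),
                 bytes = pos))
}

colsig_prelude <- function(blob) {
  if (length(blob) < 16 + 8 + 5 + 4 ||
      !identical(blob[1:8], MAGIC_COLSIG)) {
    abort_integrity("not a columnar signal file (bad magic)")
  }
  n <- length(blob)
  if (!identical(blob[(n - 7):n], MAGIC_COLEND)) {
    abort_integrity("truncated columnar file (missing trailer)")
  }
  footer_offset <- unpack_u64_cpp(blob[(n - 15):(n - 8)])
  version <- as.integer(blob[9:11])
  hlen <- readBin(blob[14:17], "integer", size = 4L, endian = "little")
  hblob <- blob[17 + seq_len(hlen)]
  header <- header_from_blob(hblob, "none", "none")
  header$version <- version
  footer <- reclassify_cpp_error(
    colsig_footer_decode_cpp(blob[(footer_offset + 1):(n - 16)]))
  list(header = header, footer = footer)
}

decode_colsig_column <- function(blob, footer, k, n) {
  a <- footer$col_offsets[k]
  len <- footer$col_lengths[k]
  slice <- blob[a + seq_len(len)]
  type <- names(COLSIG_TYPES)[match(footer$col_types[k], COLSIG_TYPES)]
  switch(type,
    f64 = {
      v <- readBin(slice, "double", n = n, size = 8L, endian = "little")
      ifelse(is.nan(v), NA_real_, v)
    },
    u32 = readBin(slice, "integer", n = n, size = 4L, endian = "little"),
    u8 = as.integer(slice),
    str = unpack_str_col_cpp(slice, footer$str_tables[[k]]))
}

#' Read a columnar file into a read table
#'
#' Decodes every column and reassembles each read's signal from its chunks
#' (in chunk-ordinal order), returning rows in original write order.
#'
#' @param path Path to a `.colsig` file.
#' @return A read tibble with the file header attached.
#' @export
read_colsig <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  blob <- readBin(path, "raw", n = file.size(path))
  p <- colsig_prelude(blob)
  footer <- p$footer
  n <- length(footer$chunk_offsets)
  cols <- list()
  for (k in seq_along(footer$col_names)) {
    cols[[footer$col_names[k]]] <- decode_colsig_column(blob, footer, k, n)
  }
  signals <- reclassify_cpp_error(
    colsig_decode_chunks_cpp(blob, footer$chunk_offsets,
                             footer$chunk_nsamples, seq_len(n) - 1L))
  extras <- setdiff(footer$col_names, CANONICAL_COLS)
  fields <- list(
    read_id = cols$read_id,
    read_group = as.integer(cols$read_group),
    digitisation = cols$digitisation,
    offset = cols$offset,
    range = cols$range,
    sampling_rate = cols$sampling_rate,
    len_raw_signal = as.integer(cols$len_raw_signal),
    raw_signal = signals,
    channel_number = cols$channel_number,
    median_before = cols$median_before,
    read_number = as.integer(cols$read_number),
    start_mux = as.integer(cols$start_mux),
    start_time = cols$start_time,
    extra_names = extras,
    extras = unname(cols[extras]))
  mismatch <- which(lengths(signals) != fields$len_raw_signal)
  if (length(mismatch) > 0) {
    abort_integrity(sprintf(
      "read '%s': len_raw_signal does not match reassembled chunks",
      fields$read_id[mismatch[1]]))
  }
  set_header(fields_to_tibble(fields), p$header)
}

read_str_at <- function(f, at) {
  aud_seek(f, at)
  len <- readBin(f$con, "integer", size = 4L, endian = "little")
  if (is.na(len)) abort_integrity("corrupt string value")
  if (len == -1L) return(NA_character_)  # 0xFFFFFFFF sentinel
  if (len == 0L) return("")
  rawToChar(aud_read(f, len))
}

#' Index-free walker retrieval from a columnar file
#'
#' Pass 1 traverses the file's footer into an in-memory look-up table of
#' chunk and column locations for all reads (plus the full read-ID column
#' to resolve identifiers). Pass 2 fetches each requested read with one
#' seek per signal chunk and one seek per attribute column. The total seek
#' count is recorded in `attr(, "seeks")`.
#'
#' @param path Path to a `.colsig` file.
#' @param read_ids Character vector of read IDs (duplicates fetched per
#'   occurrence).
#' @return A read tibble in request order with the header attached.
#' @export
walker_fetch <- function(path, read_ids) {
  f <- aud_open(path)
  on.exit(aud_close(f))
  n_file <- f$size

  # pass 1: trailer -> footer -> header -> read_id column
  aud_seek(f, n_file - 16)
  trailer <- aud_read(f, 16)
  if (!identical(trailer[9:16], MAGIC_COLEND)) {
    abort_integrity("truncated columnar file (missing trailer)")
  }
  footer_offset <- unpack_u64_cpp(trailer[1:8])
  aud_seek(f, footer_offset)
  footer <- colsig_footer_decode_cpp(aud_read(f, n_file - 16 - footer_offset))
  aud_seek(f, 0)
  head_blob <- aud_read(f, 13 + 4)
  hlen <- readBin(head_blob[14:17], "integer", size = 4L, endian = "little")
  header <- header_from_blob(aud_read(f, hlen), "none", "none")
  header$version <- as.integer(head_blob[9:11])
  idcol <- match("read_id", footer$col_names)
  aud_seek(f, footer$col_offsets[idcol])
  all_ids <- unpack_str_col_cpp(aud_read(f, footer$col_lengths[idcol]),
                                footer$str_tables[[idcol]])

  ords <- match(read_ids, all_ids)
  if (anyNA(ords)) {
    abort_not_found(sprintf("read_id not present in columnar file: %s",
                            read_ids[which(is.na(ords))[1]]))
  }

  # pass 2: per requested read, one seek per attribute column (including a
  # verifying re-read of the ID) and one per signal chunk
  plan_types <- names(COLSIG_TYPES)[match(footer$col_types, COLSIG_TYPES)]
  all_cols <- seq_along(footer$col_names)
  k_req <- length(ords)
  cols <- lapply(seq_along(footer$col_names), function(k) {
    switch(plan_types[k], str = character(k_req), u8 = integer(k_req),
           u32 = integer(k_req), f64 = numeric(k_req))
  })
  names(cols) <- footer$col_names
  signals <- vector("list", k_req)
  for (i in seq_len(k_req)) {
    ord <- ords[i]
    for (k in all_cols) {
      base <- footer$col_offsets[k]
      v <- switch(plan_types[k],
        f64 = {
          aud_seek(f, base + 8 * (ord - 1))
          x <- readBin(f$con, "double", size = 8L, endian = "little")
          if (is.nan(x)) NA_real_ else x
        },
        u32 = {
          aud_seek(f, base + 4 * (ord - 1))
          readBin(f$con, "integer", size = 4L, endian = "little")
        },
        u8 = {
          aud_seek(f, base + (ord - 1))
          as.integer(aud_read(f, 1))
        },
        str = read_str_at(f, base + footer$str_tables[[k]][ord]))
      cols[[k]][i] <- v
    }
    offs <- footer$chunk_offsets[[ord]]
    nsamp <- footer$chunk_nsamples[[ord]]
    pieces <- vector("list", length(offs))
    for (ci in seq_along(offs)) {
      aud_seek(f, offs[ci])
      hdr <- readBin(f$con, "integer", n = 3L, size = 4L, endian = "little")
      if (hdr[1] != ord - 1L || hdr[2] != ci - 1L || hdr[3] != nsamp[ci]) {
        abort_integrity(sprintf("chunk tag mismatch for read '%s'", read_ids[i]))
      }
      pieces[[ci]] <- readBin(f$con, "integer", n = nsamp[ci], size = 2L,
                              signed = TRUE, endian = "little")
    }
    signals[[i]] <- as.integer(unlist(pieces) %||% integer())
    if (!identical(cols$read_id[i], read_ids[i])) {
      abort_integrity(sprintf(
        "columnar look-up table is inconsistent for read '%s'", read_ids[i]))
    }
  }
  extras <- setdiff(footer$col_names, CANONICAL_COLS)
  fields <- list(
    read_id = cols$read_id,
    read_group = as.integer(cols$read_group),
    digitisation = cols$digitisation,
    offset = cols$offset,
    range = cols$range,
    sampling_rate = cols$sampling_rate,
    len_raw_signal = as.integer(cols$len_raw_signal),
    raw_signal = signals,
    channel_number = cols$channel_number,
    median_before = cols$median_before,
    read_number = as.integer(cols$read_number),
    start_mux = as.integer(cols$start_mux),
    start_time = cols$start_time,
    extra_names = extras,
    extras = unname(cols[extras]))
  out <- set_header(fields_to_tibble(fields), header)
  attr(out, "seeks") <- f$seeks
  out
}
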