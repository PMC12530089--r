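# Read-ID index sidecar (.blow5.idx): maps each read ID to the byte offset
# and framed length of its record, enabling one-seek random access.
# Sidecar layout: magic, u64 data-file size, 8-byte FNV of the data file's
# first 4 KiB (stale-index detection), u32 payload length, zlib-compressed
# entry payload.

index_path_for <- function(path) paste0(path, ".idx")

data_fingerprint <- function(path) {
  f <- aud_open(path)
  on.exit(aud_close(f))
  head_bytes <- aud_read(f, min(4096, f$size))
  list(size = f$size, fnv = fnv_bytes_cpp(head_bytes))
}

#' Build the random-access index for a binary file
#'
#' Scans the file sequentially and writes a sidecar (`<path>.idx`) with one
#' entry per record: read ID, byte offset of the record's length prefix,
#' and total framed length. Content is deterministic for a given data file.
#'
#' @param path Path to a `.blow5` file.
#' @param index_path Sidecar path; defaults to `<path>.idx`.
#' @return Invisibly, the number of entries written.
#' @export
build_index <- function(path, index_path = index_path_for(path)) {
  r <- blow5_reader(path)
  on.exit(r$close())
  ids <- list(); offs <- list(); lens <- list()
  repeat {
    b <- r$read_batch(10000L)
    if (is.null(b)) break
    ids[[length(ids) + 1L]] <- b$read_id
    offs[[length(offs) + 1L]] <- attr(b, "frame_offsets")
    lens[[length(lens) + 1L]] <- attr(b, "frame_lengths")
  }
  ids <- unlist(ids) %||% character()
  offs <- unlist(offs) %||% numeric()
  lens <- unlist(lens) %||% numeric()
  dup <- anyDuplicated(ids)
  if (dup > 0) {
    abort_validation(sprintf("duplicate read_id '%s' cannot be indexed", ids[dup]))
  }
  fp <- data_fingerprint(path)
  payload <- compress_cpp(pack_index_cpp(ids, offs, lens), RECORD_CODECS[["zlib"]])
  con <- file(index_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(MAGIC_INDEX, con)
  write_u64(con, fp$size)
  writeBin(fp$fnv, con)
  write_u32(con, length(payload))
  writeBin(payload, con)
  invisible(length(ids))
}

#' Load an index sidecar
#'
#' Validates the sidecar against the data file (size and header
#' fingerprint); a mismatch raises a stale-index error rather than risking
#' silent wrong-offset reads.
#'
#' @param path Path to the `.blow5` data file.
#' @param index_path Sidecar path; defaults to `<path>.idx`.
#' @return A tibble with columns `read_id`, `offset`, `length`.
#' @export
load_index <- function(path, index_path = index_path_for(path)) {
  if (!file.exists(index_path)) {
    abort_io(sprintf("index sidecar not found: %s (run build_index first)", index_path))
  }
  con <- file(index_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, MAGIC_INDEX)) abort_integrity("bad index magic")
  size <- read_u64(con)
  fnv <- readBin(con, "raw", n = 8L)
  fp <- data_fingerprint(path)
  if (size != fp$size || !identical(fnv, fp$fnv)) {
    abort_integrity(sprintf(
      "stale index: %s no longer matches %s (rebuild with build_index)",
      index_path, path))
  }
  plen <- read_u32(con)
  payload <- readBin(con, "raw", n = plen)
  if (length(payload) != plen) abort_integrity("truncated index sidecar")
  entries <- unpack_index_cpp(decompress_cpp(payload, RECORD_CODECS[["zlib"]]))
  tibble::as_tibble(entries)
}

#' Fetch reads by ID through the index
#'
#' Retrieves the requested reads in request order; each retrieval performs
#' exactly one seek plus one bounded read of the record's framed length.
#' Duplicate IDs are fetched once per occurrence.
#'
#' @param path Path to a `.blow5` file.
#' @param read_ids Character vector of read IDs.
#' @param index Optional pre-loaded index tibble from [load_index()].
#' @param on_missing `"error"` (default) or `"skip"` (drop unknown IDs with
#'   a warning).
#' @return A read tibble in request order, with the file header attached
#'   and the seek count in `attr(, "seeks")`.
#' @export
fetch_reads <- function(path, read_ids, index = NULL,
                        on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  if (is.null(index)) index <- load_index(path)
  hit <- match(read_ids, index$read_id)
  if (anyNA(hit)) {
    missing_ids <- read_ids[is.na(hit)]
    if (on_missing == "error") {
      abort_not_found(sprintf("read_id not in index: %s", missing_ids[1]))
    }
    warning(sprintf("skipping %d unknown read ID(s)", length(missing_ids)))
    read_ids <- read_ids[!is.na(hit)]
    hit <- hit[!is.na(hit)]
  }
  con <- file(path, "rb")
  prelude <- read_blow5_prelude(con)
  close(con)
  f <- aud_open(path)
  on.exit(aud_close(f))
  f$seeks <- 0L  # discount the open itself; count only per-record seeks
  frames <- vector("list", length(hit))
  for (i in seq_along(hit)) {
    aud_seek(f, index$offset[hit[i]])
    frames[[i]] <- aud_read(f, index$length[hit[i]])
  }
  fields <- reclassify_cpp_error(
    decode_framed_records_cpp(frames, prelude$rc, prelude$sc))
  out <- fields_to_tibble(fields)
  out <- set_header(out, prelude$header)
  attr(out, "seeks") <- f$seeks
  out
}
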