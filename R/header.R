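#' Construct a file header
#'
#' A header carries the container format version, the codecs used by the
#' binary dialect, the number of read groups, and a per-group map of run
#' attributes (each attribute holds exactly one text value per read group).
#'
#' @param num_read_groups Positive integer number of read groups.
#' @param attributes Named list; each element is a character vector with one
#'   value per read group (e.g. `run_id`, `flow_cell_id`).
#' @param record_codec One of `"none"`, `"zlib"`, `"zstd"`; whole-record
#'   compression used by the binary dialect.
#' @param signal_codec One of `"none"`, `"svb32-zd"`, `"svb16-zd"`; signal
#'   compression used by the binary dialect.
#' @param version Integer vector of length 3 (semantic version triple).
#' @return An object of class `slow5_header`.
#' @export
#' @examples
#' slow5_header(attributes = list(run_id = "run0"))
slow5_header <- function(num_read_groups = 1L,
                         attributes = list(),
                         record_codec = "zlib",
                         signal_codec = "svb16-zd",
                         version = c(0L, 1L, 0L)) {
  num_read_groups <- as.integer(num_read_groups)
  if (is.na(num_read_groups) || num_read_groups < 1L) {
    abort_validation("num_read_groups must be a positive integer")
  }
  codec_id(record_codec, RECORD_CODECS, "record")
  codec_id(signal_codec, SIGNAL_CODECS, "signal")
  if (length(attributes) > 0 &&
      (is.null(names(attributes)) || any(names(attributes) == ""))) {
    abort_validation("header attributes must be named")
  }
  attributes <- lapply(attributes, function(v) {
    v <- as.character(v)
    if (length(v) == 1L && num_read_groups > 1L) v <- rep(v, num_read_groups)
    if (length(v) != num_read_groups) {
      abort_validation("each header attribute needs one value per read group")
    }
    v
  })
  structure(
    list(version = as.integer(version)[1:3],
         num_read_groups = num_read_groups,
         record_codec = record_codec,
         signal_codec = signal_codec,
         attributes = attributes),
    class = "slow5_header")
}

#' @export
print.slow5_header <- function(x, ...) {
  cat(sprintf("<slow5_header> v%s, %d read group(s), record codec %s, signal codec %s\n",
              paste(x$version, collapse = "."), x$num_read_groups,
              x$record_codec, x$signal_codec))
  for (k in names(x$attributes)) {
    cat(sprintf("  @%s: %s\n", k, paste(x$attributes[[k]], collapse = "\t")))
  }
  invisible(x)
}

#' Retrieve the header attached to a read table
#'
#' Readers return a tibble of reads with the file header attached as an
#' attribute; this accessor extracts it.
#'
#' @param reads A tibble returned by one of the file readers.
#' @return A `slow5_header`, or a default header when none is attached.
#' @export
s5_header <- function(reads) {
  attr(reads, "slow5_header") %||% slow5_header()
}

set_header <- function(reads, header) {
  attr(reads, "slow5_header") <- header
  reads
}

header_to_blob <- function(header) {
  keys <- names(header$attributes)
  header_encode_cpp(header$version, header$num_read_groups,
                    as.character(keys %||% character()),
                    unname(header$attributes))
}

header_from_blob <- function(blob, record_codec, signal_codec) {
  h <- header_decode_cpp(blob)
  attributes <- setNames(h$values, h$keys)
  slow5_header(num_read_groups = h$num_read_groups,
               attributes = attributes,
               record_codec = record_codec,
               signal_codec = signal_codec,
               version = h$version)
}
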