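# The canonical read table: one row per read, signal as a list-column of
# integer vectors.  Character columns beyond the canonical set are treated
# as auxiliary fields and survive round trips through every container.

CANONICAL_COLS <- c("read_id", "read_group", "digitisation", "offset", "range",
                    "sampling_rate", "len_raw_signal", "raw_signal",
                    "channel_number", "median_before", "read_number",
                    "start_mux", "start_time")

extra_col_names <- function(reads) {
  setdiff(names(reads), CANONICAL_COLS)
}

#' Validate a read table
#'
#' Checks the structural invariants of a read table: canonical columns are
#' present and well-typed, `len_raw_signal` matches the stored signal
#' lengths, read IDs are non-empty and free of tabs/newlines, signal values
#' fit in a signed 16-bit integer, and `start_mux` lies in 1..4.
#'
#' @param reads A read tibble.
#' @param header Optional `slow5_header`; when given, `read_group` values
#'   are checked against `num_read_groups`.
#' @return `reads`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_reads <- function(reads, header = NULL) {
  missing <- setdiff(CANONICAL_COLS, names(reads))
  if (length(missing) > 0) {
    abort_validation(paste0("read table is missing columns: ",
                            paste(missing, collapse = ", ")))
  }
  ids <- reads$read_id
  if (anyNA(ids) || any(ids == "") || any(grepl("[\t\n]", ids))) {
    abort_validation("read_id values must be non-empty and contain no tab or newline")
  }
  lens <- lengths(reads$raw_signal)
  if (!all(lens == reads$len_raw_signal)) {
    bad <- which(lens != reads$len_raw_signal)[1]
    abort_integrity(sprintf(
      "len_raw_signal mismatch for read '%s': field says %d, signal has %d values",
      ids[bad], as.integer(reads$len_raw_signal[bad]), lens[bad]))
  }
  if (any(reads$start_mux < 1L | reads$start_mux > 4L, na.rm = TRUE)) {
    abort_validation("start_mux must lie in 1..4")
  }
  if (!is.null(header) && any(reads$read_group >= header$num_read_groups)) {
    abort_validation("read_group must be < num_read_groups declared in the header")
  }
  extras <- extra_col_names(reads)
  not_chr <- extras[!vapply(reads[extras], is.character, logical(1))]
  if (length(not_chr) > 0) {
    abort_validation(paste0("auxiliary columns must be character: ",
                            paste(not_chr, collapse = ", ")))
  }
  invisible(reads)
}

# Marshal a read tibble into the flat field list the C++ encoders expect.
fields_for_cpp <- function(reads) {
  extras <- extra_col_names(reads)
  list(
    read_id = as.character(reads$read_id),
    read_group = as.integer(reads$read_group),
    digitisation = as.numeric(reads$digitisation),
    offset = as.numeric(reads$offset),
    range = as.numeric(reads$range),
    sampling_rate = as.numeric(reads$sampling_rate),
    raw_signal = reads$raw_signal,
    channel_number = as.character(reads$channel_number),
    median_before = as.numeric(reads$median_before),
    read_number = as.integer(reads$read_number),
    start_mux = as.integer(reads$start_mux),
    start_time = as.numeric(reads$start_time),
    extra_names = extras,
    extras = lapply(unname(reads[extras]), as.character)
  )
}

fields_to_tibble <- function(fields) {
  tbl <- tibble::tibble(
    read_id = fields$read_id,
    read_group = fields$read_group,
    digitisation = fields$digitisation,
    offset = fields$offset,
    range = fields$range,
    sampling_rate = fields$sampling_rate,
    len_raw_signal = as.integer(fields$len_raw_signal),
    raw_signal = fields$raw_signal,
    channel_number = fields$channel_number,
    median_before = fields$median_before,
    read_number = fields$read_number,
    start_mux = fields$start_mux,
    start_time = fields$start_time
  )
  extras <- fields$extra_names
  for (i in seq_along(extras)) tbl[[extras[i]]] <- fields$extras[[i]]
  tbl
}

# Concatenate field lists from successive decode calls (buffer refills),
# aligning auxiliary columns by name with NA fill.
combine_fields <- function(pieces) {
  pieces <- pieces[vapply(pieces, function(p) length(p$read_id) > 0, logical(1))]
  if (length(pieces) == 0) return(NULL)
  if (length(pieces) == 1) return(pieces[[1]])
  all_extras <- unique(unlist(lapply(pieces, function(p) p$extra_names)))
  out <- list()
  for (nm in setdiff(names(pieces[[1]]), c("extra_names", "extras", "raw_signal"))) {
    out[[nm]] <- do.call(c, lapply(pieces, `[[`, nm))
  }
  out$raw_signal <- do.call(c, lapply(pieces, `[[`, "raw_signal"))
  out$extra_names <- all_extras
  out$extras <- lapply(all_extras, function(nm) {
    do.call(c, lapply(pieces, function(p) {
      i <- match(nm, p$extra_names)
      if (is.na(i)) rep(NA_character_, length(p$read_id)) else p$extras[[i]]
    }))
  })
  out
}

#' Convert one read's raw signal to picoamperes
#'
#' Applies the standard calibration: `pA[i] = (raw[i] + offset) * range /
#' digitisation`. The ratio `range / digitisation` is the per-read scale.
#'
#' @param record A one-row read tibble or a named list with `raw_signal`,
#'   `digitisation`, `offset` and `range` entries.
#' @return A numeric vector of picoampere values, the same length as the
#'   raw signal.
#' @export
#' @examples
#' r <- list(raw_signal = c(-10L, 0L, 10L), digitisation = 8192,
#'           offset = 10, range = 819.2)
#' pa_convert(r)
pa_convert <- function(record) {
  sig <- record$raw_signal
  if (is.list(sig)) sig <- sig[[1]]
  pa_convert_signal(sig, record$digitisation[[1]], record$offset[[1]],
                    record$range[[1]])
}

#' @rdname pa_convert
#' @param raw_signal Integer vector of raw ADC values.
#' @param digitisation Positive number of ADC levels.
#' @param offset Calibration offset in ADC units.
#' @param range Full-scale range in picoamperes.
#' @export
pa_convert_signal <- function(raw_signal, digitisation, offset, range) {
  if (!is.finite(digitisation) || digitisation <= 0) {
    abort_validation("invalid calibration: digitisation must be positive")
  }
  (as.numeric(raw_signal) + offset) * (range / digitisation)
}
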