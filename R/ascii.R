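# ASCII dialect (.slow5): tab-delimited, one data row per read.
#   #slow5_version <x.y.z>
#   #num_read_groups <n>
#   @<key>\t<value_group0>[\t<value_group1>...]
#   #<col1>\t<col2>...
# Signal values are comma-joined inside a single field; "." is the missing
# sentinel; floats use shortest round-trip-safe formatting (%.17g).

fmt_f64 <- function(x) {
  out <- rep(".", length(x))
  idx <- which(!is.na(x))
  if (length(idx) > 0) {
    v <- x[idx]
    res <- sprintf("%.17g", v)
    # prefer the shortest representation that still round-trips exactly
    for (digits in c(16L, 15L)) {
      short <- sprintf(paste0("%.", digits, "g"), v)
      ok <- as.numeric(short) == v
      res[ok] <- short[ok]
    }
    out[idx] <- res
  }
  out
}

fmt_chr <- function(x) ifelse(is.na(x), ".", x)

check_text_field <- function(x, what) {
  bad <- grepl("[\t\n]", x)
  if (any(bad, na.rm = TRUE)) {
    abort_validation(sprintf("%s contains a tab or newline: %s",
                             what, x[which(bad)[1]]))
  }
  invisible(x)
}

#' Write reads to the ASCII dialect
#'
#' Serializes a read table to a tab-delimited text file with all elements of
#' each read stored contiguously in one row (the signal is comma-joined in a
#' single field). Floats are written with round-trip-safe precision, so an
#' ASCII round trip preserves every field bit-for-bit.
#'
#' @param reads A read tibble (see [generate_reads()]).
#' @param path Output path (conventionally `.slow5`).
#' @param header A [slow5_header()]; defaults to the one attached to `reads`.
#' @return Invisibly, a list with `rows` written.
#' @export
write_slow5 <- function(reads, path, header = s5_header(reads)) {
  validate_reads(reads, header)
  check_text_field(reads$channel_number, "channel_number")
  extras <- extra_col_names(reads)
  for (e in extras) check_text_field(reads[[e]], e)
  for (k in names(header$attributes)) {
    check_text_field(header$attributes[[k]], sprintf("attribute '%s'", k))
  }

  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#slow5_version\t%s", paste(header$version, collapse = ".")), con)
  writeLines(sprintf("#num_read_groups\t%d", header$num_read_groups), con)
  for (k in names(header$attributes)) {
    writeLines(paste(c(paste0("@", k), fmt_chr(header$attributes[[k]])),
                     collapse = "\t"), con)
  }
  cols <- c(CANONICAL_COLS, extras)
  writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  if (nrow(reads) > 0) {
    sig <- vapply(reads$raw_signal, function(s) {
      if (length(s) == 0) "." else paste(s, collapse = ",")
    }, "")
    row_cols <- list(
      reads$read_id,
      as.character(reads$read_group),
      fmt_f64(reads$digitisation),
      fmt_f64(reads$offset),
      fmt_f64(reads$range),
      fmt_f64(reads$sampling_rate),
      as.character(reads$len_raw_signal),
      sig,
      reads$channel_number,
      fmt_f64(reads$median_before),
      as.character(reads$read_number),
      as.character(reads$start_mux),
      sprintf("%.0f", as.numeric(reads$start_time))
    )
    for (e in extras) row_cols <- c(row_cols, list(fmt_chr(reads[[e]])))
    writeLines(do.call(paste, c(row_cols, sep = "\t")), con)
  }
  invisible(list(rows = nrow(reads)))
}

parse_f64 <- function(x) {
  out <- suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  out
}

#' Read the ASCII dialect
#'
#' Parses a `.slow5` file back into a read tibble, cross-checking
#' `len_raw_signal` against the parsed signal length. Unknown extra columns
#' are preserved as character auxiliary fields.
#'
#' @param path Path to a `.slow5` file.
#' @return A read tibble with the file's [slow5_header()] attached.
#' @export
read_slow5 <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^#slow5_version\t", lines[1])) {
    abort_integrity(sprintf("%s does not begin with a #slow5_version line", path))
  }
  version <- as.integer(strsplit(sub("^#slow5_version\t", "", lines[1]), ".",
                                 fixed = TRUE)[[1]])
  if (length(lines) < 2 || !grepl("^#num_read_groups\t", lines[2])) {
    abort_integrity("missing #num_read_groups line")
  }
  ng <- as.integer(sub("^#num_read_groups\t", "", lines[2]))
  i <- 3L
  attributes <- list()
  while (i <= length(lines) && startsWith(lines[i], "@")) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    key <- sub("^@", "", parts[1])
    vals <- parts[-1]
    if (length(vals) != ng) {
      abort_integrity(sprintf(
        "line %d: attribute '%s' has %d values, expected %d",
        i, key, length(vals), ng))
    }
    attributes[[key]] <- ifelse(vals == ".", NA_character_, vals)
    i <- i + 1L
  }
  if (i > length(lines) || !startsWith(lines[i], "#")) {
    abort_integrity("missing column schema line")
  }
  cols <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(CANONICAL_COLS, cols)
  if (length(missing) > 0) {
    abort_integrity(paste0("column schema is missing: ",
                           paste(missing, collapse = ", ")))
  }
  header <- slow5_header(num_read_groups = ng, attributes = attributes,
                         record_codec = "none", signal_codec = "none",
                         version = version)
  data_lines <- lines[seq_len(length(lines) - i) + i]
  data_lines <- data_lines[nzchar(data_lines)]
  n <- length(data_lines)
  if (n == 0) {
    return(set_header(fields_to_tibble(list(
      read_id = character(), read_group = integer(), digitisation = numeric(),
      offset = numeric(), range = numeric(), sampling_rate = numeric(),
      len_raw_signal = integer(), raw_signal = list(),
      channel_number = character(), median_before = numeric(),
      read_number = integer(), start_mux = integer(), start_time = numeric(),
      extra_names = setdiff(cols, CANONICAL_COLS), extras = rep(list(character()),
      length(setdiff(cols, CANONICAL_COLS))))), header))
  }
  parts <- strsplit(data_lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != length(cols))) {
    bad <- which(ncols != length(cols))[1]
    abort_integrity(sprintf(
      "line %d: expected %d columns, found %d", i + bad, length(cols), ncols[bad]))
  }
  m <- matrix(unlist(parts), nrow = n, byrow = TRUE)
  colnames(m) <- cols
  col <- function(nm) m[, nm]
  len_raw <- as.integer(col("len_raw_signal"))
  sig_str <- col("raw_signal")
  signals <- vector("list", n)
  empty <- sig_str == "."
  signals[empty] <- list(integer())
  if (any(!empty)) {
    split_sig <- strsplit(sig_str[!empty], ",", fixed = TRUE)
    signals[!empty] <- lapply(split_sig, as.integer)
  }
  plens <- lengths(signals)
  if (any(plens != len_raw)) {
    bad <- which(plens != len_raw)[1]
    abort_integrity(sprintf(
      "line %d: len_raw_signal is %d but the signal field has %d values",
      i + bad, len_raw[bad], plens[bad]))
  }
  extra_cols <- setdiff(cols, CANONICAL_COLS)
  fields <- list(
    read_id = col("read_id"),
    read_group = as.integer(col("read_group")),
    digitisation = parse_f64(col("digitisation")),
    offset = parse_f64(col("offset")),
    range = parse_f64(col("range")),
    sampling_rate = parse_f64(col("sampling_rate")),
    len_raw_signal = len_raw,
    raw_signal = signals,
    channel_number = col("channel_number"),
    median_before = parse_f64(col("median_before")),
    read_number = as.integer(col("read_number")),
    start_mux = as.integer(col("start_mux")),
    start_time = as.numeric(col("start_time")),
    extra_names = extra_cols,
    extras = lapply(extra_cols, function(nm) {
      v <- col(nm)
      ifelse(v == ".", NA_character_, v)
    })
  )
  set_header(fields_to_tibble(fields), header)
}
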