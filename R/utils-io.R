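# Low-level binary I/O helpers shared by the container formats.

MAGIC_BLOW5  <- charToRaw("SROWBLW1")
MAGIC_COLSIG <- charToRaw("SROWCOL1")
MAGIC_COLEND <- charToRaw("COLSEND1")
MAGIC_INDEX  <- charToRaw("SROWIDX1")
EOF_MARKER   <- as.raw(c(0xFF, 0xFF, 0xFF, 0xFF, charToRaw("EOF5")))

RECORD_CODECS <- c(none = 0L, zlib = 1L, zstd = 2L)
SIGNAL_CODECS <- c(none = 0L, "svb32-zd" = 1L, "svb16-zd" = 2L)

codec_id <- function(name, table, what) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(table)) {
    abort_validation(sprintf(
      "unknown %s codec '%s' (expected one of %s)",
      what, as.character(name)[1], paste(names(table), collapse = ", ")))
  }
  if (what == "record" && name == "zstd" && !has_zstd_cpp()) {
    abort_capability("record codec 'zstd' is not available in this build")
  }
  unname(table[[name]])
}

codec_name <- function(id, table) names(table)[match(id, table)]

write_u32 <- function(con, x) {
  writeBin(as.integer(x), con, size = 4L, endian = "little")
}

read_u32 <- function(con, n = 1L) {
  readBin(con, "integer", n = n, size = 4L, endian = "little")
}

write_u64 <- function(con, x) {
  writeBin(pack_u64_cpp(as.numeric(x)), con)
}

read_u64 <- function(con, n = 1L) {
  raw <- readBin(con, "raw", n = 8L * n)
  if (length(raw) != 8L * n) abort_integrity("truncated file: short 64-bit field")
  unpack_u64_cpp(raw)
}

# Seek-audited read handle: every explicit repositioning counts as one seek.
aud_open <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("file not found: %s", path))
  env <- new.env(parent = emptyenv())
  env$con <- file(path, "rb")
  env$seeks <- 0L
  env$size <- file.size(path)
  env
}

aud_seek <- function(f, where) {
  seek(f$con, where, origin = "start")
  f$seeks <- f$seeks + 1L
  invisible(f)
}

aud_read <- function(f, n) {
  readBin(f$con, "raw", n = n)
}

aud_close <- function(f) {
  close(f$con)
  invisible(NULL)
}

# Deterministic RNG scope that restores the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Peak resident set size in bytes (Linux VmHWM), or NA where unavailable.
peak_rss_bytes <- function() {
  status <- "/proc/self/status"
  if (file.exists(status)) {
    lines <- readLines(status, warn = FALSE)
    hwm <- grep("^VmHWM:", lines, value = TRUE)
    if (length(hwm) == 1L) {
      kb <- suppressWarnings(as.numeric(gsub("[^0-9]", "", hwm)))
      if (!is.na(kb)) return(kb * 1024)
    }
  }
  NA_real_
}
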