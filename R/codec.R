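#' Zigzag-delta transform of a signal
#'
#' Differences successive samples in wrapping signed 16-bit arithmetic
#' (the first value is a delta from zero) and maps each delta `d` through
#' the zigzag function `z = (d << 1) XOR (d >> 15)`, producing non-negative
#' integers that small-magnitude deltas keep small. The transform is
#' losslessly invertible for any signed 16-bit input.
#'
#' @param signal Integer vector of signed 16-bit values.
#' @return Integer vector of zigzag codes in `[0, 65535]`.
#' @export
#' @examples
#' zigzag_delta(c(100L, 102L, 101L))  # 200 4 1
zigzag_delta <- function(signal) {
  zigzag_delta_cpp(as.integer(signal))
}

#' @rdname zigzag_delta
#' @param zz Integer vector of zigzag codes.
#' @export
unzigzag_delta <- function(zz) {
  reclassify_cpp_error(unzigzag_delta_cpp(as.integer(zz)))
}

#' StreamVByte-style variable-byte packing
#'
#' Packs non-negative integers with a control-byte block followed by
#' little-endian data bytes of minimal length. The `svb32-zd` variant uses
#' 2 control bits per value (1-4 data bytes, 4 values per control byte);
#' the `svb16-zd` variant uses 1 control bit per value (1-2 data bytes,
#' 8 values per control byte). The payload begins with an unsigned 64-bit
#' little-endian value count; pad bits in the final control byte are zero.
#'
#' @param values Integer vector of non-negative values (each must fit the
#'   variant's maximum byte width).
#' @param variant `"svb16-zd"` or `"svb32-zd"`.
#' @return A raw vector (`svb_encode`) or the decoded integer vector
#'   (`svb_decode`).
#' @export
svb_encode <- function(values, variant = c("svb16-zd", "svb32-zd")) {
  variant <- match.arg(variant)
  reclassify_cpp_error(
    svb_encode_cpp(as.integer(values), if (variant == "svb16-zd") 2L else 4L))
}

#' @rdname svb_encode
#' @param payload Raw vector produced by `svb_encode()`.
#' @export
svb_decode <- function(payload, variant = c("svb16-zd", "svb32-zd")) {
  variant <- match.arg(variant)
  reclassify_cpp_error(
    svb_decode_cpp(payload, if (variant == "svb16-zd") 2L else 4L))
}

#' General-purpose record compression
#'
#' Compresses an arbitrary byte blob with the requested codec. `"none"` is
#' the identity; `"zlib"` and `"zstd"` payloads carry an 8-byte
#' little-endian uncompressed-size prefix.
#'
#' @param blob A raw vector.
#' @param codec `"none"`, `"zlib"` or `"zstd"`.
#' @return A raw vector.
#' @export
record_compress <- function(blob, codec = c("none", "zlib", "zstd")) {
  codec <- match.arg(codec)
  compress_cpp(blob, codec_id(codec, RECORD_CODECS, "record"))
}

#' @rdname record_compress
#' @export
record_decompress <- function(blob, codec = c("none", "zlib", "zstd")) {
  codec <- match.arg(codec)
  reclassify_cpp_error(
    decompress_cpp(blob, codec_id(codec, RECORD_CODECS, "record")))
}
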