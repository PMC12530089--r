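#include <Rcpp.h>
#include <zlib.h>
#include <zstd.h>
#include "sigrow.h"

using namespace Rcpp;

namespace sigrow {

void svb_encode_vec(const std::vector<uint32_t> &vals, int max_bytes,
                    std::vector<uint8_t> &out) {
  const size_t n = vals.size();
  put_u64(out, (uint64_t)n);
  const int per_ctrl = (max_bytes == 2) ? 8 : 4;
  const size_t n_ctrl = (n + per_ctrl - 1) / per_ctrl;
  const size_t ctrl_at = out.size();
  out.resize(out.size() + n_ctrl, 0);
  for (size_t i = 0; i < n; ++i) {
    uint32_t v = vals[i];
    int len = (v < 0x100u) ? 1 : (v < 0x10000u) ? 2 : (v < 0x1000000u) ? 3 : 4;
    if (len > max_bytes)
      throw std::range_error("value " + std::to_string(v) +
                             " does not fit the " + std::to_string(max_bytes) +
                             "-byte codec variant");
    if (max_bytes == 2) {
      if (len == 2) out[ctrl_at + i / 8] |= (uint8_t)(1u << (i % 8));
    } else {
      out[ctrl_at + i / 4] |= (uint8_t)((len - 1) << (2 * (i % 4)));
    }
    for (int b = 0; b < len; ++b) out.push_back((v >> (8 * b)) & 0xFF);
  }
}

std::vector<uint32_t> svb_decode_vec(const uint8_t *p, size_t len, int max_bytes) {
  Cursor c{p, len, 0};
  if (!c.ok(8)) throw std::invalid_argument("malformed payload: truncated count header");
  uint64_t n = c.u64();
  const int per_ctrl = (max_bytes == 2) ? 8 : 4;
  const size_t n_ctrl = (size_t)((n + per_ctrl - 1) / per_ctrl);
  if (!c.ok(n_ctrl)) throw std::invalid_argument("malformed payload: truncated control bytes");
  const size_t ctrl_at = c.at;
  c.at += n_ctrl;
  std::vector<uint32_t> out((size_t)n);
  for (uint64_t i = 0; i < n; ++i) {
    int vlen;
    if (max_bytes == 2) {
      vlen = ((p[ctrl_at + i / 8] >> (i % 8)) & 1u) ? 2 : 1;
    } else {
      vlen = ((p[ctrl_at + i / 4] >> (2 * (i % 4))) & 3u) + 1;
    }
    if (!c.ok((size_t)vlen)) throw std::invalid_argument("malformed payload: truncated data bytes");
    uint32_t v = 0;
    for (int b = 0; b < vlen; ++b) v |= (uint32_t)c.u8() << (8 * b);
    out[(size_t)i] = v;
  }
  // pad bits of the final control byte must be zero
  if (n % per_ctrl != 0 && n_ctrl > 0) {
    uint8_t last = p[ctrl_at + n_ctrl - 1];
    int used = (int)(n % per_ctrl);
    int used_bits = (max_bytes == 2) ? used : 2 * used;
    if ((last >> used_bits) != 0)
      throw std::invalid_argument("malformed payload: nonzero pad bits");
  }
  if (c.at != len) throw std::invalid_argument("malformed payload: trailing bytes");
  return out;
}

std::vector<uint8_t> compress_blob(const uint8_t *p, size_t n, int codec) {
  if (codec == 0) return std::vector<uint8_t>(p, p + n);
  std::vector<uint8_t> out;
  put_u64(out, (uint64_t)n);
  if (codec == 1) {
    uLongf bound = compressBound((uLong)n);
    size_t at = out.size();
    out.resize(at + bound);
    if (compress2(out.data() + at, &bound, p, (uLong)n, Z_DEFAULT_COMPRESSION) != Z_OK)
      throw std::runtime_error("zlib compression failed");
    out.resize(at + bound);
  } else if (codec == 2) {
    size_t bound = ZSTD_compressBound(n);
    size_t at = out.size();
    out.resize(at + bound);
    size_t r = ZSTD_compress(out.data() + at, bound, p, n, 1);
    if (ZSTD_isError(r)) throw std::runtime_error("zstd compression failed");
    out.resize(at + r);
  } else {
    throw std::invalid_argument("unknown record codec id");
  }
  return out;
}

std::vector<uint8_t> decompress_blob(const uint8_t *p, size_t n, int codec) {
  if (codec == 0) return std::vector<uint8_t>(p, p + n);
  Cursor c{p, n, 0};
  if (!c.ok(8)) throw std::invalid_argument("compressed blob shorter than its size prefix");
  uint64_t usize = c.u64();
  // an implausible size prefix means the frame bytes are corrupt
  if (usize > (1ULL << 32))
    throw std::invalid_argument("corrupt size prefix in compressed blob");
  std::vector<uint8_t> out((size_t)usize);
  if (codec == 1) {
    uLongf dlen = (uLongf)usize;
    int rc = uncompress(out.data(), &dlen, p + 8, (uLong)(n - 8));
    if (rc != Z_OK || dlen != usize)
      throw std::runtime_error("zlib decompression failed");
  } else if (codec == 2) {
    size_t r = ZSTD_decompress(out.data(), (size_t)usize, p + 8, n - 8);
    if (ZSTD_isError(r) || r != usize)
      throw std::runtime_error("zstd decompression failed");
  } else {
    throw std::invalid_argument("unknown record codec id");
  }
  return out;
}

uint64_t fnv1a64(const uint8_t *p, size_t n, uint64_t h) {
  for (size_t i = 0; i < n; ++i) {
    h ^= p[i];
    h *= 1099511628211ULL;
  }
  return h;
}

} // namespace sigrow

using namespace sigrow;

static std::vector<uint32_t> zigzag_of(IntegerVector signal) {
  R_xlen_t n = signal.size();
  std::vector<uint32_t> out((size_t)n);
  int16_t prev = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    int v = signal[i];
    if (v == NA_INTEGER || v < -32768 || v > 32767)
      stop("signal value out of signed 16-bit range at position %lld", (long long)(i + 1));
    int16_t cur = (int16_t)v;
    int16_t d = (int16_t)((uint16_t)cur - (uint16_t)prev);
    uint16_t z = (uint16_t)(((uint16_t)d << 1) ^ (uint16_t)(d >> 15));
    out[(size_t)i] = z;
    prev = cur;
  }
  return out;
}

static void unzigzag_into(const std::vector<uint32_t> &z, int *out) {
  int16_t prev = 0;
  for (size_t i = 0; i < z.size(); ++i) {
    if (z[i] > 0xFFFFu)
      stop("zigzag value %u exceeds the 16-bit transform range", (unsigned)z[i]);
    uint16_t u = (uint16_t)z[i];
    int16_t d = (int16_t)((u >> 1) ^ (uint16_t)(-(int16_t)(u & 1)));
    prev = (int16_t)((uint16_t)prev + (uint16_t)d);
    out[i] = (int)prev;
  }
}

// [[Rcpp::export]]
IntegerVector zigzag_delta_cpp(IntegerVector signal) {
  std::vector<uint32_t> z = zigzag_of(signal);
  IntegerVector out((R_xlen_t)z.size());
  for (size_t i = 0; i < z.size(); ++i) out[(R_xlen_t)i] = (int)z[i];
  return out;
}

// [[Rcpp::export]]
IntegerVector unzigzag_delta_cpp(IntegerVector zz) {
  std::vector<uint32_t> z((size_t)zz.size());
  for (R_xlen_t i = 0; i < zz.size(); ++i) {
    if (zz[i] == NA_INTEGER || zz[i] < 0) stop("zigzag values must be non-negative");
    z[(size_t)i] = (uint32_t)zz[i];
  }
  IntegerVector out(zz.size());
  unzigzag_into(z, INTEGER(out));
  return out;
}

// [[Rcpp::export]]
RawVector svb_encode_cpp(IntegerVector values, int max_bytes) {
  std::vector<uint32_t> v((size_t)values.size());
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    if (values[i] == NA_INTEGER || values[i] < 0) stop("values must be non-negative integers");
    v[(size_t)i] = (uint32_t)values[i];
  }
  std::vector<uint8_t> out;
  try {
    svb_encode_vec(v, max_bytes, out);
  } catch (const std::range_error &e) {
    stop("codec-range: %s", e.what());
  }
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector svb_decode_cpp(RawVector payload, int max_bytes) {
  std::vector<uint32_t> v;
  try {
    v = svb_decode_vec(RAW(payload), (size_t)payload.size(), max_bytes);
  } catch (const std::invalid_argument &e) {
    stop("malformed-payload: %s", e.what());
  }
  IntegerVector out((R_xlen_t)v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    if (v[i] > (uint32_t)INT_MAX) stop("decoded value exceeds R integer range");
    out[(R_xlen_t)i] = (int)v[i];
  }
  return out;
}

// [[Rcpp::export]]
RawVector compress_cpp(RawVector blob, int codec) {
  std::vector<uint8_t> out = compress_blob(RAW(blob), (size_t)blob.size(), codec);
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
RawVector decompress_cpp(RawVector blob, int codec) {
  std::vector<uint8_t> out;
  try {
    out = decompress_blob(RAW(blob), (size_t)blob.size(), codec);
  } catch (const std::exception &e) {
    stop("%s", e.what());
  }
  return RawVector(out.begin(), out.end());
}

// Full signal pipeline used by the binary writer/reader.
// [[Rcpp::export]]
RawVector signal_encode_cpp(IntegerVector signal, int signal_codec) {
  if (signal_codec == 0) {
    std::vector<uint8_t> out;
    out.reserve((size_t)signal.size() * 2);
    for (R_xlen_t i = 0; i < signal.size(); ++i) {
      int v = signal[i];
      if (v == NA_INTEGER || v < -32768 || v > 32767)
        stop("signal value out of signed 16-bit range at position %lld", (long long)(i + 1));
      put_u16(out, (uint16_t)(int16_t)v);
    }
    return RawVector(out.begin(), out.end());
  }
  std::vector<uint32_t> z = zigzag_of(signal);
  std::vector<uint8_t> out;
  svb_encode_vec(z, signal_codec == 2 ? 2 : 4, out);
  return RawVector(out.begin(), out.end());
}

// [[Rcpp::export]]
IntegerVector signal_decode_cpp(RawVector payload, int signal_codec) {
  if (signal_codec == 0) {
    if (payload.size() % 2 != 0) stop("malformed-payload: odd raw int16 payload");
    R_xlen_t n = payload.size() / 2;
    IntegerVector out(n);
    const uint8_t *p = RAW(payload);
    for (R_xlen_t i = 0; i < n; ++i) {
      uint16_t u = (uint16_t)p[2 * i] | ((uint16_t)p[2 * i + 1] << 8);
      out[i] = (int)(int16_t)u;
    }
    return out;
  }
  std::vector<uint32_t> z;
  try {
    z = svb_decode_vec(RAW(payload), (size_t)payload.size(),
                       signal_codec == 2 ? 2 : 4);
  } catch (const std::invalid_argument &e) {
    stop("malformed-payload: %s", e.what());
  }
  IntegerVector out((R_xlen_t)z.size());
  unzigzag_into(z, INTEGER(out));
  return out;
}

// [[Rcpp::export]]
bool has_zstd_cpp() { return true; }

// Order-insensitive callers must sort before calling; the digest walks pairs
// in the order given.
// [[Rcpp::export]]
std::string fnv_digest_cpp(CharacterVector ids, NumericVector sums) {
  if (ids.size() != sums.size()) stop("ids and sums differ in length");
  uint64_t h = 14695981039346656037ULL;
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    const char *s = CHAR(STRING_ELT(ids, i));
    h = fnv1a64((const uint8_t *)s, std::strlen(s), h);
    uint8_t sep = 0;
    h = fnv1a64(&sep, 1, h);
    double d = sums[i];
    uint8_t b[8];
    std::memcpy(b, &d, 8);
    h = fnv1a64(b, 8, h);
  }
  char buf[17];
  snprintf(buf, sizeof buf, "%016llx", (unsigned long long)h);
  return std::string(buf);
}

// [[Rcpp::export]]
RawVector fnv_bytes_cpp(RawVector blob) {
  uint64_t h = fnv1a64(RAW(blob), (size_t)blob.size(), 14695981039346656037ULL);
  RawVector out(8);
  for (int i = 0; i < 8; ++i) out[i] = (h >> (8 * i)) & 0xFF;
  return out;
}

// [[Rcpp::export]]
List split_by_lengths_cpp(IntegerVector values, IntegerVector lengths) {
  R_xlen_t total = 0;
  for (R_xlen_t i = 0; i < lengths.size(); ++i) total += lengths[i];
  if (total != values.size()) stop("lengths do not sum to the value count");
  List out(lengths.size());
  R_xlen_t at = 0;
  for (R_xlen_t i = 0; i < lengths.size(); ++i) {
    IntegerVector v(lengths[i]);
    std::memcpy(INTEGER(v), INTEGER(values) + at, sizeof(int) * (size_t)lengths[i]);
    at += lengths[i];
    out[i] = v;
  }
  return out;
}
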