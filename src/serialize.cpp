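#include <Rcpp.h>
#include "sigrow.h"

using namespace Rcpp;
using namespace sigrow;

RawVector signal_encode_cpp(IntegerVector signal, int signal_codec);
IntegerVector signal_decode_cpp(RawVector payload, int signal_codec);

// Binary record body layout (all little-endian):
//   u16 id_len, id bytes
//   u32 read_group
//   f64 digitisation, offset, range, sampling_rate
//   u64 len_raw_signal
//   u64 payload_len, payload (signal_codec applied)
//   u16 channel_len, channel bytes
//   f64 median_before (NaN = absent)
//   u32 read_number
//   u8  start_mux
//   u64 start_time
//   u16 n_extras, then per extra: u16 klen, key, u32 vlen (0xFFFFFFFF = NA), value
// A framed record is: u32 L, then the L-byte record_codec-compressed body.
// The end-of-file marker is FF FF FF FF 'E' 'O' 'F' '5' — a frame length of
// 0xFFFFFFFF is invalid, which makes the marker unambiguous during scans.

static const uint32_t EOF_SENTINEL = 0xFFFFFFFFu;

static void encode_one_body(std::vector<uint8_t> &body,
                            const char *id, uint32_t read_group,
                            double dig, double off, double range, double srate,
                            SEXP signal_sxp, int signal_codec,
                            const char *channel, double median_before,
                            uint32_t read_number, uint8_t start_mux,
                            double start_time,
                            const std::vector<std::string> &extra_keys,
                            const std::vector<const char *> &extra_vals) {
  size_t idlen = std::strlen(id);
  if (idlen == 0 || idlen > 0xFFFF) throw std::invalid_argument("read_id empty or too long");
  put_u16(body, (uint16_t)idlen);
  body.insert(body.end(), id, id + idlen);
  put_u32(body, read_group);
  put_f64(body, dig);
  put_f64(body, off);
  put_f64(body, range);
  put_f64(body, srate);
  IntegerVector signal(signal_sxp);
  put_u64(body, (uint64_t)signal.size());
  RawVector payload = signal_encode_cpp(signal, signal_codec);
  put_u64(body, (uint64_t)payload.size());
  body.insert(body.end(), RAW(payload), RAW(payload) + payload.size());
  put_str(body, std::string(channel));
  put_f64(body, median_before);
  put_u32(body, read_number);
  put_u8(body, start_mux);
  put_u64(body, (uint64_t)start_time);
  put_u16(body, (uint16_t)extra_keys.size());
  for (size_t k = 0; k < extra_keys.size(); ++k) {
    put_str(body, extra_keys[k]);
    if (extra_vals[k] == nullptr) {
      put_u32(body, 0xFFFFFFFFu);
    } else {
      size_t vl = std::strlen(extra_vals[k]);
      put_u32(body, (uint32_t)vl);
      body.insert(body.end(), extra_vals[k], extra_vals[k] + vl);
    }
  }
}

// [[Rcpp::export]]
List encode_records_cpp(List fields, int signal_codec, int record_codec) {
  CharacterVector read_id = fields["read_id"];
  IntegerVector read_group = fields["read_group"];
  NumericVector dig = fields["digitisation"];
  NumericVector off = fields["offset"];
  NumericVector range = fields["range"];
  NumericVector srate = fields["sampling_rate"];
  List signals = fields["raw_signal"];
  CharacterVector channel = fields["channel_number"];
  NumericVector median_before = fields["median_before"];
  IntegerVector read_number = fields["read_number"];
  IntegerVector start_mux = fields["start_mux"];
  NumericVector start_time = fields["start_time"];
  CharacterVector extra_names = fields["extra_names"];
  List extras = fields["extras"];

  R_xlen_t n = read_id.size();
  std::vector<std::string> ekeys;
  for (R_xlen_t k = 0; k < extra_names.size(); ++k)
    ekeys.push_back(std::string(CHAR(STRING_ELT(extra_names, k))));

  std::vector<uint8_t> blob;
  NumericVector offsets(n), lengths(n);
  std::vector<uint8_t> body;
  for (R_xlen_t i = 0; i < n; ++i) {
    body.clear();
    std::vector<const char *> evals(ekeys.size(), nullptr);
    for (size_t k = 0; k < ekeys.size(); ++k) {
      CharacterVector col = extras[k];
      if (STRING_ELT(col, i) != NA_STRING) evals[k] = CHAR(STRING_ELT(col, i));
    }
    double mb = median_before[i];
    if (NumericVector::is_na(mb)) mb = R_NaN;
    try {
      encode_one_body(body, CHAR(STRING_ELT(read_id, i)),
                      (uint32_t)read_group[i], dig[i], off[i], range[i],
                      srate[i], signals[i], signal_codec,
                      CHAR(STRING_ELT(channel, i)), mb,
                      (uint32_t)read_number[i], (uint8_t)start_mux[i],
                      start_time[i], ekeys, evals);
    } catch (const std::exception &e) {
      stop("record %lld: %s", (long long)(i + 1), e.what());
    }
    std::vector<uint8_t> framed = compress_blob(body.data(), body.size(), record_codec);
    offsets[i] = (double)blob.size();
    lengths[i] = (double)(framed.size() + 4);
    put_u32(blob, (uint32_t)framed.size());
    blob.insert(blob.end(), framed.begin(), framed.end());
  }
  return List::create(_["blob"] = RawVector(blob.begin(), blob.end()),
                      _["offsets"] = offsets, _["lengths"] = lengths);
}

struct DecodedCols {
  std::vector<std::string> read_id, channel;
  std::vector<int> read_group, read_number, start_mux;
  std::vector<double> dig, off, range, srate, median_before, start_time;
  std::vector<uint64_t> len_raw;
  List signals;
  std::vector<std::string> extra_names;            // union, in first-seen order
  std::vector<std::vector<std::string>> extra_vals; // per key, per record ("" + na flag)
  std::vector<std::vector<bool>> extra_na;
  DecodedCols(R_xlen_t n) : signals(n) {}
};

static void decode_one_body(const uint8_t *p, size_t n, int signal_codec,
                            bool parse_signal, DecodedCols &out, R_xlen_t slot) {
  Cursor c{p, n, 0};
  if (!c.ok(2)) throw std::invalid_argument("truncated record body");
  uint16_t idlen = c.u16();
  if (!c.ok(idlen)) throw std::invalid_argument("truncated read id");
  out.read_id.emplace_back((const char *)p + c.at, idlen);
  c.at += idlen;
  if (!c.ok(4 + 8 * 4 + 8 + 8)) throw std::invalid_argument("truncated record fields");
  out.read_group.push_back((int)c.u32());
  out.dig.push_back(c.f64());
  out.off.push_back(c.f64());
  out.range.push_back(c.f64());
  out.srate.push_back(c.f64());
  uint64_t len_raw = c.u64();
  uint64_t plen = c.u64();
  if (!c.ok((size_t)plen)) throw std::invalid_argument("truncated signal payload");
  out.len_raw.push_back(len_raw);
  if (parse_signal) {
    RawVector payload((R_xlen_t)plen);
    std::memcpy(RAW(payload), p + c.at, (size_t)plen);
    IntegerVector sig = signal_decode_cpp(payload, signal_codec);
    if ((uint64_t)sig.size() != len_raw)
      throw std::invalid_argument("len_raw_signal does not match decoded signal length");
    out.signals[slot] = sig;
  }
  c.at += (size_t)plen;
  if (!c.ok(2)) throw std::invalid_argument("truncated auxiliary block");
  uint16_t chlen = c.u16();
  if (!c.ok((size_t)chlen + 8 + 4 + 1 + 8 + 2)) throw std::invalid_argument("truncated auxiliary block");
  out.channel.emplace_back((const char *)p + c.at, chlen);
  c.at += chlen;
  out.median_before.push_back(c.f64());
  out.read_number.push_back((int)c.u32());
  out.start_mux.push_back((int)c.u8());
  out.start_time.push_back((double)c.u64());
  uint16_t n_extras = c.u16();
  for (uint16_t k = 0; k < n_extras; ++k) {
    if (!c.ok(2)) throw std::invalid_argument("truncated extra field");
    uint16_t klen = c.u16();
    if (!c.ok((size_t)klen + 4)) throw std::invalid_argument("truncated extra field");
    std::string key((const char *)p + c.at, klen);
    c.at += klen;
    uint32_t vlen = c.u32();
    std::string val;
    bool is_na = (vlen == 0xFFFFFFFFu);
    if (!is_na) {
      if (!c.ok(vlen)) throw std::invalid_argument("truncated extra value");
      val.assign((const char *)p + c.at, vlen);
      c.at += vlen;
    }
    size_t ki = out.extra_names.size();
    for (size_t j = 0; j < out.extra_names.size(); ++j)
      if (out.extra_names[j] == key) { ki = j; break; }
    if (ki == out.extra_names.size()) {
      out.extra_names.push_back(key);
      out.extra_vals.emplace_back();
      out.extra_na.emplace_back();
      // back-fill records seen before this key appeared
      out.extra_vals[ki].resize((size_t)slot, "");
      out.extra_na[ki].resize((size_t)slot, true);
    }
    out.extra_vals[ki].resize((size_t)slot + 1, "");
    out.extra_na[ki].resize((size_t)slot + 1, true);
    out.extra_vals[ki][(size_t)slot] = val;
    out.extra_na[ki][(size_t)slot] = is_na;
  }
  if (c.at != n) throw std::invalid_argument("trailing bytes in record body");
}

static List cols_to_list(DecodedCols &d, R_xlen_t n) {
  CharacterVector read_id(n), channel(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    read_id[i] = d.read_id[(size_t)i];
    channel[i] = d.channel[(size_t)i];
  }
  NumericVector median_before(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = d.median_before[(size_t)i];
    median_before[i] = ISNAN(v) ? NA_REAL : v;
  }
  List extras(d.extra_names.size());
  CharacterVector extra_names(d.extra_names.size());
  for (size_t k = 0; k < d.extra_names.size(); ++k) {
    extra_names[(R_xlen_t)k] = d.extra_names[k];
    d.extra_vals[k].resize((size_t)n, "");
    d.extra_na[k].resize((size_t)n, true);
    CharacterVector col(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      if (d.extra_na[k][(size_t)i]) col[i] = NA_STRING;
      else col[i] = d.extra_vals[k][(size_t)i];
    }
    extras[(R_xlen_t)k] = col;
  }
  NumericVector len_raw(n);
  for (R_xlen_t i = 0; i < n; ++i) len_raw[i] = (double)d.len_raw[(size_t)i];
  return List::create(
      _["read_id"] = read_id,
      _["read_group"] = IntegerVector(d.read_group.begin(), d.read_group.end()),
      _["digitisation"] = NumericVector(d.dig.begin(), d.dig.end()),
      _["offset"] = NumericVector(d.off.begin(), d.off.end()),
      _["range"] = NumericVector(d.range.begin(), d.range.end()),
      _["sampling_rate"] = NumericVector(d.srate.begin(), d.srate.end()),
      _["len_raw_signal"] = len_raw,
      _["raw_signal"] = d.signals,
      _["channel_number"] = channel,
      _["median_before"] = median_before,
      _["read_number"] = IntegerVector(d.read_number.begin(), d.read_number.end()),
      _["start_mux"] = IntegerVector(d.start_mux.begin(), d.start_mux.end()),
      _["start_time"] = NumericVector(d.start_time.begin(), d.start_time.end()),
      _["extra_names"] = extra_names,
      _["extras"] = extras);
}

// Scan frames in `buf` starting at 0-based `start`, decoding at most
// `max_records` records.  `index_base` is the absolute record number of the
// first frame, used in error messages.  Returns fields plus scan state:
// status "ok" (hit max_records), "eof" (hit the end-of-file marker),
// "partial" (ran out of buffer mid-frame).
// [[Rcpp::export]]
List decode_frames_cpp(RawVector buf, double start, int max_records,
                       int record_codec, int signal_codec, double index_base) {
  const uint8_t *p = RAW(buf);
  size_t n = (size_t)buf.size();
  size_t at = (size_t)start;
  // first pass: find frame offsets
  std::vector<size_t> frame_at, frame_len;
  std::string status = "ok";
  size_t eof_at = 0;
  while ((int)frame_at.size() < max_records) {
    if (at + 4 > n) { status = "partial"; break; }
    Cursor c{p, n, at};
    uint32_t L = c.u32();
    if (L == EOF_SENTINEL) {
      if (at + 8 > n) { status = "partial"; break; }
      if (std::memcmp(p + at + 4, "EOF5", 4) == 0) { status = "eof"; eof_at = at + 8; break; }
      stop("corrupt frame length at byte %llu", (unsigned long long)at);
    }
    if (at + 4 + (size_t)L > n) { status = "partial"; break; }
    frame_at.push_back(at);
    frame_len.push_back((size_t)L);
    at += 4 + (size_t)L;
  }
  R_xlen_t nr = (R_xlen_t)frame_at.size();
  DecodedCols d(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    std::vector<uint8_t> body;
    try {
      body = decompress_blob(p + frame_at[(size_t)i] + 4, frame_len[(size_t)i], record_codec);
      decode_one_body(body.data(), body.size(), signal_codec, true, d, i);
    } catch (const std::exception &e) {
      stop("record %lld: %s", (long long)(index_base + i + 1), e.what());
    }
  }
  List fields = cols_to_list(d, nr);
  NumericVector offs(nr), lens(nr);
  for (R_xlen_t i = 0; i < nr; ++i) {
    offs[i] = (double)frame_at[(size_t)i];
    lens[i] = (double)(frame_len[(size_t)i] + 4);
  }
  return List::create(_["fields"] = fields, _["n"] = (int)nr,
                      _["status"] = status,
                      _["next"] = (double)(status == "eof" ? eof_at : at),
                      _["frame_offsets"] = offs, _["frame_lengths"] = lens);
}

// Decode a list of individually framed records (each raw vector is one
// u32-length-prefixed frame), e.g. the result of indexed random access.
// [[Rcpp::export]]
List decode_framed_records_cpp(List frames, int record_codec, int signal_codec) {
  R_xlen_t n = frames.size();
  DecodedCols d(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    RawVector f = frames[i];
    if (f.size() < 4) stop("record %lld: frame shorter than its length prefix", (long long)(i + 1));
    Cursor c{RAW(f), (size_t)f.size(), 0};
    uint32_t L = c.u32();
    if ((size_t)L + 4 != (size_t)f.size())
      stop("record %lld: frame length mismatch", (long long)(i + 1));
    try {
      std::vector<uint8_t> body = decompress_blob(RAW(f) + 4, (size_t)L, record_codec);
      decode_one_body(body.data(), body.size(), signal_codec, true, d, i);
    } catch (const std::exception &e) {
      stop("record %lld: %s", (long long)(i + 1), e.what());
    }
  }
  return cols_to_list(d, n);
}

// ---- header block ----
// u8 ver x3, u32 num_read_groups, u16 n_keys,
// then per key: u16 klen, key, num_read_groups x (u32 vlen, value)

// [[Rcpp::export]]
RawVector header_encode_cpp(IntegerVector version, int num_read_groups,
                            CharacterVector keys, List values) {
  std::vector<uint8_t> b;
  for (int i = 0; i < 3; ++i) put_u8(b, (uint8_t)version[i]);
  put_u32(b, (uint32_t)num_read_groups);
  put_u16(b, (uint16_t)keys.size());
  for (R_xlen_t k = 0; k < keys.size(); ++k) {
    put_str(b, std::string(CHAR(STRING_ELT(keys, k))));
    CharacterVector vals = values[k];
    if (vals.size() != num_read_groups)
      stop("attribute '%s' must have one value per read group", CHAR(STRING_ELT(keys, k)));
    for (R_xlen_t g = 0; g < vals.size(); ++g) {
      if (STRING_ELT(vals, g) == NA_STRING) {
        put_u32(b, 0xFFFFFFFFu);
      } else {
        const char *v = CHAR(STRING_ELT(vals, g));
        size_t vl = std::strlen(v);
        put_u32(b, (uint32_t)vl);
        b.insert(b.end(), v, v + vl);
      }
    }
  }
  return RawVector(b.begin(), b.end());
}

// [[Rcpp::export]]
List header_decode_cpp(RawVector blob) {
  Cursor c{RAW(blob), (size_t)blob.size(), 0};
  if (!c.ok(3 + 4 + 2)) stop("truncated header block");
  IntegerVector version(3);
  for (int i = 0; i < 3; ++i) version[i] = (int)c.u8();
  uint32_t ng = c.u32();
  uint16_t nk = c.u16();
  CharacterVector keys(nk);
  List values(nk);
  for (uint16_t k = 0; k < nk; ++k) {
    if (!c.ok(2)) stop("truncated header block");
    uint16_t klen = c.u16();
    if (!c.ok(klen)) stop("truncated header block");
    keys[k] = std::string((const char *)RAW(blob) + c.at, klen);
    c.at += klen;
    CharacterVector vals((R_xlen_t)ng);
    for (uint32_t g = 0; g < ng; ++g) {
      if (!c.ok(4)) stop("truncated header block");
      uint32_t vlen = c.u32();
      if (vlen == 0xFFFFFFFFu) { vals[(R_xlen_t)g] = NA_STRING; continue; }
      if (!c.ok(vlen)) stop("truncated header block");
      vals[(R_xlen_t)g] = std::string((const char *)RAW(blob) + c.at, vlen);
      c.at += vlen;
    }
    values[k] = vals;
  }
  if (c.at != (size_t)blob.size()) stop("trailing bytes in header block");
  return List::create(_["version"] = version, _["num_read_groups"] = (int)ng,
                      _["keys"] = keys, _["values"] = values);
}

// ---- index sidecar payload ----
// u64 n, then per entry: u16 idlen, id, u64 offset, u32 length

// [[Rcpp::export]]
RawVector pack_index_cpp(CharacterVector ids, NumericVector offsets,
                         NumericVector lengths) {
  std::vector<uint8_t> b;
  put_u64(b, (uint64_t)ids.size());
  for (R_xlen_t i = 0; i < ids.size(); ++i) {
    put_str(b, std::string(CHAR(STRING_ELT(ids, i))));
    put_u64(b, (uint64_t)offsets[i]);
    put_u32(b, (uint32_t)lengths[i]);
  }
  return RawVector(b.begin(), b.end());
}

// [[Rcpp::export]]
List unpack_index_cpp(RawVector blob) {
  Cursor c{RAW(blob), (size_t)blob.size(), 0};
  if (!c.ok(8)) stop("truncated index payload");
  uint64_t n = c.u64();
  CharacterVector ids((R_xlen_t)n);
  NumericVector offsets((R_xlen_t)n), lengths((R_xlen_t)n);
  for (uint64_t i = 0; i < n; ++i) {
    if (!c.ok(2)) stop("truncated index payload");
    uint16_t idlen = c.u16();
    if (!c.ok((size_t)idlen + 12)) stop("truncated index payload");
    ids[(R_xlen_t)i] = std::string((const char *)RAW(blob) + c.at, idlen);
    c.at += idlen;
    offsets[(R_xlen_t)i] = (double)c.u64();
    lengths[(R_xlen_t)i] = (double)c.u32();
  }
  if (c.at != (size_t)blob.size()) stop("trailing bytes in index payload");
  return List::create(_["read_id"] = ids, _["offset"] = offsets,
                      _["length"] = lengths);
}

// ---- columnar comparator ----
// Signal region: sequence of chunk records, each
//   u32 read_ordinal (0-based), u32 chunk_ordinal (0-based), u32 n_samples,
//   n_samples x int16 LE.
// `policy` 0 = contiguous, 1 = round_robin with concurrency `width`.

// [[Rcpp::export]]
List colsig_encode_signal_cpp(List signals, int chunk_size, int policy, int width) {
  R_xlen_t n = signals.size();
  std::vector<std::vector<double>> offs((size_t)n);
  std::vector<std::vector<int>> nsamp((size_t)n);
  std::vector<uint8_t> blob;

  // chunk plan per read
  std::vector<int> n_chunks((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) {
    IntegerVector s = signals[i];
    n_chunks[(size_t)i] = (int)((s.size() + chunk_size - 1) / chunk_size);
    if (s.size() == 0) n_chunks[(size_t)i] = 0;
  }

  auto emit = [&](R_xlen_t read, int chunk) {
    IntegerVector s = signals[read];
    R_xlen_t from = (R_xlen_t)chunk * chunk_size;
    R_xlen_t len = std::min((R_xlen_t)chunk_size, s.size() - from);
    offs[(size_t)read].push_back((double)blob.size());
    nsamp[(size_t)read].push_back((int)len);
    put_u32(blob, (uint32_t)read);
    put_u32(blob, (uint32_t)chunk);
    put_u32(blob, (uint32_t)len);
    for (R_xlen_t j = 0; j < len; ++j) {
      int v = s[from + j];
      if (v == NA_INTEGER || v < -32768 || v > 32767)
        stop("signal value out of signed 16-bit range in read %lld", (long long)(read + 1));
      put_u16(blob, (uint16_t)(int16_t)v);
    }
  };

  if (policy == 0) {
    for (R_xlen_t i = 0; i < n; ++i)
      for (int ch = 0; ch < n_chunks[(size_t)i]; ++ch) emit(i, ch);
  } else {
    // keep up to `width` reads open; emit one chunk from each in rotation
    std::vector<R_xlen_t> open;
    std::vector<int> next_chunk;
    R_xlen_t next_read = 0;
    size_t turn = 0;
    auto refill = [&]() {
      while ((int)open.size() < width && next_read < n) {
        if (n_chunks[(size_t)next_read] == 0) { ++next_read; continue; }
        open.push_back(next_read);
        next_chunk.push_back(0);
        ++next_read;
      }
    };
    refill();
    while (!open.empty()) {
      if (turn >= open.size()) turn = 0;
      R_xlen_t r = open[turn];
      emit(r, next_chunk[turn]);
      if (++next_chunk[turn] >= n_chunks[(size_t)r]) {
        open.erase(open.begin() + turn);
        next_chunk.erase(next_chunk.begin() + turn);
        refill();
      } else {
        ++turn;
      }
    }
  }

  List chunk_offsets(n), chunk_nsamples(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    chunk_offsets[i] = NumericVector(offs[(size_t)i].begin(), offs[(size_t)i].end());
    chunk_nsamples[i] = IntegerVector(nsamp[(size_t)i].begin(), nsamp[(size_t)i].end());
  }
  return List::create(_["blob"] = RawVector(blob.begin(), blob.end()),
                      _["chunk_offsets"] = chunk_offsets,
                      _["chunk_nsamples"] = chunk_nsamples);
}

// Reassemble selected reads from the in-memory file blob (sequential path).
// `read_ords` are 0-based ordinals matching the chunk tags.
// [[Rcpp::export]]
List colsig_decode_chunks_cpp(RawVector file_blob, List chunk_offsets,
                              List chunk_nsamples, IntegerVector read_ords) {
  const uint8_t *p = RAW(file_blob);
  size_t n = (size_t)file_blob.size();
  R_xlen_t k = read_ords.size();
  List out(k);
  for (R_xlen_t i = 0; i < k; ++i) {
    NumericVector offs = chunk_offsets[i];
    IntegerVector ns = chunk_nsamples[i];
    R_xlen_t total = 0;
    for (R_xlen_t c = 0; c < ns.size(); ++c) total += ns[c];
    IntegerVector sig(total);
    R_xlen_t at_out = 0;
    for (R_xlen_t c = 0; c < offs.size(); ++c) {
      size_t at = (size_t)offs[c];
      if (at + 12 > n) stop("chunk offset out of bounds");
      Cursor cur{p, n, at};
      uint32_t rtag = cur.u32();
      uint32_t ctag = cur.u32();
      uint32_t len = cur.u32();
      if ((int)rtag != read_ords[i] || (int)ctag != (int)c)
        stop("chunk tag mismatch: expected read %d chunk %lld, found read %u chunk %u",
             read_ords[i], (long long)c, rtag, ctag);
      if ((int)len != ns[c]) stop("chunk sample-count mismatch");
      if (!cur.ok((size_t)len * 2)) stop("chunk payload out of bounds");
      for (uint32_t j = 0; j < len; ++j) {
        uint16_t u = cur.u16();
        sig[at_out++] = (int)(int16_t)u;
      }
    }
    out[i] = sig;
  }
  return out;
}

// Footer: u64 n_reads; per read u32 n_chunks then per chunk (u64 abs offset,
// u32 n_samples); u16 n_cols; per column: u16 namelen, name, u8 type,
// u64 abs offset, u64 byte length, u8 has_table, [u64 n then n x u64
// value offsets relative to the column start].
// Column types: 0 f64, 1 u32, 2 u8, 3 var-str.

// [[Rcpp::export]]
RawVector colsig_footer_encode_cpp(List chunk_offsets, List chunk_nsamples,
                                   double chunk_base, CharacterVector col_names,
                                   IntegerVector col_types, NumericVector col_offsets,
                                   NumericVector col_lengths, List str_tables) {
  std::vector<uint8_t> b;
  R_xlen_t n = chunk_offsets.size();
  put_u64(b, (uint64_t)n);
  for (R_xlen_t i = 0; i < n; ++i) {
    NumericVector offs = chunk_offsets[i];
    IntegerVector ns = chunk_nsamples[i];
    put_u32(b, (uint32_t)offs.size());
    for (R_xlen_t c = 0; c < offs.size(); ++c) {
      put_u64(b, (uint64_t)(offs[c] + chunk_base));
      put_u32(b, (uint32_t)ns[c]);
    }
  }
  put_u16(b, (uint16_t)col_names.size());
  for (R_xlen_t k = 0; k < col_names.size(); ++k) {
    put_str(b, std::string(CHAR(STRING_ELT(col_names, k))));
    put_u8(b, (uint8_t)col_types[k]);
    put_u64(b, (uint64_t)col_offsets[k]);
    put_u64(b, (uint64_t)col_lengths[k]);
    if (Rf_isNull(str_tables[k])) {
      put_u8(b, 0);
    } else {
      put_u8(b, 1);
      NumericVector tab = str_tables[k];
      put_u64(b, (uint64_t)tab.size());
      for (R_xlen_t i = 0; i < tab.size(); ++i) put_u64(b, (uint64_t)tab[i]);
    }
  }
  return RawVector(b.begin(), b.end());
}

// [[Rcpp::export]]
List colsig_footer_decode_cpp(RawVector blob) {
  Cursor c{RAW(blob), (size_t)blob.size(), 0};
  if (!c.ok(8)) stop("truncated footer");
  uint64_t n = c.u64();
  List chunk_offsets((R_xlen_t)n), chunk_nsamples((R_xlen_t)n);
  for (uint64_t i = 0; i < n; ++i) {
    if (!c.ok(4)) stop("truncated footer");
    uint32_t nc = c.u32();
    NumericVector offs((R_xlen_t)nc);
    IntegerVector ns((R_xlen_t)nc);
    for (uint32_t ch = 0; ch < nc; ++ch) {
      if (!c.ok(12)) stop("truncated footer");
      offs[(R_xlen_t)ch] = (double)c.u64();
      ns[(R_xlen_t)ch] = (int)c.u32();
    }
    chunk_offsets[(R_xlen_t)i] = offs;
    chunk_nsamples[(R_xlen_t)i] = ns;
  }
  if (!c.ok(2)) stop("truncated footer");
  uint16_t nk = c.u16();
  CharacterVector col_names(nk);
  IntegerVector col_types(nk);
  NumericVector col_offsets(nk), col_lengths(nk);
  List str_tables(nk);
  for (uint16_t k = 0; k < nk; ++k) {
    if (!c.ok(2)) stop("truncated footer");
    uint16_t klen = c.u16();
    if (!c.ok((size_t)klen + 1 + 16 + 1)) stop("truncated footer");
    col_names[k] = std::string((const char *)RAW(blob) + c.at, klen);
    c.at += klen;
    col_types[k] = (int)c.u8();
    col_offsets[k] = (double)c.u64();
    col_lengths[k] = (double)c.u64();
    uint8_t has_tab = c.u8();
    if (has_tab) {
      if (!c.ok(8)) stop("truncated footer");
      uint64_t tn = c.u64();
      NumericVector tab((R_xlen_t)tn);
      for (uint64_t i = 0; i < tn; ++i) {
        if (!c.ok(8)) stop("truncated footer");
        tab[(R_xlen_t)i] = (double)c.u64();
      }
      str_tables[k] = tab;
    } else {
      str_tables[k] = R_NilValue;
    }
  }
  if (c.at != (size_t)blob.size()) stop("trailing bytes in footer");
  return List::create(_["chunk_offsets"] = chunk_offsets,
                      _["chunk_nsamples"] = chunk_nsamples,
                      _["col_names"] = col_names, _["col_types"] = col_types,
                      _["col_offsets"] = col_offsets,
                      _["col_lengths"] = col_lengths,
                      _["str_tables"] = str_tables);
}

// var-str column: per value u32 len (0xFFFFFFFF = NA) + bytes; offsets are
// relative to the column start.
// [[Rcpp::export]]
List pack_str_col_cpp(CharacterVector x) {
  std::vector<uint8_t> b;
  NumericVector offsets(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    offsets[i] = (double)b.size();
    if (STRING_ELT(x, i) == NA_STRING) {
      put_u32(b, 0xFFFFFFFFu);
    } else {
      const char *s = CHAR(STRING_ELT(x, i));
      size_t sl = std::strlen(s);
      put_u32(b, (uint32_t)sl);
      b.insert(b.end(), s, s + sl);
    }
  }
  return List::create(_["blob"] = RawVector(b.begin(), b.end()),
                      _["offsets"] = offsets);
}

// [[Rcpp::export]]
CharacterVector unpack_str_col_cpp(RawVector blob, NumericVector offsets) {
  CharacterVector out(offsets.size());
  const uint8_t *p = RAW(blob);
  size_t n = (size_t)blob.size();
  for (R_xlen_t i = 0; i < offsets.size(); ++i) {
    size_t at = (size_t)offsets[i];
    if (at + 4 > n) stop("string column offset out of bounds");
    Cursor c{p, n, at};
    uint32_t len = c.u32();
    if (len == 0xFFFFFFFFu) { out[i] = NA_STRING; continue; }
    if (!c.ok(len)) stop("string column value out of bounds");
    out[i] = std::string((const char *)p + c.at, len);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector sum_signals_cpp(List signals) {
  NumericVector out(signals.size());
  for (R_xlen_t i = 0; i < signals.size(); ++i) {
    IntegerVector s = signals[i];
    double acc = 0;
    for (R_xlen_t j = 0; j < s.size(); ++j) acc += s[j];
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
RawVector pack_u64_cpp(NumericVector x) {
  std::vector<uint8_t> b;
  b.reserve((size_t)x.size() * 8);
  for (R_xlen_t i = 0; i < x.size(); ++i) put_u64(b, (uint64_t)x[i]);
  return RawVector(b.begin(), b.end());
}

// [[Rcpp::export]]
NumericVector unpack_u64_cpp(RawVector blob) {
  if (blob.size() % 8 != 0) stop("u64 column has ragged length");
  R_xlen_t n = blob.size() / 8;
  NumericVector out(n);
  Cursor c{RAW(blob), (size_t)blob.size(), 0};
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (double)c.u64();
  return out;
}
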