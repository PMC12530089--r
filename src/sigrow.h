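#ifndef SIGROW_H
#define SIGROW_H

#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

// codec identifiers shared between R and C++
// record codecs: 0 = none, 1 = zlib, 2 = zstd
// signal codecs: 0 = none, 1 = svb32-zd, 2 = svb16-zd

namespace sigrow {

void svb_encode_vec(const std::vector<uint32_t> &vals, int max_bytes,
                    std::vector<uint8_t> &out);
std::vector<uint32_t> svb_decode_vec(const uint8_t *p, size_t len, int max_bytes);
std::vector<uint8_t> compress_blob(const uint8_t *p, size_t n, int codec);
std::vector<uint8_t> decompress_blob(const uint8_t *p, size_t n, int codec);
uint64_t fnv1a64(const uint8_t *p, size_t n, uint64_t h);

// little-endian scalar writers on a byte buffer
inline void put_u8(std::vector<uint8_t> &b, uint8_t v) { b.push_back(v); }
inline void put_u16(std::vector<uint8_t> &b, uint16_t v) {
  b.push_back(v & 0xFF); b.push_back((v >> 8) & 0xFF);
}
inline void put_u32(std::vector<uint8_t> &b, uint32_t v) {
  for (int i = 0; i < 4; ++i) b.push_back((v >> (8 * i)) & 0xFF);
}
inline void put_u64(std::vector<uint8_t> &b, uint64_t v) {
  for (int i = 0; i < 8; ++i) b.push_back((v >> (8 * i)) & 0xFF);
}
inline void put_f64(std::vector<uint8_t> &b, double v) {
  uint64_t u; std::memcpy(&u, &v, 8); put_u64(b, u);
}
inline void put_str(std::vector<uint8_t> &b, const std::string &s) {
  put_u16(b, (uint16_t)s.size());
  b.insert(b.end(), s.begin(), s.end());
}

// bounds-checked little-endian readers
struct Cursor {
  const uint8_t *p;
  size_t n;
  size_t at;
  bool ok(size_t k) const { return at + k <= n; }
  uint8_t u8() { return p[at++]; }
  uint16_t u16() {
    uint16_t v = (uint16_t)p[at] | ((uint16_t)p[at + 1] << 8); at += 2; return v;
  }
  uint32_t u32() {
    uint32_t v = 0; for (int i = 0; i < 4; ++i) v |= (uint32_t)p[at + i] << (8 * i);
    at += 4; return v;
  }
  uint64_t u64() {
    uint64_t v = 0; for (int i = 0; i < 8; ++i) v |= (uint64_t)p[at + i] << (8 * i);
    at += 8; return v;
  }
  double f64() {
    uint64_t u = u64(); double v; std::memcpy(&v, &u, 8); return v;
  }
};

} // namespace sigrow

#endif
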