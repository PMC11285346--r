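#include <Rcpp.h>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Elias-Fano encoding of a strictly increasing sequence of m integers in
// [0, universe). Each position p is split at bit l into a high part
// (p >> l) and a low part (p & (2^l - 1)) with
//   l = max(0, floor(log2(universe / m))).
// Layout of the bitstream: the m fixed-width low parts first, then the high
// parts as unary-coded gaps (high[i] - high[i-1] zeros followed by a one).
// The low/high split keeps the total size near the information-theoretic
// minimum of m * (2 + log2(universe/m)) bits while the unary high array
// still decodes with a single left-to-right scan.

static int lowWidth(long long universe, long long m) {
  if (m <= 0) return 0;
  int l = 0;
  while ((m << (l + 1)) <= universe) ++l;
  return l;
}

static inline void setBit(std::vector<uint8_t>& buf, size_t bit) {
  size_t byte = bit >> 3;
  if (byte >= buf.size()) buf.resize(byte + 1, 0);
  buf[byte] |= (uint8_t)(1u << (bit & 7));
}

static inline int getBit(const std::vector<uint8_t>& buf, size_t bit) {
  size_t byte = bit >> 3;
  if (byte >= buf.size()) return -1;  // read past end: truncated stream
  return (buf[byte] >> (bit & 7)) & 1;
}

// [[Rcpp::export(name = ".efEncodeCpp")]]
List efEncodeCpp(IntegerVector positions, int universe) {
  const R_xlen_t m = positions.size();
  if (universe < 0) stop("universe must be non-negative");
  for (R_xlen_t i = 0; i < m; ++i) {
    if (positions[i] == NA_INTEGER || positions[i] < 0 || positions[i] >= universe)
      stop("position %d (value %d) out of range [0, %d)", (int)(i + 1),
           positions[i], universe);
    if (i > 0 && positions[i] <= positions[i - 1])
      stop("positions must be strictly increasing (violated at element %d)",
           (int)(i + 1));
  }
  const int l = lowWidth(universe, m);
  std::vector<uint8_t> buf;
  size_t bit = 0;
  // low parts, fixed width l, least-significant bit first
  for (R_xlen_t i = 0; i < m; ++i) {
    const uint32_t low = (l > 0) ? ((uint32_t)positions[i] & ((1u << l) - 1u)) : 0u;
    for (int b = 0; b < l; ++b) {
      if ((low >> b) & 1u) setBit(buf, bit);
      ++bit;
    }
  }
  // high parts, unary gap code
  int prevHigh = 0;
  for (R_xlen_t i = 0; i < m; ++i) {
    const int high = positions[i] >> l;
    bit += (size_t)(high - prevHigh);  // zeros
    setBit(buf, bit);                  // terminating one
    ++bit;
    prevHigh = high;
  }
  if (buf.size() < (bit + 7) / 8) buf.resize((bit + 7) / 8, 0);
  RawVector bytes(buf.size());
  std::copy(buf.begin(), buf.end(), bytes.begin());
  return List::create(_["bytes"] = bytes, _["m"] = (int)m,
                      _["universe"] = universe, _["l"] = l,
                      _["nbits"] = (double)bit);
}

// [[Rcpp::export(name = ".efDecodeCpp")]]
IntegerVector efDecodeCpp(RawVector bytes, int m, int universe, int l) {
  if (m < 0 || universe < 0 || l < 0) stop("invalid Elias-Fano header");
  IntegerVector out(m);
  if (m == 0) return out;
  std::vector<uint8_t> buf(bytes.begin(), bytes.end());
  size_t bit = 0;
  std::vector<uint32_t> lows(m, 0);
  for (int i = 0; i < m; ++i) {
    uint32_t low = 0;
    for (int b = 0; b < l; ++b) {
      int v = getBit(buf, bit++);
      if (v < 0) stop("truncated Elias-Fano stream (low bits)");
      low |= ((uint32_t)v) << b;
    }
    lows[i] = low;
  }
  int high = 0;
  for (int i = 0; i < m; ++i) {
    for (;;) {
      int v = getBit(buf, bit++);
      if (v < 0) stop("truncated Elias-Fano stream (high bits)");
      if (v == 1) break;
      ++high;
      if (high > (universe >> l)) stop("corrupt Elias-Fano stream");
    }
    long long p = ((long long)high << l) | lows[i];
    if (p >= universe) stop("corrupt Elias-Fano stream: decoded value out of range");
    out[i] = (int)p;
  }
  return out;
}
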