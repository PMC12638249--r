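#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// CRC-32 (IEEE 802.3 polynomial), table-driven.
// [[Rcpp::export(name = ".crc32_raw")]]
double crc32_raw(RawVector data) {
  static uint32_t table[256];
  static bool ready = false;
  if (!ready) {
    for (uint32_t i = 0; i < 256; i++) {
      uint32_t c = i;
      for (int k = 0; k < 8; k++) c = (c & 1u) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[i] = c;
    }
    ready = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); i++)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

static uint16_t f32_to_f16(float f) {
  uint32_t x;
  std::memcpy(&x, &f, 4);
  uint32_t sign = (x >> 16) & 0x8000u;
  uint32_t exp = (x >> 23) & 0xFFu;
  uint32_t man = x & 0x7FFFFFu;
  if (exp == 255u) return (uint16_t)(sign | 0x7C00u | (man ? 0x200u : 0u));
  int e = (int)exp - 127 + 15;
  if (e >= 31) return (uint16_t)(sign | 0x7C00u);           // overflow -> inf
  if (e <= 0) {                                             // subnormal / zero
    if (e < -10) return (uint16_t)sign;
    man |= 0x800000u;
    int shift = 14 - e;
    uint32_t half = man >> shift;
    uint32_t rem = man & ((1u << shift) - 1u);
    uint32_t mid = 1u << (shift - 1);
    if (rem > mid || (rem == mid && (half & 1u))) half++;
    return (uint16_t)(sign | half);
  }
  uint32_t half = ((uint32_t)e << 10) | (man >> 13);
  uint32_t rem = man & 0x1FFFu;
  if (rem > 0x1000u || (rem == 0x1000u && (half & 1u))) half++;  // RNE; carry ripples into exponent
  return (uint16_t)(sign | half);
}

static float f16_to_f32(uint16_t h) {
  uint32_t sign = ((uint32_t)(h & 0x8000u)) << 16;
  uint32_t exp = (h >> 10) & 0x1Fu;
  uint32_t man = h & 0x3FFu;
  uint32_t x;
  if (exp == 0u) {
    if (man == 0u) x = sign;
    else {
      int e = -1;
      do { man <<= 1; e++; } while (!(man & 0x400u));
      man &= 0x3FFu;
      x = sign | ((uint32_t)(127 - 15 - e) << 23) | (man << 13);
    }
  } else if (exp == 31u) {
    x = sign | 0x7F800000u | (man << 13);
  } else {
    x = sign | ((exp - 15u + 127u) << 23) | (man << 13);
  }
  float f;
  std::memcpy(&f, &x, 4);
  return f;
}

// [[Rcpp::export(name = ".f32_to_f16_bits")]]
IntegerVector f32_to_f16_bits(NumericVector x) {
  IntegerVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) out[i] = (int)f32_to_f16((float)x[i]);
  return out;
}

// [[Rcpp::export(name = ".f16_bits_to_double")]]
NumericVector f16_bits_to_double(IntegerVector bits) {
  NumericVector out(bits.size());
  for (R_xlen_t i = 0; i < bits.size(); i++)
    out[i] = (double)f16_to_f32((uint16_t)(bits[i] & 0xFFFF));
  return out;
}

// Connected-component labeling for 2D/3D logical masks (4-/6-connectivity).
// `mask` is in R's column-major layout with dims `dm` (length 2 or 3).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dm) {
  int nd = dm.size();
  if (nd < 2 || nd > 3) stop("mask must be 2D or 3D");
  int d0 = dm[0], d1 = dm[1], d2 = (nd == 3) ? dm[2] : 1;
  R_xlen_t n = (R_xlen_t)d0 * d1 * d2;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int i = (int)(p % d0);
      int j = (int)((p / d0) % d1);
      int k = (int)(p / ((R_xlen_t)d0 * d1));
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      int nn = (nd == 3) ? 6 : 4;
      for (int q = 0; q < nn; q++) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || ii >= d0 || jj < 0 || jj >= d1 || kk < 0 || kk >= d2) continue;
        R_xlen_t pp = ii + (R_xlen_t)d0 * (jj + (R_xlen_t)d1 * kk);
        if (mask[pp] && !lab[pp]) { lab[pp] = next; stack.push_back(pp); }
      }
    }
  }
  lab.attr("dim") = dm;
  return lab;
}
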