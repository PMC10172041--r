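#ifndef CENTRIFOLD_CATALOG_H
#define CENTRIFOLD_CATALOG_H

// Feature catalog layout for the SAF scoring vector theta.  The R-side
// catalog (R/catalog.R) is generated from cpp_catalog() so the two views
// cannot drift apart.  All residue codes are 1..4 = A,C,G,U.

namespace cf {

const int OFF_MATCH = 0;    // 10 unordered residue-pair match emissions
const int OFF_INS   = 10;   // 4 insert emissions (shared by I and D columns)
const int OFF_TRANS = 14;   // 9 state bigrams over {M,I,D}, prev-major
const int OFF_BP    = 23;   // 16 ordered base-pair compositions
const int OFF_STACK = 39;   // 36 = 6x6 canonical/wobble helix stackings
const int OFF_HP    = 75;   // 31 hairpin-length bins 0..30 (capped)
const int OFF_BULGE = 106;  // 31 bulge-length bins
const int OFF_INT   = 137;  // 31 internal-loop total-length bins
const int OFF_ASYM  = 168;  // 31 internal-loop asymmetry bins
const int OFF_MULTI = 199;  // multibranch: base, per-branch, per-unpaired
const int OFF_EXT   = 202;  // external: per-branch, per-unpaired
const int NFEAT     = 204;

// state codes used by transition features
const int ST_M = 0, ST_I = 1, ST_D = 2;

inline int matchem_idx(int a, int b) {
  if (a > b) { int t = a; a = b; b = t; }
  static const int base[5] = {0, 0, 4, 7, 9};
  return OFF_MATCH + base[a] + (b - a);
}

inline int insertem_idx(int a) { return OFF_INS + a - 1; }

inline int trans_idx(int prev, int cur) { return OFF_TRANS + prev * 3 + cur; }

inline int bp_idx(int a, int b) { return OFF_BP + (a - 1) * 4 + (b - 1); }

// canonical + wobble ordered pairs: AU,CG,GC,GU,UA,UG -> 0..5, else -1
inline int canon_idx(int a, int b) {
  if (a == 1 && b == 4) return 0;
  if (a == 2 && b == 3) return 1;
  if (a == 3 && b == 2) return 2;
  if (a == 3 && b == 4) return 3;
  if (a == 4 && b == 1) return 4;
  if (a == 4 && b == 3) return 5;
  return -1;
}

inline int cap30(int n) { return n > 30 ? 30 : n; }

inline int hp_idx(int len)    { return OFF_HP    + cap30(len); }
inline int bulge_idx(int len) { return OFF_BULGE + cap30(len); }
inline int int_idx(int len)   { return OFF_INT   + cap30(len); }
inline int asym_idx(int d)    { return OFF_ASYM  + cap30(d); }

const int F_MULTI_BASE = OFF_MULTI + 0;
const int F_MULTI_BRANCH = OFF_MULTI + 1;
const int F_MULTI_UNPAIR = OFF_MULTI + 2;
const int F_EXT_BRANCH = OFF_EXT + 0;
const int F_EXT_UNPAIR = OFF_EXT + 1;

}  // namespace cf

#endif
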