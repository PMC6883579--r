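// Core machinery: 64-bit hashing, minimizer scanning with a sliding-window
// deque, the compact hash table, and the genome-scale collision experiments.
// Everything that touches full 64-bit words lives here; values cross the
// R boundary as 16-character zero-padded hex strings because R's native
// numeric types cannot hold an arbitrary uint64 exactly.
#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <cstring>
#include <deque>
#include <string>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef unsigned __int128 u128;

// ---------------------------------------------------------------------------
// 64-bit helpers

// MurmurHash3 finalization mix; bijective on 64-bit words.
static inline uint64_t fmix64_(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static uint64_t hex2u64(const std::string& h) {
  if (h.empty() || h.size() > 16)
    stop("expected a hex string of 1..16 characters, got '%s'", h.c_str());
  uint64_t x = 0;
  for (char c : h) {
    x <<= 4;
    if (c >= '0' && c <= '9') x |= (uint64_t)(c - '0');
    else if (c >= 'a' && c <= 'f') x |= (uint64_t)(c - 'a' + 10);
    else if (c >= 'A' && c <= 'F') x |= (uint64_t)(c - 'A' + 10);
    else stop("invalid hex character '%c'", c);
  }
  return x;
}

static std::string u64hex(uint64_t x) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export(name = ".fmix64_cpp")]]
CharacterVector fmix64_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++)
    out[i] = u64hex(fmix64_(hex2u64(as<std::string>(x[i]))));
  return out;
}

// ---------------------------------------------------------------------------
// Sequence encoding

static inline int dna_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Reduced protein symbols occupy 'A'..'P' (codes 0..15); anything else is an
// ambiguity marker that breaks k-mers.
static inline int prot_code(char c) {
  return (c >= 'A' && c <= 'P') ? (c - 'A') : -1;
}

// [[Rcpp::export(name = ".encode_window_cpp")]]
List encode_window_cpp(std::string seq, int start, int len) {
  if (len < 0 || len > 31) stop("window length must be in 0..31");
  if (start < 1 || (size_t)(start - 1 + len) > seq.size())
    stop("window [%d, %d] outside sequence of length %d", start,
         start + len - 1, (int)seq.size());
  uint64_t code = 0;
  bool ambiguous = false;
  for (int i = 0; i < len; i++) {
    int c = dna_code(seq[start - 1 + i]);
    if (c < 0) { ambiguous = true; c = 0; }
    code = (code << 2) | (uint64_t)c;
  }
  return List::create(_["code"] = u64hex(code), _["ambiguous"] = ambiguous);
}

// [[Rcpp::export(name = ".revcomp_code_cpp")]]
std::string revcomp_code_cpp(std::string hex, int l) {
  uint64_t code = hex2u64(hex), rc = 0;
  for (int i = 0; i < l; i++) {
    rc = (rc << 2) | (3 - (code & 3));
    code >>= 2;
  }
  return u64hex(rc);
}

// [[Rcpp::export(name = ".canonical_code_cpp")]]
std::string canonical_code_cpp(std::string hex, int l) {
  uint64_t code = hex2u64(hex), c = code, rc = 0;
  for (int i = 0; i < l; i++) {
    rc = (rc << 2) | (3 - (c & 3));
    c >>= 2;
  }
  return u64hex(code < rc ? code : rc);
}

// [[Rcpp::export(name = ".spaced_mask_cpp")]]
std::string spaced_mask_cpp(int l, int s, int bits_per_char) {
  if (l < 1) stop("minimizer length must be >= 1");
  if (s < 0 || 2 * s > l)
    stop("cannot mask %d positions of a %d-character minimizer (need 2s <= l)",
         s, l);
  int b = bits_per_char;
  if (b != 2 && b != 4) stop("bits_per_char must be 2 or 4");
  if (l * b >= 64) stop("minimizer does not fit a 64-bit word");
  uint64_t m = (1ULL << (l * b)) - 1;
  // Position 1 is the rightmost character; mask every other position
  // starting from position 2 until s positions are masked.
  for (int i = 1; i <= s; i++) {
    int p = 2 * i;
    m &= ~(((1ULL << b) - 1) << ((p - 1) * b));
  }
  return u64hex(m);
}

// [[Rcpp::export(name = ".candidate_value_cpp")]]
std::string candidate_value_cpp(std::string code_hex, std::string mask_hex,
                                std::string toggle_hex) {
  return u64hex((hex2u64(code_hex) & hex2u64(mask_hex)) ^ hex2u64(toggle_hex));
}

// [[Rcpp::export(name = ".subsample_threshold_cpp")]]
std::string subsample_threshold_cpp(double f) {
  if (!(f > 0 && f <= 1)) stop("subsample fraction must satisfy 0 < f <= 1");
  if (f == 1) return u64hex(0);
  const long double M = 18446744073709551615.0L;  // 2^64 - 1
  long double v = (1.0L - (long double)f) * M;
  uint64_t lo = (uint64_t)v;
  if (v - (long double)lo >= 0.5L && lo < 0xffffffffffffffffULL) lo++;
  return u64hex(lo);
}

// ---------------------------------------------------------------------------
// Minimizer scan (sliding-window deque)

struct ScanParams {
  int k, l;
  uint64_t mask, toggle;
  bool protein;
};

// Calls emit(kmer_start0, valid, minimizer_value) for every k-mer position.
// A k-mer overlapping an ambiguous character is emitted with valid = false.
// Tie-break within a window: the leftmost minimal candidate wins (candidates
// with values strictly greater than a newcomer are popped from the back, so
// an equal earlier candidate stays in front).
template <class F>
static void scan_sequence(const std::string& seq, const ScanParams& P,
                          F&& emit) {
  const int k = P.k, l = P.l, b = P.protein ? 4 : 2;
  const int L = (int)seq.size();
  if (L < k) return;
  const uint64_t lmask = (1ULL << (uint64_t)(b * l)) - 1;
  uint64_t code = 0, rc = 0;
  int run = 0;  // consecutive valid characters ending at i
  std::deque<std::pair<uint64_t, int> > dq;  // (candidate value, l-mer start)
  for (int i = 0; i < L; i++) {
    int c = P.protein ? prot_code(seq[i]) : dna_code(seq[i]);
    if (c < 0) {
      run = 0;
      dq.clear();
    } else {
      run++;
      code = ((code << b) | (uint64_t)c) & lmask;
      if (!P.protein)
        rc = (rc >> 2) | ((uint64_t)(3 - c) << (uint64_t)(2 * (l - 1)));
      if (run >= l) {
        uint64_t canon = P.protein ? code : (code < rc ? code : rc);
        uint64_t val = (canon & P.mask) ^ P.toggle;
        int start = i - l + 1;
        while (!dq.empty() && dq.back().first > val) dq.pop_back();
        dq.push_back(std::make_pair(val, start));
      }
    }
    int q = i - k + 1;
    if (q >= 0) {
      if (run >= k) {
        while (!dq.empty() && dq.front().second < q) dq.pop_front();
        emit(q, true, dq.front().first);
      } else {
        emit(q, false, (uint64_t)0);
      }
    }
  }
}

static ScanParams make_params(int k, int l, std::string mask_hex,
                              std::string toggle_hex, bool protein) {
  if (l < 1 || l > k) stop("need 1 <= l <= k");
  int maxl = protein ? 15 : 31;
  if (l > maxl)
    stop("l must be <= %d in %s mode", maxl,
         protein ? "protein" : "nucleotide");
  if (k > 63) stop("k must be <= 63");
  ScanParams P;
  P.k = k; P.l = l;
  P.mask = hex2u64(mask_hex);
  P.toggle = hex2u64(toggle_hex);
  P.protein = protein;
  return P;
}

// [[Rcpp::export(name = ".minimizers_cpp")]]
List minimizers_cpp(std::string seq, int k, int l, std::string mask_hex,
                    std::string toggle_hex, bool protein) {
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, protein);
  std::vector<int> pos;
  std::vector<std::string> val;
  scan_sequence(seq, P, [&](int q, bool ok, uint64_t v) {
    if (ok) { pos.push_back(q + 1); val.push_back(u64hex(v)); }
  });
  return List::create(_["pos"] = wrap(pos), _["value"] = wrap(val));
}

// Exact count of distinct minimizer values over a set of sequences.
// [[Rcpp::export(name = ".distinct_minimizers_cpp")]]
double distinct_minimizers_cpp(CharacterVector seqs, int k, int l,
                               std::string mask_hex, std::string toggle_hex,
                               bool protein) {
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, protein);
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    scan_sequence(s, P, [&](int, bool ok, uint64_t v) {
      if (ok) seen.insert(v);
    });
  }
  return (double)seen.size();
}

// |Q| of the mod-F sketch: distinct minimizer values m with
// fmix64(m) mod F < E.  E == F degenerates to the exact distinct count.
// [[Rcpp::export(name = ".capacity_sketch_cpp")]]
double capacity_sketch_cpp(CharacterVector seqs, int k, int l,
                           std::string mask_hex, std::string toggle_hex,
                           bool protein, double E, double F) {
  if (E < 1 || F < E) stop("need 1 <= E <= F");
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, protein);
  uint64_t Ei = (uint64_t)E, Fi = (uint64_t)F;
  std::unordered_set<uint64_t> Q;
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    scan_sequence(s, P, [&](int, bool ok, uint64_t v) {
      if (ok && (fmix64_(v) % Fi) < Ei) Q.insert(v);
    });
  }
  return (double)Q.size();
}

// ---------------------------------------------------------------------------
// Compact hash table

struct CHT {
  uint64_t n;
  int value_bits;
  uint64_t occupied;
  uint64_t probes;  // lookup counter (diagnostics)
  std::vector<uint32_t> cells;

  int key_bits() const { return 32 - value_bits; }
  uint32_t vmask() const { return (uint32_t)((1ULL << value_bits) - 1); }
  // Most significant key_bits of the hash code; a zero code is remapped to 1
  // so that a populated cell is never the all-zero (empty) word.
  uint32_t compact(uint64_t h) const {
    uint32_t c = (uint32_t)(h >> (64 - key_bits()));
    return c == 0 ? 1 : c;
  }
};

static CHT* get_cht(SEXP ptr) {
  XPtr<CHT> p(ptr);
  if (!p) stop("invalid compact hash table pointer");
  return p.get();
}

// [[Rcpp::export(name = ".cht_create_cpp")]]
SEXP cht_create_cpp(double cell_count, int value_bits) {
  if (value_bits < 1 || value_bits > 31) stop("value_bits must be in 1..31");
  if (cell_count < 1) stop("cell_count must be >= 1");
  CHT* t = new CHT();
  t->n = (uint64_t)cell_count;
  t->value_bits = value_bits;
  t->occupied = 0;
  t->probes = 0;
  t->cells.assign(t->n, 0u);
  return XPtr<CHT>(t, true);
}

static uint32_t cht_find_one(CHT* t, uint64_t key) {
  t->probes++;
  uint64_t h = fmix64_(key);
  uint64_t idx = h % t->n;
  uint32_t code = t->compact(h);
  for (uint64_t step = 0; step < t->n; step++) {
    uint32_t cell = t->cells[idx];
    if (cell == 0) return 0;
    if ((cell >> t->value_bits) == code) return cell & t->vmask();
    if (++idx == t->n) idx = 0;
  }
  return 0;
}

static inline int lca_walk(int a, int b, const int* parent, int n_nodes) {
  while (a != b) {
    if (a < b) std::swap(a, b);
    a = parent[a];
    if (a < 1) stop("walked past the root while merging LCA values");
  }
  return a;
}

static void cht_set_lca_one(CHT* t, uint64_t key, int taxon,
                            const int* parent, int n_nodes) {
  if (taxon < 1) stop("taxon must be a positive internal ID");
  if ((uint32_t)taxon > t->vmask())
    stop("taxon %d does not fit in %d value bits", taxon, t->value_bits);
  uint64_t h = fmix64_(key);
  uint64_t idx = h % t->n;
  uint32_t code = t->compact(h);
  for (uint64_t step = 0; step < t->n; step++) {
    uint32_t cell = t->cells[idx];
    if (cell == 0) {
      t->cells[idx] = (code << t->value_bits) | (uint32_t)taxon;
      t->occupied++;
      return;
    }
    if ((cell >> t->value_bits) == code) {
      int cur = (int)(cell & t->vmask());
      int merged = lca_walk(cur, taxon, parent, n_nodes);
      t->cells[idx] = (code << t->value_bits) | (uint32_t)merged;
      return;
    }
    if (++idx == t->n) idx = 0;
  }
  stop("compact hash table is full; rebuild with a larger capacity");
}

// [[Rcpp::export(name = ".cht_find_cpp")]]
IntegerVector cht_find_cpp(SEXP ptr, CharacterVector keys) {
  CHT* t = get_cht(ptr);
  IntegerVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); i++)
    out[i] = (int)cht_find_one(t, hex2u64(as<std::string>(keys[i])));
  return out;
}

// [[Rcpp::export(name = ".cht_set_lca_cpp")]]
void cht_set_lca_cpp(SEXP ptr, CharacterVector keys, IntegerVector taxa,
                     IntegerVector parent) {
  CHT* t = get_cht(ptr);
  if (keys.size() != taxa.size()) stop("keys and taxa lengths differ");
  int n_nodes = parent.size();
  std::vector<int> par(n_nodes + 1, 0);
  for (int i = 0; i < n_nodes; i++) par[i + 1] = parent[i];
  for (R_xlen_t i = 0; i < keys.size(); i++)
    cht_set_lca_one(t, hex2u64(as<std::string>(keys[i])), taxa[i], par.data(),
                    n_nodes);
}

// [[Rcpp::export(name = ".cht_info_cpp")]]
List cht_info_cpp(SEXP ptr) {
  CHT* t = get_cht(ptr);
  return List::create(_["cell_count"] = (double)t->n,
                      _["value_bits"] = t->value_bits,
                      _["key_bits"] = t->key_bits(),
                      _["occupied"] = (double)t->occupied,
                      _["probes"] = (double)t->probes);
}

// [[Rcpp::export(name = ".cht_cells_cpp")]]
NumericVector cht_cells_cpp(SEXP ptr) {
  CHT* t = get_cht(ptr);
  NumericVector out(t->n);
  for (uint64_t i = 0; i < t->n; i++) out[i] = (double)t->cells[i];
  return out;
}

// Probe target of a key: (compact code, 0-based start index).  Used to
// construct adversarial key pairs in tests and documentation.
// [[Rcpp::export(name = ".hash_slot_cpp")]]
List hash_slot_cpp(std::string key_hex, double cell_count, int value_bits) {
  uint64_t h = fmix64_(hex2u64(key_hex));
  uint64_t n = (uint64_t)cell_count;
  int key_bits = 32 - value_bits;
  uint32_t c = (uint32_t)(h >> (64 - key_bits));
  if (c == 0) c = 1;
  return List::create(_["code"] = (double)c, _["index0"] = (double)(h % n));
}

static const char CHT_MAGIC[8] = {'M', 'I', 'N', 'L', 'C', 'A', '0', '1'};

// [[Rcpp::export(name = ".cht_save_cpp")]]
void cht_save_cpp(SEXP ptr, std::string path) {
  CHT* t = get_cht(ptr);
  std::FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  uint64_t n = t->n, occ = t->occupied;
  uint32_t vb = (uint32_t)t->value_bits, reserved = 0;
  bool ok = std::fwrite(CHT_MAGIC, 1, 8, f) == 8 &&
            std::fwrite(&n, 8, 1, f) == 1 && std::fwrite(&occ, 8, 1, f) == 1 &&
            std::fwrite(&vb, 4, 1, f) == 1 &&
            std::fwrite(&reserved, 4, 1, f) == 1 &&
            (t->n == 0 ||
             std::fwrite(t->cells.data(), 4, t->n, f) == t->n);
  std::fclose(f);
  if (!ok) stop("short write while saving table to '%s'", path.c_str());
}

// [[Rcpp::export(name = ".cht_load_cpp")]]
SEXP cht_load_cpp(std::string path) {
  std::FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s' for reading", path.c_str());
  char magic[8];
  uint64_t n = 0, occ = 0;
  uint32_t vb = 0, reserved = 0;
  if (std::fread(magic, 1, 8, f) != 8 ||
      std::memcmp(magic, CHT_MAGIC, 8) != 0) {
    std::fclose(f);
    stop("'%s' is not a compact hash table file (bad magic)", path.c_str());
  }
  if (std::fread(&n, 8, 1, f) != 1 || std::fread(&occ, 8, 1, f) != 1 ||
      std::fread(&vb, 4, 1, f) != 1 || std::fread(&reserved, 4, 1, f) != 1) {
    std::fclose(f);
    stop("truncated header in '%s'", path.c_str());
  }
  if (vb < 1 || vb > 31) {
    std::fclose(f);
    stop("corrupt header in '%s': value_bits = %u", path.c_str(), vb);
  }
  CHT* t = new CHT();
  t->n = n;
  t->value_bits = (int)vb;
  t->occupied = occ;
  t->probes = 0;
  t->cells.assign(n, 0u);
  size_t got = std::fread(t->cells.data(), 4, n, f);
  // any trailing garbage is also an error
  char extra;
  bool trailing = std::fread(&extra, 1, 1, f) == 1;
  std::fclose(f);
  if (got != n || trailing) {
    delete t;
    stop("truncated or oversized cell payload in '%s'", path.c_str());
  }
  return XPtr<CHT>(t, true);
}

// ---------------------------------------------------------------------------
// Database build / classification drivers

// Insert every retained minimizer of each sequence with its taxon, merging
// LCA values.  Consecutive duplicate minimizer values are inserted once
// (idempotent anyway).  v_hex is the hash-subsampling threshold.
// [[Rcpp::export(name = ".build_cht_cpp")]]
void build_cht_cpp(SEXP ptr, CharacterVector seqs, IntegerVector taxa, int k,
                   int l, std::string mask_hex, std::string toggle_hex,
                   bool protein, std::string v_hex, IntegerVector parent) {
  CHT* t = get_cht(ptr);
  if (seqs.size() != taxa.size()) stop("seqs and taxa lengths differ");
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, protein);
  uint64_t v = hex2u64(v_hex);
  int n_nodes = parent.size();
  std::vector<int> par(n_nodes + 1, 0);
  for (int i = 0; i < n_nodes; i++) par[i + 1] = parent[i];
  for (R_xlen_t i = 0; i < seqs.size(); i++) {
    std::string s = as<std::string>(seqs[i]);
    int taxon = taxa[i];
    bool have_prev = false;
    uint64_t prev = 0;
    scan_sequence(s, P, [&](int, bool ok, uint64_t val) {
      if (!ok) { have_prev = false; return; }
      if (have_prev && val == prev) return;
      have_prev = true;
      prev = val;
      if (fmix64_(val) >= v)
        cht_set_lca_one(t, val, taxon, par.data(), n_nodes);
    });
  }
}

// Per-k-mer LCA assignment for one fragment, run-length encoded.
// Taxon codes in the runs: >=1 internal taxon, 0 no hit, -1 ambiguous k-mer.
// A depth-1 minimizer cache avoids re-probing when consecutive k-mers share
// a minimizer; sub-threshold minimizers count as no-hit without a probe.
// [[Rcpp::export(name = ".collect_hits_cpp")]]
List collect_hits_cpp(SEXP ptr, std::string seq, int k, int l,
                      std::string mask_hex, std::string toggle_hex,
                      bool protein, std::string v_hex) {
  CHT* t = get_cht(ptr);
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, protein);
  uint64_t v = hex2u64(v_hex);
  std::vector<int> run_taxa, run_lens;
  int total = 0, lookups = 0;
  bool have_prev = false;
  uint64_t prev = 0;
  int prev_tax = 0;
  auto push = [&](int tax) {
    if (!run_taxa.empty() && run_taxa.back() == tax) {
      run_lens.back()++;
    } else {
      run_taxa.push_back(tax);
      run_lens.push_back(1);
    }
  };
  scan_sequence(seq, P, [&](int, bool ok, uint64_t val) {
    total++;
    if (!ok) {
      have_prev = false;
      push(-1);
      return;
    }
    int tax;
    if (have_prev && val == prev) {
      tax = prev_tax;
    } else {
      if (fmix64_(val) < v) {
        tax = 0;
      } else {
        tax = (int)cht_find_one(t, val);
        lookups++;
      }
      have_prev = true;
      prev = val;
      prev_tax = tax;
    }
    push(tax);
  });
  return List::create(_["run_taxa"] = wrap(run_taxa),
                      _["run_lens"] = wrap(run_lens),
                      _["total_kmers"] = total, _["n_lookups"] = lookups);
}

// ---------------------------------------------------------------------------
// Collision experiments (genome scale)

struct Hash128 {
  size_t operator()(u128 x) const {
    return (size_t)fmix64_((uint64_t)x ^ fmix64_((uint64_t)(x >> 64)));
  }
};

// Distinct canonical k-mers (k <= 63 via 128-bit codes) plus, in lockstep,
// the per-k-mer minimizer values of a sequence.
static void kmer_codes(const std::string& seq, int k,
                       std::vector<u128>& codes, std::vector<char>& valid) {
  const int L = (int)seq.size();
  int nk = L - k + 1;
  if (nk < 0) nk = 0;
  codes.assign(nk, 0);
  valid.assign(nk, 0);
  const u128 kmask = (((u128)1) << (2 * k)) - 1;
  u128 code = 0, rc = 0;
  int run = 0;
  for (int i = 0; i < L; i++) {
    int c = dna_code(seq[i]);
    if (c < 0) {
      run = 0;
    } else {
      run++;
      code = ((code << 2) | (u128)c) & kmask;
      rc = (rc >> 2) | ((u128)(3 - c) << (u128)(2 * (k - 1)));
    }
    int q = i - k + 1;
    if (q >= 0 && run >= k) {
      codes[q] = code < rc ? code : rc;
      valid[q] = 1;
    }
  }
}

// Minimizer collision experiment: over distinct query k-mers, count those
// absent from the reference k-mer set whose minimizer value occurs among the
// reference minimizer values.
// [[Rcpp::export(name = ".minimizer_collision_cpp")]]
List minimizer_collision_cpp(std::string query, std::string ref, int k, int l,
                             std::string mask_hex, std::string toggle_hex) {
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, false);

  std::vector<u128> rcodes;
  std::vector<char> rvalid;
  kmer_codes(ref, k, rcodes, rvalid);
  std::unordered_set<u128, Hash128> ref_kmers;
  ref_kmers.reserve(rcodes.size() * 2);
  for (size_t i = 0; i < rcodes.size(); i++)
    if (rvalid[i]) ref_kmers.insert(rcodes[i]);
  rcodes.clear(); rcodes.shrink_to_fit();

  std::unordered_set<uint64_t> ref_mins;
  scan_sequence(ref, P, [&](int, bool ok, uint64_t v) {
    if (ok) ref_mins.insert(v);
  });

  // query minimizer value per k-mer position
  int nq = (int)query.size() - k + 1;
  if (nq < 0) nq = 0;
  std::vector<uint64_t> qmin(nq, 0);
  std::vector<char> qok(nq, 0);
  scan_sequence(query, P, [&](int q, bool ok, uint64_t v) {
    if (ok) { qmin[q] = v; qok[q] = 1; }
  });

  std::vector<u128> qcodes;
  std::vector<char> qvalid;
  kmer_codes(query, k, qcodes, qvalid);

  std::unordered_set<u128, Hash128> seen;
  seen.reserve(qcodes.size() * 2);
  double distinct = 0, absent = 0, collisions = 0;
  for (int q = 0; q < nq; q++) {
    if (!qvalid[q]) continue;
    if (!seen.insert(qcodes[q]).second) continue;  // already evaluated
    distinct++;
    if (ref_kmers.count(qcodes[q])) continue;
    absent++;
    if (qok[q] && ref_mins.count(qmin[q])) collisions++;
  }
  return List::create(_["distinct_query_kmers"] = distinct,
                      _["absent"] = absent, _["collisions"] = collisions,
                      _["ref_distinct_kmers"] = (double)ref_kmers.size(),
                      _["ref_distinct_minimizers"] = (double)ref_mins.size());
}

// Hash-table collision experiment: populate a CHT from the reference's
// distinct minimizers at the requested load factor and key width, then query
// the distinct query minimizers absent from the true reference set; any
// returned value is a false result.
// [[Rcpp::export(name = ".cht_error_rate_cpp")]]
List cht_error_rate_cpp(std::string query, std::string ref, int k, int l,
                        std::string mask_hex, std::string toggle_hex,
                        double load_factor, int key_bits) {
  if (!(load_factor > 0 && load_factor < 1))
    stop("load factor must be in (0, 1)");
  if (key_bits < 1 || key_bits > 31) stop("key_bits must be in 1..31");
  ScanParams P = make_params(k, l, mask_hex, toggle_hex, false);

  std::unordered_set<uint64_t> ref_mins;
  scan_sequence(ref, P, [&](int, bool ok, uint64_t v) {
    if (ok) ref_mins.insert(v);
  });
  if (ref_mins.empty()) stop("reference sequence yields no minimizers");

  CHT t;
  t.n = (uint64_t)std::ceil((double)ref_mins.size() / load_factor);
  t.value_bits = 32 - key_bits;
  t.occupied = 0;
  t.probes = 0;
  t.cells.assign(t.n, 0u);
  int par[2] = {0, 0};  // single-taxon tree: node 1 is the root
  for (uint64_t m : ref_mins) cht_set_lca_one(&t, m, 1, par, 1);

  std::unordered_set<uint64_t> qmins;
  scan_sequence(query, P, [&](int, bool ok, uint64_t v) {
    if (ok) qmins.insert(v);
  });

  double absent = 0, false_hits = 0;
  for (uint64_t m : qmins) {
    if (ref_mins.count(m)) continue;
    absent++;
    if (cht_find_one(&t, m) != 0) false_hits++;
  }
  double rate = absent > 0 ? 100.0 * false_hits / absent : 0.0;
  return List::create(
      _["query_distinct_minimizers"] = (double)qmins.size(),
      _["absent"] = absent, _["false_hits"] = false_hits,
      _["rate_percent"] = rate, _["cell_count"] = (double)t.n,
      _["occupied"] = (double)t.occupied,
      _["load"] = (double)t.occupied / (double)t.n);
}

// ---------------------------------------------------------------------------
// Translation helpers

// [[Rcpp::export(name = ".revcomp_dna_cpp")]]
std::string revcomp_dna_cpp(std::string seq) {
  std::string out(seq.size(), 'N');
  for (size_t i = 0; i < seq.size(); i++) {
    char c = seq[seq.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break; case 'a': out[i] = 't'; break;
      case 'C': out[i] = 'G'; break; case 'c': out[i] = 'g'; break;
      case 'G': out[i] = 'C'; break; case 'g': out[i] = 'c'; break;
      case 'T': out[i] = 'A'; break; case 't': out[i] = 'a'; break;
      default: out[i] = 'N';
    }
  }
  return out;
}

// Translate one forward frame with a caller-supplied 64-entry codon table
// (index 16*b1 + 4*b2 + b3 with A,C,G,T = 0..3).  Codons containing an
// ambiguous base become '?', which downstream scanning treats as a k-mer
// breaker.  The trailing partial codon is dropped.
// [[Rcpp::export(name = ".translate_frame_cpp")]]
std::string translate_frame_cpp(std::string seq, int offset0,
                                std::string codon_table) {
  if (codon_table.size() != 64) stop("codon table must have 64 entries");
  if (offset0 < 0 || (size_t)offset0 >= seq.size()) return "";
  std::string out;
  out.reserve((seq.size() - offset0) / 3 + 1);
  for (size_t i = offset0; i + 2 < seq.size(); i += 3) {
    int b1 = dna_code(seq[i]), b2 = dna_code(seq[i + 1]),
        b3 = dna_code(seq[i + 2]);
    if (b1 < 0 || b2 < 0 || b3 < 0)
      out.push_back('?');
    else
      out.push_back(codon_table[16 * b1 + 4 * b2 + b3]);
  }
  return out;
}

// Map amino-acid letters onto reduced-alphabet symbols 'A'..'P' using a
// caller-supplied table; letters absent from the table become '?'.
// [[Rcpp::export(name = ".reduce_protein_cpp")]]
std::string reduce_protein_cpp(std::string aa, CharacterVector letters,
                               IntegerVector groups) {
  if (letters.size() != groups.size()) stop("letters and groups differ");
  int table[256];
  for (int i = 0; i < 256; i++) table[i] = -1;
  for (R_xlen_t i = 0; i < letters.size(); i++) {
    std::string L = as<std::string>(letters[i]);
    if (L.size() != 1) stop("alphabet letters must be single characters");
    int g = groups[i];
    if (g < 0 || g > 15) stop("group indices must be in 0..15");
    table[(unsigned char)L[0]] = g;
    table[(unsigned char)std::tolower(L[0])] = g;
  }
  std::string out(aa.size(), '?');
  for (size_t i = 0; i < aa.size(); i++) {
    int g = table[(unsigned char)aa[i]];
    if (g >= 0) out[i] = (char)('A' + g);
  }
  return out;
}
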