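// Codec, hash family, packed table and auxiliary vector internals.

#include "havec.h"

#include <Rcpp.h>

#include <cstdlib>

namespace havec {

// ---------------------------------------------------------------------------
// codec
// ---------------------------------------------------------------------------

int base_code(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

char code_base(int c) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  return bases[c & 3];
}

std::uint64_t encode_kmer(const std::string& s) {
  const std::size_t k = s.size();
  if (k < 1 || k > 32)
    Rcpp::stop("k out of range: k-mer length must be in 1..32, got %d",
               static_cast<int>(k));
  std::uint64_t code = 0;
  for (std::size_t i = 0; i < k; ++i) {
    const int c = base_code(s[i]);
    if (c < 0)
      Rcpp::stop("ambiguous base '%c' in k-mer \"%s\"", s[i], s.c_str());
    code = (code << 2) | static_cast<std::uint64_t>(c);
  }
  return code;
}

std::string decode_kmer(std::uint64_t code, int k) {
  if (k < 1 || k > 32) Rcpp::stop("k out of range: %d", k);
  std::string s(static_cast<std::size_t>(k), 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[static_cast<std::size_t>(i)] = code_base(static_cast<int>(code & 3));
    code >>= 2;
  }
  return s;
}

std::vector<Window> extract_windows(const std::string& read, int k) {
  std::vector<Window> out;
  const std::size_t L = read.size();
  if (k < 1) Rcpp::stop("k out of range: %d", k);
  if (L < static_cast<std::size_t>(k)) return out;
  const std::uint64_t mask =
      (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::uint64_t code = 0;
  int valid = 0;  // number of consecutive valid bases ending at position i
  for (std::size_t i = 0; i < L; ++i) {
    const int c = base_code(read[i]);
    if (c < 0) {
      valid = 0;  // windows overlapping this base are skipped
      continue;
    }
    code = ((code << 2) | static_cast<std::uint64_t>(c)) & mask;
    if (++valid >= k) {
      int next = -1;
      if (i + 1 < L) {
        const int nb = base_code(read[i + 1]);
        if (nb >= 0) next = nb;
      }
      out.push_back(Window{code, i + 1 - static_cast<std::size_t>(k), next});
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// hash family
// ---------------------------------------------------------------------------

std::uint64_t splitmix64(std::uint64_t& state) {
  std::uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

HashFamily HashFamily::make(int h, std::uint64_t master_seed) {
  if (h < 1 || h > HF_MAX)
    Rcpp::stop("hash-function count unsupported: h must be in 1..%d "
               "(index 0 is the free-slot sentinel), got %d", HF_MAX, h);
  HashFamily f;
  f.h = h;
  f.master_seed = master_seed;
  std::uint64_t state = master_seed;
  for (int i = 1; i <= h; ++i) {
    // fold the function index in so function i is determined by (seed, i)
    std::uint64_t s = state ^ (0xD6E8FEB86659FD93ULL * static_cast<std::uint64_t>(i));
    MixParams p;
    p.add = splitmix64(s);
    p.c1 = splitmix64(s) | 1ULL;
    p.c2 = splitmix64(s) | 1ULL;
    p.c3 = splitmix64(s) | 1ULL;
    p.d1 = splitmix64(s);
    p.d2 = splitmix64(s);
    p.d3 = splitmix64(s);
    f.fn.push_back(p);
    splitmix64(state);
  }
  return f;
}

HashFamily HashFamily::make_stipulated(
    int h,
    const std::vector<int>& which,
    const std::vector<std::uint64_t>& codes,
    const std::vector<std::uint64_t>& values) {
  if (h < 1 || h > HF_MAX)
    Rcpp::stop("hash-function count unsupported: h must be in 1..%d", HF_MAX);
  HashFamily f;
  f.h = h;
  f.stipulated = true;
  f.fwd.resize(static_cast<std::size_t>(h));
  f.rev.resize(static_cast<std::size_t>(h));
  for (std::size_t j = 0; j < which.size(); ++j) {
    const int i = which[j];
    if (i < 1 || i > h)
      Rcpp::stop("stipulated table names function %d but h = %d", i, h);
    auto& fwd = f.fwd[static_cast<std::size_t>(i - 1)];
    auto& rev = f.rev[static_cast<std::size_t>(i - 1)];
    auto it = fwd.find(codes[j]);
    if (it != fwd.end() && it->second != values[j])
      Rcpp::stop("conflicting stipulated values for one (function, k-mer) pair");
    auto rit = rev.find(values[j]);
    if (rit != rev.end() && rit->second != codes[j])
      Rcpp::stop("stipulated function %d is not injective: value %llu repeats",
                 i, static_cast<unsigned long long>(values[j]));
    fwd[codes[j]] = values[j];
    rev[values[j]] = codes[j];
  }
  return f;
}

namespace {

inline std::uint64_t width_mask(int k) {
  return (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
}

// shift amount in [w/2, w-1] derived from raw 64-bit d
inline int shift_for(std::uint64_t d, int w) {
  const int lo = w / 2 > 0 ? w / 2 : 1;
  const int span = w - lo;  // >= 1 for w >= 2
  return lo + static_cast<int>(d % static_cast<std::uint64_t>(span));
}

inline std::uint64_t unxorshift(std::uint64_t x, int s, std::uint64_t mask) {
  std::uint64_t r = x;
  for (int done = s; done < 64; done += s) r = x ^ (r >> s);
  return r & mask;
}

inline std::uint64_t odd_inverse(std::uint64_t c) {
  std::uint64_t inv = c;  // Newton iteration, converges in 5 steps for 2^64
  for (int i = 0; i < 5; ++i) inv *= 2 - c * inv;
  return inv;
}

}  // namespace

std::uint64_t HashFamily::hash(int i, std::uint64_t code, int k) const {
  if (i < 1 || i > h) Rcpp::stop("hash function index %d out of range 1..%d", i, h);
  if (stipulated) {
    const auto& m = fwd[static_cast<std::size_t>(i - 1)];
    auto it = m.find(code);
    if (it == m.end())
      Rcpp::stop("unstipulated hash query: function %d, k-mer %s", i,
                 decode_kmer(code, k).c_str());
    return it->second;
  }
  const std::uint64_t mask = width_mask(k);
  const int w = 2 * k;
  const MixParams& p = fn[static_cast<std::size_t>(i - 1)];
  std::uint64_t x = (code + p.add) & mask;
  x = (x * ((p.c1 & mask) | 1ULL)) & mask;
  x ^= x >> shift_for(p.d1, w);
  x = (x * ((p.c2 & mask) | 1ULL)) & mask;
  x ^= x >> shift_for(p.d2, w);
  x = (x * ((p.c3 & mask) | 1ULL)) & mask;
  x ^= x >> shift_for(p.d3, w);
  return x;
}

std::uint64_t HashFamily::invert(int i, std::uint64_t value, int k) const {
  if (i < 1 || i > h) Rcpp::stop("hash function index %d out of range 1..%d", i, h);
  if (stipulated) {
    const auto& m = rev[static_cast<std::size_t>(i - 1)];
    auto it = m.find(value);
    if (it == m.end())
      Rcpp::stop("not invertible: value %llu was never stipulated for function %d",
                 static_cast<unsigned long long>(value), i);
    return it->second;
  }
  const std::uint64_t mask = width_mask(k);
  const int w = 2 * k;
  const MixParams& p = fn[static_cast<std::size_t>(i - 1)];
  std::uint64_t x = value & mask;
  x = unxorshift(x, shift_for(p.d3, w), mask);
  x = (x * odd_inverse((p.c3 & mask) | 1ULL)) & mask;
  x = unxorshift(x, shift_for(p.d2, w), mask);
  x = (x * odd_inverse((p.c2 & mask) | 1ULL)) & mask;
  x = unxorshift(x, shift_for(p.d1, w), mask);
  x = (x * odd_inverse((p.c1 & mask) | 1ULL)) & mask;
  return (x - p.add) & mask;
}

// ---------------------------------------------------------------------------
// packed table
// ---------------------------------------------------------------------------

void pack_entry(const TableEntry& e, int width, std::uint8_t* out) {
  if (e.quotient > QUOTIENT_MAX) Rcpp::stop("quotient overflow: %llu needs more than 33 bits",
                                            static_cast<unsigned long long>(e.quotient));
  if (e.hf > HF_MAX) Rcpp::stop("hash function index %d exceeds 3 bits", e.hf);
  if (e.bits > 15) Rcpp::stop("neighbour mask %d exceeds 4 bits", e.bits);
  const std::uint64_t word =
      (static_cast<std::uint64_t>(e.bits) << 36) |
      (static_cast<std::uint64_t>(e.hf) << 33) | e.quotient;
  for (int j = 0; j < 5; ++j) out[j] = static_cast<std::uint8_t>((word >> (8 * j)) & 0xFF);
  if (width == 6) out[5] = e.count;
}

TableEntry unpack_entry(const std::uint8_t* in, int width) {
  std::uint64_t word = 0;
  for (int j = 4; j >= 0; --j) word = (word << 8) | in[j];
  TableEntry e;
  e.bits = static_cast<std::uint8_t>((word >> 36) & 0xF);
  e.hf = static_cast<std::uint8_t>((word >> 33) & 0x7);
  e.quotient = word & QUOTIENT_MAX;
  e.count = (width == 6) ? in[5] : 0;
  return e;
}

PackedTable::PackedTable(std::uint64_t M, int width) : M(M), width(width) {
  if (M < 1) Rcpp::stop("invalid table size: M must be >= 1");
  if (width != 5 && width != 6) Rcpp::stop("entry width must be 5 or 6 bytes");
  const std::uint64_t n_chunks = (M + CHUNK_ENTRIES - 1) / CHUNK_ENTRIES;
  chunks_.assign(static_cast<std::size_t>(n_chunks), nullptr);
}

PackedTable::~PackedTable() {
  for (auto* c : chunks_)
    if (c) std::free(c);
}

std::uint64_t PackedTable::chunk_bytes(std::size_t c) const {
  const std::uint64_t first = static_cast<std::uint64_t>(c) * CHUNK_ENTRIES;
  const std::uint64_t n = (M - first < CHUNK_ENTRIES) ? (M - first) : CHUNK_ENTRIES;
  return n * static_cast<std::uint64_t>(width);
}

std::uint8_t* PackedTable::slot(std::uint64_t index, bool create) {
  const std::size_t c = static_cast<std::size_t>(index / CHUNK_ENTRIES);
  if (!chunks_[c]) {
    if (!create) return nullptr;
    chunks_[c] = static_cast<std::uint8_t*>(std::calloc(chunk_bytes(c), 1));
    if (!chunks_[c]) Rcpp::stop("table segment allocation failed");
  }
  return chunks_[c] + (index % CHUNK_ENTRIES) * static_cast<std::uint64_t>(width);
}

const std::uint8_t* PackedTable::slot_ro(std::uint64_t index) const {
  const std::size_t c = static_cast<std::size_t>(index / CHUNK_ENTRIES);
  if (!chunks_[c]) return nullptr;
  return chunks_[c] + (index % CHUNK_ENTRIES) * static_cast<std::uint64_t>(width);
}

TableEntry PackedTable::read(std::uint64_t index) const {
  if (index >= M) Rcpp::stop("table index %llu out of range [0, %llu)",
                             static_cast<unsigned long long>(index),
                             static_cast<unsigned long long>(M));
  const std::uint8_t* p = slot_ro(index);
  if (!p) return TableEntry{};  // untouched segment: free entry
  return unpack_entry(p, width);
}

void PackedTable::write(std::uint64_t index, const TableEntry& e) {
  if (index >= M) Rcpp::stop("table index %llu out of range [0, %llu)",
                             static_cast<unsigned long long>(index),
                             static_cast<unsigned long long>(M));
  pack_entry(e, width, slot(index, true));
}

void PackedTable::or_bit(std::uint64_t index, int base) {
  TableEntry e = read(index);
  if (e.hf == 0) Rcpp::stop("update of free entry at index %llu",
                            static_cast<unsigned long long>(index));
  e.bits |= static_cast<std::uint8_t>(1 << (3 - base));  // bit3=A .. bit0=T
  write(index, e);
}

void PackedTable::bump_count(std::uint64_t index) {
  if (width != 6) Rcpp::stop("counts unavailable: table is in 5-byte mode");
  TableEntry e = read(index);
  if (e.hf == 0) Rcpp::stop("update of free entry at index %llu",
                            static_cast<unsigned long long>(index));
  if (e.count < 255) e.count++;
  write(index, e);
}

void PackedTable::copy_out(std::uint8_t* dst) const {
  for (std::size_t c = 0; c < chunks_.size(); ++c) {
    const std::uint64_t nb = chunk_bytes(c);
    const std::uint64_t off = static_cast<std::uint64_t>(c) * CHUNK_ENTRIES *
                              static_cast<std::uint64_t>(width);
    if (chunks_[c])
      std::memcpy(dst + off, chunks_[c], nb);
    else
      std::memset(dst + off, 0, nb);
  }
}

void PackedTable::copy_in(const std::uint8_t* src) {
  for (std::size_t c = 0; c < chunks_.size(); ++c) {
    const std::uint64_t nb = chunk_bytes(c);
    const std::uint64_t off = static_cast<std::uint64_t>(c) * CHUNK_ENTRIES *
                              static_cast<std::uint64_t>(width);
    bool any = false;
    for (std::uint64_t j = 0; j < nb; ++j)
      if (src[off + j]) { any = true; break; }
    if (!any) continue;
    if (!chunks_[c]) {
      chunks_[c] = static_cast<std::uint8_t*>(std::calloc(nb, 1));
      if (!chunks_[c]) Rcpp::stop("table segment allocation failed");
    }
    std::memcpy(chunks_[c], src + off, nb);
  }
}

// ---------------------------------------------------------------------------
// auxiliary vector
// ---------------------------------------------------------------------------

AuxRecord* AuxVector::insert(std::uint64_t ht_index, const AuxRecord& rec,
                             bool* created) {
  auto& bucket = buckets[static_cast<std::size_t>(ht_index % V)];
  AuxSublist* sub = nullptr;
  for (auto& s : bucket)
    if (s.ht_index == ht_index) { sub = &s; break; }
  if (!sub) {
    bucket.push_back(AuxSublist{ht_index, {}});
    sub = &bucket.back();
  }
  for (auto& r : sub->records)
    if (r.quotient == rec.quotient) {
      if (created) *created = false;
      return &r;  // caller updates the existing record
    }
  if (rec.quotient > QUOTIENT_MAX)
    Rcpp::stop("quotient overflow: %llu needs more than 33 bits",
               static_cast<unsigned long long>(rec.quotient));
  sub->records.push_back(rec);
  ++n_records;
  if (created) *created = true;
  return &sub->records.back();
}

AuxRecord* AuxVector::lookup(std::uint64_t ht_index, std::uint64_t quotient) {
  auto& bucket = buckets[static_cast<std::size_t>(ht_index % V)];
  for (auto& s : bucket)
    if (s.ht_index == ht_index) {
      for (auto& r : s.records)
        if (r.quotient == quotient) return &r;
      return nullptr;
    }
  return nullptr;
}

const AuxRecord* AuxVector::lookup(std::uint64_t ht_index,
                                   std::uint64_t quotient) const {
  return const_cast<AuxVector*>(this)->lookup(ht_index, quotient);
}

void AuxVector::stats(std::uint64_t* total, std::uint64_t* max_per_index,
                      std::uint64_t* max_per_bucket) const {
  *total = 0; *max_per_index = 0; *max_per_bucket = 0;
  for (const auto& bucket : buckets) {
    if (bucket.size() > *max_per_bucket) *max_per_bucket = bucket.size();
    for (const auto& s : bucket) {
      *total += s.records.size();
      if (s.records.size() > *max_per_index) *max_per_index = s.records.size();
    }
  }
}

std::uint64_t AuxVector::payload_bytes(bool counts) const {
  // measured: level-1 slots + (ht_index, record count) per sublist + records
  std::uint64_t bytes = V * 8;
  const std::uint64_t rec_bytes = 8 + 1 + 1 + (counts ? 1 : 0);
  for (const auto& bucket : buckets)
    for (const auto& s : bucket) bytes += 16 + s.records.size() * rec_bytes;
  return bytes;
}

}  // namespace havec
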