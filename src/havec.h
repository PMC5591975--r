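#ifndef HAVEC_H
#define HAVEC_H

#include <cstdint>
#include <cstring>
#include <memory>
#include <string>
#include <unordered_map>
#include <utility>
#include <vector>

namespace havec {

// ---------------------------------------------------------------------------
// k-mer codec: 2 bits per base, A=0 C=1 G=2 T=3, first base in the most
// significant position (big-endian base-4 packing).
// ---------------------------------------------------------------------------

int base_code(char b);               // 0..3, or -1 for non-ACGT
char code_base(int c);
std::uint64_t encode_kmer(const std::string& s);  // |s| must be 1..32, ACGT
std::string decode_kmer(std::uint64_t code, int k);

// One sliding window of a read: the k-mer code, the 0-based start position,
// and the immediately following base (0..3, or -1 when none / ambiguous).
struct Window {
  std::uint64_t code;
  std::size_t pos;
  int next;
};

// Windows containing a non-ACGT symbol are skipped entirely; a following
// non-ACGT base is reported as "none". Shared by the graph builder and the
// brute-force oracle so the skip policy cannot diverge.
std::vector<Window> extract_windows(const std::string& read, int k);

// ---------------------------------------------------------------------------
// Hash family: h invertible mixing permutations of the 2k-bit code space.
// Function indices are 1-based; index 0 is the free-slot sentinel, so at
// most 7 functions are usable within the 3-bit field.
// ---------------------------------------------------------------------------

constexpr int HF_MAX = 7;
constexpr std::uint64_t QUOTIENT_BITS = 33;
constexpr std::uint64_t QUOTIENT_MAX = (1ULL << QUOTIENT_BITS) - 1;

struct MixParams {
  std::uint64_t add, c1, c2, c3;  // odd multipliers (after |1), additive
  std::uint64_t d1, d2, d3;       // raw values the shifts derive from
};

class HashFamily {
 public:
  int h = 0;
  bool stipulated = false;
  std::uint64_t master_seed = 0;
  std::vector<MixParams> fn;  // size h when !stipulated
  // stipulated: per-function forward (code -> value) and reverse maps
  std::vector<std::unordered_map<std::uint64_t, std::uint64_t>> fwd, rev;

  static HashFamily make(int h, std::uint64_t master_seed);
  static HashFamily make_stipulated(
      int h,
      const std::vector<int>& which,
      const std::vector<std::uint64_t>& codes,
      const std::vector<std::uint64_t>& values);

  // i is 1-based; k gives the width (2k bits) of the permutation domain.
  std::uint64_t hash(int i, std::uint64_t code, int k) const;
  std::uint64_t invert(int i, std::uint64_t value, int k) const;
  bool invertible() const { return !stipulated || !rev.empty(); }
};

std::uint64_t splitmix64(std::uint64_t& state);

// ---------------------------------------------------------------------------
// Packed table: M entries of 40 bits (5-byte mode) or 48 bits (6-byte mode,
// trailing saturating count byte). 40-bit word layout, most significant
// first: neighbour_bits(4) | hf_index(3) | quotient(33). Words are laid out
// little-endian in the backing bytes. Storage is split into zero-filled
// segments allocated on first write, so a sparsely occupied giant table
// only pays for the pages it touches.
// ---------------------------------------------------------------------------

struct TableEntry {
  std::uint8_t bits = 0;      // neighbour mask: bit3=A bit2=C bit1=G bit0=T
  std::uint8_t hf = 0;        // 0 = free
  std::uint64_t quotient = 0;
  std::uint8_t count = 0;     // 6-byte mode only
};

void pack_entry(const TableEntry& e, int width, std::uint8_t* out);
TableEntry unpack_entry(const std::uint8_t* in, int width);

class PackedTable {
 public:
  static constexpr std::uint64_t CHUNK_ENTRIES = 1ULL << 20;

  std::uint64_t M = 0;
  int width = 5;  // bytes per entry: 5 or 6

  PackedTable(std::uint64_t M, int width);
  ~PackedTable();
  PackedTable(const PackedTable&) = delete;
  PackedTable& operator=(const PackedTable&) = delete;

  TableEntry read(std::uint64_t index) const;
  void write(std::uint64_t index, const TableEntry& e);
  void or_bit(std::uint64_t index, int base);   // entry must be occupied
  void bump_count(std::uint64_t index);         // 6-byte mode only
  std::uint64_t nbytes() const { return M * static_cast<std::uint64_t>(width); }

  // raw access for serialization (reads zeros where no chunk exists)
  void copy_out(std::uint8_t* dst) const;
  void copy_in(const std::uint8_t* src);

 private:
  std::vector<std::uint8_t*> chunks_;
  std::uint64_t chunk_bytes(std::size_t c) const;
  std::uint8_t* slot(std::uint64_t index, bool create);
  const std::uint8_t* slot_ro(std::uint64_t index) const;
};

// ---------------------------------------------------------------------------
// Auxiliary vector: level 1 = V buckets; level 2 = list of collided hash
// table indices within a bucket; level 3 = list of collided k-mer records
// for one table index.
// ---------------------------------------------------------------------------

struct AuxRecord {
  std::uint64_t quotient = 0;
  std::uint8_t hf = 0;
  std::uint8_t bits = 0;
  std::uint8_t count = 0;
};

struct AuxSublist {
  std::uint64_t ht_index = 0;
  std::vector<AuxRecord> records;
};

class AuxVector {
 public:
  std::uint64_t V = 0;
  std::vector<std::vector<AuxSublist>> buckets;
  std::uint64_t n_records = 0;

  explicit AuxVector(std::uint64_t V) : V(V), buckets(V) {}

  // Returns the record with rec.quotient under ht_index, inserting rec if
  // absent; *created reports whether a new record was appended.
  AuxRecord* insert(std::uint64_t ht_index, const AuxRecord& rec, bool* created);
  AuxRecord* lookup(std::uint64_t ht_index, std::uint64_t quotient);
  const AuxRecord* lookup(std::uint64_t ht_index, std::uint64_t quotient) const;

  void stats(std::uint64_t* total, std::uint64_t* max_per_index,
             std::uint64_t* max_per_bucket) const;
  std::uint64_t payload_bytes(bool counts) const;
};

// ---------------------------------------------------------------------------
// The graph
// ---------------------------------------------------------------------------

enum class LocKind { absent = 0, table = 1, vector = 2 };

struct Location {
  LocKind kind = LocKind::absent;
  std::uint64_t index = 0;     // table slot, or ht_index for vector hits
  std::uint64_t bucket = 0;    // vector hits only
  std::size_t pos = 0;         // record position in the level-3 list
  int hf = 0;                  // hash function that placed / found it
};

std::uint64_t min_table_size(int k);

struct BuildReport {
  std::uint64_t reads = 0, observations = 0, skipped_windows = 0;
};

class HavecGraph {
 public:
  int k = 0, h = 0;
  std::uint64_t M = 0, V = 0;
  bool counts = false;  // 6-byte mode
  std::shared_ptr<HashFamily> fam;
  std::shared_ptr<PackedTable> table;
  std::shared_ptr<AuxVector> aux;
  std::uint64_t n_reads = 0, n_observations = 0;
  std::uint64_t table_kmers = 0, vector_kmers = 0;

  HavecGraph(int k, std::uint64_t M, int h, std::uint64_t V, bool counts,
             std::shared_ptr<HashFamily> fam);

  Location locate(std::uint64_t code) const;
  Location insert_observation(std::uint64_t code, int next_base);
  BuildReport build(const std::vector<std::string>& reads);

  // cutoff < 2 means "no cutoff"; cutoff >= 2 requires counts mode.
  bool contains(std::uint64_t code, int cutoff) const;
  std::uint8_t neighbour_bits(const Location& loc) const;
  std::uint32_t count_at(const Location& loc) const;
  std::vector<std::uint64_t> successors(std::uint64_t code, int cutoff) const;
  std::vector<std::uint64_t> predecessors(std::uint64_t code, int cutoff) const;
  void enumerate(std::vector<std::uint64_t>* codes,
                 std::vector<std::uint8_t>* bits,
                 std::vector<std::uint8_t>* cnts) const;

  std::vector<std::uint8_t> serialize() const;
  static std::unique_ptr<HavecGraph> deserialize(const std::uint8_t* buf,
                                                 std::size_t len);
};

// ---------------------------------------------------------------------------
// Brute-force oracle: plain map from k-mer code to observed successor set
// and multiplicity. No HaVec hashing involved.
// ---------------------------------------------------------------------------

struct OracleEntry {
  std::uint8_t bits = 0;
  std::uint64_t count = 0;
};

class ExactOracle {
 public:
  int k = 0;
  std::unordered_map<std::uint64_t, OracleEntry> map;

  static ExactOracle build(const std::vector<std::string>& reads, int k);
};

// handle wrappers so R external pointers can share C++ ownership
struct FamilyHandle { std::shared_ptr<HashFamily> p; };
struct TableHandle { std::shared_ptr<PackedTable> p; };
struct AuxHandle { std::shared_ptr<AuxVector> p; };
struct OracleHandle { std::shared_ptr<ExactOracle> p; };

}  // namespace havec

#endif  // HAVEC_H
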