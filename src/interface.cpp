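// R-facing wrappers. 64-bit quantities (k-mer codes, hash values) cross the
// boundary as decimal strings so k = 27..32 stays exact beyond double
// precision; table sizes, quotients (< 2^33) and counts travel as doubles.

#include "havec.h"

#include <Rcpp.h>

#include <cstdlib>

using namespace Rcpp;
using namespace havec;

namespace {

std::uint64_t parse_u64(const std::string& s) {
  if (s.empty()) stop("empty string where an unsigned integer was expected");
  std::uint64_t v = 0;
  for (char c : s) {
    if (c < '0' || c > '9')
      stop("not a valid unsigned 64-bit integer: \"%s\"", s.c_str());
    const std::uint64_t d = static_cast<std::uint64_t>(c - '0');
    if (v > (~0ULL - d) / 10)
      stop("unsigned integer overflow: \"%s\"", s.c_str());
    v = v * 10 + d;
  }
  return v;
}

std::string format_u64(std::uint64_t v) {
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", static_cast<unsigned long long>(v));
  return std::string(buf);
}

std::uint64_t size_from_double(double x, const char* what) {
  if (ISNAN(x) || x < 0 || x != std::floor(x) || x > 9007199254740992.0)
    stop("%s must be a non-negative integer-valued number, got %g", what, x);
  return static_cast<std::uint64_t>(x);
}

std::string mask_to_bases(std::uint8_t mask) {
  std::string s;
  for (int b = 0; b < 4; ++b)
    if (mask & (1 << (3 - b))) s.push_back(code_base(b));
  return s;
}

std::uint8_t bases_to_mask(const std::string& bases) {
  std::uint8_t mask = 0;
  for (char c : bases) {
    const int b = base_code(c);
    if (b < 0) stop("ambiguous base '%c' in neighbour set \"%s\"", c, bases.c_str());
    mask |= static_cast<std::uint8_t>(1 << (3 - b));
  }
  return mask;
}

std::shared_ptr<HashFamily> family_of(SEXP fam) {
  XPtr<FamilyHandle> p(fam);
  if (!p->p) stop("invalid hash family handle");
  return p->p;
}

HavecGraph* graph_of(SEXP g) {
  XPtr<HavecGraph> p(g);
  return p.get();
}

List location_list(const Location& loc) {
  std::string kind = "absent";
  if (loc.kind == LocKind::table) kind = "table";
  if (loc.kind == LocKind::vector) kind = "vector";
  return List::create(
      _["kind"] = kind,
      _["index"] = loc.kind == LocKind::table
                       ? NumericVector::create(static_cast<double>(loc.index))
                       : NumericVector::create(NA_REAL),
      _["bucket"] = loc.kind == LocKind::vector
                        ? NumericVector::create(static_cast<double>(loc.bucket))
                        : NumericVector::create(NA_REAL),
      _["ht_index"] = loc.kind == LocKind::vector
                          ? NumericVector::create(static_cast<double>(loc.index))
                          : NumericVector::create(NA_REAL),
      _["pos"] = loc.kind == LocKind::vector
                     ? NumericVector::create(static_cast<double>(loc.pos))
                     : NumericVector::create(NA_REAL),
      _["hf"] = loc.kind == LocKind::absent
                    ? IntegerVector::create(NA_INTEGER)
                    : IntegerVector::create(loc.hf));
}

}  // namespace

// ---------------------------------------------------------------------------
// codec
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_encode_bases(CharacterVector bases) {
  IntegerVector out(bases.size());
  for (R_xlen_t i = 0; i < bases.size(); ++i) {
    const std::string b = as<std::string>(bases[i]);
    if (b.size() != 1) stop("ambiguous base: \"%s\" is not a single nucleotide", b.c_str());
    const int c = base_code(b[0]);
    if (c < 0) stop("ambiguous base '%c'", b[0]);
    out[i] = c;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_encode_kmers(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    out[i] = format_u64(encode_kmer(as<std::string>(kmers[i])));
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_kmers(CharacterVector codes, int k) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    const std::uint64_t code = parse_u64(as<std::string>(codes[i]));
    if (k < 32 && code >= (1ULL << (2 * k)))
      stop("code %s does not fit %d bases", as<std::string>(codes[i]).c_str(), k);
    out[i] = decode_kmer(code, k);
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_extract_kmers(std::string read, int k) {
  if (k > 32) stop("k out of range: %d (must be 1..32)", k);
  const std::vector<Window> ws = extract_windows(read, k);
  CharacterVector kmer(ws.size());
  NumericVector pos(ws.size());
  CharacterVector next(ws.size());
  for (std::size_t i = 0; i < ws.size(); ++i) {
    kmer[i] = decode_kmer(ws[i].code, k);
    pos[i] = static_cast<double>(ws[i].pos) + 1;  // 1-based read position
    if (ws[i].next >= 0)
      next[i] = std::string(1, code_base(ws[i].next));
    else
      next[i] = NA_STRING;
  }
  return DataFrame::create(_["pos"] = pos, _["kmer"] = kmer,
                           _["next_base"] = next,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_successor_kmers(std::string kmer, std::string bases) {
  const std::uint64_t code = encode_kmer(kmer);
  const int k = static_cast<int>(kmer.size());
  const std::uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const std::uint8_t bits = bases_to_mask(bases);
  std::vector<std::string> out;
  for (int b = 0; b < 4; ++b)
    if (bits & (1 << (3 - b)))
      out.push_back(decode_kmer(((code << 2) | static_cast<std::uint64_t>(b)) & mask, k));
  return wrap(out);
}

// ---------------------------------------------------------------------------
// hash family
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_hash_family(int h, double seed) {
  auto handle = new FamilyHandle{std::make_shared<HashFamily>(
      HashFamily::make(h, size_from_double(seed, "seed")))};
  return XPtr<FamilyHandle>(handle, true);
}

// [[Rcpp::export]]
SEXP cpp_stipulated_family(int h, IntegerVector fun, CharacterVector kmers,
                           CharacterVector values) {
  if (fun.size() != kmers.size() || fun.size() != values.size())
    stop("fun, kmer and value columns must have equal length");
  std::vector<int> which(fun.begin(), fun.end());
  std::vector<std::uint64_t> codes, vals;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    codes.push_back(encode_kmer(as<std::string>(kmers[i])));
    vals.push_back(parse_u64(as<std::string>(values[i])));
  }
  auto handle = new FamilyHandle{std::make_shared<HashFamily>(
      HashFamily::make_stipulated(h, which, codes, vals))};
  return XPtr<FamilyHandle>(handle, true);
}

// [[Rcpp::export]]
List cpp_family_info(SEXP fam) {
  auto f = family_of(fam);
  return List::create(_["h"] = f->h, _["stipulated"] = f->stipulated,
                      _["seed"] = static_cast<double>(f->master_seed));
}

// [[Rcpp::export]]
CharacterVector cpp_hash_values(SEXP fam, int i, CharacterVector kmers) {
  auto f = family_of(fam);
  CharacterVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const std::string s = as<std::string>(kmers[j]);
    out[j] = format_u64(f->hash(i, encode_kmer(s), static_cast<int>(s.size())));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_hash_invert(SEXP fam, int i, CharacterVector values, int k) {
  auto f = family_of(fam);
  CharacterVector out(values.size());
  for (R_xlen_t j = 0; j < values.size(); ++j)
    out[j] = decode_kmer(f->invert(i, parse_u64(as<std::string>(values[j])), k), k);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_index_quotient(CharacterVector values, double M) {
  const std::uint64_t m = size_from_double(M, "table size M");
  if (m < 1) stop("invalid table size: M must be >= 1");
  NumericVector index(values.size()), quotient(values.size());
  for (R_xlen_t j = 0; j < values.size(); ++j) {
    const std::uint64_t v = parse_u64(as<std::string>(values[j]));
    index[j] = static_cast<double>(v % m);
    quotient[j] = static_cast<double>(v / m);
  }
  return DataFrame::create(_["index"] = index, _["quotient"] = quotient);
}

// exhaustive 64-bit reconstruction check, beyond double precision
// [[Rcpp::export]]
bool cpp_index_quotient_roundtrip(int n, double seed) {
  std::uint64_t state = size_from_double(seed, "seed");
  for (int j = 0; j < n; ++j) {
    const std::uint64_t v = splitmix64(state);
    std::uint64_t m = splitmix64(state) >> (splitmix64(state) % 40);
    if (m == 0) m = 1;
    if (v / m * m + v % m != v) return false;
  }
  return true;
}

// ---------------------------------------------------------------------------
// packed table
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_packed_table(double M, int bytes) {
  auto handle = new TableHandle{std::make_shared<PackedTable>(
      size_from_double(M, "table size M"), bytes)};
  return XPtr<TableHandle>(handle, true);
}

// [[Rcpp::export]]
SEXP cpp_table_from_graph(SEXP g) {
  auto handle = new TableHandle{graph_of(g)->table};
  return XPtr<TableHandle>(handle, true);
}

// [[Rcpp::export]]
List cpp_table_info(SEXP t) {
  XPtr<TableHandle> p(t);
  return List::create(_["M"] = static_cast<double>(p->p->M),
                      _["bytes_per_entry"] = p->p->width,
                      _["nbytes"] = static_cast<double>(p->p->nbytes()));
}

// [[Rcpp::export]]
List cpp_table_read(SEXP t, double index) {
  XPtr<TableHandle> p(t);
  const TableEntry e = p->p->read(size_from_double(index, "index"));
  return List::create(_["quotient"] = static_cast<double>(e.quotient),
                      _["hf"] = static_cast<int>(e.hf),
                      _["neighbours"] = mask_to_bases(e.bits),
                      _["count"] = p->p->width == 6 ? IntegerVector::create(e.count)
                                                    : IntegerVector::create(NA_INTEGER));
}

// [[Rcpp::export]]
void cpp_table_write(SEXP t, double index, double quotient, int hf,
                     std::string neighbours, int count) {
  XPtr<TableHandle> p(t);
  TableEntry e;
  e.quotient = size_from_double(quotient, "quotient");
  if (hf < 0 || hf > HF_MAX) stop("hash function index %d out of range 0..%d", hf, HF_MAX);
  e.hf = static_cast<std::uint8_t>(hf);
  e.bits = bases_to_mask(neighbours);
  if (count < 0 || count > 255) stop("count %d out of range 0..255", count);
  e.count = static_cast<std::uint8_t>(count);
  p->p->write(size_from_double(index, "index"), e);
}

// [[Rcpp::export]]
void cpp_table_or(SEXP t, double index, std::string base) {
  XPtr<TableHandle> p(t);
  if (base.size() != 1 || base_code(base[0]) < 0)
    stop("ambiguous base \"%s\"", base.c_str());
  p->p->or_bit(size_from_double(index, "index"), base_code(base[0]));
}

// [[Rcpp::export]]
void cpp_table_bump(SEXP t, double index) {
  XPtr<TableHandle> p(t);
  p->p->bump_count(size_from_double(index, "index"));
}

// [[Rcpp::export]]
RawVector cpp_pack_entry(double quotient, int hf, std::string neighbours,
                         int count, int bytes) {
  TableEntry e;
  e.quotient = size_from_double(quotient, "quotient");
  if (hf < 0 || hf > HF_MAX) stop("hash function index %d out of range 0..%d", hf, HF_MAX);
  e.hf = static_cast<std::uint8_t>(hf);
  e.bits = bases_to_mask(neighbours);
  if (count < 0 || count > 255) stop("count %d out of range 0..255", count);
  e.count = static_cast<std::uint8_t>(count);
  RawVector out(bytes);
  pack_entry(e, bytes, reinterpret_cast<std::uint8_t*>(RAW(out)));
  return out;
}

// [[Rcpp::export]]
List cpp_unpack_entry(RawVector raw, int bytes) {
  if (raw.size() != bytes) stop("expected %d bytes, got %d", bytes, (int)raw.size());
  const TableEntry e = unpack_entry(reinterpret_cast<const std::uint8_t*>(RAW(raw)), bytes);
  return List::create(_["quotient"] = static_cast<double>(e.quotient),
                      _["hf"] = static_cast<int>(e.hf),
                      _["neighbours"] = mask_to_bases(e.bits),
                      _["count"] = bytes == 6 ? IntegerVector::create(e.count)
                                              : IntegerVector::create(NA_INTEGER));
}

// ---------------------------------------------------------------------------
// auxiliary vector
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_aux_new(double V) {
  const std::uint64_t v = size_from_double(V, "vector size V");
  if (v < 1) stop("level-1 vector size V must be >= 1");
  auto handle = new AuxHandle{std::make_shared<AuxVector>(v)};
  return XPtr<AuxHandle>(handle, true);
}

// [[Rcpp::export]]
SEXP cpp_aux_from_graph(SEXP g) {
  auto handle = new AuxHandle{graph_of(g)->aux};
  return XPtr<AuxHandle>(handle, true);
}

// [[Rcpp::export]]
bool cpp_aux_insert(SEXP a, double ht_index, double quotient, int hf,
                    std::string neighbours, int count) {
  XPtr<AuxHandle> p(a);
  AuxRecord rec;
  rec.quotient = size_from_double(quotient, "quotient");
  rec.hf = static_cast<std::uint8_t>(hf);
  rec.bits = bases_to_mask(neighbours);
  rec.count = static_cast<std::uint8_t>(count);
  bool created = false;
  p->p->insert(size_from_double(ht_index, "ht_index"), rec, &created);
  return created;
}

// [[Rcpp::export]]
SEXP cpp_aux_lookup(SEXP a, double ht_index, double quotient) {
  XPtr<AuxHandle> p(a);
  const AuxRecord* r = p->p->lookup(size_from_double(ht_index, "ht_index"),
                                    size_from_double(quotient, "quotient"));
  if (!r) return R_NilValue;
  return List::create(_["quotient"] = static_cast<double>(r->quotient),
                      _["hf"] = static_cast<int>(r->hf),
                      _["neighbours"] = mask_to_bases(r->bits),
                      _["count"] = static_cast<int>(r->count));
}

// [[Rcpp::export]]
List cpp_aux_stats(SEXP a) {
  XPtr<AuxHandle> p(a);
  std::uint64_t total, per_index, per_bucket;
  p->p->stats(&total, &per_index, &per_bucket);
  return List::create(_["V"] = static_cast<double>(p->p->V),
                      _["records"] = static_cast<double>(total),
                      _["max_records_per_index"] = static_cast<double>(per_index),
                      _["max_indices_per_bucket"] = static_cast<double>(per_bucket));
}

// [[Rcpp::export]]
DataFrame cpp_aux_dump(SEXP a) {
  XPtr<AuxHandle> p(a);
  std::vector<double> bucket, ht, pos, quot;
  std::vector<int> hf, count;
  std::vector<std::string> neigh;
  for (std::uint64_t bi = 0; bi < p->p->V; ++bi)
    for (const auto& s : p->p->buckets[static_cast<std::size_t>(bi)])
      for (std::size_t j = 0; j < s.records.size(); ++j) {
        const AuxRecord& r = s.records[j];
        bucket.push_back(static_cast<double>(bi));
        ht.push_back(static_cast<double>(s.ht_index));
        pos.push_back(static_cast<double>(j));
        quot.push_back(static_cast<double>(r.quotient));
        hf.push_back(r.hf);
        neigh.push_back(mask_to_bases(r.bits));
        count.push_back(r.count);
      }
  return DataFrame::create(_["bucket"] = bucket, _["ht_index"] = ht,
                           _["pos"] = pos, _["quotient"] = quot, _["hf"] = hf,
                           _["neighbours"] = neigh, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// graph
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_min_table_size(int k) {
  if (k < 1 || k > 32) stop("k out of range: %d (must be 1..32)", k);
  return static_cast<double>(min_table_size(k));
}

// [[Rcpp::export]]
SEXP cpp_graph_new(int k, double M, int h, double V, bool counts, SEXP fam) {
  auto g = new HavecGraph(k, size_from_double(M, "table size M"), h,
                          size_from_double(V, "vector size V"), counts,
                          family_of(fam));
  return XPtr<HavecGraph>(g, true);
}

// [[Rcpp::export]]
List cpp_graph_params(SEXP g) {
  HavecGraph* p = graph_of(g);
  return List::create(
      _["k"] = p->k, _["h"] = p->h, _["M"] = static_cast<double>(p->M),
      _["V"] = static_cast<double>(p->V),
      _["mode"] = p->counts ? "6-byte" : "5-byte",
      _["stipulated"] = p->fam->stipulated,
      _["seed"] = static_cast<double>(p->fam->master_seed),
      _["reads"] = static_cast<double>(p->n_reads),
      _["observations"] = static_cast<double>(p->n_observations),
      _["table_kmers"] = static_cast<double>(p->table_kmers),
      _["vector_kmers"] = static_cast<double>(p->vector_kmers));
}

// [[Rcpp::export]]
List cpp_graph_build(SEXP g, CharacterVector reads) {
  HavecGraph* p = graph_of(g);
  std::vector<std::string> rs(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) rs[i] = as<std::string>(reads[i]);
  const BuildReport rep = p->build(rs);
  return List::create(
      _["reads"] = static_cast<double>(rep.reads),
      _["observations"] = static_cast<double>(rep.observations),
      _["skipped_windows"] = static_cast<double>(rep.skipped_windows),
      _["distinct_kmers"] = static_cast<double>(p->table_kmers + p->vector_kmers),
      _["table_kmers"] = static_cast<double>(p->table_kmers),
      _["vector_kmers"] = static_cast<double>(p->vector_kmers));
}

// [[Rcpp::export]]
List cpp_graph_insert(SEXP g, std::string kmer, std::string next_base) {
  HavecGraph* p = graph_of(g);
  if (static_cast<int>(kmer.size()) != p->k)
    stop("k-mer length %d does not match graph k = %d", (int)kmer.size(), p->k);
  int nb = -1;
  if (!next_base.empty()) {
    nb = base_code(next_base[0]);
    if (nb < 0 || next_base.size() != 1)
      stop("ambiguous base \"%s\"", next_base.c_str());
  }
  const Location loc = p->insert_observation(encode_kmer(kmer), nb);
  return location_list(loc);
}

// [[Rcpp::export]]
DataFrame cpp_graph_locate(SEXP g, CharacterVector kmers) {
  HavecGraph* p = graph_of(g);
  const R_xlen_t n = kmers.size();
  CharacterVector kind(n);
  NumericVector index(n), bucket(n), ht_index(n), pos(n);
  IntegerVector hf(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string s = as<std::string>(kmers[i]);
    if (static_cast<int>(s.size()) != p->k)
      stop("k-mer length %d does not match graph k = %d", (int)s.size(), p->k);
    const Location loc = p->locate(encode_kmer(s));
    index[i] = bucket[i] = ht_index[i] = pos[i] = NA_REAL;
    hf[i] = NA_INTEGER;
    if (loc.kind == LocKind::table) {
      kind[i] = "table";
      index[i] = static_cast<double>(loc.index);
      hf[i] = loc.hf;
    } else if (loc.kind == LocKind::vector) {
      kind[i] = "vector";
      bucket[i] = static_cast<double>(loc.bucket);
      ht_index[i] = static_cast<double>(loc.index);
      pos[i] = static_cast<double>(loc.pos);
      hf[i] = loc.hf;
    } else {
      kind[i] = "absent";
    }
  }
  return DataFrame::create(_["kmer"] = kmers, _["kind"] = kind,
                           _["index"] = index, _["bucket"] = bucket,
                           _["ht_index"] = ht_index, _["pos"] = pos,
                           _["hf"] = hf, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
LogicalVector cpp_graph_contains(SEXP g, CharacterVector kmers, int cutoff) {
  HavecGraph* p = graph_of(g);
  LogicalVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    const std::string s = as<std::string>(kmers[i]);
    if (static_cast<int>(s.size()) != p->k)
      stop("k-mer length %d does not match graph k = %d", (int)s.size(), p->k);
    out[i] = p->contains(encode_kmer(s), cutoff);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_graph_successors(SEXP g, std::string kmer, int cutoff) {
  HavecGraph* p = graph_of(g);
  const std::vector<std::uint64_t> succ =
      p->successors(encode_kmer(kmer), cutoff);
  CharacterVector out(succ.size());
  for (std::size_t i = 0; i < succ.size(); ++i)
    out[i] = decode_kmer(succ[i], p->k);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_graph_predecessors(SEXP g, std::string kmer, int cutoff) {
  HavecGraph* p = graph_of(g);
  const std::vector<std::uint64_t> pred =
      p->predecessors(encode_kmer(kmer), cutoff);
  CharacterVector out(pred.size());
  for (std::size_t i = 0; i < pred.size(); ++i)
    out[i] = decode_kmer(pred[i], p->k);
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_graph_enumerate(SEXP g) {
  HavecGraph* p = graph_of(g);
  std::vector<std::uint64_t> codes;
  std::vector<std::uint8_t> bits, cnts;
  p->enumerate(&codes, &bits, &cnts);
  CharacterVector kmer(codes.size()), neigh(codes.size());
  IntegerVector count(codes.size());
  for (std::size_t i = 0; i < codes.size(); ++i) {
    kmer[i] = decode_kmer(codes[i], p->k);
    neigh[i] = mask_to_bases(bits[i]);
    count[i] = p->counts ? static_cast<int>(cnts[i]) : NA_INTEGER;
  }
  return DataFrame::create(_["kmer"] = kmer, _["neighbours"] = neigh,
                           _["count"] = count, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
List cpp_graph_stats(SEXP g) {
  HavecGraph* p = graph_of(g);
  std::uint64_t total, per_index, per_bucket;
  p->aux->stats(&total, &per_index, &per_bucket);
  const double distinct = static_cast<double>(p->table_kmers + p->vector_kmers);
  return List::create(
      _["distinct_kmers"] = distinct,
      _["table_kmers"] = static_cast<double>(p->table_kmers),
      _["vector_kmers"] = static_cast<double>(p->vector_kmers),
      _["load_factor"] = static_cast<double>(p->table_kmers) / static_cast<double>(p->M),
      _["table_bytes"] = static_cast<double>(p->table->nbytes()),
      _["vector_bytes"] = static_cast<double>(p->aux->payload_bytes(p->counts)),
      _["max_records_per_index"] = static_cast<double>(per_index),
      _["max_indices_per_bucket"] = static_cast<double>(per_bucket),
      _["reads"] = static_cast<double>(p->n_reads),
      _["observations"] = static_cast<double>(p->n_observations));
}

// [[Rcpp::export]]
RawVector cpp_graph_serialize(SEXP g) {
  const std::vector<std::uint8_t> buf = graph_of(g)->serialize();
  RawVector out(buf.size());
  std::memcpy(RAW(out), buf.data(), buf.size());
  return out;
}

// [[Rcpp::export]]
SEXP cpp_graph_deserialize(RawVector buf) {
  auto g = HavecGraph::deserialize(
      reinterpret_cast<const std::uint8_t*>(RAW(buf)),
      static_cast<std::size_t>(buf.size()));
  return XPtr<HavecGraph>(g.release(), true);
}

// ---------------------------------------------------------------------------
// oracle
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
SEXP cpp_oracle_build(CharacterVector reads, int k) {
  if (k < 1 || k > 32) stop("k out of range: %d (must be 1..32)", k);
  std::vector<std::string> rs(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) rs[i] = as<std::string>(reads[i]);
  auto handle = new OracleHandle{
      std::make_shared<ExactOracle>(ExactOracle::build(rs, k))};
  return XPtr<OracleHandle>(handle, true);
}

// [[Rcpp::export]]
List cpp_oracle_info(SEXP o) {
  XPtr<OracleHandle> p(o);
  return List::create(_["k"] = p->p->k,
                      _["distinct_kmers"] = static_cast<double>(p->p->map.size()));
}

// [[Rcpp::export]]
DataFrame cpp_oracle_kmers(SEXP o) {
  XPtr<OracleHandle> p(o);
  const int k = p->p->k;
  std::vector<std::string> kmer, neigh;
  std::vector<double> count;
  kmer.reserve(p->p->map.size());
  for (const auto& kv : p->p->map) {
    kmer.push_back(decode_kmer(kv.first, k));
    neigh.push_back(mask_to_bases(kv.second.bits));
    count.push_back(static_cast<double>(kv.second.count));
  }
  return DataFrame::create(_["kmer"] = kmer, _["neighbours"] = neigh,
                           _["count"] = count, _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
DataFrame cpp_compare(SEXP g, SEXP o, int cutoff) {
  HavecGraph* gp = graph_of(g);
  XPtr<OracleHandle> op(o);
  const ExactOracle& oracle = *op->p;
  if (gp->k != oracle.k)
    stop("graph k = %d but oracle k = %d", gp->k, oracle.k);
  if (cutoff >= 2 && !gp->counts)
    stop("counts unavailable: cutoff comparisons need a 6-byte graph");
  std::vector<std::string> kmer, field, expected, observed;
  auto report = [&](std::uint64_t code, const char* f, std::string exp,
                    std::string obs) {
    kmer.push_back(decode_kmer(code, gp->k));
    field.push_back(f);
    expected.push_back(std::move(exp));
    observed.push_back(std::move(obs));
  };
  auto capped = [&](std::uint64_t n) -> std::uint32_t {
    return n > 255 ? 255u : static_cast<std::uint32_t>(n);
  };
  const int cf = cutoff < 2 ? 1 : cutoff;
  for (const auto& kv : oracle.map) {
    const std::uint64_t code = kv.first;
    const bool expect_present =
        cf == 1 || capped(kv.second.count) >= static_cast<std::uint32_t>(cf);
    const Location loc = gp->locate(code);
    const bool present =
        loc.kind != LocKind::absent &&
        (cf == 1 || gp->count_at(loc) >= static_cast<std::uint32_t>(cf));
    if (expect_present != present) {
      report(code, "membership", expect_present ? "present" : "absent",
             present ? "present" : "absent");
      continue;
    }
    if (!expect_present) continue;
    // neighbour sets under the cutoff: drop successors that are suppressed
    std::uint8_t want = kv.second.bits;
    if (cf > 1) {
      const std::uint64_t mask =
          (gp->k == 32) ? ~0ULL : ((1ULL << (2 * gp->k)) - 1);
      std::uint8_t kept = 0;
      for (int b = 0; b < 4; ++b) {
        if (!(want & (1 << (3 - b)))) continue;
        const std::uint64_t succ =
            ((code << 2) | static_cast<std::uint64_t>(b)) & mask;
        auto it = oracle.map.find(succ);
        if (it != oracle.map.end() &&
            capped(it->second.count) >= static_cast<std::uint32_t>(cf))
          kept |= static_cast<std::uint8_t>(1 << (3 - b));
      }
      want = kept;
    }
    std::uint8_t got = 0;
    for (const std::uint64_t s : gp->successors(code, cutoff))
      got |= static_cast<std::uint8_t>(1 << (3 - static_cast<int>(s & 3)));
    if (want != got)
      report(code, "neighbours", mask_to_bases(want), mask_to_bases(got));
    if (gp->counts) {
      const std::uint32_t wc = capped(kv.second.count);
      const std::uint32_t gc = gp->count_at(loc);
      if (wc != gc)
        report(code, "count", std::to_string(wc), std::to_string(gc));
    }
  }
  // extras: construction never drops k-mers, so totals must match exactly
  const double g_total = static_cast<double>(gp->table_kmers + gp->vector_kmers);
  const double o_total = static_cast<double>(oracle.map.size());
  if (g_total != o_total) {
    kmer.push_back("<total>");
    field.push_back("distinct_kmers");
    expected.push_back(std::to_string(static_cast<std::uint64_t>(o_total)));
    observed.push_back(std::to_string(static_cast<std::uint64_t>(g_total)));
  }
  return DataFrame::create(_["kmer"] = kmer, _["field"] = field,
                           _["expected"] = expected, _["observed"] = observed,
                           _["stringsAsFactors"] = false);
}
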