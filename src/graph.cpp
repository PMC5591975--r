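// Graph construction, queries, binary container, brute-force oracle.

#include "havec.h"

#include <Rcpp.h>

namespace havec {

std::uint64_t min_table_size(int k) {
  if (2 * k <= 33) return 1;
  return 1ULL << (2 * k - 33);
}

HavecGraph::HavecGraph(int k, std::uint64_t M, int h, std::uint64_t V,
                       bool counts, std::shared_ptr<HashFamily> fam)
    : k(k), h(h), M(M), V(V), counts(counts), fam(std::move(fam)) {
  if (k < 1 || k > 32) Rcpp::stop("k out of range: %d (must be 1..32)", k);
  if (h < 1 || h > HF_MAX)
    Rcpp::stop("hash-function count unsupported: h = %d (must be 1..%d)", h, HF_MAX);
  if (this->fam->h < h)
    Rcpp::stop("hash family provides %d functions but h = %d", this->fam->h, h);
  const std::uint64_t m_min = min_table_size(k);
  if (M < m_min)
    Rcpp::stop("table too small for 33-bit quotients (k=%d): M must be at least "
               "2^(2k-33) = %llu, got %llu",
               k, static_cast<unsigned long long>(m_min),
               static_cast<unsigned long long>(M));
  if (V < 1) Rcpp::stop("level-1 vector size V must be >= 1");
  table = std::make_shared<PackedTable>(M, counts ? 6 : 5);
  aux = std::make_shared<AuxVector>(V);
}

Location HavecGraph::locate(std::uint64_t code) const {
  std::uint64_t v_h = 0;
  for (int i = 1; i <= h; ++i) {
    const std::uint64_t v = fam->hash(i, code, k);
    if (i == h) v_h = v;
    const std::uint64_t idx = v % M, q = v / M;
    const TableEntry e = table->read(idx);
    if (e.hf == static_cast<std::uint8_t>(i) && e.quotient == q) {
      Location loc;
      loc.kind = LocKind::table;
      loc.index = idx;
      loc.hf = i;
      return loc;
    }
  }
  const std::uint64_t idx_h = v_h % M, q_h = v_h / M;
  const auto& bucket = aux->buckets[static_cast<std::size_t>(idx_h % V)];
  for (const auto& s : bucket) {
    if (s.ht_index != idx_h) continue;
    for (std::size_t p = 0; p < s.records.size(); ++p)
      if (s.records[p].quotient == q_h) {
        Location loc;
        loc.kind = LocKind::vector;
        loc.index = idx_h;
        loc.bucket = idx_h % V;
        loc.pos = p;
        loc.hf = h;
        return loc;
      }
    break;
  }
  return Location{};
}

Location HavecGraph::insert_observation(std::uint64_t code, int next_base) {
  const std::uint8_t bit =
      next_base >= 0 ? static_cast<std::uint8_t>(1 << (3 - next_base)) : 0;
  Location loc = locate(code);
  if (loc.kind == LocKind::table) {
    TableEntry e = table->read(loc.index);
    e.bits |= bit;
    if (counts && e.count < 255) e.count++;
    table->write(loc.index, e);
    return loc;
  }
  if (loc.kind == LocKind::vector) {
    auto& bucket = aux->buckets[static_cast<std::size_t>(loc.bucket)];
    for (auto& s : bucket)
      if (s.ht_index == loc.index) {
        AuxRecord& r = s.records[loc.pos];
        r.bits |= bit;
        if (counts && r.count < 255) r.count++;
        break;
      }
    return loc;
  }
  // absent: probe H_1..H_h for the first free slot
  std::uint64_t v_h = 0;
  for (int i = 1; i <= h; ++i) {
    const std::uint64_t v = fam->hash(i, code, k);
    if (i == h) v_h = v;
    const std::uint64_t idx = v % M, q = v / M;
    const TableEntry e = table->read(idx);
    if (e.hf == 0) {
      TableEntry fresh;
      fresh.bits = bit;
      fresh.hf = static_cast<std::uint8_t>(i);
      fresh.quotient = q;
      fresh.count = counts ? 1 : 0;
      table->write(idx, fresh);
      ++table_kmers;
      Location out;
      out.kind = LocKind::table;
      out.index = idx;
      out.hf = i;
      return out;
    }
  }
  // every probe collided: file under the last function's table index
  const std::uint64_t idx_h = v_h % M, q_h = v_h / M;
  AuxRecord rec;
  rec.quotient = q_h;
  rec.hf = static_cast<std::uint8_t>(h);
  rec.bits = bit;
  rec.count = 1;
  bool created = false;
  aux->insert(idx_h, rec, &created);
  if (created) ++vector_kmers;  // locate() above makes !created unreachable
  Location out;
  out.kind = LocKind::vector;
  out.index = idx_h;
  out.bucket = idx_h % V;
  const auto& bucket = aux->buckets[static_cast<std::size_t>(out.bucket)];
  for (const auto& s : bucket)
    if (s.ht_index == idx_h) { out.pos = s.records.size() - 1; break; }
  out.hf = h;
  return out;
}

BuildReport HavecGraph::build(const std::vector<std::string>& reads) {
  BuildReport rep;
  for (const auto& read : reads) {
    ++rep.reads;
    ++n_reads;
    const std::vector<Window> ws = extract_windows(read, k);
    const std::size_t L = read.size();
    const std::size_t full =
        L >= static_cast<std::size_t>(k) ? L - static_cast<std::size_t>(k) + 1 : 0;
    rep.skipped_windows += full - ws.size();
    for (const auto& w : ws) {
      insert_observation(w.code, w.next);
      ++rep.observations;
      ++n_observations;
    }
  }
  return rep;
}

std::uint8_t HavecGraph::neighbour_bits(const Location& loc) const {
  if (loc.kind == LocKind::table) return table->read(loc.index).bits;
  if (loc.kind == LocKind::vector) {
    const AuxRecord* r = nullptr;
    const auto& bucket = aux->buckets[static_cast<std::size_t>(loc.bucket)];
    for (const auto& s : bucket)
      if (s.ht_index == loc.index) { r = &s.records[loc.pos]; break; }
    return r ? r->bits : 0;
  }
  return 0;
}

std::uint32_t HavecGraph::count_at(const Location& loc) const {
  if (loc.kind == LocKind::table) return table->read(loc.index).count;
  if (loc.kind == LocKind::vector) {
    const auto& bucket = aux->buckets[static_cast<std::size_t>(loc.bucket)];
    for (const auto& s : bucket)
      if (s.ht_index == loc.index) return s.records[loc.pos].count;
  }
  return 0;
}

bool HavecGraph::contains(std::uint64_t code, int cutoff) const {
  const Location loc = locate(code);
  if (loc.kind == LocKind::absent) return false;
  if (cutoff >= 2) {
    if (!counts)
      Rcpp::stop("counts unavailable: cutoff queries need a 6-byte graph");
    return count_at(loc) >= static_cast<std::uint32_t>(cutoff);
  }
  return true;
}

std::vector<std::uint64_t> HavecGraph::successors(std::uint64_t code,
                                                  int cutoff) const {
  if (!contains(code, cutoff))
    Rcpp::stop("k-mer not in graph: %s", decode_kmer(code, k).c_str());
  const std::uint8_t bits = neighbour_bits(locate(code));
  const std::uint64_t mask =
      (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<std::uint64_t> out;
  for (int b = 0; b < 4; ++b) {  // A, C, G, T order
    if (!(bits & (1 << (3 - b)))) continue;
    const std::uint64_t succ =
        ((code << 2) | static_cast<std::uint64_t>(b)) & mask;
    if (cutoff >= 2 && !contains(succ, cutoff)) continue;  // suppressed
    out.push_back(succ);
  }
  return out;
}

std::vector<std::uint64_t> HavecGraph::predecessors(std::uint64_t code,
                                                    int cutoff) const {
  if (!contains(code, cutoff))
    Rcpp::stop("k-mer not in graph: %s", decode_kmer(code, k).c_str());
  const int last = static_cast<int>(code & 3);
  std::vector<std::uint64_t> out;
  for (int b = 0; b < 4; ++b) {
    const std::uint64_t pred =
        (static_cast<std::uint64_t>(b) << (2 * (k - 1))) | (code >> 2);
    const Location loc = locate(pred);
    if (loc.kind == LocKind::absent) continue;
    if (cutoff >= 2 && count_at(loc) < static_cast<std::uint32_t>(cutoff))
      continue;
    if (neighbour_bits(loc) & (1 << (3 - last))) out.push_back(pred);
  }
  return out;
}

void HavecGraph::enumerate(std::vector<std::uint64_t>* codes,
                           std::vector<std::uint8_t>* bits,
                           std::vector<std::uint8_t>* cnts) const {
  if (!fam->invertible())
    Rcpp::stop("not invertible: the stipulated family has no reverse entries");
  for (std::uint64_t idx = 0; idx < M; ++idx) {
    const TableEntry e = table->read(idx);
    if (e.hf == 0) continue;
    const std::uint64_t v = e.quotient * M + idx;
    codes->push_back(fam->invert(e.hf, v, k));
    bits->push_back(e.bits);
    cnts->push_back(e.count);
  }
  for (const auto& bucket : aux->buckets)
    for (const auto& s : bucket)
      for (const auto& r : s.records) {
        const std::uint64_t v = r.quotient * M + s.ht_index;
        codes->push_back(fam->invert(r.hf, v, k));
        bits->push_back(r.bits);
        cnts->push_back(r.count);
      }
}

// ---------------------------------------------------------------------------
// binary container: fixed little-endian header, table bytes, aux payload,
// trailing FNV-1a checksum of everything before it
// ---------------------------------------------------------------------------

namespace {

const char MAGIC[8] = {'H', 'A', 'V', 'E', 'C', 'G', 'R', '1'};

void put_u64(std::vector<std::uint8_t>& out, std::uint64_t v) {
  for (int j = 0; j < 8; ++j) out.push_back(static_cast<std::uint8_t>((v >> (8 * j)) & 0xFF));
}

std::uint64_t get_u64(const std::uint8_t* p) {
  std::uint64_t v = 0;
  for (int j = 7; j >= 0; --j) v = (v << 8) | p[j];
  return v;
}

std::uint64_t fnv1a(const std::uint8_t* p, std::size_t n) {
  std::uint64_t hash = 0xCBF29CE484222325ULL;
  for (std::size_t i = 0; i < n; ++i) {
    hash ^= p[i];
    hash *= 0x100000001B3ULL;
  }
  return hash;
}

}  // namespace

std::vector<std::uint8_t> HavecGraph::serialize() const {
  if (fam->stipulated)
    Rcpp::stop("stipulated hash families cannot be serialized: the container "
               "stores only the master seed");
  std::vector<std::uint8_t> out;
  out.insert(out.end(), MAGIC, MAGIC + 8);
  put_u64(out, 1);  // format version
  put_u64(out, static_cast<std::uint64_t>(k));
  put_u64(out, static_cast<std::uint64_t>(h));
  put_u64(out, counts ? 6 : 5);
  put_u64(out, M);
  put_u64(out, V);
  put_u64(out, fam->master_seed);
  put_u64(out, n_reads);
  put_u64(out, n_observations);
  put_u64(out, table_kmers);
  put_u64(out, vector_kmers);
  const std::size_t table_off = out.size();
  out.resize(table_off + table->nbytes());
  table->copy_out(out.data() + table_off);
  std::uint64_t n_nonempty = 0;
  for (const auto& b : aux->buckets)
    if (!b.empty()) ++n_nonempty;
  put_u64(out, n_nonempty);
  for (std::uint64_t bi = 0; bi < V; ++bi) {
    const auto& b = aux->buckets[static_cast<std::size_t>(bi)];
    if (b.empty()) continue;
    put_u64(out, bi);
    put_u64(out, b.size());
    for (const auto& s : b) {
      put_u64(out, s.ht_index);
      put_u64(out, s.records.size());
      for (const auto& r : s.records) {
        put_u64(out, r.quotient);
        out.push_back(r.hf);
        out.push_back(r.bits);
        out.push_back(r.count);
      }
    }
  }
  put_u64(out, fnv1a(out.data(), out.size()));
  return out;
}

std::unique_ptr<HavecGraph> HavecGraph::deserialize(const std::uint8_t* buf,
                                                    std::size_t len) {
  if (len < 8 + 11 * 8 + 8 || std::memcmp(buf, MAGIC, 8) != 0)
    Rcpp::stop("unrecognized graph file: bad magic bytes");
  const std::uint64_t stored_sum = get_u64(buf + len - 8);
  if (fnv1a(buf, len - 8) != stored_sum)
    Rcpp::stop("corrupt graph file: checksum mismatch");
  const std::uint8_t* p = buf + 8;
  const std::uint64_t version = get_u64(p); p += 8;
  if (version != 1) Rcpp::stop("unrecognized graph file: version %llu",
                               static_cast<unsigned long long>(version));
  const int k = static_cast<int>(get_u64(p)); p += 8;
  const int h = static_cast<int>(get_u64(p)); p += 8;
  const int width = static_cast<int>(get_u64(p)); p += 8;
  const std::uint64_t M = get_u64(p); p += 8;
  const std::uint64_t V = get_u64(p); p += 8;
  const std::uint64_t seed = get_u64(p); p += 8;
  auto fam = std::make_shared<HashFamily>(HashFamily::make(h, seed));
  auto g = std::unique_ptr<HavecGraph>(
      new HavecGraph(k, M, h, V, width == 6, fam));
  g->n_reads = get_u64(p); p += 8;
  g->n_observations = get_u64(p); p += 8;
  g->table_kmers = get_u64(p); p += 8;
  g->vector_kmers = get_u64(p); p += 8;
  const std::uint64_t tb = g->table->nbytes();
  if (static_cast<std::size_t>(p - buf) + tb + 16 > len)
    Rcpp::stop("corrupt graph file: truncated table payload");
  g->table->copy_in(p);
  p += tb;
  const std::uint64_t n_nonempty = get_u64(p); p += 8;
  const std::uint8_t* end = buf + len - 8;
  const std::uint64_t rec_extra = 8 + 3;
  for (std::uint64_t bj = 0; bj < n_nonempty; ++bj) {
    if (p + 16 > end) Rcpp::stop("corrupt graph file: truncated vector payload");
    const std::uint64_t bi = get_u64(p); p += 8;
    const std::uint64_t nsub = get_u64(p); p += 8;
    if (bi >= V) Rcpp::stop("corrupt graph file: bucket index out of range");
    auto& bucket = g->aux->buckets[static_cast<std::size_t>(bi)];
    for (std::uint64_t sj = 0; sj < nsub; ++sj) {
      if (p + 16 > end) Rcpp::stop("corrupt graph file: truncated vector payload");
      AuxSublist s;
      s.ht_index = get_u64(p); p += 8;
      const std::uint64_t nrec = get_u64(p); p += 8;
      if (p + nrec * rec_extra > end)
        Rcpp::stop("corrupt graph file: truncated vector payload");
      for (std::uint64_t rj = 0; rj < nrec; ++rj) {
        AuxRecord r;
        r.quotient = get_u64(p); p += 8;
        r.hf = *p++;
        r.bits = *p++;
        r.count = *p++;
        s.records.push_back(r);
        ++g->aux->n_records;
      }
      bucket.push_back(std::move(s));
    }
  }
  if (p != end) Rcpp::stop("corrupt graph file: trailing bytes");
  return g;
}

// ---------------------------------------------------------------------------
// oracle
// ---------------------------------------------------------------------------

ExactOracle ExactOracle::build(const std::vector<std::string>& reads, int k) {
  ExactOracle o;
  o.k = k;
  for (const auto& read : reads) {
    for (const auto& w : extract_windows(read, k)) {
      OracleEntry& e = o.map[w.code];
      if (w.next >= 0) e.bits |= static_cast<std::uint8_t>(1 << (3 - w.next));
      e.count++;
    }
  }
  return o;
}

}  // namespace havec
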