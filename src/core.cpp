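// Core sequence engines: de Bruijn unitig assembly, end-to-end read mapping
// (seed-and-verify), and ungapped seed-and-extend local alignment.
// All functions are deterministic: no RNG, iteration orders fixed by sorting.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static const int BASE_A = 0, BASE_C = 1, BASE_G = 2, BASE_T = 3;

static inline int encode_base(char c) {
  switch (c) {
  case 'A': case 'a': return BASE_A;
  case 'C': case 'c': return BASE_C;
  case 'G': case 'g': return BASE_G;
  case 'T': case 't': return BASE_T;
  default: return -1; // N or anything else: invalidates the k-mer
  }
}

static inline char decode_base(int b) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[b & 3];
}

// reverse complement of a 2-bit packed k-mer
static inline uint64_t revcomp_kmer(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static inline uint64_t canonical_kmer(uint64_t v, int k) {
  uint64_t r = revcomp_kmer(v, k);
  return v < r ? v : r;
}

static std::string decode_kmer(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = decode_base((int)(v & 3ULL));
    v >>= 2;
  }
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// de Bruijn unitig assembly
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_build_unitigs")]]
CharacterVector cpp_build_unitigs(CharacterVector reads, int k, int min_count) {
  if (k < 1 || k > 31 || k % 2 == 0)
    stop("k must be an odd integer between 1 and 31");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

  // 1. count canonical k-mers; k-mers touching N are skipped
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)LENGTH(STRING_ELT(reads, r));
    uint64_t v = 0;
    int valid = 0; // number of consecutive valid bases ending here
    for (int i = 0; i < len; ++i) {
      int b = encode_base(s[i]);
      if (b < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++valid >= k) counts[canonical_kmer(v, k)]++;
    }
  }

  // 2. abundance filter, deterministic ordering
  std::vector<uint64_t> kmers;
  kmers.reserve(counts.size());
  for (const auto& kv : counts)
    if ((int)kv.second >= min_count) kmers.push_back(kv.first);
  counts.clear();
  std::sort(kmers.begin(), kmers.end());
  if (kmers.empty()) return CharacterVector(0);

  std::unordered_map<uint64_t, uint32_t> index;
  index.reserve(kmers.size() * 2);
  for (uint32_t i = 0; i < kmers.size(); ++i) index[kmers[i]] = i;
  std::vector<char> used(kmers.size(), 0);

  const int shift = 2 * (k - 1);
  auto member = [&](uint64_t canon, uint32_t* idx) -> bool {
    auto it = index.find(canon);
    if (it == index.end()) return false;
    *idx = it->second;
    return true;
  };

  // out-neighbours of an oriented k-mer value
  auto out_degree = [&](uint64_t val, uint64_t* next_out) -> int {
    int deg = 0;
    for (int c = 0; c < 4; ++c) {
      uint64_t nx = ((val << 2) | (uint64_t)c) & mask;
      uint32_t dummy;
      if (member(canonical_kmer(nx, k), &dummy)) { ++deg; *next_out = nx; }
    }
    return deg;
  };
  auto in_degree = [&](uint64_t val) -> int {
    int deg = 0;
    for (int c = 0; c < 4; ++c) {
      uint64_t pv = ((uint64_t)c << shift) | (val >> 2);
      uint32_t dummy;
      if (member(canonical_kmer(pv, k), &dummy)) ++deg;
    }
    return deg;
  };

  // walk a maximal non-branching path forward, appending bases; marks k-mers
  auto walk = [&](uint64_t start_val, std::string& out) {
    uint64_t cur = start_val;
    for (;;) {
      uint64_t nx = 0;
      if (out_degree(cur, &nx) != 1) break;
      if (in_degree(nx) != 1) break;
      uint32_t ni;
      if (!member(canonical_kmer(nx, k), &ni)) break;
      if (used[ni]) break; // cycle closure
      used[ni] = 1;
      out.push_back(decode_base((int)(nx & 3ULL)));
      cur = nx;
    }
  };

  std::vector<std::string> unitigs;
  for (uint32_t i = 0; i < kmers.size(); ++i) {
    if (used[i]) continue;
    used[i] = 1;
    std::string fwd = decode_kmer(kmers[i], k);
    std::string right;
    walk(kmers[i], right);
    std::string left;
    walk(revcomp_kmer(kmers[i], k), left);
    std::string seq = revcomp_str(left) + fwd + right;
    std::string rc = revcomp_str(seq);
    unitigs.push_back(seq <= rc ? seq : rc); // canonical orientation
  }

  // longest first, lexicographic within ties: stable contig naming downstream
  std::sort(unitigs.begin(), unitigs.end(),
            [](const std::string& a, const std::string& b) {
              if (a.size() != b.size()) return a.size() > b.size();
              return a < b;
            });
  CharacterVector out(unitigs.size());
  for (size_t i = 0; i < unitigs.size(); ++i) out[i] = unitigs[i];
  return out;
}

// ---------------------------------------------------------------------------
// end-to-end read mapping: exact seed table + full-length verification
// ---------------------------------------------------------------------------

struct SeedIndex {
  int seed_len;
  uint64_t mask;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> table;
  std::vector<std::string> refs;
};

static void build_seed_index(const CharacterVector& refs, int seed_len,
                             SeedIndex& idx) {
  idx.seed_len = seed_len;
  idx.mask = (1ULL << (2 * seed_len)) - 1ULL;
  idx.refs.resize(refs.size());
  for (R_xlen_t r = 0; r < refs.size(); ++r) {
    idx.refs[r] = std::string(CHAR(STRING_ELT(refs, r)));
    const std::string& s = idx.refs[r];
    uint64_t v = 0;
    int valid = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int b = encode_base(s[i]);
      if (b < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & idx.mask;
      if (++valid >= seed_len)
        idx.table[v].push_back({(int32_t)r, (int32_t)(i - seed_len + 1)});
    }
  }
}

// count mismatches of query against refs[ref] at ref offset `start`,
// abandoning early past max_mm; returns -1 if out of bounds or exceeded
static int verify_hit(const std::string& ref, const std::string& query,
                      int start, int max_mm) {
  if (start < 0 || start + (int)query.size() > (int)ref.size()) return -1;
  int mm = 0;
  for (int i = 0; i < (int)query.size(); ++i) {
    if (ref[start + i] != query[i] && ++mm > max_mm) return -1;
  }
  return mm;
}

// [[Rcpp::export(name = ".cpp_map_reads")]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int seed_len, double min_identity) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  SeedIndex idx;
  build_seed_index(refs, seed_len, idx);

  std::vector<int> o_read, o_ref, o_start, o_mm;
  std::vector<int> o_strand; // 1 = forward, -1 = reverse

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string q = std::string(CHAR(STRING_ELT(reads, r)));
    int len = (int)q.size();
    if (len < seed_len) continue;
    int max_mm = (int)std::floor((1.0 - min_identity) * len + 1e-9);

    int best_mm = max_mm + 1, best_ref = -1, best_start = -1, best_strand = 0;
    std::unordered_set<uint64_t> seen; // (ref,start,strand) already verified

    for (int strand = 0; strand < 2; ++strand) {
      const std::string qq = strand == 0 ? q : revcomp_str(q);
      // seed offsets: stride of seed_len, plus the final window
      std::vector<int> offs;
      for (int o = 0; o + seed_len <= len; o += seed_len) offs.push_back(o);
      if (offs.empty() || offs.back() != len - seed_len)
        offs.push_back(len - seed_len);
      for (int o : offs) {
        uint64_t v = 0;
        bool ok = true;
        for (int i = 0; i < seed_len; ++i) {
          int b = encode_base(qq[o + i]);
          if (b < 0) { ok = false; break; }
          v = (v << 2) | (uint64_t)b;
        }
        if (!ok) continue;
        auto it = idx.table.find(v);
        if (it == idx.table.end()) continue;
        for (const auto& hit : it->second) {
          int start = hit.second - o;
          uint64_t key = ((uint64_t)(uint32_t)hit.first << 33) |
                         ((uint64_t)(uint32_t)(start + 1) << 1) |
                         (uint64_t)strand;
          if (!seen.insert(key).second) continue;
          int mm = verify_hit(idx.refs[hit.first], qq, start, max_mm);
          if (mm < 0) continue;
          // order: fewer mismatches, then lower ref index, lower start,
          // forward strand preferred
          bool better = mm < best_mm ||
            (mm == best_mm && (hit.first < best_ref ||
             (hit.first == best_ref && (start < best_start ||
              (start == best_start && strand == 0 && best_strand == -1)))));
          if (better) {
            best_mm = mm; best_ref = hit.first; best_start = start;
            best_strand = strand == 0 ? 1 : -1;
          }
        }
      }
    }
    if (best_ref >= 0) {
      o_read.push_back((int)r + 1);
      o_ref.push_back(best_ref + 1);
      o_start.push_back(best_start + 1); // 1-based
      o_mm.push_back(best_mm);
      o_strand.push_back(best_strand);
    }
  }
  return DataFrame::create(
    _["read"] = o_read, _["ref"] = o_ref, _["start"] = o_start,
    _["mismatches"] = o_mm, _["strand"] = o_strand);
}

// ---------------------------------------------------------------------------
// ungapped seed-and-extend local alignment (x-drop)
// ---------------------------------------------------------------------------

struct LocalHit {
  int query, ref;              // indices
  int q_start, q_end;          // 0-based half-open, on the oriented query
  int r_start, r_end;          // 0-based half-open on the reference
  int strand;                  // 1 / -1
  int score, matches;
};

// extend ungapped from (qi, ri) in direction dir (+1 right of the seed end,
// -1 left of the seed start); returns best score delta and lengths
static void extend_dir(const std::string& q, const std::string& r,
                       int qi, int ri, int dir, int match, int mismatch,
                       int xdrop, int* best_len, int* best_score,
                       int* best_matches) {
  int score = 0, best = 0, len = 0, blen = 0, matches = 0, bmatch = 0;
  while (true) {
    int qq = qi + dir * len, rr = ri + dir * len;
    if (qq < 0 || rr < 0 || qq >= (int)q.size() || rr >= (int)r.size()) break;
    bool is_match = q[qq] == r[rr] && encode_base(q[qq]) >= 0;
    score += is_match ? match : -mismatch;
    if (is_match) ++matches;
    ++len;
    if (score > best) { best = score; blen = len; bmatch = matches; }
    if (best - score > xdrop) break;
  }
  *best_len = blen; *best_score = best; *best_matches = bmatch;
}

// [[Rcpp::export(name = ".cpp_align_local")]]
DataFrame cpp_align_local(CharacterVector queries, CharacterVector refs,
                          int seed_len, int match, int mismatch, int xdrop) {
  if (seed_len < 4 || seed_len > 31) stop("seed_len must be in [4, 31]");
  const uint64_t mask = (1ULL << (2 * seed_len)) - 1ULL;

  // seed table over queries, both orientations
  struct QSeed { int32_t query, pos; int8_t strand; };
  std::unordered_map<uint64_t, std::vector<QSeed>> table;
  std::vector<std::string> qs_fwd(queries.size()), qs_rev(queries.size());
  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    qs_fwd[qi] = std::string(CHAR(STRING_ELT(queries, qi)));
    qs_rev[qi] = revcomp_str(qs_fwd[qi]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand == 0 ? qs_fwd[qi] : qs_rev[qi];
      uint64_t v = 0;
      int valid = 0;
      for (int i = 0; i < (int)s.size(); ++i) {
        int b = encode_base(s[i]);
        if (b < 0) { valid = 0; v = 0; continue; }
        v = ((v << 2) | (uint64_t)b) & mask;
        if (++valid >= seed_len)
          table[v].push_back({(int32_t)qi, (int32_t)(i - seed_len + 1),
                              (int8_t)strand});
      }
    }
  }

  // best hit per (query, ref, strand, diagonal)
  std::unordered_map<uint64_t, LocalHit> best;
  for (R_xlen_t ri = 0; ri < refs.size(); ++ri) {
    const std::string rs = std::string(CHAR(STRING_ELT(refs, ri)));
    uint64_t v = 0;
    int valid = 0;
    for (int i = 0; i < (int)rs.size(); ++i) {
      int b = encode_base(rs[i]);
      if (b < 0) { valid = 0; v = 0; continue; }
      v = ((v << 2) | (uint64_t)b) & mask;
      if (++valid < seed_len) continue;
      auto it = table.find(v);
      if (it == table.end()) continue;
      int rpos = i - seed_len + 1;
      for (const QSeed& sd : it->second) {
        const std::string& qseq = sd.strand == 0 ? qs_fwd[sd.query]
                                                 : qs_rev[sd.query];
        int llen, lsc, lmt, rlen, rsc, rmt;
        extend_dir(qseq, rs, sd.pos - 1, rpos - 1, -1, match, mismatch,
                   xdrop, &llen, &lsc, &lmt);
        extend_dir(qseq, rs, sd.pos + seed_len, rpos + seed_len, +1, match,
                   mismatch, xdrop, &rlen, &rsc, &rmt);
        LocalHit h;
        h.query = sd.query; h.ref = (int)ri;
        h.strand = sd.strand == 0 ? 1 : -1;
        h.q_start = sd.pos - llen; h.q_end = sd.pos + seed_len + rlen;
        h.r_start = rpos - llen; h.r_end = rpos + seed_len + rlen;
        h.score = seed_len * match + lsc + rsc;
        h.matches = seed_len + lmt + rmt;
        int diag = rpos - sd.pos; // constant along an ungapped alignment
        uint64_t key = ((uint64_t)(uint32_t)sd.query << 40) ^
                       ((uint64_t)(uint32_t)ri << 20) ^
                       ((uint64_t)(uint32_t)(diag + (1 << 18)) << 1) ^
                       (uint64_t)sd.strand;
        auto bit = best.find(key);
        if (bit == best.end() || h.score > bit->second.score) best[key] = h;
      }
    }
  }

  std::vector<LocalHit> hits;
  hits.reserve(best.size());
  for (const auto& kv : best) hits.push_back(kv.second);
  std::sort(hits.begin(), hits.end(), [](const LocalHit& a, const LocalHit& b) {
    if (a.query != b.query) return a.query < b.query;
    if (a.ref != b.ref) return a.ref < b.ref;
    if (a.score != b.score) return a.score > b.score;
    if (a.r_start != b.r_start) return a.r_start < b.r_start;
    return a.strand > b.strand;
  });

  int n = (int)hits.size();
  IntegerVector o_query(n), o_ref(n), o_qstart(n), o_qend(n), o_rstart(n),
      o_rend(n), o_strand(n), o_score(n), o_len(n), o_matches(n);
  for (int i = 0; i < n; ++i) {
    const LocalHit& h = hits[i];
    int qlen = (int)qs_fwd[h.query].size();
    // report query coordinates on the original (forward) query
    int qs = h.q_start, qe = h.q_end;
    if (h.strand < 0) { qs = qlen - h.q_end; qe = qlen - h.q_start; }
    o_query[i] = h.query + 1; o_ref[i] = h.ref + 1;
    o_qstart[i] = qs + 1; o_qend[i] = qe;
    o_rstart[i] = h.r_start + 1; o_rend[i] = h.r_end;
    o_strand[i] = h.strand; o_score[i] = h.score;
    o_len[i] = h.q_end - h.q_start; o_matches[i] = h.matches;
  }
  return DataFrame::create(
    _["query"] = o_query, _["ref"] = o_ref,
    _["query_start"] = o_qstart, _["query_end"] = o_qend,
    _["ref_start"] = o_rstart, _["ref_end"] = o_rend,
    _["strand"] = o_strand, _["score"] = o_score,
    _["length"] = o_len, _["matches"] = o_matches);
}
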