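// k-mer seeded, band-verified species classifier for short reads against a
// dual-species transcriptome. Seeds are canonical (strand-collapsed) k-mers;
// candidate placements are verified gaplessly on +/- `band` diagonals around
// the seed diagonal (substitution-only error model, so gaps never pay under
// the match +1 / mismatch -1 / gap -2 scoring).
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

namespace {

static int codes[256];
static bool codes_ready = false;

inline void init_codes() {
  if (codes_ready) return;
  for (int i = 0; i < 256; ++i) codes[i] = -1;
  codes[(unsigned char)'A'] = 0; codes[(unsigned char)'a'] = 0;
  codes[(unsigned char)'C'] = 1; codes[(unsigned char)'c'] = 1;
  codes[(unsigned char)'G'] = 2; codes[(unsigned char)'g'] = 2;
  codes[(unsigned char)'T'] = 3; codes[(unsigned char)'t'] = 3;
  codes_ready = true;
}

inline uint64_t revcomp_kmer(uint64_t kmer, int k) {
  uint64_t rc = 0;
  for (int i = 0; i < k; ++i) {
    rc = (rc << 2) | (3ULL - (kmer & 3ULL));
    kmer >>= 2;
  }
  return rc;
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

struct KmerIndex {
  int k;
  // parallel arrays sorted by key
  std::vector<uint64_t> keys;
  // payload: bit0 = canonical-is-forward, bit1 = species (0 = A, 1 = B),
  // bits 2..23 transcript index, bits 24..55 position
  std::vector<uint64_t> payload;
  std::vector<std::string> seqs;
  std::vector<int> species;     // 0 = A, 1 = B
  std::vector<int> gene;        // gene index per transcript
  std::vector<std::string> tx_ids;
  std::vector<std::string> gene_ids;
};

inline uint64_t make_payload(bool fwd, int sp, uint32_t tx, uint32_t pos) {
  return (fwd ? 1ULL : 0ULL) | ((uint64_t)(sp & 1) << 1) |
         ((uint64_t)tx << 2) | ((uint64_t)pos << 24);
}
inline bool pl_fwd(uint64_t p) { return p & 1ULL; }
inline int pl_sp(uint64_t p) { return (int)((p >> 1) & 1ULL); }
inline uint32_t pl_tx(uint64_t p) { return (uint32_t)((p >> 2) & 0x3FFFFFULL); }
inline uint32_t pl_pos(uint64_t p) { return (uint32_t)(p >> 24); }

struct Candidate {
  uint32_t tx;
  int32_t diag;   // transcript position of read base 0 under this placement
  bool fwd;       // read aligns forward (true) or as reverse complement
};

struct SpeciesHit {
  bool mappable = false;
  double identity = 0.0;  // identity of the qualifying window at best placement
  int best_score = -1;    // full-overlap matches at best placement
  int best_tx = -1;       // lowest transcript index among best-scoring
  std::vector<int> best_genes; // genes attaining best_score
};

// Verify a candidate placement: gapless alignment of `read` (already
// orientation-resolved) to transcript at offsets diag-band .. diag+band.
// Mappability: some window of length win_len has <= max_mm mismatches.
// Score for gene ranking: matches over the full read/transcript overlap.
void verify_candidate(const std::string& tseq, const std::string& read,
                      int diag, int band, int win_len, int max_mm,
                      bool& mappable, double& identity, int& score) {
  const int L = (int)read.size();
  const int T = (int)tseq.size();
  mappable = false; identity = 0.0; score = -1;
  for (int shift = -band; shift <= band; ++shift) {
    int off = diag + shift;  // transcript coordinate of read base 0
    int rs = std::max(0, -off);          // first read base in overlap
    int re = std::min(L, T - off);       // one-past-last read base
    int n = re - rs;
    if (n < win_len) continue;
    // mismatch indicator over the overlap
    std::vector<uint8_t> mm((size_t)n);
    int full_matches = 0;
    for (int i = 0; i < n; ++i) {
      bool m = read[(size_t)(rs + i)] == tseq[(size_t)(off + rs + i)];
      mm[(size_t)i] = m ? 0 : 1;
      full_matches += m ? 1 : 0;
    }
    if (full_matches > score) score = full_matches;
    // sliding window of length win_len
    int wmm = 0;
    for (int i = 0; i < win_len; ++i) wmm += mm[(size_t)i];
    int best_wmm = wmm;
    for (int i = win_len; i < n; ++i) {
      wmm += mm[(size_t)i] - mm[(size_t)(i - win_len)];
      if (wmm < best_wmm) best_wmm = wmm;
    }
    if (best_wmm <= max_mm) {
      mappable = true;
      double id = (double)(win_len - best_wmm) / (double)win_len;
      if (id > identity) identity = id;
    }
  }
}

std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// Collect seed candidates for one read against the index.
void collect_candidates(const KmerIndex& idx, const std::string& read,
                        std::vector<Candidate>& cand_a,
                        std::vector<Candidate>& cand_b) {
  const int k = idx.k;
  const int L = (int)read.size();
  if (L < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int valid = 0;
  for (int i = 0; i < L; ++i) {
    int c = codes[(unsigned char)read[(size_t)i]];
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++valid < k) continue;
    int pos = i - k + 1;  // read position of this k-mer
    uint64_t rc = revcomp_kmer(kmer, k);
    bool read_fwd = kmer <= rc;
    uint64_t canon = read_fwd ? kmer : rc;
    auto lo = std::lower_bound(idx.keys.begin(), idx.keys.end(), canon);
    if (lo == idx.keys.end() || *lo != canon) continue;
    auto hi = std::upper_bound(lo, idx.keys.end(), canon);
    for (auto it = lo; it != hi; ++it) {
      uint64_t pl = idx.payload[(size_t)(it - idx.keys.begin())];
      bool fwd = (pl_fwd(pl) == read_fwd);
      int tpos = (int)pl_pos(pl);
      int diag;
      if (fwd) {
        diag = tpos - pos;
      } else {
        // read maps as reverse complement; k-mer at read pos `pos` sits at
        // revcomp-read position L - k - pos
        diag = tpos - (L - k - pos);
      }
      Candidate cd{pl_tx(pl), diag, fwd};
      std::vector<Candidate>& v = (pl_sp(pl) == 0) ? cand_a : cand_b;
      bool dup = false;
      for (const auto& e : v)
        if (e.tx == cd.tx && e.diag == cd.diag && e.fwd == cd.fwd) { dup = true; break; }
      if (!dup) v.push_back(cd);
    }
  }
}

SpeciesHit evaluate_species(const KmerIndex& idx, const std::string& read,
                            const std::string& read_rc,
                            const std::vector<Candidate>& cands,
                            int band, int win_len, int max_mm) {
  SpeciesHit hit;
  for (const auto& cd : cands) {
    const std::string& oriented = cd.fwd ? read : read_rc;
    bool mp; double id; int sc;
    verify_candidate(idx.seqs[cd.tx], oriented, cd.diag, band, win_len, max_mm,
                     mp, id, sc);
    if (mp) {
      hit.mappable = true;
      if (id > hit.identity) hit.identity = id;
    }
    if (sc > hit.best_score) {
      hit.best_score = sc;
      hit.best_tx = (int)cd.tx;
      hit.best_genes.clear();
      hit.best_genes.push_back(idx.gene[cd.tx]);
    } else if (sc == hit.best_score && sc >= 0) {
      int g = idx.gene[cd.tx];
      if (std::find(hit.best_genes.begin(), hit.best_genes.end(), g) ==
          hit.best_genes.end())
        hit.best_genes.push_back(g);
      if ((int)cd.tx < hit.best_tx) hit.best_tx = (int)cd.tx;
    }
  }
  return hit;
}

} // namespace

// [[Rcpp::export(name = ".xs_index_build")]]
SEXP xs_index_build(CharacterVector seqs, CharacterVector tx_ids,
                    IntegerVector species, CharacterVector gene_ids,
                    IntegerVector gene, int k) {
  init_codes();
  if (k < 1 || k > 31) stop("k must be in 1..31");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  size_t n = (size_t)seqs.size();
  idx->seqs.reserve(n);
  size_t total = 0;
  for (size_t t = 0; t < n; ++t) {
    std::string s = as<std::string>(seqs[(R_xlen_t)t]);
    if (s.size() >= (size_t)k) total += s.size() - (size_t)k + 1;
    idx->seqs.push_back(std::move(s));
    idx->species.push_back(species[(R_xlen_t)t]);
    idx->gene.push_back(gene[(R_xlen_t)t]);
    idx->tx_ids.push_back(as<std::string>(tx_ids[(R_xlen_t)t]));
  }
  for (R_xlen_t g = 0; g < gene_ids.size(); ++g)
    idx->gene_ids.push_back(as<std::string>(gene_ids[g]));
  idx->keys.reserve(total);
  idx->payload.reserve(total);
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  for (size_t t = 0; t < n; ++t) {
    const std::string& s = idx->seqs[t];
    uint64_t kmer = 0; int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = codes[(unsigned char)s[i]];
      if (c < 0) { valid = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++valid < k) continue;
      uint32_t pos = (uint32_t)(i - (size_t)k + 1);
      uint64_t rc = revcomp_kmer(kmer, k);
      bool fwd = kmer <= rc;
      idx->keys.push_back(fwd ? kmer : rc);
      idx->payload.push_back(make_payload(fwd, idx->species[t], (uint32_t)t, pos));
    }
  }
  // sort both arrays by key
  std::vector<size_t> ord(idx->keys.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return idx->keys[a] < idx->keys[b] ||
           (idx->keys[a] == idx->keys[b] && idx->payload[a] < idx->payload[b]);
  });
  std::vector<uint64_t> k2(ord.size()), p2(ord.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    k2[i] = idx->keys[ord[i]];
    p2[i] = idx->payload[ord[i]];
  }
  idx->keys.swap(k2);
  idx->payload.swap(p2);
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".xs_index_size")]]
double xs_index_size(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  return (double)idx->keys.size();
}

// [[Rcpp::export(name = ".xs_index_lookup")]]
DataFrame xs_index_lookup(SEXP xp, std::string kmer) {
  init_codes();
  XPtr<KmerIndex> idx(xp);
  int k = idx->k;
  if ((int)kmer.size() != k) stop("query length must equal index k");
  uint64_t key = 0;
  for (char c : kmer) {
    int b = codes[(unsigned char)c];
    if (b < 0) stop("query contains a non-ACGT base");
    key = (key << 2) | (uint64_t)b;
  }
  uint64_t rc = revcomp_kmer(key, k);
  uint64_t canon = std::min(key, rc);
  auto lo = std::lower_bound(idx->keys.begin(), idx->keys.end(), canon);
  auto hi = std::upper_bound(lo, idx->keys.end(), canon);
  std::vector<std::string> sp, tx;
  std::vector<int> pos;
  std::vector<bool> fwd;
  for (auto it = lo; it != hi && *it == canon; ++it) {
    uint64_t pl = idx->payload[(size_t)(it - idx->keys.begin())];
    sp.push_back(pl_sp(pl) == 0 ? "A" : "B");
    tx.push_back(idx->tx_ids[pl_tx(pl)]);
    pos.push_back((int)pl_pos(pl));
    fwd.push_back(pl_fwd(pl));
  }
  return DataFrame::create(_["species"] = sp, _["transcript_id"] = tx,
                           _["position"] = pos, _["canonical_is_forward"] = fwd,
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export(name = ".xs_classify")]]
DataFrame xs_classify(SEXP xp, CharacterVector reads1, Nullable<CharacterVector> reads2,
                      double min_identity, double min_coverage, int band) {
  init_codes();
  XPtr<KmerIndex> idx(xp);
  const bool paired = reads2.isNotNull();
  CharacterVector r2;
  if (paired) {
    r2 = reads2.get();
    if (r2.size() != reads1.size()) stop("mate vectors differ in length");
  }
  R_xlen_t n = reads1.size();
  IntegerVector cls(n);
  LogicalVector map_a(n), map_b(n), gene_tie(n);
  NumericVector id_a(n), id_b(n), identity(n);
  CharacterVector best_tx(n), best_gene(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    SpeciesHit ha, hb;
    int n_mates = paired ? 2 : 1;
    // aggregate per-gene scores across mates for gene assignment
    std::vector<std::pair<int,int>> gene_best_a, gene_best_b; // (gene, score sum)
    int tx_a = -1, tx_b = -1;
    for (int m = 0; m < n_mates; ++m) {
      std::string rd = as<std::string>(m == 0 ? reads1[i] : r2[i]);
      int L = (int)rd.size();
      int win_len = (int)std::ceil(min_coverage * (double)L);
      if (win_len < 1) win_len = 1;
      int max_mm = (int)std::floor((1.0 - min_identity) * (double)win_len);
      std::string rc = revcomp_str(rd);
      std::vector<Candidate> ca, cb;
      collect_candidates(*idx, rd, ca, cb);
      SpeciesHit a = evaluate_species(*idx, rd, rc, ca, band, win_len, max_mm);
      SpeciesHit b = evaluate_species(*idx, rd, rc, cb, band, win_len, max_mm);
      // pair species-mappability is the OR over mates
      if (a.mappable) { ha.mappable = true; if (a.identity > ha.identity) ha.identity = a.identity; }
      if (b.mappable) { hb.mappable = true; if (b.identity > hb.identity) hb.identity = b.identity; }
      auto fold = [](std::vector<std::pair<int,int>>& acc, const SpeciesHit& h) {
        if (h.best_score < 0) return;
        for (int g : h.best_genes) {
          bool found = false;
          for (auto& e : acc) if (e.first == g) { e.second += h.best_score; found = true; break; }
          if (!found) acc.push_back({g, h.best_score});
        }
      };
      fold(gene_best_a, a);
      fold(gene_best_b, b);
      if (a.best_tx >= 0 && (tx_a < 0 || a.best_score > 0)) tx_a = a.best_tx;
      if (b.best_tx >= 0 && (tx_b < 0 || b.best_score > 0)) tx_b = b.best_tx;
    }
    map_a[i] = ha.mappable; map_b[i] = hb.mappable;
    id_a[i] = ha.mappable ? ha.identity : NA_REAL;
    id_b[i] = hb.mappable ? hb.identity : NA_REAL;
    int code;
    if (ha.mappable && hb.mappable) code = 3;        // ambiguous
    else if (ha.mappable) code = 1;                  // species A
    else if (hb.mappable) code = 2;                  // species B
    else code = 4;                                   // unmapped
    cls[i] = code;
    bool tie = false;
    int g_assigned = -1, tx_assigned = -1;
    double id_assigned = NA_REAL;
    if (code == 1 || code == 2) {
      const std::vector<std::pair<int,int>>& acc = (code == 1) ? gene_best_a : gene_best_b;
      int best = -1;
      for (const auto& e : acc) if (e.second > best) best = e.second;
      int n_best = 0;
      for (const auto& e : acc) if (e.second == best) { ++n_best; g_assigned = std::min(g_assigned < 0 ? e.first : g_assigned, e.first); }
      tie = n_best > 1;
      tx_assigned = (code == 1) ? tx_a : tx_b;
      id_assigned = (code == 1) ? id_a[i] : id_b[i];
    }
    gene_tie[i] = tie;
    identity[i] = id_assigned;
    if (tx_assigned >= 0 && (code == 1 || code == 2)) {
      best_tx[i] = idx->tx_ids[(size_t)tx_assigned];
      best_gene[i] = (tie || g_assigned < 0) ? NA_STRING : String(idx->gene_ids[(size_t)g_assigned]);
    } else {
      best_tx[i] = NA_STRING;
      best_gene[i] = NA_STRING;
    }
  }
  return DataFrame::create(
      _["class_code"] = cls, _["mappable_a"] = map_a, _["mappable_b"] = map_b,
      _["identity_a"] = id_a, _["identity_b"] = id_b,
      _["best_transcript"] = best_tx, _["best_gene"] = best_gene,
      _["gene_tie"] = gene_tie, _["identity"] = identity,
      _["stringsAsFactors"] = false);
}

// Fast substring extraction for read simulation: reads[i] is
// seqs[tx[i]][start[i] .. start[i]+len-1] (0-based starts).
// [[Rcpp::export(name = ".xs_extract_reads")]]
CharacterVector xs_extract_reads(CharacterVector seqs, IntegerVector tx,
                                 IntegerVector start, int len) {
  R_xlen_t n = tx.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[tx[i]]);
    out[i] = s.substr((size_t)start[i], (size_t)len);
  }
  return out;
}

// Apply point substitutions to reads. read_idx is 1-based into `reads`,
// pos is 0-based within the read; entries for the same read accumulate.
// [[Rcpp::export(name = ".xs_apply_substitutions")]]
CharacterVector xs_apply_substitutions(CharacterVector reads,
                                       IntegerVector read_idx,
                                       IntegerVector pos,
                                       CharacterVector base) {
  CharacterVector out = clone(reads);
  R_xlen_t m = read_idx.size();
  for (R_xlen_t i = 0; i < m; ++i) {
    std::string s = as<std::string>(out[read_idx[i] - 1]);
    std::string b = as<std::string>(base[i]);
    s[(size_t)pos[i]] = b[0];
    out[read_idx[i] - 1] = s;
  }
  return out;
}
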