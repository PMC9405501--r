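#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <functional>
using namespace Rcpp;

// 2-bit encoding; -1 for non-ACGT
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct AnchorHit {
  int32_t seq_idx;   // index into donor sequence list
  int32_t pos;       // 0-based offset of k-mer start on donor
  bool fwd_is_canon; // canonical form == forward strand of donor
};

struct AnchorIndex {
  int k;
  int max_occ;
  std::unordered_map<uint64_t, std::vector<AnchorHit>> map;
};

// canonical code of the k-mer starting at i, or false if it contains non-ACGT.
// Rolling encodes are handled by the callers to keep this O(1) per step.
static void scan_kmers(const std::string& s, int k,
                       const std::function<void(uint64_t, int, bool)>& emit) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int c = base_code(s[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++valid >= k) {
      bool fwd_canon = fwd <= rev;
      emit(fwd_canon ? fwd : rev, (int)(i - k + 1), fwd_canon);
    }
  }
}

// [[Rcpp::export]]
SEXP cpp_build_anchor_index(CharacterVector seqs, int k, int max_occ) {
  AnchorIndex* idx = new AnchorIndex();
  idx->k = k;
  idx->max_occ = max_occ;
  for (int s = 0; s < seqs.size(); ++s) {
    std::string str = as<std::string>(seqs[s]);
    scan_kmers(str, k, [&](uint64_t key, int pos, bool fwd_canon) {
      auto& v = idx->map[key];
      // one extra slot marks "over max_occ"; purged below
      if ((int)v.size() <= max_occ)
        v.push_back(AnchorHit{(int32_t)s, (int32_t)pos, fwd_canon});
    });
  }
  // drop repetitive k-mers
  for (auto it = idx->map.begin(); it != idx->map.end();) {
    if ((int)it->second.size() > max_occ) it = idx->map.erase(it);
    else ++it;
  }
  XPtr<AnchorIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) {
  XPtr<AnchorIndex> idx(xp);
  return (int)idx->map.size();
}

// Query a scaffold against the index. Returns one row per (query k-mer,
// donor occurrence) pair: qpos/rpos are 0-based k-mer starts, strand is +1 if
// the scaffold k-mer matches the donor forward strand, -1 if reverse.
// [[Rcpp::export]]
DataFrame cpp_query_anchors(SEXP xp, std::string scaffold) {
  XPtr<AnchorIndex> idx(xp);
  std::vector<int> qpos, ridx, rpos, strand;
  scan_kmers(scaffold, idx->k, [&](uint64_t key, int pos, bool q_fwd_canon) {
    auto it = idx->map.find(key);
    if (it == idx->map.end()) return;
    for (const AnchorHit& h : it->second) {
      qpos.push_back(pos);
      ridx.push_back(h.seq_idx + 1);
      rpos.push_back(h.pos);
      strand.push_back(q_fwd_canon == h.fwd_is_canon ? 1 : -1);
    }
  });
  return DataFrame::create(_["qpos"] = qpos, _["ref_seq"] = ridx,
                           _["rpos"] = rpos, _["strand"] = strand);
}

// Per-base depth over concatenated scaffold coordinate space.
// offsets[i] is the 0-based start of scaffold i in the concatenated vector;
// reads contribute +1 at covered positions whose base quality passes
// min_baseq (qual strings are Phred+33) for reads with mapq >= min_mapq.
// [[Rcpp::export]]
IntegerVector cpp_depth_concat(IntegerVector scaf_idx, IntegerVector start,
                               CharacterVector qual, IntegerVector mapq,
                               IntegerVector offsets, IntegerVector scaf_len,
                               int min_mapq, int min_baseq, int total_len) {
  IntegerVector depth(total_len);
  int n = scaf_idx.size();
  for (int i = 0; i < n; ++i) {
    if (mapq[i] < min_mapq) continue;
    int s = scaf_idx[i] - 1;
    int off = offsets[s];
    int slen = scaf_len[s];
    const char* q = CHAR(STRING_ELT(qual, i));
    int rl = (int)LENGTH(STRING_ELT(qual, i));
    int st = start[i];
    for (int j = 0; j < rl; ++j) {
      int p = st + j;
      if (p < 0 || p >= slen) continue;
      if ((int)q[j] - 33 >= min_baseq) depth[off + p] += 1;
    }
  }
  return depth;
}
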