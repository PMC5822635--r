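// Gapless k-mer-seeded sequence comparison kernels.
//
// Shared machinery: a hash index from 2-bit-encoded k-mers to (sequence,
// position) occurrences.  Candidate alignments between two sequences are
// diagonals (offset differences) voted for by shared k-mers; the one or two
// most-voted diagonals are evaluated by direct gapless column comparison.
// Substitution-only alignments are exact on such data; on gapped data this
// is a documented heuristic (an exact Smith-Waterman path exists in R).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// Visit all exact k-mers (skipping any window containing a non-ACGT base).
// f(code, pos) is called with the 2-bit encoding and 0-based start position.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) f(code, (int)(i + 1 - k));
  }
}

typedef std::unordered_map<uint64_t, std::vector<uint64_t> > KmerIndex;

static inline uint64_t pack_occ(int seq_id, int pos) {
  return ((uint64_t)seq_id << 32) | (uint32_t)pos;
}

// Count matching columns of a gapless alignment a[p] ~ b[p - diag].
static inline void overlap_identity(const std::string& a, const std::string& b,
                                    int diag, int& matches, int& ovl) {
  int start = std::max(0, diag);
  int end = std::min((int)a.size(), (int)b.size() + diag);
  matches = 0;
  ovl = end - start;
  if (ovl <= 0) { ovl = 0; return; }
  for (int p = start; p < end; ++p) {
    if (a[p] == b[p - diag] && base_code(a[p]) >= 0) ++matches;
  }
}

// Candidate (target, strand, diagonal) packed for sorting/grouping.
// diag is shifted to be non-negative; sequences are assumed < 2^27 long.
static inline uint64_t pack_cand(int target, int strand, int diag) {
  return ((uint64_t)target << 30) | ((uint64_t)strand << 29) |
         (uint64_t)(diag + (1 << 28));
}
static inline int cand_target(uint64_t c) { return (int)(c >> 30); }
static inline int cand_strand(uint64_t c) { return (int)((c >> 29) & 1ULL); }
static inline int cand_diag(uint64_t c) {
  return (int)(c & ((1ULL << 29) - 1)) - (1 << 28);
}

// From a sorted candidate vector, evaluate at most the two most-voted
// diagonals per (target, strand) group through `eval`.
template <typename Eval>
static void scan_candidates(std::vector<uint64_t>& cand, Eval eval) {
  std::sort(cand.begin(), cand.end());
  size_t i = 0;
  const size_t n = cand.size();
  while (i < n) {
    int tgt = cand_target(cand[i]);
    int strand = cand_strand(cand[i]);
    // locate group end
    size_t j = i;
    int best_diag = 0, best_votes = 0, second_diag = 0, second_votes = 0;
    while (j < n && cand_target(cand[j]) == tgt && cand_strand(cand[j]) == strand) {
      size_t r = j;
      while (r < n && cand[r] == cand[j]) ++r;
      int votes = (int)(r - j);
      int diag = cand_diag(cand[j]);
      if (votes > best_votes) {
        second_votes = best_votes; second_diag = best_diag;
        best_votes = votes; best_diag = diag;
      } else if (votes > second_votes) {
        second_votes = votes; second_diag = diag;
      }
      j = r;
    }
    eval(tgt, strand, best_diag, true);
    if (second_votes > 0 && second_diag != best_diag) eval(tgt, strand, second_diag, false);
    i = j;
  }
}

// [[Rcpp::export]]
DataFrame cpp_similarity_edges(CharacterVector seqs, int k, double min_sim,
                               double min_ovl_frac) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp(fwd[i]);
  }

  KmerIndex index;
  std::vector<int> out_i, out_j, out_ovl;
  std::vector<double> out_sim;
  std::vector<int> out_orient;  // 0 = forward, 1 = reverse

  std::vector<uint64_t> cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    // forward k-mers of i vs the index of reads < i
    for_each_kmer(fwd[i], k, [&](uint64_t code, int p) {
      KmerIndex::const_iterator it = index.find(code);
      if (it == index.end()) return;
      for (uint64_t occ : it->second) {
        int j = (int)(occ >> 32);
        int q = (int)(uint32_t)(occ & 0xffffffffULL);
        cand.push_back(pack_cand(j, 0, p - q));
      }
    });
    // reverse-complement k-mers of i vs the same index
    for_each_kmer(rc[i], k, [&](uint64_t code, int p) {
      KmerIndex::const_iterator it = index.find(code);
      if (it == index.end()) return;
      for (uint64_t occ : it->second) {
        int j = (int)(occ >> 32);
        int q = (int)(uint32_t)(occ & 0xffffffffULL);
        cand.push_back(pack_cand(j, 1, p - q));
      }
    });

    // best result per target j over both strands
    int cur_j = -1;
    int bm = -1, bo = 0, bstrand = 0;
    auto flush = [&]() {
      if (cur_j < 0 || bo <= 0) return;
      int min_len = std::min((int)fwd[i].size(), (int)fwd[cur_j].size());
      double need = min_ovl_frac * (double)min_len;
      double sim = (double)bm / (double)bo;
      if (sim >= min_sim - 1e-12 && (double)bo >= need - 1e-9) {
        out_i.push_back(i + 1);
        out_j.push_back(cur_j + 1);
        out_sim.push_back(sim);
        out_ovl.push_back(bo);
        out_orient.push_back(bstrand);
      }
    };
    scan_candidates(cand, [&](int j, int strand, int diag, bool /*primary*/) {
      if (j != cur_j) { flush(); cur_j = j; bm = -1; bo = 0; bstrand = 0; }
      int matches, ovl;
      const std::string& a = strand == 0 ? fwd[i] : rc[i];
      overlap_identity(a, fwd[j], diag, matches, ovl);
      // prefer more matches, then longer overlap, then forward strand
      if (matches > bm || (matches == bm && ovl > bo)) {
        bm = matches; bo = ovl; bstrand = strand;
      }
    });
    flush();

    // now index read i
    for_each_kmer(fwd[i], k, [&](uint64_t code, int p) {
      index[code].push_back(pack_occ(i, p));
    });
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  CharacterVector orient(out_orient.size());
  for (size_t t = 0; t < out_orient.size(); ++t)
    orient[t] = out_orient[t] == 0 ? "F" : "R";
  return DataFrame::create(_["i"] = out_i, _["j"] = out_j,
                           _["similarity"] = out_sim,
                           _["overlap"] = out_ovl,
                           _["orientation"] = orient,
                           _["stringsAsFactors"] = false);
}

// Map each read to its single best gapless placement on a set of contigs.
// Returns 0-based offsets (possibly negative: read overhangs the contig
// start); matches/ovl are counted over the overlapping columns only.
// Ties broken by more matches, then lower contig index, then lower offset,
// then forward strand.
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs, int k,
                        double min_identity, int min_overlap) {
  const int n = reads.size(), m = contigs.size();
  std::vector<std::string> ctg(m);
  KmerIndex index;
  for (int j = 0; j < m; ++j) {
    ctg[j] = as<std::string>(contigs[j]);
    for_each_kmer(ctg[j], k, [&](uint64_t code, int p) {
      index[code].push_back(pack_occ(j, p));
    });
  }

  IntegerVector out_contig(n, NA_INTEGER), out_off(n, NA_INTEGER),
      out_matches(n, NA_INTEGER), out_ovl(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);

  std::vector<uint64_t> cand;
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rc = revcomp(fwd);
    cand.clear();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand == 0 ? fwd : rc;
      for_each_kmer(s, k, [&](uint64_t code, int p) {
        KmerIndex::const_iterator it = index.find(code);
        if (it == index.end()) return;
        for (uint64_t occ : it->second) {
          int j = (int)(occ >> 32);
          int q = (int)(uint32_t)(occ & 0xffffffffULL);
          cand.push_back(pack_cand(j, strand, p - q));
        }
      });
    }
    int bm = -1, bovl = 0, bcontig = -1, boff = 0, bstrand = 0;
    scan_candidates(cand, [&](int j, int strand, int diag, bool) {
      int matches, ovl;
      const std::string& a = strand == 0 ? fwd : rc;
      overlap_identity(a, ctg[j], diag, matches, ovl);  // a[p] ~ ctg[p - diag]
      if (ovl < min_overlap) return;
      if ((double)matches < min_identity * (double)ovl - 1e-9) return;
      int off = -diag;  // read position 0 sits at contig position -diag
      bool better = matches > bm ||
        (matches == bm && (j < bcontig ||
          (j == bcontig && (off < boff ||
            (off == boff && strand < bstrand)))));
      if (better) { bm = matches; bovl = ovl; bcontig = j; boff = off; bstrand = strand; }
    });
    if (bm >= 0) {
      out_contig[i] = bcontig + 1;
      out_off[i] = boff;
      out_matches[i] = bm;
      out_ovl[i] = bovl;
      out_strand[i] = bstrand == 0 ? "F" : "R";
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["contig"] = out_contig, _["offset"] = out_off,
                           _["strand"] = out_strand, _["matches"] = out_matches,
                           _["aln_len"] = out_ovl,
                           _["stringsAsFactors"] = false);
}

// Per-contig base counts from gapless placements.  `oriented` must already
// be on the contig strand; columns outside [0, contig_len) are clipped.
// Returns one 4 x L integer matrix (rows A,C,G,T) per contig.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector contig_idx, IntegerVector offset,
                CharacterVector oriented, IntegerVector contig_len) {
  const int m = contig_len.size();
  std::vector<IntegerMatrix> mats;
  for (int j = 0; j < m; ++j) mats.push_back(IntegerMatrix(4, contig_len[j]));
  const int n = contig_idx.size();
  for (int i = 0; i < n; ++i) {
    if (contig_idx[i] == NA_INTEGER) continue;
    int j = contig_idx[i] - 1;
    if (j < 0 || j >= m) stop("contig index out of range");
    std::string s = as<std::string>(oriented[i]);
    int off = offset[i];
    int L = contig_len[j];
    for (int p = 0; p < (int)s.size(); ++p) {
      int pos = off + p;
      if (pos < 0 || pos >= L) continue;
      int b = base_code(s[p]);
      if (b >= 0) mats[j](b, pos) += 1;
    }
  }
  List out(m);
  for (int j = 0; j < m; ++j) out[j] = mats[j];
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}
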