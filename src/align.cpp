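// Desk-scale seed-and-extend read alignment.
//
// Seeding: exact match of the read's 5'-most k-mer against both strands of
// every reference sequence.  Extension: banded dynamic programming toward the
// read 3' end allowing mismatches and short reference deletions (the
// reverse-transcriptase microdeletion signature); unextendable trailing bases
// become a 3' soft clip so non-templated tails survive alignment.

#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <cstdint>
#include <vector>
#include <string>

using namespace Rcpp;

static const int NEG = -100000000;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

static inline int base2code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// 2-bit encode a k-mer; returns false if it contains N.
static bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base2code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

struct Candidate {
  int ref;      // reference index
  int strandrc; // 0 = forward, 1 = reverse complement
  int pos;      // seed position on the strand sequence
};

struct AlnResult {
  int ref = -1;
  int strandrc = 0;
  long fwd_start = -1;
  int score = NEG;
  int aligned = 0;   // read bases consumed (soft clip = L - aligned)
  int dtotal = 0;
  std::string cigar; // forward-reference order, including trailing/leading S
  int n_best = 0;
};

// Extend read r at position p0 of strand sequence S.  Returns best score and
// fills aligned length, total deletion and read-space op list via refs.
static int extend_read(const std::string& r, const std::string& S, int p0,
                       int max_del_total, int max_del_event,
                       int match, int mismatch, int gap_pen,
                       int& best_i, int& best_d,
                       std::vector<std::vector<int>>& gpar_out) {
  const int L = (int)r.size();
  const int D = max_del_total;
  // score[i][d]: best score after consuming i read bases with d reference
  // bases deleted, gaps already relaxed within the row.
  std::vector<std::vector<int>> score(L + 1, std::vector<int>(D + 1, NEG));
  gpar_out.assign(L + 1, std::vector<int>(D + 1, -1));
  score[0][0] = 0;
  int best = NEG; best_i = 0; best_d = 0;
  for (int i = 0; i < L; ++i) {
    if (i > 0) { // gap events (reference deletion) between consumed bases
      for (int d = 0; d <= D; ++d) {
        if (score[i][d] == NEG) continue;
        for (int g = 1; g <= max_del_event && d + g <= D; ++g) {
          int cand = score[i][d] - gap_pen;
          if (cand > score[i][d + g]) {
            score[i][d + g] = cand;
            gpar_out[i][d + g] = d;
          }
        }
      }
    }
    for (int d = 0; d <= D; ++d) {
      if (score[i][d] == NEG) continue;
      long rp = (long)p0 + i + d;
      if (rp >= (long)S.size()) continue;
      char rc = r[i], gc = S[rp];
      int sc = (rc == gc && rc != 'N') ? match : mismatch;
      if (score[i][d] + sc > score[i + 1][d]) {
        score[i + 1][d] = score[i][d] + sc;
        // consume parent is (i, d) by construction
      }
    }
    // Track the best prefix (trailing bases become the 3' soft clip).  Ties
    // prefer the shorter extension: only strictly score-improving segments
    // are aligned, and exactly templated clip prefixes are re-absorbed by
    // the downstream tail-calling step.
    for (int d = 0; d <= D; ++d) {
      int s = score[i + 1][d];
      if (s == NEG) continue;
      if (s > best || (s == best && (i + 1 < best_i || (i + 1 == best_i && d < best_d)))) {
        best = s; best_i = i + 1; best_d = d;
      }
    }
  }
  return best;
}

// Reconstruct the read-space op list (M/D runs) for the best cell.
static std::vector<std::pair<int, char>> traceback(
    int best_i, int best_d, const std::vector<std::vector<int>>& gpar) {
  std::vector<std::pair<int, char>> ops; // reversed
  int i = best_i, d = best_d;
  while (i > 0 || d > 0) {
    if (d > 0 && gpar[i][d] != -1) {
      int pd = gpar[i][d];
      ops.push_back(std::make_pair(d - pd, 'D'));
      d = pd;
    } else {
      ops.push_back(std::make_pair(1, 'M'));
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // merge adjacent ops of the same kind
  std::vector<std::pair<int, char>> merged;
  for (auto& op : ops) {
    if (!merged.empty() && merged.back().second == op.second) {
      merged.back().first += op.first;
    } else merged.push_back(op);
  }
  return merged;
}

static std::string ops_to_cigar(const std::vector<std::pair<int, char>>& ops) {
  std::string out;
  for (auto& op : ops) {
    out += std::to_string(op.first);
    out += op.second;
  }
  return out;
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads,
                     CharacterVector ref_seqs,
                     LogicalVector allow_rc,
                     IntegerVector boundary,
                     int k = 12,
                     int max_del_total = 6,
                     int max_del_event = 3,
                     int match = 1,
                     int mismatch = -2,
                     int gap_pen = 3) {
  const int nref = ref_seqs.size();
  std::vector<std::string> fwd(nref), rc(nref);
  for (int i = 0; i < nref; ++i) {
    fwd[i] = as<std::string>(ref_seqs[i]);
    if (allow_rc[i]) rc[i] = revcomp_str(fwd[i]);
  }
  // k-mer index over both strands; position packed as ref * 2 + strand
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  for (int i = 0; i < nref; ++i) {
    for (int sb = 0; sb < 2; ++sb) {
      const std::string& S = (sb == 0) ? fwd[i] : rc[i];
      if ((int)S.size() < k) continue;
      for (int p = 0; p + k <= (int)S.size(); ++p) {
        uint64_t key;
        if (encode_kmer(S.c_str() + p, k, key)) {
          index[key].push_back(std::make_pair(i * 2 + sb, p));
        }
      }
    }
  }

  const int n = reads.size();
  IntegerVector out_ref(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  IntegerVector out_start(n, NA_INTEGER);
  CharacterVector out_cigar(n, NA_STRING);
  IntegerVector out_score(n, NA_INTEGER);
  IntegerVector out_nbest(n, 0);
  IntegerVector out_clip3(n, NA_INTEGER);
  LogicalVector out_mapped(n, false);

  std::vector<std::vector<int>> gpar;
  for (int ri = 0; ri < n; ++ri) {
    std::string r = as<std::string>(reads[ri]);
    const int L = (int)r.size();
    if (L < k) continue;
    uint64_t key;
    if (!encode_kmer(r.c_str(), k, key)) continue;
    auto it = index.find(key);
    if (it == index.end()) continue;

    AlnResult best;
    std::vector<std::pair<long, long>> best_loci; // (refcode, fwd_start)
    for (auto& hit : it->second) {
      int refi = hit.first / 2, sb = hit.first % 2;
      const std::string& S = (sb == 0) ? fwd[refi] : rc[refi];
      int bi, bd;
      int sc = extend_read(r, S, hit.second, max_del_total, max_del_event,
                           match, mismatch, gap_pen, bi, bd, gpar);
      if (sc <= NEG / 2) continue;
      int refspan = bi + bd;
      // junction entries are only valid loci for boundary-crossing alignments;
      // one-sided hits are redundant with the genomic locus
      if (boundary[refi] >= 0) {
        int b = boundary[refi];
        if (!(hit.second < b && hit.second + refspan > b)) continue;
      }
      long fstart = (sb == 0) ? (long)hit.second
                              : (long)S.size() - (hit.second + refspan);
      if (sc > best.score ||
          (sc == best.score &&
           (refi < best.ref ||
            (refi == best.ref &&
             (fstart < best.fwd_start ||
              (fstart == best.fwd_start && sb < best.strandrc)))))) {
        if (sc > best.score) best_loci.clear();
        best.score = sc; best.ref = refi; best.strandrc = sb;
        best.fwd_start = fstart; best.aligned = bi; best.dtotal = bd;
        auto ops = traceback(bi, bd, gpar);
        if (bi < L) ops.push_back(std::make_pair(L - bi, 'S'));
        if (sb == 1) std::reverse(ops.begin(), ops.end());
        best.cigar = ops_to_cigar(ops);
      }
      if (sc == best.score) {
        long code = (long)refi * 4 + sb;
        std::pair<long, long> locus(code, fstart);
        bool seen = false;
        for (auto& l : best_loci) if (l == locus) { seen = true; break; }
        if (!seen) best_loci.push_back(locus);
      }
    }
    if (best.ref < 0) continue;
    out_ref[ri] = best.ref + 1;
    out_strand[ri] = best.strandrc == 0 ? "+" : "-";
    out_start[ri] = (int)best.fwd_start;
    out_cigar[ri] = best.cigar;
    out_score[ri] = best.score;
    out_nbest[ri] = (int)best_loci.size();
    out_clip3[ri] = L - best.aligned;
    out_mapped[ri] = true;
  }

  return List::create(
    _["ref"] = out_ref, _["strand"] = out_strand, _["start"] = out_start,
    _["cigar"] = out_cigar, _["score"] = out_score, _["n_best"] = out_nbest,
    _["clip3"] = out_clip3, _["mapped"] = out_mapped);
}

// Adapter trimming: remove the longest read suffix matching a prefix of the
// adapter with at least min_overlap matched nt and at most one mismatch.
// Returns the trimmed length of each read.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap = 5, int max_mismatch = 1) {
  const int n = reads.size();
  const int alen = (int)adapter.size();
  IntegerVector out(n);
  for (int ri = 0; ri < n; ++ri) {
    std::string r = as<std::string>(reads[ri]);
    const int L = (int)r.size();
    int keep = L;
    for (int p = 0; p <= L - min_overlap; ++p) { // leftmost match wins
      int mlen = std::min(L - p, alen);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < mlen; ++j) {
        if (r[p + j] != adapter[j]) {
          if (++mm > max_mismatch) { ok = false; break; }
        }
      }
      if (ok && mlen >= min_overlap) { keep = p; break; }
    }
    out[ri] = keep;
  }
  return out;
}
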