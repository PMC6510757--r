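// Brute-force reference enumerator for stem-loop detection.
//
// Independently coded cross-check for the banded search in hairpin_search.cpp:
// enumerates every (loop interval, stem length, bulge placement) partition and
// tests the constraints one by one, recomputing the paired positions and the
// mismatch count from scratch for every partition.  No incremental
// bookkeeping is shared with the optimized search; only the *definition* of a
// reported hairpin is common (see hairpin_search.cpp for that definition).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

inline char wc_complement(char c) {
  if (c == 'A') return 'T';
  if (c == 'T') return 'A';
  if (c == 'C') return 'G';
  if (c == 'G') return 'C';
  return '\0';  // N has no complement
}

inline bool is_pair(char left, char right, bool wobble) {
  const char comp = wc_complement(left);
  if (comp != '\0' && right == comp) return true;
  if (wobble && ((left == 'G' && right == 'T') || (left == 'T' && right == 'G')))
    return true;
  return false;
}

struct Partition {
  int loop_start, loop_end, stem, mismatches;
  int bulge_left_len, bulge_left_offset, bulge_right_len, bulge_right_offset;
};

inline int left_pos(const Partition &p, int t) {
  return p.loop_start - 1 - t -
         ((p.bulge_left_len > 0 && t >= p.bulge_left_offset)
              ? p.bulge_left_len : 0);
}

inline int right_pos(const Partition &p, int t) {
  return p.loop_end + t +
         ((p.bulge_right_len > 0 && t >= p.bulge_right_offset)
              ? p.bulge_right_len : 0);
}

// (stem desc, mismatches asc, total bulge asc) -- must agree with the
// optimized search; all partitions tying on this triple are reported.
inline bool outranks(const Partition &x, const Partition &y) {
  if (x.stem != y.stem) return x.stem > y.stem;
  if (x.mismatches != y.mismatches) return x.mismatches < y.mismatches;
  return x.bulge_left_len + x.bulge_right_len <
         y.bulge_left_len + y.bulge_right_len;
}

inline bool rank_ties(const Partition &x, const Partition &y) {
  return x.stem == y.stem && x.mismatches == y.mismatches &&
         x.bulge_left_len + x.bulge_right_len ==
             y.bulge_left_len + y.bulge_right_len;
}

}  // namespace

// [[Rcpp::export(name = ".hairpin_enum_cpp")]]
DataFrame hairpin_enum_cpp(std::string seq, int stem_min, int stem_max,
                           int loop_min, int loop_max, int max_mm,
                           int max_bulge, bool wobble) {
  const int n = static_cast<int>(seq.size());
  std::vector<Partition> winners;

  for (int a = 0; a < n; ++a) {
    for (int llen = loop_min; llen <= loop_max; ++llen) {
      const int b = a + llen;
      // The innermost pair (a-1, b) is part of every partition of this loop
      // and must be a Watson-Crick pair.
      if (a - 1 < 0 || b >= n) continue;
      if (!is_pair(seq[a - 1], seq[b], wobble)) continue;

      std::vector<Partition> best;

      for (int k = stem_min; k <= stem_max; ++k) {
        for (int bl = 0; bl <= max_bulge; ++bl) {
          for (int gl = (bl == 0 ? 0 : 1); gl <= (bl == 0 ? 0 : k - 1); ++gl) {
            for (int br = 0; br <= max_bulge; ++br) {
              for (int gr = (br == 0 ? 0 : 1); gr <= (br == 0 ? 0 : k - 1);
                   ++gr) {
                Partition p;
                p.loop_start = a; p.loop_end = b; p.stem = k;
                p.bulge_left_len = bl; p.bulge_left_offset = (bl == 0 ? 0 : gl);
                p.bulge_right_len = br;
                p.bulge_right_offset = (br == 0 ? 0 : gr);

                // Bounds: outermost paired positions must exist.
                if (left_pos(p, k - 1) < 0) continue;
                if (right_pos(p, k - 1) >= n) continue;
                // A stem must close on a Watson-Crick pair.
                if (!is_pair(seq[left_pos(p, k - 1)],
                             seq[right_pos(p, k - 1)], wobble))
                  continue;

                int mism = 0;
                for (int t = 0; t < k; ++t) {
                  if (!is_pair(seq[left_pos(p, t)], seq[right_pos(p, t)],
                               wobble))
                    if (++mism > max_mm) break;
                }
                if (mism > max_mm) continue;
                p.mismatches = mism;

                if (best.empty() || outranks(p, best.front())) {
                  best.clear();
                  best.push_back(p);
                } else if (rank_ties(p, best.front())) {
                  best.push_back(p);
                }
              }
            }
          }
        }
      }
      for (size_t q = 0; q < best.size(); ++q) winners.push_back(best[q]);
    }
  }

  // Maximality filter: discard partitions whose paired positions are all
  // contained in some other winner's paired positions.
  std::vector<bool> dominated(winners.size(), false);
  for (size_t i = 0; i < winners.size(); ++i) {
    for (size_t j = 0; j < winners.size(); ++j) {
      if (i == j || dominated[i]) continue;
      if (winners[j].stem <= winners[i].stem) continue;
      bool all_in = true;
      for (int u = 0; u < winners[i].stem && all_in; ++u) {
        bool hit = false;
        for (int v = 0; v < winners[j].stem; ++v) {
          if (left_pos(winners[j], v) == left_pos(winners[i], u) &&
              right_pos(winners[j], v) == right_pos(winners[i], u)) {
            hit = true;
            break;
          }
        }
        all_in = hit;
      }
      if (all_in) dominated[i] = true;
    }
  }

  std::vector<int> la, lb, lk, lmm, lbl, lgl, lbr, lgr;
  for (size_t i = 0; i < winners.size(); ++i) {
    if (dominated[i]) continue;
    la.push_back(winners[i].loop_start);
    lb.push_back(winners[i].loop_end);
    lk.push_back(winners[i].stem);
    lmm.push_back(winners[i].mismatches);
    lbl.push_back(winners[i].bulge_left_len);
    lgl.push_back(winners[i].bulge_left_offset);
    lbr.push_back(winners[i].bulge_right_len);
    lgr.push_back(winners[i].bulge_right_offset);
  }

  return DataFrame::create(
      _["loop_start"] = la, _["loop_end"] = lb, _["stem_length"] = lk,
      _["mismatch_count"] = lmm, _["bulge_left_len"] = lbl,
      _["bulge_left_offset"] = lgl, _["bulge_right_len"] = lbr,
      _["bulge_right_offset"] = lgr);
}
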