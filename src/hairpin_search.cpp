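// Banded stem-loop search.
//
// A hairpin candidate is parameterised by a loop interval [a, b), a stem of k
// paired positions per arm, and at most one bulge run per arm (length bl/br,
// placed after gl/gr paired positions counting outward from the loop, strictly
// interior to the arm).  Paired positions, counting t = 0..k-1 from the loop:
//   left(t)  = a - 1 - t - (bl if t >= gl else 0)
//   right(t) = b + t     + (br if t >= gr else 0)
// Constraints: stem_min <= k <= stem_max, loop_min <= b-a <= loop_max,
// mismatches <= max_mm, bulge lengths <= max_bulge, the innermost (t = 0) and
// outermost (t = k-1) pairs must be Watson-Crick matches, and N never pairs.
//
// For each loop interval only the best configuration is kept
// (k desc, mm asc, total bulge asc, deterministic tiebreaks), then annotations
// whose pair set is a strict subset of another kept annotation's pair set are
// dropped (maximality).  The same definition is implemented naively in
// hairpin_enum.cpp as a cross-check.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N and anything unexpected: never pairs
  }
}

// Watson-Crick on codes (A=0,C=1,G=2,T=3): complementary pairs sum to 3.
inline bool pairs_ok(int l, int r, bool wobble) {
  if (l > 3 || r > 3) return false;
  if (l + r == 3) return true;
  if (wobble && ((l == 2 && r == 3) || (l == 3 && r == 2))) return true;  // G.T
  return false;
}

struct Cand {
  int a, b, k, mm, bl, gl, br, gr;
};

// Per-loop ranking: longer stem, then fewer mismatches, then less bulged.
// All configurations tying on this triple are kept (the triple is invariant
// under strand reflection, so the output maps onto the reverse complement).
inline bool better(const Cand &x, const Cand &y) {
  if (x.k != y.k) return x.k > y.k;
  if (x.mm != y.mm) return x.mm < y.mm;
  return x.bl + x.br < y.bl + y.br;
}

inline bool rank_equal(const Cand &x, const Cand &y) {
  return x.k == y.k && x.mm == y.mm && x.bl + x.br == y.bl + y.br;
}

inline void pair_positions(const Cand &c, std::vector<std::pair<int, int>> &out) {
  out.clear();
  for (int t = 0; t < c.k; ++t) {
    const int i = c.a - 1 - t - ((c.bl > 0 && t >= c.gl) ? c.bl : 0);
    const int j = c.b + t + ((c.br > 0 && t >= c.gr) ? c.br : 0);
    out.push_back(std::make_pair(i, j));
  }
}

}  // namespace

// [[Rcpp::export(name = ".hairpin_search_cpp")]]
DataFrame hairpin_search_cpp(std::string seq, int stem_min, int stem_max,
                             int loop_min, int loop_max, int max_mm,
                             int max_bulge, bool wobble) {
  const int n = static_cast<int>(seq.size());
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = base_code(seq[i]);

  std::vector<Cand> kept;

  for (int a = 1; a + loop_min < n; ++a) {
    for (int llen = loop_min; llen <= loop_max; ++llen) {
      const int b = a + llen;
      if (b >= n) break;
      // The innermost pair (a-1, b) is shared by every configuration of this
      // loop and must match: gate the whole loop on it.
      if (!pairs_ok(s[a - 1], s[b], wobble)) continue;

      std::vector<Cand> loop_best;

      for (int bl = 0; bl <= max_bulge; ++bl) {
        const int gl_hi = (bl == 0) ? 0 : stem_max - 1;
        for (int gl = (bl == 0) ? 0 : 1; gl <= gl_hi; ++gl) {
          for (int br = 0; br <= max_bulge; ++br) {
            const int gr_hi = (br == 0) ? 0 : stem_max - 1;
            for (int gr = (br == 0) ? 0 : 1; gr <= gr_hi; ++gr) {
              int mm = 0, bestk = -1, bestmm = 0;
              for (int t = 0; t < stem_max; ++t) {
                const int i = a - 1 - t - ((bl > 0 && t >= gl) ? bl : 0);
                const int j = b + t + ((br > 0 && t >= gr) ? br : 0);
                if (i < 0 || j >= n) break;
                const bool m = pairs_ok(s[i], s[j], wobble);
                if (!m && ++mm > max_mm) break;
                // A valid stem ends on a match, with any bulge strictly
                // interior (gl <= t ensures the bulge sits between pairs).
                if (m && t + 1 >= stem_min && (bl == 0 || gl <= t) &&
                    (br == 0 || gr <= t)) {
                  bestk = t + 1;
                  bestmm = mm;
                }
              }
              if (bestk >= stem_min) {
                Cand c;
                c.a = a; c.b = b; c.k = bestk; c.mm = bestmm;
                c.bl = bl; c.gl = (bl == 0) ? 0 : gl;
                c.br = br; c.gr = (br == 0) ? 0 : gr;
                if (loop_best.empty() || better(c, loop_best.front())) {
                  loop_best.clear();
                  loop_best.push_back(c);
                } else if (rank_equal(c, loop_best.front())) {
                  loop_best.push_back(c);
                }
              }
            }
          }
        }
      }
      for (size_t q = 0; q < loop_best.size(); ++q)
        kept.push_back(loop_best[q]);
    }
  }

  // Maximality: drop a candidate whose pair set is a strict subset of another
  // kept candidate's pair set (only candidates with a longer stem can cover).
  const int m = static_cast<int>(kept.size());
  std::vector<std::vector<std::pair<int, int>>> pairs(m);
  for (int i = 0; i < m; ++i) pair_positions(kept[i], pairs[i]);

  std::vector<bool> drop(m, false);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < m && !drop[i]; ++j) {
      if (j == i || kept[j].k <= kept[i].k) continue;
      bool subset = true;
      for (size_t u = 0; u < pairs[i].size() && subset; ++u) {
        bool found = false;
        for (size_t v = 0; v < pairs[j].size(); ++v) {
          if (pairs[j][v] == pairs[i][u]) { found = true; break; }
        }
        if (!found) subset = false;
      }
      if (subset) drop[i] = true;
    }
  }

  std::vector<int> la, lb, lk, lmm, lbl, lgl, lbr, lgr;
  for (int i = 0; i < m; ++i) {
    if (drop[i]) continue;
    la.push_back(kept[i].a);  lb.push_back(kept[i].b);
    lk.push_back(kept[i].k);  lmm.push_back(kept[i].mm);
    lbl.push_back(kept[i].bl); lgl.push_back(kept[i].gl);
    lbr.push_back(kept[i].br); lgr.push_back(kept[i].gr);
  }

  return DataFrame::create(
      _["loop_start"] = la, _["loop_end"] = lb, _["stem_length"] = lk,
      _["mismatch_count"] = lmm, _["bulge_left_len"] = lbl,
      _["bulge_left_offset"] = lgl, _["bulge_right_len"] = lbr,
      _["bulge_right_offset"] = lgr);
}
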