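#include <Rcpp.h>
#include <functional>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// Penalty-capped semi-global alignment of a short read against a hairpin.
//
// Cost model: match 0, mismatch `mismatch`, a gap of length L costs
// gap_open + gap_ext * L (the opening fee plus an extension fee for every
// gapped base).  Terminal read bases may be soft clipped for zero penalty;
// the aligned core must keep at least `min_core` read bases.  Leading and
// trailing gaps are disallowed (a terminal gap is never part of an optimal
// alignment and would duplicate the role of a clip / reference offset).
//
// Optimality is lexicographic: minimise penalty first, then total clipped
// bases, so a clip is only taken when it lowers the penalty.  All distinct
// alignments attaining that optimum are enumerated (deduplicated by start
// and operation string), up to max_ties.
//
// Combined DP cost packs both criteria into one integer:
//   combined = penalty * PENW + clipped_bases            (clips < PENW)

namespace {

const int BIG = 1 << 28;
const int PENW = 1024;

inline int min3(int a, int b, int c) { return std::min(a, std::min(b, c)); }

}  // namespace

// [[Rcpp::export]]
List align_read_cpp(std::string read, std::string hairpin, int mismatch,
                    int gap_open, int gap_ext, int cap, int min_core,
                    int max_ties) {
  const int n = static_cast<int>(read.size());
  const int m = static_cast<int>(hairpin.size());

  List empty = List::create(
      _["penalty"] = R_NilValue, _["start"] = IntegerVector(0),
      _["end"] = IntegerVector(0), _["ops"] = CharacterVector(0),
      _["n_mismatch"] = IntegerVector(0), _["n_ins"] = IntegerVector(0),
      _["n_del"] = IntegerVector(0), _["clip5"] = IntegerVector(0),
      _["clip3"] = IntegerVector(0), _["n_n"] = IntegerVector(0),
      _["truncated"] = false);
  if (n < min_core || m < 1) return empty;

  const int MM = mismatch * PENW;
  const int OPEN = (gap_open + gap_ext) * PENW;  // first gapped base
  const int EXT = gap_ext * PENW;                // each further gapped base
  const int W = m + 1;

  // substitution cost; N never matches anything (costs a mismatch)
  std::vector<int> sub((n + 1) * W, 0);
  for (int i = 1; i <= n; ++i) {
    const char a = read[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = hairpin[j - 1];
      sub[i * W + j] = (a == b && a != 'N' && b != 'N') ? 0 : MM;
    }
  }

  const int maxc5 = n - min_core;
  std::vector<std::vector<int> > Ms(maxc5 + 1), Xs(maxc5 + 1), Ys(maxc5 + 1);
  int best = BIG;

  for (int c5 = 0; c5 <= maxc5; ++c5) {
    std::vector<int>& M = Ms[c5];
    std::vector<int>& X = Xs[c5];  // insertion: read-only bases
    std::vector<int>& Y = Ys[c5];  // deletion: hairpin-only bases
    M.assign((n + 1) * W, BIG);
    X.assign((n + 1) * W, BIG);
    Y.assign((n + 1) * W, BIG);

    for (int i = c5 + 1; i <= n; ++i) {
      for (int j = 1; j <= m; ++j) {
        const int id = i * W + j;
        if (i == c5 + 1) {
          M[id] = c5 + sub[id];  // clip5 cost, start anywhere on the hairpin
        } else {
          const int dm =
              min3(M[(i - 1) * W + j - 1], X[(i - 1) * W + j - 1],
                   Y[(i - 1) * W + j - 1]);
          if (dm < BIG) M[id] = dm + sub[id];
          int xv = BIG;
          if (M[(i - 1) * W + j] < BIG)
            xv = M[(i - 1) * W + j] + OPEN;
          if (X[(i - 1) * W + j] < BIG)
            xv = std::min(xv, X[(i - 1) * W + j] + EXT);
          X[id] = xv;
        }
        int yv = BIG;
        if (M[i * W + j - 1] < BIG) yv = M[i * W + j - 1] + OPEN;
        if (Y[i * W + j - 1] < BIG) yv = std::min(yv, Y[i * W + j - 1] + EXT);
        Y[id] = yv;
      }
    }
    for (int i = c5 + min_core; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        const int v = M[i * W + j];
        if (v < BIG && v + (n - i) < best) best = v + (n - i);
      }
  }

  if (best >= BIG) return empty;
  const int penalty = best / PENW;
  if (penalty > cap) return empty;

  // enumerate every optimal alignment by traceback with ties
  std::set<std::pair<int, std::string> > seen;
  std::vector<int> o_start, o_end, o_mis, o_ins, o_del, o_c5, o_c3, o_nn;
  std::vector<std::string> o_ops;
  bool truncated = false;

  for (int c5 = 0; c5 <= maxc5 && !truncated; ++c5) {
    std::vector<int>& M = Ms[c5];
    std::vector<int>& X = Xs[c5];
    std::vector<int>& Y = Ys[c5];
    std::string path;  // built back-to-front

    std::function<void(int, int, int, int)> rec =
        [&](int state, int i, int j, int i_end) {
          if (truncated) return;
          if (state == 0) {  // M
            path.push_back(sub[i * W + j] == 0 ? '=' : 'X');
            if (i == c5 + 1) {
              // complete: start of the aligned core
              std::string ops(c5, 'S');
              ops.append(path.rbegin(), path.rend());
              ops.append(n - i_end, 'S');
              const int start0 = j - 1;
              if (seen.insert(std::make_pair(start0, ops)).second) {
                if (static_cast<int>(seen.size()) > max_ties) {
                  truncated = true;
                } else {
                  int mis = 0, ins = 0, del = 0, ref = 0, nn = 0;
                  for (size_t k = 0; k < ops.size(); ++k) {
                    const char c = ops[k];
                    if (c == 'X') ++mis;
                    if (c == 'I') ++ins;
                    if (c == 'D') ++del;
                    if (c == '=' || c == 'X' || c == 'D') ++ref;
                  }
                  for (int k = c5; k < i_end; ++k)
                    if (read[k] == 'N') ++nn;
                  o_start.push_back(start0);
                  o_end.push_back(start0 + ref);
                  o_ops.push_back(ops);
                  o_mis.push_back(mis);
                  o_ins.push_back(ins);
                  o_del.push_back(del);
                  o_c5.push_back(c5);
                  o_c3.push_back(n - i_end);
                  o_nn.push_back(nn);
                }
              }
            } else {
              const int need = M[i * W + j] - sub[i * W + j];
              if (M[(i - 1) * W + j - 1] == need) rec(0, i - 1, j - 1, i_end);
              if (X[(i - 1) * W + j - 1] == need) rec(1, i - 1, j - 1, i_end);
              if (Y[(i - 1) * W + j - 1] == need) rec(2, i - 1, j - 1, i_end);
            }
            path.pop_back();
          } else if (state == 1) {  // insertion run
            path.push_back('I');
            const int v = X[i * W + j];
            if (M[(i - 1) * W + j] < BIG && M[(i - 1) * W + j] + OPEN == v)
              rec(0, i - 1, j, i_end);
            if (X[(i - 1) * W + j] < BIG && X[(i - 1) * W + j] + EXT == v)
              rec(1, i - 1, j, i_end);
            path.pop_back();
          } else {  // deletion run
            path.push_back('D');
            const int v = Y[i * W + j];
            if (M[i * W + j - 1] < BIG && M[i * W + j - 1] + OPEN == v)
              rec(0, i, j - 1, i_end);
            if (Y[i * W + j - 1] < BIG && Y[i * W + j - 1] + EXT == v)
              rec(2, i, j - 1, i_end);
            path.pop_back();
          }
        };

    for (int i = c5 + min_core; i <= n && !truncated; ++i)
      for (int j = 1; j <= m && !truncated; ++j)
        if (M[i * W + j] < BIG && M[i * W + j] + (n - i) == best)
          rec(0, i, j, i);
  }

  return List::create(
      _["penalty"] = penalty, _["start"] = wrap(o_start),
      _["end"] = wrap(o_end), _["ops"] = wrap(o_ops),
      _["n_mismatch"] = wrap(o_mis), _["n_ins"] = wrap(o_ins),
      _["n_del"] = wrap(o_del), _["clip5"] = wrap(o_c5),
      _["clip3"] = wrap(o_c3), _["n_n"] = wrap(o_nn),
      _["truncated"] = truncated);
}
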