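#include <Rcpp.h>
#include <string>

using namespace Rcpp;

// Error-tolerant adapter occurrence search.
//
// An occurrence anchored at read position s matches the adapter from its
// first base, tolerating up to max_errors unit-cost edits (mismatch,
// read insertion, adapter deletion).  It qualifies when either the whole
// adapter is consumed inside the read, or the match runs to the read's 3'
// end having consumed >= min_adapter_len adapter bases.  Occurrences with
// fewer errors win, then the leftmost position, then a longer adapter
// match — error count before position, otherwise every exact occurrence
// would be shadowed by a spurious one-error occurrence one base to its
// left whenever the insert's last base equals the adapter's first.
// N matches nothing.

namespace {

struct Hit {
  bool found;
  int errors;
  int adapter_len;
};

inline bool base_eq(char a, char b) { return a == b && a != 'N'; }

void search(const std::string& read, const std::string& adapter, int ri,
            int ai, int errors, int max_errors, int min_adapter_len,
            Hit& best) {
  const int L = static_cast<int>(read.size());
  const int A = static_cast<int>(adapter.size());
  while (ri < L && ai < A && base_eq(read[ri], adapter[ai])) {
    ++ri;
    ++ai;
  }
  const bool full = (ai == A);
  const bool at_end = (ri == L);
  if ((full || (at_end && ai >= min_adapter_len))) {
    if (!best.found || errors < best.errors ||
        (errors == best.errors && ai > best.adapter_len)) {
      best.found = true;
      best.errors = errors;
      best.adapter_len = ai;
    }
    return;
  }
  if (errors >= max_errors) return;
  if (ri < L && ai < A)  // mismatch
    search(read, adapter, ri + 1, ai + 1, errors + 1, max_errors,
           min_adapter_len, best);
  // extra read base (insertion in the read); a leading insertion is
  // disallowed: it would merely shift the occurrence start
  if (ri < L && ai > 0)
    search(read, adapter, ri + 1, ai, errors + 1, max_errors,
           min_adapter_len, best);
  if (ai < A && ri < L)  // adapter base absent from the read
    search(read, adapter, ri, ai + 1, errors + 1, max_errors,
           min_adapter_len, best);
}

}  // namespace

// Returns a matrix with one row per read:
//   insert_len (-1 when no occurrence), n_errors, adapter_len matched.
// [[Rcpp::export]]
IntegerMatrix trim_scan_cpp(CharacterVector reads, std::string adapter,
                            int max_errors, int min_adapter_len) {
  const int nr = reads.size();
  IntegerMatrix out(nr, 3);
  for (int r = 0; r < nr; ++r) {
    const std::string read = as<std::string>(reads[r]);
    const int L = static_cast<int>(read.size());
    int insert_len = -1, errors = -1, alen = -1;
    for (int s = 0; s <= L - 1; ++s) {
      Hit best = {false, 0, 0};
      search(read, adapter, s, 0, 0, max_errors, min_adapter_len, best);
      if (best.found &&
          (insert_len < 0 || best.errors < errors)) {
        insert_len = s;
        errors = best.errors;
        alen = best.adapter_len;
        if (errors == 0) break;  // nothing can beat an exact occurrence
      }
    }
    out(r, 0) = insert_len;
    out(r, 1) = errors;
    out(r, 2) = alen;
  }
  return out;
}
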