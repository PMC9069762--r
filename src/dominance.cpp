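#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// 2-D dominance counts with a Fenwick tree, O((nq + nr) log nr).
// out[i] = #{ j : rx[j] <= qx[i] and ry[j] <= qy[i] }, ties inclusive.
// [[Rcpp::export]]
IntegerVector dominance_count(NumericVector qx, NumericVector qy,
                              NumericVector rx, NumericVector ry) {
  const int nq = qx.size(), nr = rx.size();
  std::vector<double> xs(rx.begin(), rx.end());
  std::sort(xs.begin(), xs.end());

  std::vector<int> qord(nq), rord(nr);
  std::iota(qord.begin(), qord.end(), 0);
  std::iota(rord.begin(), rord.end(), 0);
  std::sort(qord.begin(), qord.end(),
            [&](int a, int b) { return qy[a] < qy[b]; });
  std::sort(rord.begin(), rord.end(),
            [&](int a, int b) { return ry[a] < ry[b]; });

  std::vector<int> bit(nr + 1, 0);
  auto add = [&](int pos) {
    for (; pos <= nr; pos += pos & -pos) bit[pos]++;
  };
  auto prefix = [&](int pos) {
    int s = 0;
    for (; pos > 0; pos -= pos & -pos) s += bit[pos];
    return s;
  };

  IntegerVector out(nq);
  int r = 0;
  for (int k = 0; k < nq; ++k) {
    const int i = qord[k];
    while (r < nr && ry[rord[r]] <= qy[i]) {
      int pos = int(std::lower_bound(xs.begin(), xs.end(), rx[rord[r]]) -
                    xs.begin()) + 1;
      add(pos);
      ++r;
    }
    int pos = int(std::upper_bound(xs.begin(), xs.end(), qx[i]) - xs.begin());
    out[i] = prefix(pos);
  }
  return out;
}
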