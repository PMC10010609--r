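#include <Rcpp.h>
using namespace Rcpp;

// Direct solve of a linear system whose adjacency graph is a rooted tree.
// Row i couples only to itself and to parent(i):
//   diag[i]*x[i] + aup[i]*x[parent(i)] = rhs[i]     (+ children terms, held
// in the parent's row through alo[c] for each child c).
// post_order lists nodes children-before-parents (1-based), parent[i] is the
// 1-based parent index (0 for the root). Elimination in post-order is
// fill-in free, so the solve is exact in O(n).
// [[Rcpp::export(name = ".tree_solve_cpp")]]
NumericVector tree_solve_cpp(IntegerVector post_order,
                             IntegerVector parent,
                             NumericVector diag,
                             NumericVector aup,
                             NumericVector alo,
                             NumericVector rhs) {
  int n = diag.size();
  NumericVector d = clone(diag);
  NumericVector r = clone(rhs);
  NumericVector x(n);

  for (int k = 0; k < n; ++k) {
    int i = post_order[k] - 1;
    int p = parent[i] - 1;
    if (p >= 0) {
      if (d[i] == 0.0) stop("singular tree system (zero pivot)");
      double m = alo[i] / d[i];
      d[p] -= m * aup[i];
      r[p] -= m * r[i];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    int i = post_order[k] - 1;
    int p = parent[i] - 1;
    if (d[i] == 0.0) stop("singular tree system (zero pivot)");
    if (p >= 0) {
      x[i] = (r[i] - aup[i] * x[p]) / d[i];
    } else {
      x[i] = r[i] / d[i];
    }
  }
  return x;
}
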