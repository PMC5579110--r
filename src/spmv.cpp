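#include <Rcpp.h>
using namespace Rcpp;

// Sparse matrix-vector product for compressed-sparse-column storage
// (the slots of a Matrix::dgCMatrix).  The time stepper applies the same
// operators thousands of times; calling straight into the slots avoids
// per-call S4 dispatch and result-object construction.
// [[Rcpp::export]]
NumericVector csc_matvec(IntegerVector p, IntegerVector i, NumericVector x,
                         NumericVector v, int nrow) {
  const int ncol = p.size() - 1;
  NumericVector y(nrow);
  for (int col = 0; col < ncol; ++col) {
    const double vc = v[col];
    if (vc == 0.0) continue;
    const int end = p[col + 1];
    for (int k = p[col]; k < end; ++k) {
      y[i[k]] += x[k] * vc;
    }
  }
  return y;
}
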