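#include <Rcpp.h>
using namespace Rcpp;

// Cohort-wise coancestry propagation.
//
// The extended parent set is [cohort (n animals); tracked bulls (m animals)].
// K  : n x n  symmetric coancestry matrix of the parent cohort
// Ct : n x m  coancestry of cohort members (rows) with tracked bulls (cols)
// Bb : m x m  coancestry among tracked bulls
// sire, dam : 1-based indices into the extended set for each offspring
//
// Off-diagonals follow
//   phi(o1,o2) = 1/4 [phi(s1,s2) + phi(s1,d2) + phi(d1,s2) + phi(d1,d2)]
// and the diagonal is phi(o,o) = 1/2 (1 + phi(s,d)).
//
// The offspring matrix is written into a caller-supplied buffer so the
// engine can ping-pong between a fixed set of large matrices instead of
// allocating ~0.8 GB per generation.

static void propagate_core(const NumericMatrix &K, const NumericMatrix &Ct,
                           const NumericMatrix &Bb, const IntegerVector &sire,
                           const IntegerVector &dam, NumericMatrix &Ko,
                           NumericMatrix &Cto, NumericVector &Fo) {
  const int n = K.nrow();
  const int m = Ct.ncol();
  const int no = sire.size();
  if (Ct.nrow() != n || Bb.nrow() != m || Bb.ncol() != m)
    stop("inconsistent kinship component dimensions");
  if (Ko.nrow() != no || Ko.ncol() != no)
    stop("output buffer has the wrong dimensions");

  std::vector<int> s(no), d(no);
  for (int o = 0; o < no; ++o) {
    s[o] = sire[o] - 1;
    d[o] = dam[o] - 1;
    if (s[o] < 0 || s[o] >= n + m || d[o] < 0 || d[o] >= n + m)
      stop("parent index out of range");
  }

  // extended-set lookup (i, j are 0-based extended indices)
  auto phi = [&](int i, int j) -> double {
    if (i < n) {
      if (j < n) return K(i, j);
      return Ct(i, j - n);
    }
    if (j < n) return Ct(j, i - n);
    return Bb(i - n, j - n);
  };

  // process offspring grouped by sire (then dam) so the parent columns of K
  // stay cache-resident across consecutive offspring
  std::vector<int> ord(no);
  for (int o = 0; o < no; ++o) ord[o] = o;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (s[a] != s[b]) return s[a] < s[b];
    return d[a] < d[b];
  });

  for (int oo = 0; oo < no; ++oo) {
    const int o1 = ord[oo];
    const int s1 = s[o1], d1 = d[o1];
    const double f = phi(s1, d1);
    Fo[o1] = f;
    Ko(o1, o1) = 0.5 * (1.0 + f);

    // fill only the strict lower triangle of column o1 (contiguous writes);
    // mirrored into the upper triangle in a tiled pass below
    double *col = &Ko(0, o1);
    if (s1 < n && d1 < n) {
      // fast path: parents are cohort members, so phi(s1, .) over the cohort
      // is a contiguous column of the symmetric K
      const double *cs = &K(0, s1);
      const double *cd = &K(0, d1);
      for (int o2 = o1 + 1; o2 < no; ++o2) {
        const int s2 = s[o2], d2 = d[o2];
        if (s2 < n && d2 < n)
          col[o2] = 0.25 * (cs[s2] + cs[d2] + cd[s2] + cd[d2]);
        else
          col[o2] = 0.25 * (phi(s1, s2) + phi(s1, d2) + phi(d1, s2) + phi(d1, d2));
      }
    } else {
      for (int o2 = o1 + 1; o2 < no; ++o2) {
        const int s2 = s[o2], d2 = d[o2];
        col[o2] = 0.25 * (phi(s1, s2) + phi(s1, d2) + phi(d1, s2) + phi(d1, d2));
      }
    }

    for (int b = 0; b < m; ++b)
      Cto(o1, b) = 0.5 * (phi(s1, n + b) + phi(d1, n + b));
  }

  // tiled symmetrization: upper(i, j) <- lower(j, i)
  const int B = 128;
  for (int jb = 0; jb < no; jb += B)
    for (int ib = 0; ib <= jb; ib += B) {
      const int jmax = std::min(jb + B, no);
      const int imax = std::min(ib + B, no);
      for (int j = jb; j < jmax; ++j)
        for (int i = ib; i < std::min(imax, j); ++i)
          Ko(i, j) = Ko(j, i);
    }
}

// [[Rcpp::export]]
List propagate_kinship_cpp(NumericMatrix K, NumericMatrix Ct, NumericMatrix Bb,
                           IntegerVector sire, IntegerVector dam) {
  const int no = sire.size();
  NumericMatrix Ko(no, no);
  NumericMatrix Cto(no, Ct.ncol());
  NumericVector Fo(no);
  propagate_core(K, Ct, Bb, sire, dam, Ko, Cto, Fo);
  return List::create(_["K"] = Ko, _["Ct"] = Cto, _["F"] = Fo);
}

// [[Rcpp::export]]
List propagate_kinship_buf_cpp(NumericMatrix K, NumericMatrix Ct,
                               NumericMatrix Bb, IntegerVector sire,
                               IntegerVector dam, NumericMatrix Kout) {
  if (K.size() > 0 && Kout.size() > 0 && &K(0, 0) == &Kout(0, 0))
    stop("output buffer must not alias the parent matrix");
  const int no = sire.size();
  NumericMatrix Cto(no, Ct.ncol());
  NumericVector Fo(no);
  propagate_core(K, Ct, Bb, sire, dam, Kout, Cto, Fo);
  return List::create(_["Ct"] = Cto, _["F"] = Fo);
}

// overwrite a buffer with the kinship matrix of unrelated base animals
// (zero off-diagonal, diagonal 0.5 * (1 + F))

// [[Rcpp::export]]
void founder_fill_cpp(NumericMatrix K, NumericVector diag) {
  const int n = K.nrow();
  if (K.ncol() != n || diag.size() != n) stop("dimension mismatch");
  std::fill(K.begin(), K.end(), 0.0);
  for (int i = 0; i < n; ++i) K(i, i) = diag[i];
}

// Mean of the off-diagonal entries of the symmetric submatrix K[idx, idx]
// (1-based idx); avoids materialising large submatrices in R.

// [[Rcpp::export]]
double mean_offdiag_cpp(NumericMatrix K, IntegerVector idx) {
  const int k = idx.size();
  if (k < 2) stop("need at least two animals");
  long double acc = 0.0;
  for (int a = 1; a < k; ++a) {
    const double *col = &K(0, idx[a] - 1);
    for (int b = 0; b < a; ++b) acc += col[idx[b] - 1];
  }
  return (double)(acc / ((long double)k * (k - 1) / 2.0));
}
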