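#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter. a[0] must be 1 (normalised on the R
// side).  Used by filtfilt_ba(); kept minimal on purpose.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x,
                             Nullable<NumericVector> zi = R_NilValue) {
  const int nb = b.size(), na = a.size(), n = x.size();
  const int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz, 0.0), bb(nz + 1, 0.0), aa(nz + 1, 0.0);
  if (zi.isNotNull()) {
    NumericVector z0(zi);
    for (int i = 0; i < nz && i < z0.size(); ++i) z[i] = z0[i];
  }
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  NumericVector y(n);
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double* zp = z.data();
  const double* bp = bb.data();
  const double* ap = aa.data();
  const double b0 = bp[0];
  for (int i = 0; i < n; ++i) {
    const double xi = xp[i];
    const double yi = b0 * xi + zp[0];
    for (int j = 0; j < nz - 1; ++j)
      zp[j] = bp[j + 1] * xi + zp[j + 1] - ap[j + 1] * yi;
    zp[nz - 1] = bp[nz] * xi - ap[nz] * yi;
    yp[i] = yi;
  }
  return y;
}
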