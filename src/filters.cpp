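#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering of the columns of X (time x signals): odd
// (point-reflected) padding of npad samples at both ends, one forward and one
// time-reversed pass of the direct-form-II-transposed recursion with zero
// initial states, then the padding is trimmed off.
// [[Rcpp::export]]
NumericMatrix filtfilt_cols(NumericVector b, NumericVector a, NumericMatrix X,
                            int npad) {
  int nord = std::max(b.size(), a.size());
  std::vector<double> bb(nord, 0.0), aa(nord, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  for (int i = 0; i < nord; ++i) { bb[i] /= a0; aa[i] /= a0; }

  int nt = X.nrow(), nc = X.ncol();
  if (npad > nt - 1) npad = nt - 1;
  int np = nt + 2 * npad;
  NumericMatrix Y(nt, nc);
  std::vector<double> buf(np), z(nord - 1);
  const double *px;
  double *py;

  for (int j = 0; j < nc; ++j) {
    px = &X(0, j);
    for (int t = 0; t < npad; ++t)                 // odd reflection, leading
      buf[t] = 2.0 * px[0] - px[npad - t];
    std::copy(px, px + nt, buf.begin() + npad);
    for (int t = 0; t < npad; ++t)                 // odd reflection, trailing
      buf[npad + nt + t] = 2.0 * px[nt - 1] - px[nt - 2 - t];

    if (nord == 5) {                               // order-4 fast path: states in registers
      double b0 = bb[0], b1 = bb[1], b2 = bb[2], b3 = bb[3], b4 = bb[4];
      double a1 = aa[1], a2 = aa[2], a3 = aa[3], a4 = aa[4];
      double z0 = 0, z1 = 0, z2 = 0, z3 = 0;
      for (int t = 0; t < np; ++t) {
        double x = buf[t];
        double y = b0 * x + z0;
        z0 = b1 * x + z1 - a1 * y;
        z1 = b2 * x + z2 - a2 * y;
        z2 = b3 * x + z3 - a3 * y;
        z3 = b4 * x - a4 * y;
        buf[t] = y;
      }
      z0 = z1 = z2 = z3 = 0;
      for (int t = np - 1; t >= 0; --t) {
        double x = buf[t];
        double y = b0 * x + z0;
        z0 = b1 * x + z1 - a1 * y;
        z1 = b2 * x + z2 - a2 * y;
        z2 = b3 * x + z3 - a3 * y;
        z3 = b4 * x - a4 * y;
        buf[t] = y;
      }
    } else {
      std::fill(z.begin(), z.end(), 0.0);
      for (int t = 0; t < np; ++t) {               // forward pass
        double x = buf[t];
        double y = bb[0] * x + z[0];
        for (int k = 0; k < nord - 2; ++k)
          z[k] = bb[k + 1] * x + z[k + 1] - aa[k + 1] * y;
        z[nord - 2] = bb[nord - 1] * x - aa[nord - 1] * y;
        buf[t] = y;
      }
      std::fill(z.begin(), z.end(), 0.0);
      for (int t = np - 1; t >= 0; --t) {          // backward pass
        double x = buf[t];
        double y = bb[0] * x + z[0];
        for (int k = 0; k < nord - 2; ++k)
          z[k] = bb[k + 1] * x + z[k + 1] - aa[k + 1] * y;
        z[nord - 2] = bb[nord - 1] * x - aa[nord - 1] * y;
        buf[t] = y;
      }
    }
    py = &Y(0, j);
    std::copy(buf.begin() + npad, buf.begin() + npad + nt, py);
  }
  return Y;
}
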