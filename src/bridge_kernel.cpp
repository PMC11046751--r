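#include <Rcpp.h>
using namespace Rcpp;

// Accumulate weighted isotropic Gaussian cell masses onto a grid.
// For each quadrature point k the per-cell mass is the product of exact 1-D
// normal integrals over the cell edges (separable), restricted to a window
// of +-4.5 SD. `mass` is modified in place.
// [[Rcpp::export(name = ".accumulate_gaussians")]]
void accumulate_gaussians(NumericMatrix mass,
                          double x0, double y0, double res,
                          NumericVector mx, NumericVector my,
                          NumericVector sd, NumericVector w) {
  const int nx = mass.nrow(), ny = mass.ncol();
  const int K = mx.size();
  std::vector<double> px, py;
  for (int k = 0; k < K; ++k) {
    const double s = sd[k];
    const double half = 4.5 * s;
    int ix0 = (int)std::floor((mx[k] - half - x0) / res);
    int ix1 = (int)std::floor((mx[k] + half - x0) / res);
    int iy0 = (int)std::floor((my[k] - half - y0) / res);
    int iy1 = (int)std::floor((my[k] + half - y0) / res);
    if (ix0 < 0) ix0 = 0;
    if (iy0 < 0) iy0 = 0;
    if (ix1 > nx - 1) ix1 = nx - 1;
    if (iy1 > ny - 1) iy1 = ny - 1;
    if (ix1 < ix0 || iy1 < iy0) continue;
    const int wx = ix1 - ix0 + 1, wy = iy1 - iy0 + 1;
    px.resize(wx); py.resize(wy);
    double lo = R::pnorm(x0 + ix0 * res, mx[k], s, 1, 0);
    for (int i = 0; i < wx; ++i) {
      double hi = R::pnorm(x0 + (ix0 + i + 1) * res, mx[k], s, 1, 0);
      px[i] = hi - lo;
      lo = hi;
    }
    lo = R::pnorm(y0 + iy0 * res, my[k], s, 1, 0);
    for (int j = 0; j < wy; ++j) {
      double hi = R::pnorm(y0 + (iy0 + j + 1) * res, my[k], s, 1, 0);
      py[j] = hi - lo;
      lo = hi;
    }
    for (int j = 0; j < wy; ++j) {
      const double wpy = w[k] * py[j];
      double *col = &mass(ix0, iy0 + j);
      for (int i = 0; i < wx; ++i) col[i] += wpy * px[i];
    }
  }
}
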