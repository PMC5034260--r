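#include <Rcpp.h>
using namespace Rcpp;

// Explicit forward-Euler reaction-diffusion substepping on the lattice.
// Zero-flux boundaries at grid edges and at non-admissible (lumen) nodes:
// a non-admissible neighbor contributes nothing to the Laplacian, and
// non-admissible nodes stay at zero. The total step dt is split into nsub
// equal substeps; the caller guarantees dt/nsub satisfies the stability
// bound dt_sub <= 1/(4*D + lambda).

// [[Rcpp::export]]
NumericMatrix cpp_diffuse(NumericMatrix C, IntegerMatrix adm,
                          IntegerVector src, double D, double lambda,
                          double s, double dt, int nsub) {
  const int w = C.nrow(), h = C.ncol(), n = w * h;
  const double dts = dt / nsub;
  const double sdt = s * dts;

  std::vector<double> a(C.begin(), C.end());
  std::vector<double> b(n, 0.0);
  const int *ad = adm.begin();
  double *cur = a.data();
  double *nxt = b.data();

  for (int it = 0; it < nsub; ++it) {
    for (int y = 0; y < h; ++y) {
      const int off = y * w;
      for (int x = 0; x < w; ++x) {
        const int i = off + x;
        if (!ad[i]) { nxt[i] = 0.0; continue; }
        const double c0 = cur[i];
        double lap = 0.0;
        if (x > 0     && ad[i - 1]) lap += cur[i - 1] - c0;
        if (x < w - 1 && ad[i + 1]) lap += cur[i + 1] - c0;
        if (y > 0     && ad[i - w]) lap += cur[i - w] - c0;
        if (y < h - 1 && ad[i + w]) lap += cur[i + w] - c0;
        nxt[i] = c0 + dts * (D * lap - lambda * c0);
      }
    }
    for (int k = 0; k < src.size(); ++k) {
      nxt[src[k] - 1] += sdt;  // 1-based linear indices
    }
    std::swap(cur, nxt);
  }
  NumericMatrix out(w, h);
  std::copy(cur, cur + n, out.begin());
  return out;
}
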