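#include <Rcpp.h>
#include <complex>
#include <vector>
using namespace Rcpp;

typedef std::complex<double> cplx;

static inline double bilin(const NumericMatrix& m, double x, double y) {
  // pixel (r, c) holds the sample at (x = c, y = r), 0-based
  int nr = m.nrow(), nc = m.ncol();
  if (x < 0) x = 0;
  if (y < 0) y = 0;
  if (x > nc - 1) x = nc - 1;
  if (y > nr - 1) y = nr - 1;
  int c0 = (int)std::floor(x), r0 = (int)std::floor(y);
  if (c0 > nc - 2) c0 = nc - 2;
  if (r0 > nr - 2) r0 = nr - 2;
  if (c0 < 0) c0 = 0;
  if (r0 < 0) r0 = 0;
  double fx = x - c0, fy = y - r0;
  return m(r0, c0) * (1 - fx) * (1 - fy) + m(r0, c0 + 1) * fx * (1 - fy) +
         m(r0 + 1, c0) * (1 - fx) * fy + m(r0 + 1, c0 + 1) * fx * fy;
}

static inline double prior_dist2(const std::vector<cplx>& z,
                                 const std::vector<cplx>& zhat_star) {
  // squared distance between normalized Fourier descriptors
  // (k in DFT order; k = 0 descriptor is zeroed on both sides)
  int n = (int)z.size();
  double r1 = std::abs(z[1]);
  if (r1 < 1e-12) return 1e12;
  cplx ph1 = z[1] / r1;  // exp(i theta1)
  double acc = 0.0;
  for (int k = 1; k < n; ++k) {
    cplx zh = (z[k] / r1) * std::conj(ph1);  // (Rk/R1) e^{i(thk - th1)}
    cplx dfl = zh - zhat_star[k];
    acc += std::norm(dfl);
  }
  return acc;
}

// One full sequential pass of the greedy Fourier-prior snake.
// C, normals: n x 2 (x, y); emag2: squared smoothed gradient magnitude;
// Z: DFT of x + iy in stats::fft order; zhat_star: normalized prior
// descriptors. Points are updated in sequence; Z is maintained by rank-one
// updates. Returns the updated contour, descriptors and the move count.
// [[Rcpp::export(name = ".cpp_greedy_pass")]]
List cpp_greedy_pass(NumericMatrix C, NumericMatrix normals,
                     NumericMatrix emag2, ComplexVector Z,
                     ComplexVector zhat_star, double alpha, double beta,
                     double wedge, double delta, double gamma0, int radius,
                     double e_floor) {
  int n = C.nrow();
  NumericMatrix pts = clone(C);
  std::vector<cplx> z(n), zs(n);
  for (int k = 0; k < n; ++k) {
    z[k] = cplx(Z[k].r, Z[k].i);
    zs[k] = cplx(zhat_star[k].r, zhat_star[k].i);
  }
  int nr = emag2.nrow(), nc = emag2.ncol();
  // mean spacing of the closed polyline at pass start
  double dbar = 0.0;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    dbar += std::hypot(pts(j, 0) - pts(i, 0), pts(j, 1) - pts(i, 1));
  }
  dbar /= n;
  int side = 2 * radius + 1, ncand = side * side;
  std::vector<double> e_cont(ncand), e_curv(ncand), e_img(ncand),
      e_ball(ncand), e_pri(ncand), cx(ncand), cy(ncand);
  std::vector<cplx> wk(n);
  int moved = 0;
  for (int i = 0; i < n; ++i) {
    int ip = (i - 1 + n) % n, in = (i + 1) % n;
    double px = pts(ip, 0), py = pts(ip, 1);
    double nx = pts(in, 0), ny = pts(in, 1);
    double x0 = pts(i, 0), y0 = pts(i, 1);
    // DFT row factors exp(-2*pi*1i*k*i/n)
    cplx step = std::exp(cplx(0.0, -2.0 * M_PI * (double)i / (double)n));
    wk[0] = cplx(1.0, 0.0);
    for (int k = 1; k < n; ++k) wk[k] = wk[k - 1] * step;
    int self = -1, j = 0;
    for (int dy = -radius; dy <= radius; ++dy) {
      for (int dx = -radius; dx <= radius; ++dx, ++j) {
        double x = x0 + dx, y = y0 + dy;
        if (x < 0) x = 0;
        if (y < 0) y = 0;
        if (x > nc - 1) x = nc - 1;
        if (y > nr - 1) y = nr - 1;
        if (dx == 0 && dy == 0) self = j;
        cx[j] = x;
        cy[j] = y;
        double dprev = std::hypot(x - px, y - py);
        e_cont[j] = (dbar - dprev) * (dbar - dprev);
        double kx = px - 2 * x + nx, ky = py - 2 * y + ny;
        e_curv[j] = kx * kx + ky * ky;
        e_img[j] = -bilin(emag2, x, y);
        e_ball[j] =
            -((x - x0) * normals(i, 0) + (y - y0) * normals(i, 1)) / radius;
        cplx dz(x - x0, y - y0);
        if (gamma0 > 0) {
          std::vector<cplx> z2(z);
          for (int k = 0; k < n; ++k) z2[k] += dz * wk[k];
          e_pri[j] = prior_dist2(z2, zs);
        } else {
          e_pri[j] = 0.0;
        }
      }
    }
    // classic greedy min-max normalization of each term over the window
    auto norm01 = [&](std::vector<double>& v) {
      double lo = v[0], hi = v[0];
      for (int k = 1; k < ncand; ++k) {
        lo = std::min(lo, v[k]);
        hi = std::max(hi, v[k]);
      }
      double rng = hi - lo;
      for (int k = 0; k < ncand; ++k) v[k] = rng > 0 ? (v[k] - lo) / rng : 0.0;
    };
    norm01(e_cont);
    norm01(e_curv);
    // flat neighborhoods carry no edge information: without a floor the
    // min-max normalization would amplify numerical noise to full weight
    {
      double lo = e_img[0], hi = e_img[0];
      for (int k = 1; k < ncand; ++k) {
        lo = std::min(lo, e_img[k]);
        hi = std::max(hi, e_img[k]);
      }
      if (hi - lo < e_floor) {
        std::fill(e_img.begin(), e_img.end(), 0.0);
      } else {
        norm01(e_img);
      }
    }
    norm01(e_ball);
    norm01(e_pri);
    std::vector<double> etot(ncand);
    for (int k = 0; k < ncand; ++k) {
      etot[k] = alpha * e_cont[k] + beta * e_curv[k] + wedge * e_img[k] +
                delta * e_ball[k] + gamma0 * e_pri[k];
    }
    int best = self;  // stay on ties
    for (int k = 0; k < ncand; ++k) {
      if (etot[k] < etot[best] - 1e-12) best = k;
    }
    if (best != self) {
      cplx dz(cx[best] - x0, cy[best] - y0);
      for (int k = 0; k < n; ++k) z[k] += dz * wk[k];
      pts(i, 0) = cx[best];
      pts(i, 1) = cy[best];
      ++moved;
    }
  }
  ComplexVector zout(n);
  for (int k = 0; k < n; ++k) {
    zout[k].r = z[k].real();
    zout[k].i = z[k].imag();
  }
  return List::create(_["points"] = pts, _["Z"] = zout, _["moved"] = moved);
}
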