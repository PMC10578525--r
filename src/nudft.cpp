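#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward simulation of one echo readout: discrete pixel-sum of the signal
// model s(t_i) = sum_p m_p exp(-i [2 pi k_i . r_p + dw_p t_i + dwc_p tc_i]).
// dw, dwc in rad/s; kx,ky in cycles/m; x,y in m.
// [[Rcpp::export]]
ComplexVector cpp_sim_echo(ComplexVector m, NumericVector x, NumericVector y,
                           NumericVector dw, NumericVector dwc,
                           NumericVector kx, NumericVector ky,
                           NumericVector t, NumericVector tc) {
  const R_xlen_t P = m.size(), S = kx.size();
  ComplexVector out(S);
  std::vector<double> mre(P), mim(P);
  for (R_xlen_t p = 0; p < P; ++p) { mre[p] = m[p].r; mim[p] = m[p].i; }
  for (R_xlen_t i = 0; i < S; ++i) {
    const double kxi = 2.0 * M_PI * kx[i], kyi = 2.0 * M_PI * ky[i];
    const double ti = t[i], tci = tc[i];
    double sre = 0.0, sim = 0.0;
    for (R_xlen_t p = 0; p < P; ++p) {
      if (mre[p] == 0.0 && mim[p] == 0.0) continue;
      const double ph = -(kxi * x[p] + kyi * y[p] + dw[p] * ti + dwc[p] * tci);
      const double c = std::cos(ph), s = std::sin(ph);
      sre += mre[p] * c - mim[p] * s;
      sim += mre[p] * s + mim[p] * c;
    }
    out[i].r = sre; out[i].i = sim;
  }
  return out;
}

// Multi-weight adjoint non-uniform DFT: for each basis column b,
// I_b(p) = sum_i basis[i,b] w_i s_i exp(+i 2 pi k_i . r_p).
// Returns a P x B complex matrix. Used for gridding (B=1, basis=1) and for
// Chebyshev base-image stacks.
// [[Rcpp::export]]
ComplexMatrix cpp_adjoint_multi(ComplexVector s, NumericVector w,
                                NumericMatrix basis,
                                NumericVector kx, NumericVector ky,
                                NumericVector x, NumericVector y) {
  const R_xlen_t S = s.size(), P = x.size();
  const int B = basis.ncol();
  ComplexMatrix out(P, B);
  std::vector<double> acc_re(B), acc_im(B);
  // data weighted once
  std::vector<double> dre(S), dim(S);
  for (R_xlen_t i = 0; i < S; ++i) { dre[i] = s[i].r * w[i]; dim[i] = s[i].i * w[i]; }
  for (R_xlen_t p = 0; p < P; ++p) {
    for (int b = 0; b < B; ++b) { acc_re[b] = 0.0; acc_im[b] = 0.0; }
    const double xp = 2.0 * M_PI * x[p], yp = 2.0 * M_PI * y[p];
    for (R_xlen_t i = 0; i < S; ++i) {
      const double ph = kx[i] * xp + ky[i] * yp;
      const double c = std::cos(ph), si = std::sin(ph);
      const double re = dre[i] * c - dim[i] * si;
      const double im = dre[i] * si + dim[i] * c;
      for (int b = 0; b < B; ++b) {
        const double bw = basis(i, b);
        if (bw == 0.0) continue;
        acc_re[b] += bw * re;
        acc_im[b] += bw * im;
      }
    }
    for (int b = 0; b < B; ++b) { out(p, b).r = acc_re[b]; out(p, b).i = acc_im[b]; }
  }
  return out;
}

// Max over probe points of the distance to the nearest sample point,
// using cell binning (cell size h >= max expected NN distance).
// [[Rcpp::export]]
double cpp_max_nn_dist(NumericVector px, NumericVector py,
                       NumericVector qx, NumericVector qy, double h) {
  const R_xlen_t P = px.size(), Q = qx.size();
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (R_xlen_t i = 0; i < Q; ++i) {
    xmin = std::min(xmin, qx[i]); xmax = std::max(xmax, qx[i]);
    ymin = std::min(ymin, qy[i]); ymax = std::max(ymax, qy[i]);
  }
  const int nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
  const int ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
  std::vector<std::vector<int> > cells((size_t)nx * ny);
  for (R_xlen_t i = 0; i < Q; ++i) {
    int cx = std::min(nx - 1, (int)std::floor((qx[i] - xmin) / h));
    int cy = std::min(ny - 1, (int)std::floor((qy[i] - ymin) / h));
    cells[(size_t)cx * ny + cy].push_back((int)i);
  }
  double worst = 0.0;
  for (R_xlen_t p = 0; p < P; ++p) {
    int cx = (int)std::floor((px[p] - xmin) / h);
    int cy = (int)std::floor((py[p] - ymin) / h);
    double best = R_PosInf;
    // grow the search ring until a neighbor is guaranteed nearest
    for (int ring = 0; ring < std::max(nx, ny) + 1; ++ring) {
      for (int ix = cx - ring; ix <= cx + ring; ++ix) {
        if (ix < 0 || ix >= nx) continue;
        for (int iy = cy - ring; iy <= cy + ring; ++iy) {
          if (iy < 0 || iy >= ny) continue;
          if (std::max(std::abs(ix - cx), std::abs(iy - cy)) != ring) continue;
          const std::vector<int>& cell = cells[(size_t)ix * ny + iy];
          for (size_t j = 0; j < cell.size(); ++j) {
            const double dx = qx[cell[j]] - px[p], dy = qy[cell[j]] - py[p];
            const double d = std::sqrt(dx * dx + dy * dy);
            if (d < best) best = d;
          }
        }
      }
      if (best <= (double)ring * h) break;  // nearer points impossible outside
    }
    if (best > worst) worst = best;
  }
  return worst;
}

// Nearest-sample index for each probe point (cell-binned search).
// Returns 1-based indices.
// [[Rcpp::export]]
IntegerVector cpp_nn_assign(NumericVector px, NumericVector py,
                            NumericVector qx, NumericVector qy, double h) {
  const R_xlen_t P = px.size(), Q = qx.size();
  double xmin = R_PosInf, ymin = R_PosInf, xmax = R_NegInf, ymax = R_NegInf;
  for (R_xlen_t i = 0; i < Q; ++i) {
    xmin = std::min(xmin, qx[i]); xmax = std::max(xmax, qx[i]);
    ymin = std::min(ymin, qy[i]); ymax = std::max(ymax, qy[i]);
  }
  const int nx = std::max(1, (int)std::floor((xmax - xmin) / h) + 1);
  const int ny = std::max(1, (int)std::floor((ymax - ymin) / h) + 1);
  std::vector<std::vector<int> > cells((size_t)nx * ny);
  for (R_xlen_t i = 0; i < Q; ++i) {
    int cx = std::min(nx - 1, std::max(0, (int)std::floor((qx[i] - xmin) / h)));
    int cy = std::min(ny - 1, std::max(0, (int)std::floor((qy[i] - ymin) / h)));
    cells[(size_t)cx * ny + cy].push_back((int)i);
  }
  IntegerVector out(P);
  for (R_xlen_t p = 0; p < P; ++p) {
    int cx = std::max(0, std::min(nx - 1, (int)std::floor((px[p] - xmin) / h)));
    int cy = std::max(0, std::min(ny - 1, (int)std::floor((py[p] - ymin) / h)));
    double best = R_PosInf; int bi = 0;
    for (int ring = 0; ring < std::max(nx, ny) + 1; ++ring) {
      for (int ix = cx - ring; ix <= cx + ring; ++ix) {
        if (ix < 0 || ix >= nx) continue;
        for (int iy = cy - ring; iy <= cy + ring; ++iy) {
          if (iy < 0 || iy >= ny) continue;
          if (std::max(std::abs(ix - cx), std::abs(iy - cy)) != ring) continue;
          const std::vector<int>& cell = cells[(size_t)ix * ny + iy];
          for (size_t j = 0; j < cell.size(); ++j) {
            const double dx = qx[cell[j]] - px[p], dy = qy[cell[j]] - py[p];
            const double d = dx * dx + dy * dy;
            if (d < best) { best = d; bi = cell[j]; }
          }
        }
      }
      if (best <= (double)ring * h * (double)ring * h) break;
    }
    out[p] = bi + 1;
  }
  return out;
}
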