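#include <Rcpp.h>
using namespace Rcpp;

static void gauss_kernel(double sigma, std::vector<double>& k) {
  int h = std::max(1, static_cast<int>(std::ceil(3.0 * sigma)));
  k.assign(2 * h + 1, 0.0);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    double v = std::exp(-0.5 * i * i / (sigma * sigma));
    k[i + h] = v;
    s += v;
  }
  for (double& v : k) v /= s;
}

// Separable convolution with reflecting edges; branch-free interior.
static void conv_sep(const NumericMatrix& img, const std::vector<double>& k,
                     std::vector<double>& out) {
  const int h = img.nrow(), w = img.ncol();
  const int half = (static_cast<int>(k.size()) - 1) / 2;
  const double* src = img.begin();
  std::vector<double> tmp(static_cast<size_t>(h) * w);
  for (int j = 0; j < w; ++j) {
    const double* col = src + static_cast<size_t>(h) * j;
    double* dst = tmp.data() + static_cast<size_t>(h) * j;
    for (int i = 0; i < std::min(half, h); ++i) {
      double s = 0.0;
      for (int d = -half; d <= half; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= h) ii = 2 * h - ii - 1;
        s += k[d + half] * col[ii];
      }
      dst[i] = s;
    }
    for (int i = half; i < h - half; ++i) {
      double s = 0.0;
      const double* c = col + i - half;
      for (int d = 0; d <= 2 * half; ++d) s += k[d] * c[d];
      dst[i] = s;
    }
    for (int i = std::max(half, h - half); i < h; ++i) {
      double s = 0.0;
      for (int d = -half; d <= half; ++d) {
        int ii = i + d;
        if (ii < 0) ii = -ii - 1;
        if (ii >= h) ii = 2 * h - ii - 1;
        s += k[d + half] * col[ii];
      }
      dst[i] = s;
    }
  }
  out.assign(static_cast<size_t>(h) * w, 0.0);
  for (int j = 0; j < w; ++j) {
    double* dst = out.data() + static_cast<size_t>(h) * j;
    for (int d = -half; d <= half; ++d) {
      int jj = j + d;
      if (jj < 0) jj = -jj - 1;
      if (jj >= w) jj = 2 * w - jj - 1;
      const double kd = k[d + half];
      const double* c = tmp.data() + static_cast<size_t>(h) * jj;
      for (int i = 0; i < h; ++i) dst[i] += kd * c[i];
    }
  }
}

//' Difference-of-Gaussians band-pass, then 8-connected local maxima above
//' mean + k*sd of the filtered image. Returns 1-based (row, col) pairs.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix dog_maxima_cpp(NumericMatrix img, double sigma_small,
                             double sigma_large, double k_sd) {
  const int h = img.nrow(), w = img.ncol();
  std::vector<double> ks, kl, fs, fl;
  gauss_kernel(sigma_small, ks);
  gauss_kernel(sigma_large, kl);
  conv_sep(img, ks, fs);
  conv_sep(img, kl, fl);
  const size_t n = fs.size();
  for (size_t p = 0; p < n; ++p) fs[p] -= fl[p];
  // Robust threshold: median + k * MAD-based sd of the band-passed image,
  // insensitive to the bright spots themselves.
  std::vector<double> tmp2(fs);
  std::nth_element(tmp2.begin(), tmp2.begin() + n / 2, tmp2.end());
  const double med = tmp2[n / 2];
  for (size_t p = 0; p < n; ++p) tmp2[p] = std::fabs(fs[p] - med);
  std::nth_element(tmp2.begin(), tmp2.begin() + n / 2, tmp2.end());
  const double mad_sd = tmp2[n / 2] * 1.4826;
  const double thr = med + k_sd * mad_sd;

  std::vector<int> rows, cols;
  for (int j = 1; j < w - 1; ++j)
    for (int i = 1; i < h - 1; ++i) {
      const double v = fs[i + static_cast<size_t>(h) * j];
      if (v <= thr) continue;
      bool mx = true;
      for (int dj = -1; dj <= 1 && mx; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          if (fs[(i + di) + static_cast<size_t>(h) * (j + dj)] > v) {
            mx = false;
            break;
          }
        }
      if (mx) {
        rows.push_back(i + 1);
        cols.push_back(j + 1);
      }
    }
  IntegerMatrix out(rows.size(), 2);
  for (size_t r = 0; r < rows.size(); ++r) {
    out(r, 0) = rows[r];
    out(r, 1) = cols[r];
  }
  return out;
}

static inline double pix_int(double p, double c, double s) {
  const double inv = 1.0 / (s * M_SQRT2);
  return 0.5 * (std::erf((p + 1.0 - c) * inv) - std::erf((p - c) * inv));
}

// Model: value(i,j) = bg + N * Ey(i) * Ex(j), pixel-integrated Gaussian.
// Params p = (xc, yc, N, bg, sigma). Coordinates are 0-based pixel indices
// of the window; centre positions are continuous (pixel centre at idx+0.5).
static void model_and_jac(const NumericMatrix& win, const double* p,
                          bool fit_sigma, std::vector<double>& r,
                          std::vector<double>& J, int npar) {
  const int h = win.nrow(), w = win.ncol();
  const double xc = p[0], yc = p[1], N = p[2], bg = p[3], sg = p[4];
  const double inv = 1.0 / (sg * M_SQRT2);
  std::vector<double> ex(w), ey(h), dex(w), dey(h), sex(w), sey(h);
  for (int j = 0; j < w; ++j) {
    ex[j] = pix_int(j, xc, sg);
    const double gl = std::exp(-0.5 * std::pow((j - xc) * inv * M_SQRT2, 2) / 1.0);
    // derivative of erf-based integral wrt xc:
    const double a = (j + 1.0 - xc) * inv, b = (j - xc) * inv;
    dex[j] = -(std::exp(-a * a) - std::exp(-b * b)) / (sg * std::sqrt(2.0 * M_PI));
    sex[j] = -((j + 1.0 - xc) * std::exp(-a * a) - (j - xc) * std::exp(-b * b)) /
             (sg * sg * std::sqrt(2.0 * M_PI));
    (void)gl;
  }
  for (int i = 0; i < h; ++i) {
    ey[i] = pix_int(i, yc, sg);
    const double a = (i + 1.0 - yc) * inv, b = (i - yc) * inv;
    dey[i] = -(std::exp(-a * a) - std::exp(-b * b)) / (sg * std::sqrt(2.0 * M_PI));
    sey[i] = -((i + 1.0 - yc) * std::exp(-a * a) - (i - yc) * std::exp(-b * b)) /
             (sg * sg * std::sqrt(2.0 * M_PI));
  }
  r.resize(static_cast<size_t>(h) * w);
  J.resize(static_cast<size_t>(h) * w * npar);
  size_t q = 0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i, ++q) {
      const double m = bg + N * ey[i] * ex[j];
      r[q] = win(i, j) - m;
      J[q * npar + 0] = N * ey[i] * dex[j];
      J[q * npar + 1] = N * dey[i] * ex[j];
      J[q * npar + 2] = ey[i] * ex[j];
      J[q * npar + 3] = 1.0;
      if (fit_sigma) J[q * npar + 4] = N * (sey[i] * ex[j] + ey[i] * sex[j]);
    }
}

static bool solve_sym(std::vector<double>& A, std::vector<double>& b, int n) {
  // Gaussian elimination with partial pivoting on small n.
  for (int c = 0; c < n; ++c) {
    int piv = c;
    for (int rw = c + 1; rw < n; ++rw)
      if (std::fabs(A[rw * n + c]) > std::fabs(A[piv * n + c])) piv = rw;
    if (std::fabs(A[piv * n + c]) < 1e-300) return false;
    if (piv != c) {
      for (int k = 0; k < n; ++k) std::swap(A[c * n + k], A[piv * n + k]);
      std::swap(b[c], b[piv]);
    }
    for (int rw = c + 1; rw < n; ++rw) {
      const double f = A[rw * n + c] / A[c * n + c];
      for (int k = c; k < n; ++k) A[rw * n + k] -= f * A[c * n + k];
      b[rw] -= f * b[c];
    }
  }
  for (int c = n - 1; c >= 0; --c) {
    double s = b[c];
    for (int k = c + 1; k < n; ++k) s -= A[c * n + k] * b[k];
    b[c] = s / A[c * n + c];
  }
  return true;
}

//' Levenberg-Marquardt least-squares fit of a pixel-integrated symmetric 2-D
//' Gaussian plus constant background. Returns c(x, y, N, bg, sigma,
//' converged, rss). Start values in window coordinates (0-based pixels).
//' @noRd
// [[Rcpp::export]]
NumericVector fit_gauss2d_cpp(NumericMatrix win, double x0, double y0,
                              double sigma0, bool fit_sigma) {
  const int h = win.nrow(), w = win.ncol();
  const int npar = fit_sigma ? 5 : 4;
  double bg0 = R_PosInf, mx = R_NegInf, tot = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      bg0 = std::min(bg0, win(i, j));
      mx = std::max(mx, win(i, j));
      tot += win(i, j);
    }
  double p[5] = {x0, y0, std::max(1.0, tot - bg0 * h * w), bg0, sigma0};
  std::vector<double> r, J, A(npar * npar), g(npar);
  model_and_jac(win, p, fit_sigma, r, J, npar);
  double rss = 0.0;
  for (double v : r) rss += v * v;
  double lambda = 1e-3;
  bool converged = false;
  for (int iter = 0; iter < 100; ++iter) {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(g.begin(), g.end(), 0.0);
    const size_t nq = r.size();
    for (size_t q = 0; q < nq; ++q) {
      const double* Jq = &J[q * npar];
      for (int a = 0; a < npar; ++a) {
        g[a] += Jq[a] * r[q];
        for (int b = a; b < npar; ++b) A[a * npar + b] += Jq[a] * Jq[b];
      }
    }
    for (int a = 0; a < npar; ++a)
      for (int b = 0; b < a; ++b) A[a * npar + b] = A[b * npar + a];
    std::vector<double> Ad(A), bd(g);
    for (int a = 0; a < npar; ++a) Ad[a * npar + a] *= (1.0 + lambda);
    if (!solve_sym(Ad, bd, npar)) break;
    double pn[5] = {p[0] + bd[0], p[1] + bd[1], p[2] + bd[2], p[3] + bd[3],
                    fit_sigma ? p[4] + bd[4] : p[4]};
    if (pn[4] < 0.3) pn[4] = 0.3;
    if (pn[4] > std::max(h, w)) pn[4] = std::max(h, w);
    std::vector<double> rn, Jn;
    model_and_jac(win, pn, fit_sigma, rn, Jn, npar);
    double rssn = 0.0;
    for (double v : rn) rssn += v * v;
    if (rssn < rss) {
      double step = 0.0;
      for (int a = 0; a < npar; ++a) step = std::max(step, std::fabs(bd[a]));
      std::copy(pn, pn + 5, p);
      r.swap(rn);
      J.swap(Jn);
      const double drop = rss - rssn;
      rss = rssn;
      lambda = std::max(1e-9, lambda * 0.3);
      if (step < 1e-6 || drop < 1e-10 * (rss + 1e-30)) {
        converged = true;
        break;
      }
    } else {
      lambda *= 10.0;
      if (lambda > 1e9) break;
    }
  }
  return NumericVector::create(p[0], p[1], p[2], p[3], p[4],
                               converged ? 1.0 : 0.0, rss);
}

//' Levenberg-Marquardt fit of two pixel-integrated Gaussians with shared,
//' fixed sigma plus constant background. Params: x1,y1,x2,y2,N1,N2,bg.
//' Returns c(x1,y1,x2,y2,N1,N2,bg,converged).
//' @noRd
// [[Rcpp::export]]
NumericVector fit_gauss2d_pair_cpp(NumericMatrix win, double x1, double y1,
                                   double x2, double y2, double sigma) {
  const int h = win.nrow(), w = win.ncol();
  const int npar = 7;
  double mn = R_PosInf, tot = 0.0;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      mn = std::min(mn, win(i, j));
      tot += win(i, j);
    }
  const double amp0 = std::max(1.0, (tot - mn * h * w) / 2.0);
  double p[7] = {x1, y1, x2, y2, amp0, amp0, mn};
  std::vector<double> ex1(w), ey1(h), ex2(w), ey2(h), dx1(w), dy1(h),
      dx2(w), dy2(h);
  auto fill = [&](const double* q, std::vector<double>& exa,
                  std::vector<double>& eya, std::vector<double>& dxa,
                  std::vector<double>& dya) {
    const double norm = 1.0 / (sigma * std::sqrt(2.0 * M_PI));
    const double inv = 1.0 / (sigma * M_SQRT2);
    for (int j = 0; j < w; ++j) {
      exa[j] = pix_int(j, q[0], sigma);
      const double a = (j + 1.0 - q[0]) * inv, b = (j - q[0]) * inv;
      dxa[j] = -(std::exp(-a * a) - std::exp(-b * b)) * norm;
    }
    for (int i = 0; i < h; ++i) {
      eya[i] = pix_int(i, q[1], sigma);
      const double a = (i + 1.0 - q[1]) * inv, b = (i - q[1]) * inv;
      dya[i] = -(std::exp(-a * a) - std::exp(-b * b)) * norm;
    }
  };
  std::vector<double> r(static_cast<size_t>(h) * w),
      J(static_cast<size_t>(h) * w * npar);
  auto eval = [&](const double* q, std::vector<double>& rr,
                  std::vector<double>& JJ) {
    fill(q, ex1, ey1, dx1, dy1);
    fill(q + 2, ex2, ey2, dx2, dy2);
    size_t k = 0;
    double rss = 0.0;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i, ++k) {
        const double m = q[6] + q[4] * ey1[i] * ex1[j] + q[5] * ey2[i] * ex2[j];
        rr[k] = win(i, j) - m;
        rss += rr[k] * rr[k];
        JJ[k * npar + 0] = q[4] * ey1[i] * dx1[j];
        JJ[k * npar + 1] = q[4] * dy1[i] * ex1[j];
        JJ[k * npar + 2] = q[5] * ey2[i] * dx2[j];
        JJ[k * npar + 3] = q[5] * dy2[i] * ex2[j];
        JJ[k * npar + 4] = ey1[i] * ex1[j];
        JJ[k * npar + 5] = ey2[i] * ex2[j];
        JJ[k * npar + 6] = 1.0;
      }
    return rss;
  };
  double rss = eval(p, r, J);
  double lambda = 1e-3;
  bool converged = false;
  std::vector<double> A(npar * npar), g(npar), rn(r.size()), Jn(J.size());
  for (int iter = 0; iter < 60; ++iter) {
    std::fill(A.begin(), A.end(), 0.0);
    std::fill(g.begin(), g.end(), 0.0);
    for (size_t q = 0; q < r.size(); ++q) {
      const double* Jq = &J[q * npar];
      for (int a = 0; a < npar; ++a) {
        g[a] += Jq[a] * r[q];
        for (int b = a; b < npar; ++b) A[a * npar + b] += Jq[a] * Jq[b];
      }
    }
    for (int a = 0; a < npar; ++a)
      for (int b = 0; b < a; ++b) A[a * npar + b] = A[b * npar + a];
    std::vector<double> Ad(A), bd(g);
    for (int a = 0; a < npar; ++a) Ad[a * npar + a] *= (1.0 + lambda);
    if (!solve_sym(Ad, bd, npar)) break;
    double pn[7];
    for (int a = 0; a < npar; ++a) pn[a] = p[a] + bd[a];
    const double rssn = eval(pn, rn, Jn);
    if (rssn < rss) {
      double step = 0.0;
      for (int a = 0; a < npar; ++a) step = std::max(step, std::fabs(bd[a]));
      std::copy(pn, pn + 7, p);
      r.swap(rn);
      J.swap(Jn);
      const double drop = rss - rssn;
      rss = rssn;
      lambda = std::max(1e-9, lambda * 0.3);
      if (step < 1e-6 || drop < 1e-10 * (rss + 1e-30)) {
        converged = true;
        break;
      }
    } else {
      lambda *= 10.0;
      if (lambda > 1e8) break;
    }
  }
  return NumericVector::create(p[0], p[1], p[2], p[3], p[4], p[5], p[6],
                               converged ? 1.0 : 0.0);
}

//' Fixed-position photometry: linear LS of value = bg + N * PSF(i,j) with the
//' PSF pixel-integrated at (x, y) with width sigma. Returns c(N, bg).
//' @noRd
// [[Rcpp::export]]
NumericVector photometry_cpp(NumericMatrix win, double x, double y,
                             double sigma) {
  const int h = win.nrow(), w = win.ncol();
  double spp = 0.0, sp = 0.0, spy = 0.0, sy = 0.0;
  const double n = static_cast<double>(h) * w;
  for (int j = 0; j < w; ++j) {
    const double ex = pix_int(j, x, sigma);
    for (int i = 0; i < h; ++i) {
      const double pij = ex * pix_int(i, y, sigma);
      spp += pij * pij;
      sp += pij;
      spy += pij * win(i, j);
      sy += win(i, j);
    }
  }
  const double det = n * spp - sp * sp;
  if (std::fabs(det) < 1e-300) return NumericVector::create(NA_REAL, NA_REAL);
  const double N = (n * spy - sp * sy) / det;
  const double bg = (sy - N * sp) / n;
  return NumericVector::create(N, bg);
}
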