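#include <Rcpp.h>
using namespace Rcpp;

// Integral of a unit-area 1-D Gaussian centred at c over pixel [p, p+1).
static inline double pix_int(double p, double c, double s) {
  const double inv = 1.0 / (s * M_SQRT2);
  return 0.5 * (std::erf((p + 1.0 - c) * inv) - std::erf((p - c) * inv));
}

//' @noRd
// [[Rcpp::export]]
IntegerVector render_frames_cpp(int height, int width, int n_frames,
                                IntegerVector frame, NumericVector x_px,
                                NumericVector y_px, NumericVector rate,
                                double psf_sigma_px, double bg_mean,
                                double gain, double baseline) {
  // Expected photon image per frame, then per-pixel Poisson draw through
  // R's RNG stream so movies are reproducible under set.seed().
  const int npix = height * width;
  std::vector<double> expected(static_cast<size_t>(npix) * n_frames, bg_mean);
  const int halfw = static_cast<int>(std::ceil(4.0 * psf_sigma_px));

  for (int k = 0; k < frame.size(); ++k) {
    const int f = frame[k] - 1;  // 1-based in R
    if (f < 0 || f >= n_frames) stop("frame index out of chunk range");
    const double xc = x_px[k], yc = y_px[k], amp = rate[k];
    if (amp <= 0.0) continue;
    const int j0 = std::max(0, static_cast<int>(std::floor(xc)) - halfw);
    const int j1 = std::min(width - 1, static_cast<int>(std::floor(xc)) + halfw);
    const int i0 = std::max(0, static_cast<int>(std::floor(yc)) - halfw);
    const int i1 = std::min(height - 1, static_cast<int>(std::floor(yc)) + halfw);
    double* img = expected.data() + static_cast<size_t>(npix) * f;
    for (int j = j0; j <= j1; ++j) {
      const double ex = pix_int(static_cast<double>(j), xc, psf_sigma_px);
      for (int i = i0; i <= i1; ++i) {
        const double ey = pix_int(static_cast<double>(i), yc, psf_sigma_px);
        img[i + static_cast<size_t>(height) * j] += amp * ex * ey;
      }
    }
  }

  // Cached inverse-CDF sampler for the constant background rate (the vast
  // majority of pixels), keeping draws on R's RNG stream.
  std::vector<double> cdf;
  if (bg_mean > 0.0) {
    double term = std::exp(-bg_mean), cum = term;
    cdf.push_back(cum);
    for (int kk = 1; cum < 1.0 - 1e-14 && kk < 1000; ++kk) {
      term *= bg_mean / kk;
      cum += term;
      cdf.push_back(cum);
    }
  }
  IntegerVector out(static_cast<R_xlen_t>(npix) * n_frames);
  for (size_t p = 0; p < expected.size(); ++p) {
    double photons;
    if (expected[p] == bg_mean && bg_mean > 0.0) {
      const double u = unif_rand();
      size_t kk = 0;
      while (kk < cdf.size() && u > cdf[kk]) ++kk;
      photons = static_cast<double>(kk);
    } else {
      photons = (expected[p] > 0.0) ? R::rpois(expected[p]) : 0.0;
    }
    double adu = baseline + gain * photons;
    if (adu < 0.0) adu = 0.0;
    if (adu > 65535.0) adu = 65535.0;
    out[p] = static_cast<int>(std::lround(adu));
  }
  out.attr("dim") = IntegerVector::create(height, width, n_frames);
  return out;
}
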