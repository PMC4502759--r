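// Hot loops of the spectral pipeline: windowed multitaper power and
// zero-phase FIR filtering with decimation. Everything else stays in R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Multitaper power over sliding windows.
// x: signal; starts: 0-based window start samples; tapers: K x nwin
// (unit-energy DPSS); nf: number of one-sided frequency bins kept.
// Returns nf x n_windows matrix of mean-over-tapers |FFT|^2 (no fs or
// one-sided scaling; the R caller applies those). Windows are demeaned
// before tapering.
// [[Rcpp::export]]
arma::mat cpp_mt_power(const arma::vec& x, const arma::uvec& starts,
                       const arma::mat& tapers, const int nf) {
  const int nwin = tapers.n_cols, K = tapers.n_rows, nw = starts.n_elem;
  mat out(nf, nw);
  vec win(nwin), tw(nwin), acc(nf);
  cx_vec F(nwin);
  for (int w = 0; w < nw; ++w) {
    win = x.subvec(starts[w], starts[w] + nwin - 1);
    win -= mean(win);
    acc.zeros();
    for (int k = 0; k < K; ++k) {
      tw = win % tapers.row(k).t();
      F = fft(tw);
      acc += square(real(F.subvec(0, nf - 1))) +
             square(imag(F.subvec(0, nf - 1)));
    }
    out.col(w) = acc / K;
  }
  return out;
}

static double median_inplace(arma::vec& v) {
  const arma::uword n = v.n_elem, h = n / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = (m + lo) / 2.0;
  }
  return m;
}

// Median-denoised cross-spectral matrix.
// data: samples x channels; tapers: K x nwin DPSS; nf: one-sided bins kept;
// block: windows per median block. Per non-overlapping window the K-taper
// cross-spectral matrix is formed; real and imaginary parts are median'd
// element-wise over each block of `block` windows, and block medians are
// averaged. Returns cx_cube (nf x nch x nch), Hermitian by construction.
// No fs scaling (cancels in all coherence ratios).
// [[Rcpp::export]]
arma::cx_cube cpp_csm(const arma::mat& data, const arma::mat& tapers,
                      const int nf, const int block) {
  const int nwin = tapers.n_cols, K = tapers.n_rows;
  const int n = data.n_rows, nch = data.n_cols;
  const int nw = n / nwin, nblocks = nw / block;
  const int npair = nch * (nch + 1) / 2;
  arma::cx_cube Sacc(nf, nch, nch, arma::fill::zeros);
  std::vector<arma::cx_mat> X(K, arma::cx_mat(nf, nch));
  arma::mat bufRe(block, (size_t)nf * npair), bufIm(block, (size_t)nf * npair);
  arma::vec win(nwin), tw(nwin), tmp(block);
  for (int b = 0; b < nblocks; ++b) {
    for (int wi = 0; wi < block; ++wi) {
      const int w = b * block + wi;
      for (int c = 0; c < nch; ++c) {
        win = data.col(c).subvec((size_t)w * nwin, (size_t)(w + 1) * nwin - 1);
        win -= arma::mean(win);
        for (int k = 0; k < K; ++k) {
          tw = win % tapers.row(k).t();
          arma::cx_vec F = arma::fft(tw);
          X[k].col(c) = F.subvec(0, nf - 1);
        }
      }
      size_t idx = 0;
      for (int j = 0; j < nch; ++j) {
        for (int i = 0; i <= j; ++i) {
          for (int f = 0; f < nf; ++f, ++idx) {
            std::complex<double> s(0.0, 0.0);
            for (int k = 0; k < K; ++k) {
              s += X[k](f, i) * std::conj(X[k](f, j));
            }
            s /= (double)K;
            bufRe(wi, idx) = s.real();
            bufIm(wi, idx) = s.imag();
          }
        }
      }
    }
    size_t idx = 0;
    for (int j = 0; j < nch; ++j) {
      for (int i = 0; i <= j; ++i) {
        for (int f = 0; f < nf; ++f, ++idx) {
          tmp = bufRe.col(idx);
          const double mre = median_inplace(tmp);
          tmp = bufIm.col(idx);
          const double mim = median_inplace(tmp);
          const std::complex<double> m(mre, mim);
          Sacc(f, i, j) += m;
          if (i != j) Sacc(f, j, i) += std::conj(m);
        }
      }
    }
  }
  return Sacc / (double)nblocks;
}

// Zero-phase FIR low-pass + integer decimation.
// h must be symmetric with odd length L; the linear-phase delay (L-1)/2 is
// compensated exactly, and the input is reflect-padded so a constant input
// maps to itself (up to the filter's unity DC gain). Output keeps samples
// 0, q, 2q, ... of the filtered signal.
// [[Rcpp::export]]
arma::mat cpp_fir_decimate(const arma::mat& x, const arma::vec& h,
                           const int q) {
  const int n = x.n_rows, nc = x.n_cols, L = h.n_elem, d = (L - 1) / 2;
  const int nout = (n - 1) / q + 1;
  mat out(nout, nc);
  vec xp(n + 2 * d);
  for (int c = 0; c < nc; ++c) {
    // reflect padding (no sample repeated at the edge)
    for (int i = 0; i < d; ++i) xp[i] = x(d - i, c);
    xp.subvec(d, d + n - 1) = x.col(c);
    for (int i = 0; i < d; ++i) xp[d + n + i] = x(n - 2 - i, c);
    for (int m = 0; m < nout; ++m) {
      const int base = m * q;  // output sample aligns with x[base]
      double s = 0.0;
      for (int k = 0; k < L; ++k) s += h[k] * xp[base + k];
      out(m, c) = s;
    }
  }
  return out;
}
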