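#include <Rcpp.h>
#include <fftw3.h>
#include <vector>

using namespace Rcpp;

// Time-frequency energy by FFT convolution with precomputed kernel spectra.
//
// X:      npad x ncol real matrix, columns are mirror-padded single-trial
//         single-channel series (length npad <= nfft; the rest is zero-padded,
//         which together with the mirror padding yields linear convolution).
// K:      nfft x nfreq complex matrix; column j holds Conj(fft(kernel_j))/nfft
//         so that ifft(fft(x) * K_j) is the correlation of x with kernel_j.
// pad0:   number of leading padding samples (0-based offset of the first
//         retained time point).
// bin_id: length-ntime integer vector, 1-based output bin for each retained
//         time point (0 drops the point).
// nbins:  number of output time bins.
//
// Returns an nbins x ncol x nfreq array of bin-averaged squared magnitudes.
// [[Rcpp::export]]
NumericVector wavelet_energy_fft(NumericMatrix X, ComplexMatrix K,
                                 int pad0, IntegerVector bin_id, int nbins) {
  const int npad = X.nrow(), ncol = X.ncol();
  const int nfft = K.nrow(), nfreq = K.ncol();
  const int ntime = bin_id.size();
  if (pad0 + ntime > npad || npad > nfft)
    stop("inconsistent padding/fft sizes");

  NumericVector out(static_cast<R_xlen_t>(nbins) * ncol * nfreq);
  std::vector<double> bincount(nbins, 0.0);
  for (int t = 0; t < ntime; ++t)
    if (bin_id[t] > 0) bincount[bin_id[t] - 1] += 1.0;

  fftw_complex* buf = fftw_alloc_complex(nfft);
  fftw_complex* spec = fftw_alloc_complex(nfft);
  fftw_complex* prod = fftw_alloc_complex(nfft);
  fftw_complex* y = fftw_alloc_complex(nfft);
  fftw_plan pf = fftw_plan_dft_1d(nfft, buf, spec, FFTW_FORWARD, FFTW_ESTIMATE);
  fftw_plan pb = fftw_plan_dft_1d(nfft, prod, y, FFTW_BACKWARD, FFTW_ESTIMATE);

  for (int c = 0; c < ncol; ++c) {
    const double* xc = &X(0, c);
    for (int i = 0; i < npad; ++i) { buf[i][0] = xc[i]; buf[i][1] = 0.0; }
    for (int i = npad; i < nfft; ++i) { buf[i][0] = 0.0; buf[i][1] = 0.0; }
    fftw_execute(pf);
    for (int j = 0; j < nfreq; ++j) {
      const Rcomplex* kj = &K(0, j);
      for (int i = 0; i < nfft; ++i) {
        prod[i][0] = spec[i][0] * kj[i].r - spec[i][1] * kj[i].i;
        prod[i][1] = spec[i][0] * kj[i].i + spec[i][1] * kj[i].r;
      }
      fftw_execute(pb);
      double* oj = &out[static_cast<R_xlen_t>(nbins) * (c + static_cast<R_xlen_t>(ncol) * j)];
      for (int t = 0; t < ntime; ++t) {
        const int b = bin_id[t];
        if (b > 0) {
          const double re = y[pad0 + t][0], im = y[pad0 + t][1];
          oj[b - 1] += re * re + im * im;
        }
      }
    }
  }
  fftw_destroy_plan(pf);
  fftw_destroy_plan(pb);
  fftw_free(buf); fftw_free(spec); fftw_free(prod); fftw_free(y);

  for (int j = 0; j < nfreq; ++j)
    for (int c = 0; c < ncol; ++c) {
      double* oj = &out[static_cast<R_xlen_t>(nbins) * (c + static_cast<R_xlen_t>(ncol) * j)];
      for (int b = 0; b < nbins; ++b)
        if (bincount[b] > 0) oj[b] /= bincount[b];
    }

  out.attr("dim") = IntegerVector::create(nbins, ncol, nfreq);
  return out;
}
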