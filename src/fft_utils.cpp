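#include <Rcpp.h>
#include <fftw3.h>

using namespace Rcpp;

// Inverse hermitian FFT per column: spec is the positive-frequency half
// (n/2 + 1 rows, complex) of a length-n real signal's spectrum. Returns the
// n x ncol real matrix (unnormalised, like stats::fft(inverse = TRUE)).
// [[Rcpp::export]]
NumericMatrix fft_c2r_cols(ComplexMatrix spec, int n) {
  const int nr = spec.nrow(), ncol = spec.ncol();
  if (nr != n / 2 + 1) stop("spec must have n/2 + 1 rows");
  NumericMatrix out(n, ncol);
  fftw_complex* in = fftw_alloc_complex(nr);
  double* buf = fftw_alloc_real(n);
  fftw_plan p = fftw_plan_dft_c2r_1d(n, in, buf, FFTW_ESTIMATE);
  for (int c = 0; c < ncol; ++c) {
    for (int i = 0; i < nr; ++i) {
      in[i][0] = spec(i, c).r;
      in[i][1] = spec(i, c).i;
    }
    fftw_execute(p);
    std::copy(buf, buf + n, &out(0, c));
  }
  fftw_destroy_plan(p);
  fftw_free(in); fftw_free(buf);
  return out;
}

// Zero-phase frequency-domain filtering per column: multiplies each
// column's spectrum by the real response h (length n/2 + 1, applied
// symmetrically to negative frequencies) and transforms back.
// [[Rcpp::export]]
NumericMatrix fft_filter_cols(NumericMatrix x, NumericVector h) {
  const int n = x.nrow(), ncol = x.ncol();
  const int nr = n / 2 + 1;
  if (h.size() != nr) stop("h must have n/2 + 1 elements");
  NumericMatrix out(n, ncol);
  double* buf = fftw_alloc_real(n);
  fftw_complex* spec = fftw_alloc_complex(nr);
  fftw_plan pf = fftw_plan_dft_r2c_1d(n, buf, spec, FFTW_ESTIMATE);
  fftw_plan pb = fftw_plan_dft_c2r_1d(n, spec, buf, FFTW_ESTIMATE);
  for (int c = 0; c < ncol; ++c) {
    std::copy(&x(0, c), &x(0, c) + n, buf);
    fftw_execute(pf);
    for (int i = 0; i < nr; ++i) {
      spec[i][0] *= h[i] / n;
      spec[i][1] *= h[i] / n;
    }
    fftw_execute(pb);
    std::copy(buf, buf + n, &out(0, c));
  }
  fftw_destroy_plan(pf);
  fftw_destroy_plan(pb);
  fftw_free(buf); fftw_free(spec);
  return out;
}
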