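// Dense kernels for the 3D convolution front end.
//
// A sample tensor is stored as an R array with dim (C, T, H, W), column
// major, so the (channel, time) pair of a fixed grid cell is one contiguous
// block of C*T doubles and a temporal window of all channels at one cell is
// a contiguous block of C*k_t doubles.  im2col exploits that: each kernel
// placement becomes one column assembled from k_h*k_w memcpy calls, and the
// convolution (and its weight gradient) reduce to a single BLAS gemm.
//
// Row ordering of the patch matrix is (c fastest, then dt, dh, dw), which is
// exactly the column-major flattening of a kernel array with dim
// (C, k_t, k_h, k_w); column ordering is (t_out fastest, then h_out, w_out).
//
// No input gradient (col2im) is provided: the 3D convolution is the first
// layer of the network, so only the weight gradient is ever needed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat im2col_impl(const arma::vec& x, const arma::ivec& dims,
                             const arma::ivec& kernel,
                             const arma::ivec& stride) {
  const int C = dims[0], T = dims[1], H = dims[2], W = dims[3];
  const int kt = kernel[0], kh = kernel[1], kw = kernel[2];
  const int st = stride[0], sh = stride[1], sw = stride[2];
  if (kt > T || kh > H || kw > W)
    Rcpp::stop("convolution kernel exceeds input extent");
  const int t_out = (T - kt) / st + 1;
  const int h_out = (H - kh) / sh + 1;
  const int w_out = (W - kw) / sw + 1;
  const size_t block = (size_t)C * kt;  // contiguous (c, dt) run
  const size_t krows = block * kh * kw;
  arma::mat P(krows, (size_t)t_out * h_out * w_out);
  const double* xp = x.memptr();
  double* pp = P.memptr();
  size_t col = 0;
  for (int w0 = 0; w0 < w_out; ++w0)
    for (int h0 = 0; h0 < h_out; ++h0)
      for (int t0 = 0; t0 < t_out; ++t0, ++col) {
        double* dst = pp + col * krows;
        for (int dw = 0; dw < kw; ++dw)
          for (int dh = 0; dh < kh; ++dh) {
            const size_t src = (size_t)C * ((size_t)t0 * st)
              + (size_t)C * T * ((size_t)h0 * sh + dh)
              + (size_t)C * T * H * ((size_t)w0 * sw + dw);
            std::memcpy(dst + block * (dh + (size_t)kh * dw), xp + src,
                        sizeof(double) * block);
          }
      }
  return P;
}

// [[Rcpp::export]]
arma::mat cpp_conv3d_im2col(const arma::vec& x, const arma::ivec& dims,
                            const arma::ivec& kernel,
                            const arma::ivec& stride) {
  return im2col_impl(x, dims, kernel, stride);
}

// Forward pass: returns (n_positions x n_filters); positions ordered
// (t_out, h_out, w_out), t fastest.  wmat is (C*kt*kh*kw x n_filters).
// [[Rcpp::export]]
arma::mat cpp_conv3d_forward(const arma::vec& x, const arma::ivec& dims,
                             const arma::mat& wmat, const arma::ivec& kernel,
                             const arma::ivec& stride) {
  arma::mat P = im2col_impl(x, dims, kernel, stride);
  if (P.n_rows != wmat.n_rows)
    Rcpp::stop("weight matrix rows do not match patch size");
  return P.t() * wmat;
}

// Weight gradient: dy is (n_positions x n_filters) on the same ordering as
// the forward output; returns (C*kt*kh*kw x n_filters).
// [[Rcpp::export]]
arma::mat cpp_conv3d_wgrad(const arma::vec& x, const arma::ivec& dims,
                           const arma::mat& dy, const arma::ivec& kernel,
                           const arma::ivec& stride) {
  arma::mat P = im2col_impl(x, dims, kernel, stride);
  if (P.n_cols != dy.n_rows)
    Rcpp::stop("gradient rows do not match output positions");
  return P * dy;
}
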