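#' Low-level network layers
#'
#' Minimal dense implementations of the layers the classifier needs:
#' valid-mode 3D convolution (im2col + BLAS gemm, compiled), batch
#' normalization and ReLU, each with a hand-written backward pass.  Tensors
#' follow the (C, T, H, W) axis order of the sample tensors; batches append a
#' trailing axis.
#'
#' @name nn-layers
NULL

#' 3D convolution forward pass (valid, strided)
#'
#' `y[f, t, h, w] = sum_{c, dt, dh, dw} x[c, t*st+dt, h*sh+dh, w*sw+dw] *
#' k[c, dt, dh, dw, f]` with 0-based positions -- a direct strided valid
#' convolution over all input channels.
#'
#' @param x input array (C, T, H, W).
#' @param kernel weight array (C, k_t, k_h, k_w, n_filters).
#' @param stride integer vector (s_t, s_h, s_w).
#' @param bias optional per-filter bias.
#' @return Array (n_filters, t_out, h_out, w_out) with
#'   `t_out = floor((T - k_t)/s_t) + 1` (similarly h, w).
#' @export
conv3d_forward <- function(x, kernel, stride = c(1L, 1L, 1L), bias = NULL) {
  dx <- dim(x)
  dk <- dim(kernel)
  stopifnot(length(dx) == 4L, length(dk) == 5L)
  if (dx[1] != dk[1])
    stop("input channel count ", dx[1], " does not match kernel ", dk[1])
  if (any(dk[2:4] > dx[2:4]))
    stop("convolution kernel exceeds input extent")
  nf <- dk[5]
  wmat <- matrix(kernel, prod(dk[1:4]), nf)
  y <- cpp_conv3d_forward(as.numeric(x), as.integer(dx), wmat,
                          as.integer(dk[2:4]), as.integer(stride))
  t_out <- (dx[2] - dk[2]) %/% stride[1] + 1L
  h_out <- (dx[3] - dk[3]) %/% stride[2] + 1L
  w_out <- (dx[4] - dk[4]) %/% stride[3] + 1L
  out <- array(t(y), dim = c(nf, t_out, h_out, w_out))
  if (!is.null(bias)) out <- out + bias  # recycles over the filter axis
  out
}

bn_init <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       running_mean = rep(0, n), running_var = rep(1, n))
}

# x: (channels x m) matrix; statistics per channel over the m columns.
bn_forward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans((x - mu)^2)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * v
  } else {
    mu <- bn$running_mean
    v <- bn$running_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * istd
  y <- bn$gamma * xhat + bn$beta
  list(y = y, bn = bn,
       cache = list(xhat = xhat, istd = istd, gamma = bn$gamma,
                    training = training))
}

bn_backward <- function(dy, cache) {
  m <- ncol(dy)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  if (cache$training) {
    dx <- (cache$gamma * cache$istd) *
      (dy - dbeta / m - cache$xhat * (dgamma / m))
  } else {
    dx <- (cache$gamma * cache$istd) * dy
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

relu_backward <- function(dy, mask) dy * mask

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# rows of `v` replicated into an (n x length(v)) matrix
rep_rows <- function(v, n) matrix(v, n, length(v), byrow = TRUE)
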