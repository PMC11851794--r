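#' The temporal-spatial-frequency capsule classifier
#'
#' Architecture (default hyperparameters in parentheses, input
#' (C=5, T=1280, H=5, W=5)):
#'
#' 1. **ConvBlock** -- valid 3D convolution (32 filters, kernel (512, 3, 3),
#'    stride (16, 1, 1)) + BatchNorm + ReLU, giving (32, 49, 3, 3); the
#'    filter and temporal axes are merged into one channel axis (1568) and a
#'    1x1 2D convolution maps to 512 channels (+ BN + ReLU) at 3x3.
#' 2. **PrimaryCaps** -- D_P (8) parallel 3x3 valid 2D convolutions with C4
#'    (128) filters each, concatenated into N_P = C4*H4*W4 (128) primary
#'    capsules of dimension D_P, squashed.
#' 3. **EEGCaps** -- dynamic routing (3 iterations) from the primary
#'    capsules to N_E = 2 class capsules of dimension D_E = 16.
#' 4. Class scores are the capsule norms; a softmax over the two norms gives
#'    reported probabilities, while training minimizes the margin loss on
#'    the raw norms.
#'
#' The `conv_fc` variant replaces stages 2-4 by flatten + one fully
#' connected layer + softmax, trained with cross-entropy.
#'
#' @name capsnet
NULL

#' Model configuration
#'
#' Defaults reproduce the reference architecture exactly (and its published
#' layer-by-layer output shapes).  One published table entry is internally
#' inconsistent: after merging 32 filters x 49 time steps the channel count
#' is 1568, not the printed 392; the merge here is generic in
#' `n_filters * t_out`.
#'
#' @param c_in input band count (5; 1 for the TS-only variant).
#' @param t_len,grid_h,grid_w input tensor extent.
#' @param n_filters,kernel_t,kernel_h,kernel_w,stride_t,stride_h,stride_w
#'   3D-convolution geometry.
#' @param conv2d_filters channels after the 1x1 convolution.
#' @param c4 primary-capsule channels per parallel branch.
#' @param d_p,d_e primary / class capsule dimensionality.
#' @param n_class number of class capsules.
#' @param routing_iters dynamic-routing iterations (>= 1).
#' @param m_plus,m_minus,lambda_neg margin-loss constants.
#' @param variant `"caps"` (full model) or `"conv_fc"` (ablation).
#' @param w_init half-width of the uniform init for the routing transform
#'   matrices.
#' @param conv_init default initialization scheme for [capsnet_init()]:
#'   `"spectral"` (band-separable spectral kernels) or `"glorot"`.
#' @param init_bands optional band table used by the spectral init to match
#'   filter frequencies to their input slice.
#' @param sampling_rate_hz input sampling rate (used by the spectral init).
#' @return A `capsnet_config` list with derived shape fields
#'   (`t_out`, `h_out`, `w_out`, `merged`, `h4`, `w4`, `n_primary`).
#' @export
capsnet_config <- function(c_in = 5L, t_len = 1280L, grid_h = 5L,
                           grid_w = 5L, n_filters = 32L, kernel_t = 512L,
                           kernel_h = 3L, kernel_w = 3L, stride_t = 16L,
                           stride_h = 1L, stride_w = 1L,
                           conv2d_filters = 512L, c4 = 128L, d_p = 8L,
                           d_e = 16L, n_class = 2L, routing_iters = 3L,
                           m_plus = 0.9, m_minus = 0.1, lambda_neg = 0.5,
                           variant = c("caps", "conv_fc"), w_init = 0.1,
                           conv_init = c("spectral", "glorot"),
                           init_bands = NULL, sampling_rate_hz = 256) {
  variant <- match.arg(variant)
  conv_init <- match.arg(conv_init)
  stopifnot(routing_iters >= 1L, m_minus > 0, m_plus < 1, m_minus < m_plus)
  t_out <- (t_len - kernel_t) %/% stride_t + 1L
  h_out <- (grid_h - kernel_h) %/% stride_h + 1L
  w_out <- (grid_w - kernel_w) %/% stride_w + 1L
  if (t_out < 1L || h_out < 1L || w_out < 1L)
    stop("convolution kernel exceeds input extent")
  h4 <- h_out - 3L + 1L
  w4 <- w_out - 3L + 1L
  if (variant == "caps" && (h4 < 1L || w4 < 1L))
    stop("ConvBlock output too small for the 3x3 primary-capsule convolution")
  cfg <- list(c_in = c_in, t_len = t_len, grid_h = grid_h, grid_w = grid_w,
              n_filters = n_filters, kernel_t = kernel_t,
              kernel_h = kernel_h, kernel_w = kernel_w, stride_t = stride_t,
              stride_h = stride_h, stride_w = stride_w,
              conv2d_filters = conv2d_filters, c4 = c4, d_p = d_p,
              d_e = d_e, n_class = n_class, routing_iters = routing_iters,
              m_plus = m_plus, m_minus = m_minus, lambda_neg = lambda_neg,
              variant = variant, w_init = w_init,
              conv_init = conv_init, init_bands = init_bands,
              sampling_rate_hz = sampling_rate_hz,
              t_out = t_out, h_out = h_out, w_out = w_out,
              merged = n_filters * t_out, h4 = h4, w4 = w4,
              n_primary = c4 * max(h4, 0L) * max(w4, 0L))
  class(cfg) <- "capsnet_config"
  cfg
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Band-separable spectral initialization of the 3D-convolution kernels.
# Each filter starts as a *depthwise* probe: it attends to a single input
# band slice and a single spatial offset, with a Hann-windowed random-phase
# sinusoid as its temporal profile, frequency drawn log-uniformly inside
# that slice's nominal band (or 1-45 Hz when no band table is available).
# This is a sparse, band-separable prior in the spirit of sinc-filter and
# depthwise-separable EEG architectures: at initialization the filter bank
# already measures per-band, per-electrode oscillation amplitude -- the
# quantity the classifier must aggregate -- while remaining a free dense
# kernel for the optimizer.  Which bands or electrodes matter is left
# entirely to training (slots and frequencies are random).
spectral_conv3d_init <- function(cf, bands = NULL, sampling_rate_hz = 256) {
  krows <- cf$c_in * cf$kernel_t * cf$kernel_h * cf$kernel_w
  w <- matrix(0, krows, cf$n_filters)
  f_cap <- min(45, sampling_rate_hz / 2 * 0.7)
  tt <- seq_len(cf$kernel_t)
  win <- 0.5 - 0.5 * cos(2 * pi * (tt - 1) / (cf$kernel_t - 1))
  band_ok <- !is.null(bands) && nrow(bands) == cf$c_in &&
    !anyNA(bands$low_hz)
  for (f in seq_len(cf$n_filters)) {
    c0 <- sample.int(cf$c_in, 1L)
    dh <- sample.int(cf$kernel_h, 1L)
    dw <- sample.int(cf$kernel_w, 1L)
    if (band_ok) {
      # the slice's own band-pass kernel: the filter then reads off the
      # slice's instantaneous value, so its rectified output tracks the
      # per-band per-electrode oscillation amplitude
      f_lo <- max(bands$low_hz[c0], 0.5)
      f_hi <- max(min(bands$high_hz[c0], f_cap), f_lo * 1.2)
      nt <- cf$kernel_t - 1 + cf$kernel_t %% 2   # odd length <= kernel_t
      prof <- numeric(cf$kernel_t)
      prof[seq_len(nt)] <- fir_design(f_lo, f_hi, sampling_rate_hz, nt,
                                      window = "hanning")
      # random circular shift breaks ties between filters on the same slot
      prof <- prof[1L + (seq_len(cf$kernel_t) - 1L +
                           sample.int(cf$kernel_t, 1L)) %% cf$kernel_t]
    } else {
      f_lo <- 1
      f_hi <- f_cap
      f0 <- exp(stats::runif(1, log(f_lo), log(f_hi)))
      phi <- stats::runif(1, 0, 2 * pi)
      prof <- win * sin(2 * pi * f0 * tt / sampling_rate_hz + phi)
    }
    prof <- prof / sqrt(sum(prof^2))
    kern <- array(0, dim = c(cf$c_in, cf$kernel_t, cf$kernel_h, cf$kernel_w))
    kern[c0, , dh, dw] <- prof
    w[, f] <- as.numeric(kern)
  }
  w
}

# Temporal-average initialization of the 1x1 merge convolution: every
# output channel starts as a random mixture of *filters*, with weights
# shared across the merged temporal positions (plus a small symmetry-
# breaking perturbation), so time-averaged filter amplitude is linearly
# available to the capsule layers from the first step.
merge_conv_init <- function(cf) {
  g <- glorot(cf$conv2d_filters, cf$n_filters)
  # merged channel ordering is (filter fastest, then time)
  base <- g[, rep(seq_len(cf$n_filters), times = cf$t_out), drop = FALSE]
  base / cf$t_out + glorot(cf$conv2d_filters, cf$merged) * 0.1
}

#' Initialize model parameters
#'
#' @param config a `capsnet_config`.
#' @param seed RNG seed; initialization is deterministic given the seed.
#' @param conv_init `"spectral"` (default) gives the band-separable
#'   spectral initialization: each 3D kernel starts as a Hann-windowed
#'   random-frequency sinusoid probing one input band slice at one spatial
#'   offset, and the 1x1 merge convolution starts with time-shared mixing
#'   weights.  `"glorot"` gives plain uniform Glorot kernels everywhere.
#' @param bands optional band table (see [default_bands()]); with the
#'   spectral init, each filter's frequency is drawn inside its slice's
#'   nominal band.
#' @param sampling_rate_hz input sampling rate, used by the spectral init.
#' @return A `capsnet_model` (list of `config` and `params`).
#' @export
capsnet_init <- function(config, seed = 1L, conv_init = NULL, bands = NULL,
                         sampling_rate_hz = NULL) {
  if (is.null(conv_init))
    conv_init <- if (is.null(config$conv_init)) "spectral" else
      config$conv_init
  conv_init <- match.arg(conv_init, c("spectral", "glorot"))
  if (is.null(bands)) bands <- config$init_bands
  if (is.null(sampling_rate_hz))
    sampling_rate_hz <- if (is.null(config$sampling_rate_hz)) 256 else
      config$sampling_rate_hz
  set.seed(seed)
  cf <- config
  krows <- cf$c_in * cf$kernel_t * cf$kernel_h * cf$kernel_w
  p <- list(
    w1 = if (conv_init == "spectral")
      spectral_conv3d_init(cf, bands, sampling_rate_hz) else
        glorot(krows, cf$n_filters),
    b1 = rep(0, cf$n_filters),
    bn1 = bn_init(cf$n_filters),
    w2 = if (conv_init == "spectral") merge_conv_init(cf) else
      glorot(cf$conv2d_filters, cf$merged),
    b2 = rep(0, cf$conv2d_filters),
    bn2 = bn_init(cf$conv2d_filters)
  )
  sp <- cf$h_out * cf$w_out
  if (cf$variant == "caps") {
    p$w3 <- glorot(cf$c4 * cf$d_p, cf$conv2d_filters * 9L)
    p$b3 <- rep(0, cf$c4 * cf$d_p)
    # routing transforms: rows ordered (d_e fastest, then class)
    p$wr <- array(stats::runif(cf$n_class * cf$d_e * cf$d_p * cf$n_primary,
                               -cf$w_init, cf$w_init),
                  dim = c(cf$n_class * cf$d_e, cf$d_p, cf$n_primary))
  } else {
    p$wfc <- glorot(cf$n_class, cf$conv2d_filters * sp)
    p$bfc <- rep(0, cf$n_class)
  }
  structure(list(config = cf, params = p), class = "capsnet_model")
}

#' Squash nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`, with `||s||` computed as
#' `sqrt(sum(s^2) + 1e-9)` so the zero vector maps to the zero vector.
#' Output is parallel to the input with norm in `[0, 1)`.
#'
#' @param s numeric vector, or a matrix whose *columns* are squashed
#'   independently.
#' @return Same shape as `s`.
#' @export
squash <- function(s) {
  if (is.matrix(s)) {
    n <- sqrt(colSums(s^2) + 1e-9)
    return(sweep(s, 2L, n / (1 + n^2), "*"))
  }
  n <- sqrt(sum(s^2) + 1e-9)
  s * n / (1 + n^2)
}

# backward of column-wise squash: s, dv (d x m) -> ds
squash_backward <- function(s, dv) {
  n <- sqrt(colSums(s^2) + 1e-9)
  alpha <- n / (1 + n^2)
  alphap <- (1 - n^2) / (1 + n^2)^2
  dot <- colSums(s * dv)
  sweep(dv, 2L, alpha, "*") + sweep(s, 2L, dot * alphap / n, "*")
}

#' Margin loss on class-capsule norms
#'
#' `L_l = T_l max(0, m+ - ||v_l||)^2 + lambda (1 - T_l)
#' max(0, ||v_l|| - m-)^2`, summed over the class capsules.  Zero exactly
#' when the true capsule's norm reaches `m_plus` and every other norm is at
#' or below `m_minus`.
#'
#' @param v class capsules as an (n_class x d_e) matrix, or a vector of
#'   capsule norms.
#' @param label true class in `0:(n_class-1)`.
#' @param m_plus,m_minus,lambda_neg loss constants.
#' @return Scalar total loss.
#' @export
margin_loss <- function(v, label, m_plus = 0.9, m_minus = 0.1,
                        lambda_neg = 0.5) {
  norms <- if (is.matrix(v)) sqrt(rowSums(v^2)) else v
  tl <- as.numeric(seq_along(norms) - 1L == label)
  sum(tl * pmax(0, m_plus - norms)^2 +
        lambda_neg * (1 - tl) * pmax(0, norms - m_minus)^2)
}

# vectorized margin loss over a batch: norms (n_class x B), labels in 0..
margin_loss_batch <- function(norms, labels, cf) {
  tl <- outer(seq_len(nrow(norms)) - 1L, labels, "==") * 1
  per_caps <- tl * pmax(0, cf$m_plus - norms)^2 +
    cf$lambda_neg * (1 - tl) * pmax(0, norms - cf$m_minus)^2
  colSums(per_caps)
}

margin_loss_grad_norms <- function(norms, labels, cf) {
  tl <- outer(seq_len(nrow(norms)) - 1L, labels, "==") * 1
  -2 * tl * pmax(0, cf$m_plus - norms) +
    2 * cf$lambda_neg * (1 - tl) * pmax(0, norms - cf$m_minus)
}

#' Dynamic routing between capsule layers
#'
#' Iterative routing-by-agreement: prediction vectors
#' `u_hat[i, j] = W[, , i, j] %*% u[i, ]`, coupling coefficients
#' `c_ij = softmax_j(b_ij)` starting from zero logits, weighted sums
#' `s_j = sum_i c_ij u_hat[i, j]`, outputs `v_j = squash(s_j)`, and logit
#' updates `b_ij <- b_ij + <v_j, u_hat[i, j]>` after every iteration except
#' the last.
#'
#' @param u primary capsules (n_primary x d_p).
#' @param w transform array (d_e, d_p, n_primary, n_class).
#' @param iterations number of routing iterations r >= 1.
#' @return List: `v` (n_class x d_e), `coupling` (n_primary x n_class,
#'   rows summing to 1), `logits`, `uhat` (n_primary x n_class x d_e),
#'   `s` (n_class x d_e).
#' @export
dynamic_routing <- function(u, w, iterations = 3L) {
  np <- nrow(u)
  dp <- ncol(u)
  de <- dim(w)[1]
  nc <- dim(w)[4]
  stopifnot(dim(w)[2] == dp, dim(w)[3] == np, iterations >= 1L)
  uhat <- array(0, dim = c(np, nc, de))
  for (i in seq_len(np))
    for (j in seq_len(nc))
      uhat[i, j, ] <- w[, , i, j] %*% u[i, ]
  b <- matrix(0, np, nc)
  for (it in seq_len(iterations)) {
    cc <- t(apply(b, 1L, function(r) {
      e <- exp(r - max(r))
      e / sum(e)
    }))
    s <- matrix(0, nc, de)
    for (j in seq_len(nc))
      s[j, ] <- colSums(cc[, j] * uhat[, j, ])
    v <- t(squash(t(s)))
    if (it < iterations) {
      for (j in seq_len(nc))
        b[, j] <- b[, j] + uhat[, j, ] %*% v[j, ]
    }
  }
  list(v = v, coupling = cc, logits = b, uhat = uhat, s = s)
}

#' PrimaryCaps stage as a standalone operation
#'
#' Applies the D_P parallel 3x3 valid convolutions (realized as one matrix
#' multiply with `c4 * d_p` output channels), reshapes and concatenates into
#' the primary capsule matrix, and squashes each capsule.
#'
#' @param feature_map array (conv2d_filters, h, w) from the ConvBlock.
#' @param w3,b3 weights `(c4*d_p) x (conv2d_filters*9)` and bias; taken from
#'   `model$params` when a model is given instead.
#' @param config a `capsnet_config`.
#' @return Capsule matrix (n_primary x d_p).
#' @export
primary_caps <- function(feature_map, w3, b3, config) {
  cf <- config
  d <- dim(feature_map)
  stopifnot(length(d) == 3L, d[1] == cf$conv2d_filters)
  xb <- array(feature_map, dim = c(d, 1L))
  pp <- primary_patches(xb, cf)
  upre <- w3 %*% pp$patches + b3
  u <- array(upre, dim = c(cf$c4, cf$d_p, pp$p4))
  u <- aperm(u, c(2L, 1L, 3L))           # (d_p, c4, p4)
  dim(u) <- c(cf$d_p, cf$n_primary)
  t(squash(u))
}

# gather 3x3 patches of a (cf$conv2d_filters, h_out, w_out, B) array into a
# (conv2d_filters*9 x p4*B) matrix, columns ordered (position fastest, batch)
primary_patches <- function(z, cf) {
  ch <- dim(z)[1]
  B <- dim(z)[4]
  p4 <- cf$h4 * cf$w4
  if (p4 == 1L) {
    patches <- matrix(z, ch * 9L, B)
    return(list(patches = patches, p4 = 1L))
  }
  patches <- matrix(0, ch * 9L, p4 * B)
  for (b in seq_len(B)) {
    k <- 0L
    for (w0 in seq_len(cf$w4)) for (h0 in seq_len(cf$h4)) {
      k <- k + 1L
      patch <- z[, h0:(h0 + 2L), w0:(w0 + 2L), b]
      patches[, (b - 1L) * p4 + k] <- as.numeric(patch)
    }
  }
  list(patches = patches, p4 = p4)
}

# scatter-add the patch gradient back (inverse of primary_patches)
primary_patches_backward <- function(dpatches, zdim, cf) {
  ch <- zdim[1]
  B <- zdim[4]
  p4 <- cf$h4 * cf$w4
  if (p4 == 1L) return(array(dpatches, dim = zdim))
  dz <- array(0, dim = zdim)
  for (b in seq_len(B)) {
    k <- 0L
    for (w0 in seq_len(cf$w4)) for (h0 in seq_len(cf$h4)) {
      k <- k + 1L
      dz[, h0:(h0 + 2L), w0:(w0 + 2L), b] <-
        dz[, h0:(h0 + 2L), w0:(w0 + 2L), b] +
        array(dpatches[, (b - 1L) * p4 + k], dim = c(ch, 3L, 3L))
    }
  }
  dz
}

as_input_batch <- function(x, cf) {
  if (inherits(x, "tsf_sample")) x <- list(x)
  if (is.list(x)) {
    x <- lapply(x, function(s) if (inherits(s, "tsf_sample")) s$tensor else s)
    dims <- dim(x[[1]])
    xb <- array(0, dim = c(dims, length(x)))
    for (b in seq_along(x)) xb[, , , , b] <- x[[b]]
    x <- xb
  }
  d <- dim(x)
  if (length(d) == 4L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  stopifnot(length(d) == 5L)
  if (!all(d[1:4] == c(cf$c_in, cf$t_len, cf$grid_h, cf$grid_w)))
    stop("input tensor dims (", paste(d[1:4], collapse = ", "),
         ") do not match model config (",
         paste(c(cf$c_in, cf$t_len, cf$grid_h, cf$grid_w), collapse = ", "),
         ")")
  x
}

#' Forward pass of the classifier
#'
#' @param model a `capsnet_model`.
#' @param x one sample tensor (C, T, H, W), a list of samples /
#'   `tsf_sample`s, or a batched array (C, T, H, W, B).
#' @param training use batch statistics (and record caches for the backward
#'   pass) instead of running statistics.
#' @return List with `probs` (n_class x B softmax over capsule norms or FC
#'   logits), `norms` (caps variant), `v` (d_e, n_class, B), `conv_out`
#'   (conv2d_filters, h_out, w_out, B), `model` (with updated BN running
#'   statistics when training), and `cache` when `training = TRUE`.
#' @export
capsnet_forward <- function(model, x, training = FALSE) {
  cf <- model$config
  p <- model$params
  xb <- as_input_batch(x, cf)
  B <- dim(xb)[5]
  n_pos <- cf$t_out * cf$h_out * cf$w_out
  sp <- cf$h_out * cf$w_out
  dims <- as.integer(c(cf$c_in, cf$t_len, cf$grid_h, cf$grid_w))
  kern <- as.integer(c(cf$kernel_t, cf$kernel_h, cf$kernel_w))
  strd <- as.integer(c(cf$stride_t, cf$stride_h, cf$stride_w))

  a1 <- array(0, dim = c(cf$n_filters, n_pos, B))
  for (b in seq_len(B)) {
    y <- cpp_conv3d_forward(as.numeric(xb[, , , , b]), dims, p$w1, kern, strd)
    a1[, , b] <- t(y) + p$b1
  }
  a1m <- matrix(a1, cf$n_filters, n_pos * B)
  bn1 <- bn_forward(a1m, p$bn1, training)
  r1 <- relu_forward(bn1$y)
  z1 <- array(r1$y, dim = c(cf$n_filters, cf$t_out, sp, B))
  x2 <- matrix(z1, cf$merged, sp * B)
  a2 <- p$w2 %*% x2 + p$b2
  bn2 <- bn_forward(a2, p$bn2, training)
  r2 <- relu_forward(bn2$y)
  z2 <- array(r2$y, dim = c(cf$conv2d_filters, cf$h_out, cf$w_out, B))

  model$params$bn1 <- bn1$bn
  model$params$bn2 <- bn2$bn

  if (cf$variant == "conv_fc") {
    xf <- matrix(r2$y, cf$conv2d_filters * sp, B)
    logits <- p$wfc %*% xf + p$bfc
    probs <- softmax_cols(logits)
    cache <- if (training)
      list(xb = xb, a1 = a1, bn1 = bn1$cache, r1mask = r1$mask,
           x2 = x2, bn2 = bn2$cache, r2mask = r2$mask, xf = xf,
           probs = probs, B = B)
    return(list(probs = probs, logits = logits, conv_out = z2,
                model = model, cache = cache))
  }

  pp <- primary_patches(z2, cf)
  upre <- p$w3 %*% pp$patches + p$b3
  u4 <- array(upre, dim = c(cf$c4, cf$d_p, pp$p4, B))
  u4 <- aperm(u4, c(2L, 1L, 3L, 4L))       # (d_p, c4, p4, B)
  u0 <- matrix(u4, cf$d_p, cf$n_primary * B) # capsule columns, i fastest
  usq <- squash(u0)

  # prediction vectors per class: uj[[j]] is (n_primary x d_e*B),
  # columns ordered (d_e fastest, then batch)
  uhat <- array(0, dim = c(cf$n_class * cf$d_e, cf$n_primary, B))
  for (i in seq_len(cf$n_primary)) {
    ui <- matrix(usq[, seq(i, by = cf$n_primary, length.out = B)],
                 cf$d_p, B)
    uhat[, i, ] <- p$wr[, , i] %*% ui
  }
  uh4 <- array(uhat, dim = c(cf$d_e, cf$n_class, cf$n_primary, B))
  uj <- vector("list", cf$n_class)
  for (j in seq_len(cf$n_class)) {
    tmp <- aperm(array(uh4[, j, , ], dim = c(cf$d_e, cf$n_primary, B)),
                 c(2L, 1L, 3L))
    uj[[j]] <- matrix(tmp, cf$n_primary, cf$d_e * B)
  }

  blog <- array(0, dim = c(cf$n_primary, cf$n_class, B))
  iters <- vector("list", cf$routing_iters)
  de_idx <- rep(seq_len(B), each = cf$d_e)
  for (it in seq_len(cf$routing_iters)) {
    bmax <- blog[, 1L, ]
    for (j in seq_len(cf$n_class))
      bmax <- pmax(bmax, blog[, j, ])
    esum <- 0
    emat <- vector("list", cf$n_class)
    for (j in seq_len(cf$n_class)) {
      emat[[j]] <- exp(matrix(blog[, j, ], cf$n_primary, B) - bmax)
      esum <- esum + emat[[j]]
    }
    cc <- lapply(emat, function(e) e / esum)   # list of (n_primary x B)
    s <- array(0, dim = c(cf$d_e, cf$n_class, B))
    v <- array(0, dim = c(cf$d_e, cf$n_class, B))
    norms <- matrix(0, cf$n_class, B)
    for (j in seq_len(cf$n_class)) {
      cj_rep <- cc[[j]][, de_idx, drop = FALSE]
      sj <- matrix(colSums(uj[[j]] * cj_rep), cf$d_e, B)
      nj <- sqrt(colSums(sj^2) + 1e-9)
      s[, j, ] <- sj
      v[, j, ] <- sweep(sj, 2L, nj / (1 + nj^2), "*")
      norms[j, ] <- sqrt(colSums(matrix(v[, j, ], cf$d_e, B)^2))
    }
    iters[[it]] <- list(cc = cc, s = s, v = v)
    if (it < cf$routing_iters) {
      for (j in seq_len(cf$n_class)) {
        tmp <- uj[[j]] * rep_rows(as.numeric(v[, j, ]), cf$n_primary)
        dim(tmp) <- c(cf$n_primary, cf$d_e, B)
        agree <- colSums(aperm(tmp, c(2L, 1L, 3L)))
        blog[, j, ] <- matrix(blog[, j, ], cf$n_primary, B) + agree
      }
    }
  }
  vfin <- iters[[cf$routing_iters]]$v
  norms <- matrix(0, cf$n_class, B)
  for (j in seq_len(cf$n_class))
    norms[j, ] <- sqrt(colSums(matrix(vfin[, j, ], cf$d_e, B)^2))
  probs <- softmax_cols(norms)

  cache <- if (training)
    list(xb = xb, a1 = a1, bn1 = bn1$cache, r1mask = r1$mask, x2 = x2,
         bn2 = bn2$cache, r2mask = r2$mask, zdim = dim(z2), pp = pp,
         u0 = u0, usq = usq, uj = uj, iters = iters, B = B)
  list(probs = probs, norms = norms, v = vfin, conv_out = z2,
       model = model, cache = cache)
}

#' Backward pass: margin-loss (or cross-entropy) gradients
#'
#' Backpropagates the batch-mean loss through the unrolled routing loop,
#' the capsule layers and the convolution block.  Returns gradients with the
#' same shapes as the parameters (BN running statistics excluded).
#'
#' @param model a `capsnet_model`.
#' @param fwd result of `capsnet_forward(..., training = TRUE)`.
#' @param labels integer vector in `0:(n_class-1)`, length B.
#' @return List with `loss` (batch mean) and `grads`.
#' @keywords internal
capsnet_backward <- function(model, fwd, labels) {
  cf <- model$config
  p <- model$params
  cache <- fwd$cache
  B <- cache$B
  sp <- cf$h_out * cf$w_out
  grads <- list()

  if (cf$variant == "conv_fc") {
    probs <- cache$probs
    onehot <- outer(seq_len(cf$n_class) - 1L, labels, "==") * 1
    eps <- 1e-12
    loss <- -mean(colSums(onehot * log(probs + eps)))
    dlogits <- (probs - onehot) / B
    grads$wfc <- dlogits %*% t(cache$xf)
    grads$bfc <- rowSums(dlogits)
    dxf <- t(p$wfc) %*% dlogits
    dz2 <- matrix(dxf, cf$conv2d_filters, sp * B)
  } else {
    vfin <- fwd$v
    norms <- fwd$norms
    loss <- mean(margin_loss_batch(norms, labels, cf))
    dnorm <- margin_loss_grad_norms(norms, labels, cf) / B
    dv <- array(0, dim = c(cf$d_e, cf$n_class, B))
    for (j in seq_len(cf$n_class)) {
      vj <- matrix(vfin[, j, ], cf$d_e, B)
      nj <- pmax(norms[j, ], 1e-12)
      dv[, j, ] <- sweep(vj, 2L, dnorm[j, ] / nj, "*")
    }

    de_idx <- rep(seq_len(B), each = cf$d_e)
    duj <- lapply(seq_len(cf$n_class),
                  function(j) matrix(0, cf$n_primary, cf$d_e * B))
    db <- array(0, dim = c(cf$n_primary, cf$n_class, B))
    for (it in seq(cf$routing_iters, 1L)) {
      st <- cache$iters[[it]]
      dvt <- array(0, dim = c(cf$d_e, cf$n_class, B))
      if (it == cf$routing_iters) dvt <- dv
      if (it < cf$routing_iters) {
        # b_it = b_{it-1} + <v_it, uhat>; db currently holds grad wrt b_it
        for (j in seq_len(cf$n_class)) {
          dbj <- matrix(db[, j, ], cf$n_primary, B)
          dbj_rep <- dbj[, de_idx, drop = FALSE]
          dvt[, j, ] <- matrix(dvt[, j, ], cf$d_e, B) +
            matrix(colSums(cache$uj[[j]] * dbj_rep), cf$d_e, B)
          duj[[j]] <- duj[[j]] +
            dbj_rep * rep_rows(as.numeric(st$v[, j, ]), cf$n_primary)
        }
      }
      dc <- array(0, dim = c(cf$n_primary, cf$n_class, B))
      for (j in seq_len(cf$n_class)) {
        sj <- matrix(st$s[, j, ], cf$d_e, B)
        dsj <- squash_backward(sj, matrix(dvt[, j, ], cf$d_e, B))
        dsj_flat <- as.numeric(dsj)
        tmp <- cache$uj[[j]] * rep_rows(dsj_flat, cf$n_primary)
        dim(tmp) <- c(cf$n_primary, cf$d_e, B)
        dc[, j, ] <- colSums(aperm(tmp, c(2L, 1L, 3L)))
        duj[[j]] <- duj[[j]] +
          st$cc[[j]][, de_idx, drop = FALSE] * rep_rows(dsj_flat, cf$n_primary)
      }
      # softmax over classes, rows (i, b) independent
      dot <- matrix(0, cf$n_primary, B)
      for (j in seq_len(cf$n_class))
        dot <- dot + st$cc[[j]] * matrix(dc[, j, ], cf$n_primary, B)
      dbprev <- array(0, dim = dim(db))
      for (j in seq_len(cf$n_class))
        dbprev[, j, ] <- st$cc[[j]] *
          (matrix(dc[, j, ], cf$n_primary, B) - dot)
      if (it < cf$routing_iters) dbprev <- dbprev + db
      db <- dbprev
    }
    # assemble duhat (d_e*n_class, n_primary, B) from the per-class pieces
    duh4 <- array(0, dim = c(cf$d_e, cf$n_class, cf$n_primary, B))
    for (j in seq_len(cf$n_class)) {
      tmp <- array(duj[[j]], dim = c(cf$n_primary, cf$d_e, B))
      duh4[, j, , ] <- aperm(tmp, c(2L, 1L, 3L))
    }
    duhat <- array(duh4, dim = c(cf$n_class * cf$d_e, cf$n_primary, B))
    grads$wr <- array(0, dim = dim(p$wr))
    dusq <- matrix(0, cf$d_p, cf$n_primary * B)
    for (i in seq_len(cf$n_primary)) {
      cols <- seq(i, by = cf$n_primary, length.out = B)
      ui <- matrix(cache$usq[, cols], cf$d_p, B)
      dui_hat <- matrix(duhat[, i, ], cf$n_class * cf$d_e, B)
      grads$wr[, , i] <- dui_hat %*% t(ui)
      dusq[, cols] <- t(p$wr[, , i]) %*% dui_hat
    }
    du0 <- squash_backward(cache$u0, dusq)
    du4 <- array(du0, dim = c(cf$d_p, cf$c4, cache$pp$p4, B))
    dupre <- matrix(aperm(du4, c(2L, 1L, 3L, 4L)),
                    cf$c4 * cf$d_p, cache$pp$p4 * B)
    grads$w3 <- dupre %*% t(cache$pp$patches)
    grads$b3 <- rowSums(dupre)
    dpatches <- t(p$w3) %*% dupre
    dz2arr <- primary_patches_backward(dpatches, cache$zdim, cf)
    dz2 <- matrix(dz2arr, cf$conv2d_filters, sp * B)
  }

  dr2 <- relu_backward(dz2, cache$r2mask)
  bn2b <- bn_backward(dr2, cache$bn2)
  grads$bn2 <- list(gamma = bn2b$dgamma, beta = bn2b$dbeta)
  da2 <- bn2b$dx
  grads$w2 <- da2 %*% t(cache$x2)
  grads$b2 <- rowSums(da2)
  dx2 <- t(p$w2) %*% da2
  dz1 <- array(dx2, dim = c(cf$n_filters,
                            cf$t_out * sp * B))
  dr1 <- relu_backward(dz1, matrix(cache$r1mask, cf$n_filters,
                                   cf$t_out * sp * B))
  bn1b <- bn_backward(dr1, cache$bn1)
  grads$bn1 <- list(gamma = bn1b$dgamma, beta = bn1b$dbeta)
  da1 <- array(bn1b$dx, dim = c(cf$n_filters,
                                cf$t_out * sp, B))
  dims <- as.integer(c(cf$c_in, cf$t_len, cf$grid_h, cf$grid_w))
  kern <- as.integer(c(cf$kernel_t, cf$kernel_h, cf$kernel_w))
  strd <- as.integer(c(cf$stride_t, cf$stride_h, cf$stride_w))
  grads$w1 <- matrix(0, nrow(p$w1), ncol(p$w1))
  for (b in seq_len(B)) {
    dy <- t(matrix(da1[, , b], cf$n_filters, cf$t_out * sp))
    grads$w1 <- grads$w1 +
      cpp_conv3d_wgrad(as.numeric(cache$xb[, , , , b]), dims, dy, kern, strd)
  }
  grads$b1 <- rowSums(matrix(da1, cf$n_filters, cf$t_out * sp * B))
  list(loss = loss, grads = grads)
}

#' Save / load a model checkpoint
#'
#' Serializes the model together with a hash of its configuration; loading
#' verifies the hash so a checkpoint cannot silently be used with a
#' different architecture.
#'
#' @param model a `capsnet_model`.
#' @param path destination `.rds` file.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(model = model, config_hash = config_hash(model$config))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$config_hash, config_hash(obj$model$config)))
    stop("checkpoint config hash mismatch; file corrupted?")
  obj$model
}

#' Class probabilities and predictions for a batch
#'
#' Runs the model in inference mode (BN running statistics) and reports the
#' softmax over class-capsule norms (or FC logits for the `conv_fc`
#' variant); the predicted label is the argmax.
#'
#' @param model a trained `capsnet_model`.
#' @param samples list of samples / batched array (see [capsnet_forward()]).
#' @param batch_size evaluation micro-batch size.
#' @return data.frame with `pred` and one probability column per class.
#' @export
capsnet_predict <- function(model, samples, batch_size = 32L) {
  if (inherits(samples, "tsf_sample")) samples <- list(samples)
  n <- if (is.list(samples)) length(samples) else dim(samples)[5]
  idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  out <- lapply(idx, function(ii) {
    batch <- if (is.list(samples)) samples[ii] else
      samples[, , , , ii, drop = FALSE]
    fwd <- capsnet_forward(model, batch, training = FALSE)
    t(fwd$probs)
  })
  probs <- do.call(rbind, out)
  colnames(probs) <- paste0("prob_", seq_len(ncol(probs)) - 1L)
  data.frame(pred = max.col(probs, ties.method = "first") - 1L, probs)
}
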