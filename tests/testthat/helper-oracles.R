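# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (triple loops, step-by-step transcriptions) and share
# no code with the implementation they check.

# direct triple-loop strided valid 3D convolution
brute_conv3d <- function(x, k, stride) {
  d <- dim(x)
  dk <- dim(k)
  to <- (d[2] - dk[2]) %/% stride[1] + 1
  ho <- (d[3] - dk[3]) %/% stride[2] + 1
  wo <- (d[4] - dk[4]) %/% stride[3] + 1
  y <- array(0, c(dk[5], to, ho, wo))
  for (f in 1:dk[5]) for (t0 in 1:to) for (h0 in 1:ho) for (w0 in 1:wo) {
    acc <- 0
    for (c in 1:d[1]) for (dt in 1:dk[2]) for (dh in 1:dk[3])
      for (dw in 1:dk[4])
        acc <- acc + x[c, (t0 - 1) * stride[1] + dt,
                       (h0 - 1) * stride[2] + dh,
                       (w0 - 1) * stride[3] + dw] * k[c, dt, dh, dw, f]
    y[f, t0, h0, w0] <- acc
  }
  y
}

# step-by-step routing transcription: softmax over classes, weighted sum,
# squash, agreement update (skipped on the last iteration)
routing_transcription <- function(u, w, r) {
  np <- nrow(u); nc <- dim(w)[4]; de <- dim(w)[1]
  uhat <- array(0, c(np, nc, de))
  for (i in 1:np) for (j in 1:nc) uhat[i, j, ] <- w[, , i, j] %*% u[i, ]
  b <- matrix(0, np, nc)
  cc <- NULL; s <- NULL; v <- NULL
  for (it in 1:r) {
    cc <- matrix(0, np, nc)
    for (i in 1:np) {
      e <- exp(b[i, ] - max(b[i, ]))
      cc[i, ] <- e / sum(e)
    }
    s <- matrix(0, nc, de)
    for (j in 1:nc) for (i in 1:np) s[j, ] <- s[j, ] + cc[i, j] * uhat[i, j, ]
    v <- matrix(0, nc, de)
    for (j in 1:nc) {
      nrm <- sqrt(sum(s[j, ]^2) + 1e-9)
      v[j, ] <- s[j, ] * nrm / (1 + nrm^2)
    }
    if (it < r)
      for (i in 1:np) for (j in 1:nc)
        b[i, j] <- b[i, j] + sum(v[j, ] * uhat[i, j, ])
  }
  list(v = v, coupling = cc, s = s)
}

# scalar transcription of the per-class hinge-squared margin loss
margin_loss_scalar <- function(norms, label, m_plus = 0.9, m_minus = 0.1,
                               lambda = 0.5) {
  total <- 0
  for (l in seq_along(norms)) {
    tl <- if (l - 1 == label) 1 else 0
    total <- total + tl * max(0, m_plus - norms[l])^2 +
      lambda * (1 - tl) * max(0, norms[l] - m_minus)^2
  }
  total
}

# spectral power of a signal inside [low, high) Hz via the raw periodogram
periodogram_band_power <- function(x, fs, low, high) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  sum(p[half & freqs >= low & freqs < high])
}

# small helpers for building fixtures ------------------------------------

toy_recording <- function(n_seconds = 10, fs = 256, seed = 1,
                          subject_id = "t01", label = 0,
                          channels = eegcaps:::MONTAGE_CHANNELS) {
  set.seed(seed)
  n <- floor(n_seconds * fs)
  data <- matrix(rnorm(length(channels) * n, sd = 10),
                 length(channels), n,
                 dimnames = list(channels, NULL))
  new_recording(data, channels, fs, subject_id, label)
}

sine_recording <- function(freq_hz, n_seconds = 8, fs = 256, amp = 10,
                           channels = c("Fp1", "Fp2")) {
  t <- seq_len(n_seconds * fs) / fs
  data <- matrix(rep(amp * sin(2 * pi * freq_hz * t), length(channels)),
                 length(channels), length(t), byrow = TRUE,
                 dimnames = list(channels, NULL))
  new_recording(data, channels, fs, "sine", 0)
}

tiny_caps_config <- function(...) {
  capsnet_config(c_in = 2L, t_len = 32L, grid_h = 5L, grid_w = 5L,
                 n_filters = 3L, kernel_t = 8L, stride_t = 4L,
                 conv2d_filters = 6L, c4 = 4L, d_p = 3L, d_e = 4L,
                 routing_iters = 3L, ...)
}

tiny_segment <- function(fs = 256, seconds = 5, seed = 1,
                         channels = eegcaps:::MONTAGE_CHANNELS) {
  set.seed(seed)
  data <- matrix(rnorm(length(channels) * fs * seconds),
                 length(channels), fs * seconds,
                 dimnames = list(channels, NULL))
  new_segment(zscore_standardize(data), "t01", 0, 1, fs)
}
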