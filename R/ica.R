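#' ICA-based artifact removal with pluggable component selection
#'
#' Artifact removal decomposes the multichannel signal into independent
#' components (FastICA, logcosh nonlinearity, symmetric decorrelation) and
#' reconstructs it from the components a *selection policy* decides to keep.
#' The decomposition is standard; which components count as artifacts is not
#' automatable faithfully, so the policy is injected: the bundled identity
#' policy keeps everything (and short-circuits, returning the input exactly),
#' and a variance/kurtosis threshold policy rejects components that are
#' extreme outliers on either statistic, which captures high-amplitude
#' ocular/spike components.
#'
#' @name ica
NULL

#' FastICA decomposition
#'
#' Symmetric fixed-point FastICA with the logcosh contrast.  Rows of `x` are
#' centered and whitened through an eigendecomposition of the channel
#' covariance before the rotation is estimated.
#'
#' @param x numeric matrix (n_channels x n_samples).
#' @param n_components number of components (default: all channels).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed RNG seed for the random orthonormal start.
#' @return List with `sources` (k x n_samples), `mixing` (n_channels x k)
#'   and `means` (per-channel means) such that
#'   `x = mixing %*% sources + means`.
#' @export
fastica_decompose <- function(x, n_components = nrow(x), max_iter = 200L,
                              tol = 1e-6, seed = 1L) {
  stopifnot(is.matrix(x), n_components <= nrow(x))
  n <- ncol(x)
  means <- rowMeans(x)
  xc <- x - means
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values))
    stop("rank-deficient input; check for duplicate or flat channels")
  k <- n_components
  d <- eg$values[seq_len(k)]
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  wh <- diag(1 / sqrt(d), k) %*% t(E)       # whitening: z = wh %*% xc
  dewh <- E %*% diag(sqrt(d), k)            # xc = dewh %*% z
  z <- wh %*% xc
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    W1 <- g %*% t(z) / n - diag(rowMeans(gp), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  sources <- W %*% z
  mixing <- dewh %*% t(W)
  list(sources = sources, mixing = mixing, means = means)
}

#' Component-selection policies
#'
#' A selector is a function `f(sources, mixing)` returning a logical keep
#' vector, wrapped with class `ica_selector`.
#'
#' @return An `ica_selector`.
#' @export
selector_identity <- function() {
  structure(function(sources, mixing) rep(TRUE, nrow(sources)),
            class = "ica_selector", identity = TRUE)
}

#' @rdname selector_identity
#' @export
selector_none <- function() {
  structure(function(sources, mixing) rep(FALSE, nrow(sources)),
            class = "ica_selector", identity = FALSE)
}

#' @rdname selector_identity
#' @param var_z,kurt_z robust z-score thresholds on per-component projected
#'   variance and excess kurtosis; components exceeding either are rejected.
#' @export
selector_threshold <- function(var_z = 3, kurt_z = 3) {
  f <- function(sources, mixing) {
    # variance each component contributes to the sensors
    contrib <- colSums(mixing^2) * apply(sources, 1L, stats::var)
    kurt <- apply(sources, 1L, function(s) {
      s <- s - mean(s)
      mean(s^4) / mean(s^2)^2 - 3
    })
    rz <- function(v) {
      md <- stats::median(v)
      sc <- stats::mad(v)
      if (sc < 1e-12) sc <- stats::sd(v) + 1e-12
      (v - md) / sc
    }
    !(rz(contrib) > var_z | rz(kurt) > kurt_z)
  }
  structure(f, class = "ica_selector", identity = FALSE)
}

#' Remove artifact components from a recording
#'
#' With the identity selector the recording is returned unchanged (bitwise).
#' Otherwise the signal is decomposed with [fastica_decompose()] and
#' reconstructed from the kept components (plus the channel means).
#'
#' @param rec an `eeg_recording` (already filtered).
#' @param selector an `ica_selector` policy.
#' @param seed seed forwarded to the decomposition.
#' @return The cleaned recording, same shape and metadata.
#' @export
remove_artifacts <- function(rec, selector = selector_identity(), seed = 1L) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(selector, "ica_selector"))
  if (isTRUE(attr(selector, "identity"))) return(rec)
  dec <- fastica_decompose(rec$data, seed = seed)
  keep <- selector(dec$sources, dec$mixing)
  clean <- dec$mixing[, keep, drop = FALSE] %*%
    dec$sources[keep, , drop = FALSE] + dec$means
  dimnames(clean) <- dimnames(rec$data)
  rec$data <- clean
  rec
}
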