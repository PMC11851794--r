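test_that("conv3d matches the brute-force triple-loop oracle", {
  set.seed(31)
  cases <- list(list(d = c(2, 8, 4, 4), k = c(4, 2, 2), s = c(2, 1, 1), f = 3),
                list(d = c(1, 6, 3, 3), k = c(3, 3, 3), s = c(1, 1, 1), f = 2),
                list(d = c(2, 8, 4, 4), k = c(2, 2, 2), s = c(3, 2, 2), f = 4))
  for (cs in cases) {
    x <- array(rnorm(prod(cs$d)), cs$d)
    k <- array(rnorm(cs$d[1] * prod(cs$k) * cs$f),
               c(cs$d[1], cs$k, cs$f))
    expect_equal(conv3d_forward(x, k, cs$s), brute_conv3d(x, k, cs$s),
                 tolerance = 1e-5)
  }
  # constant-sum check: all-ones kernel and input
  x <- array(1, c(5, 520, 3, 3))
  k <- array(1, c(5, 512, 3, 3, 1))
  y <- conv3d_forward(x, k, c(16, 1, 1))
  expect_true(all(y == 512 * 3 * 3 * 5))
  expect_error(conv3d_forward(array(0, c(2, 4, 3, 3)),
                              array(0, c(2, 8, 3, 3, 1)), c(1, 1, 1)),
               "exceeds")
})

test_that("the default configuration reproduces the published shape chain", {
  cfg <- capsnet_config()
  expect_equal(cfg$t_out, 49L)
  expect_equal(c(cfg$h_out, cfg$w_out), c(3L, 3L))
  expect_equal(cfg$merged, 1568L)             # 32 filters x 49 steps
  expect_equal(cfg$n_primary, 128L)
  m <- capsnet_init(cfg, seed = 1)
  set.seed(2)
  x <- array(rnorm(5 * 1280 * 5 * 5, sd = 0.3), c(5, 1280, 5, 5))
  fwd <- capsnet_forward(m, x)
  expect_equal(dim(fwd$conv_out), c(512L, 3L, 3L, 1L))
  expect_equal(dim(fwd$v), c(16L, 2L, 1L))
  expect_equal(dim(fwd$probs), c(2L, 1L))
  expect_equal(sum(fwd$probs), 1, tolerance = 1e-8)
  # ReLU stage output is nonnegative; capsule norms inside [0, 1)
  expect_true(all(fwd$conv_out >= 0))
  expect_true(all(fwd$norms >= 0 & fwd$norms < 1))
})

test_that("primary caps concatenate to (n_primary x d_p) with branch isolation", {
  cfg <- capsnet_config()
  m <- capsnet_init(cfg, seed = 1)
  set.seed(3)
  fmap <- array(rnorm(512 * 3 * 3), c(512, 3, 3))
  u <- primary_caps(fmap, m$params$w3, m$params$b3, cfg)
  expect_equal(dim(u), c(128L, 8L))
  # zero input and bias give zero capsules
  u0 <- primary_caps(array(0, c(512, 3, 3)), m$params$w3 * 0,
                     m$params$b3 * 0, cfg)
  expect_true(all(u0 == 0))
  # only branch d's weights nonzero -> only capsule dimension d nonzero
  w3 <- m$params$w3 * 0
  d_iso <- 3L
  rows <- (d_iso - 1L) * cfg$c4 + seq_len(cfg$c4)
  w3[rows, ] <- m$params$w3[rows, ]
  u_iso <- primary_caps(fmap, w3, m$params$b3 * 0, cfg)
  expect_true(all(u_iso[, -d_iso] == 0))
  expect_gt(max(abs(u_iso[, d_iso])), 0)
})

test_that("squash has the closed-form norm profile", {
  expect_equal(squash(rep(0, 8)), rep(0, 8))
  set.seed(4)
  s <- rnorm(16)
  s1 <- s / sqrt(sum(s^2))
  expect_equal(sqrt(sum(squash(s1)^2)), 0.5, tolerance = 1e-6)
  s1000 <- 1000 * s1
  v <- squash(s1000)
  expect_equal(sqrt(sum(v^2)), 1e6 / (1 + 1e6), tolerance = 1e-6)
  expect_equal(v / sqrt(sum(v^2)), s1, tolerance = 1e-6)
  # output always parallel to input, norm < 1
  for (k in 1:5) {
    s <- rnorm(8) * 10^runif(1, -3, 3)
    v <- squash(s)
    expect_lt(sqrt(sum(v^2)), 1)
    cosang <- sum(v * s) / sqrt(sum(v^2) * sum(s^2))
    expect_equal(cosang, 1, tolerance = 1e-6)
  }
})

test_that("dynamic routing matches a step-by-step transcription", {
  set.seed(5)
  for (rep in 1:3) {
    u <- matrix(rnorm(2 * 3), 2, 3)
    w <- array(rnorm(2 * 3 * 2 * 2), c(2, 3, 2, 2))
    got <- dynamic_routing(u, w, iterations = 3)
    want <- routing_transcription(u, w, 3)
    expect_equal(got$v, want$v, tolerance = 1e-6)
    expect_equal(got$coupling, want$coupling, tolerance = 1e-6)
  }
  # zero logits at start: every coupling coefficient is 1/n_class
  u <- matrix(rnorm(4 * 3), 4, 3)
  w <- array(rnorm(2 * 3 * 4 * 2), c(2, 3, 4, 2))
  got <- dynamic_routing(u, w, iterations = 1)
  expect_true(all(abs(got$coupling - 0.5) < 1e-12))
  # coupling rows always sum to 1; class-capsule norms in [0, 1)
  got <- dynamic_routing(u, w, iterations = 4)
  expect_equal(rowSums(got$coupling), rep(1, 4), tolerance = 1e-6)
  expect_true(all(sqrt(rowSums(got$v^2)) < 1))
})

test_that("uniform identical predictions with class symmetry are a routing fixed point", {
  # If u_hat is identical across primary capsules and the two classes see
  # sign-flipped copies, the agreement update is equal for both classes, so
  # coupling stays at 1/2 and v_j = squash((N_P/N_E) u_hat_j) for every r.
  set.seed(6)
  np <- 4; de <- 3; dp <- 2
  base <- matrix(rnorm(de * dp), de, dp)
  w <- array(0, c(de, dp, np, 2))
  for (i in 1:np) {
    w[, , i, 1] <- base
    w[, , i, 2] <- -base
  }
  u <- matrix(rep(rnorm(dp), each = np), np, dp)
  uh <- as.numeric(base %*% u[1, ])
  for (r in c(1L, 3L, 5L)) {
    got <- dynamic_routing(u, w, r)
    expect_true(all(abs(got$coupling - 0.5) < 1e-9))
    expect_equal(got$v[1, ], squash((np / 2) * uh), tolerance = 1e-9)
    expect_equal(got$v[2, ], squash(-(np / 2) * uh), tolerance = 1e-9)
  }
})

test_that("margin loss matches its scalar transcription and hand values", {
  # both margins met -> zero loss
  v <- matrix(0, 2, 16)
  v[1, 1] <- 0.9; v[2, 1] <- 0.1
  expect_equal(margin_loss(v, 0), 0)
  # ||v_true|| = 0, ||v_other|| = 1 -> 0.9^2 + 0.5 * 0.9^2 = 1.215
  v <- matrix(0, 2, 4); v[2, 1] <- 1
  expect_equal(margin_loss(v, 0), 1.215)
  set.seed(7)
  for (rep in 1:100) {
    norms <- runif(2)
    lab <- sample(0:1, 1)
    expect_equal(margin_loss(norms, lab), margin_loss_scalar(norms, lab),
                 tolerance = 1e-7)
  }
  # monotone: non-increasing in the true norm, non-decreasing in the other
  ls <- sapply(seq(0, 1, 0.05), function(nt) margin_loss(c(nt, 0.4), 0))
  expect_true(all(diff(ls) <= 1e-12))
  lo <- sapply(seq(0, 1, 0.05), function(no) margin_loss(c(0.4, no), 0))
  expect_true(all(diff(lo) >= -1e-12))
})

test_that("prediction is a softmax over capsule norms", {
  cfg <- tiny_caps_config()
  m <- capsnet_init(cfg, seed = 8)
  set.seed(8)
  xb <- array(rnorm(2 * 32 * 5 * 5 * 3), c(2, 32, 5, 5, 3))
  fwd <- capsnet_forward(m, xb)
  expect_equal(colSums(fwd$probs), rep(1, 3), tolerance = 1e-8)
  expect_equal(fwd$probs,
               apply(fwd$norms, 2L, function(z) exp(z) / sum(exp(z))),
               tolerance = 1e-6)
  pr <- capsnet_predict(m, xb)
  expect_equal(pr$pred, unname(apply(fwd$probs, 2L, which.max) - 1L))
})

test_that("the conv_fc variant is a softmax classifier over ConvBlock features", {
  cfg <- tiny_caps_config(variant = "conv_fc")
  m <- capsnet_init(cfg, seed = 9)
  set.seed(9)
  xb <- array(rnorm(2 * 32 * 5 * 5 * 4), c(2, 32, 5, 5, 4))
  fwd <- capsnet_forward(m, xb)
  expect_equal(colSums(fwd$probs), rep(1, 4), tolerance = 1e-8)
  m0 <- m
  m0$params$wfc[] <- 0
  m0$params$bfc[] <- 0
  fwd0 <- capsnet_forward(m0, xb)
  expect_true(all(abs(fwd0$probs - 0.5) < 1e-12))
})

test_that("backpropagated gradients match finite differences", {
  for (variant in c("caps", "conv_fc")) {
    cfg <- tiny_caps_config(variant = variant)
    m <- capsnet_init(cfg, seed = 10, conv_init = "glorot")
    set.seed(10)
    xb <- array(rnorm(2 * 32 * 5 * 5 * 4), c(2, 32, 5, 5, 4))
    labels <- c(0, 1, 1, 0)
    lossfn <- function(mm) {
      fwd <- capsnet_forward(mm, xb, training = TRUE)
      eegcaps:::capsnet_backward(mm, fwd, labels)
    }
    bwd <- lossfn(m)
    eps <- 1e-5
    params <- if (variant == "caps") c("w1", "w2", "w3", "wr", "b3") else
      c("w1", "w2", "wfc", "bfc")
    for (nm in params) {
      idx <- min(5L, length(m$params[[nm]]))
      m2 <- m
      m2$params[[nm]][idx] <- m2$params[[nm]][idx] + eps
      lp <- lossfn(m2)$loss
      m2$params[[nm]][idx] <- m2$params[[nm]][idx] - 2 * eps
      lm <- lossfn(m2)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- bwd$grads[[nm]][idx]
      expect_equal(an, fd, tolerance = 1e-3,
                   label = paste0(variant, ":", nm, " analytic"),
                   expected.label = "finite difference")
    }
    # BN parameters (nested)
    m2 <- m
    m2$params$bn1$gamma[2] <- m2$params$bn1$gamma[2] + eps
    lp <- lossfn(m2)$loss
    m2$params$bn1$gamma[2] <- m2$params$bn1$gamma[2] - 2 * eps
    lm <- lossfn(m2)$loss
    expect_equal(bwd$grads$bn1$gamma[2], (lp - lm) / (2 * eps),
                 tolerance = 1e-3)
  }
})

test_that("batch forward equals per-sample forward (inference mode)", {
  cfg <- tiny_caps_config()
  m <- capsnet_init(cfg, seed = 11)
  set.seed(11)
  xs <- lapply(1:3, function(i) array(rnorm(2 * 32 * 5 * 5), c(2, 32, 5, 5)))
  fwd_b <- capsnet_forward(m, xs)
  for (i in 1:3) {
    fwd_i <- capsnet_forward(m, xs[[i]])
    expect_equal(fwd_i$probs[, 1], fwd_b$probs[, i], tolerance = 1e-10)
  }
})

test_that("config validation catches impossible geometries", {
  expect_error(capsnet_config(t_len = 100, kernel_t = 512), "exceeds")
  expect_error(capsnet_config(m_plus = 0.1, m_minus = 0.9))
  expect_error(capsnet_config(routing_iters = 0), "not TRUE")
})
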