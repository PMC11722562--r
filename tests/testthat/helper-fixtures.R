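# Shared fixtures: tiny model/generator configurations and independent
# oracle implementations used across the test files.

tinyModelConfig <- function(...) {
  modelConfig(H = 32L, W = 64L, cEmbed = 4L, n1 = 1L, n2 = 1L, nMp = 2L,
              nHeads = 2L, sState = 4L, dR = 16L, bvpLen = 64L, ...)
}

tinySynthConfig <- function(seed = 1L, ...) {
  synthConfig(rows = 32L, width = 64L, durationS = 64 / 30 + 0.1,
              seed = seed, ...)
}

tinySamples <- function(n, seed = 1L, ...) {
  sc <- tinySynthConfig(seed = seed, ...)
  lapply(seq_len(n), function(i) makeStmapSample(sc, i))
}

# random stable continuous system (negative-definite-shifted A)
randomStableParams <- function(s, deltaRange = c(0.05, 1)) {
  M <- matrix(stats::rnorm(s * s, sd = 0.5), s, s)
  A <- M - diag(s) * (max(abs(eigen(M, only.values = TRUE)$values)) + 0.2)
  ssmParams(A, stats::rnorm(s), stats::rnorm(s),
            stats::runif(1, deltaRange[1], deltaRange[2]))
}

# independent straight-line selective scan: plain per-sample, per-step,
# per-state loops; no vectorization shared with the layer implementation
naiveSelectiveScanLayer <- function(mod, x, B, L) {
  D <- mod$D; S <- mod$S
  a <- -exp(mod$par$Alog)
  y <- x * 0
  for (b in seq_len(B)) {
    psi <- matrix(0, S, D)
    for (t in seq_len(L)) {
      row <- (b - 1L) * L + t
      xt <- x[row, ]
      pre <- drop(xt %*% mod$par$Wd) + mod$par$bd
      delta <- log1p(exp(-abs(pre))) + pmax(pre, 0)
      Bt <- drop(xt %*% mod$par$Wb)
      Ct <- drop(xt %*% mod$par$Wc)
      for (d in seq_len(D)) {
        for (s in seq_len(S)) {
          ab <- exp(delta[d] * a[s])
          bb <- (ab - 1) / a[s] * Bt[s]
          psi[s, d] <- ab * psi[s, d] + bb * xt[d]
        }
        y[row, d] <- sum(Ct * psi[, d])
      }
    }
  }
  y
}

# direct-loop 3x3 convolution oracle (stride/pad general), input (h*w, cin)
naiveConv2d <- function(x, h, w, W, b, k, stride, pad) {
  cin <- ncol(x)
  cout <- length(b)
  ho <- (h + 2 * pad - k) %/% stride + 1
  wo <- (w + 2 * pad - k) %/% stride + 1
  xp <- array(0, c(h + 2 * pad, w + 2 * pad, cin))
  for (c in seq_len(cin))
    xp[pad + seq_len(h), pad + seq_len(w), c] <- matrix(x[, c], h, w)
  y <- matrix(0, ho * wo, cout)
  for (oh in seq_len(ho)) for (ow in seq_len(wo)) {
    acc <- numeric(cout)
    for (ki in seq_len(k)) for (kj in seq_len(k)) for (c in seq_len(cin)) {
      wrow <- (ki + k * (kj - 1)) + k * k * (c - 1)
      acc <- acc + xp[(oh - 1) * stride + ki, (ow - 1) * stride + kj, c] *
        W[wrow, ]
    }
    y[oh + ho * (ow - 1), ] <- acc + b
  }
  list(y = y, h = ho, w = wo)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y)) / max(abs(y), 1e-12), tol)
}
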