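# Backbone architecture: shapes, residual identities, attention contracts,
# determinism, and gradient correctness of the hand-written backward passes.

test_that("the stem and downsampling chain follows the documented stride sequence", {
  cfg <- modelConfig(H = 64L, W = 256L, cEmbed = 8L, n1 = 1L, n2 = 1L,
                     nMp = 2L, nHeads = 2L, sState = 4L, dR = 32L)
  m <- rppgModel(cfg, seed = 1)
  sc <- synthConfig(seed = 2)
  s <- makeStmapSample(sc, 1)
  X <- rppgmamba:::stmapsToInput(list(s@stmap), cfg)
  st <- rppgmamba:::stemForward(m@state$modules, X, 64L, 256L, 1L, FALSE)
  expect_identical(c(st$h, st$w), c(16L, 64L))             # stride 4
  fwd <- rppgmamba:::modelForward(m, X, 1L, training = FALSE)
  expect_identical(fwd$geom$L1, 4L * 16L)                  # stride 16 tokens
  expect_identical(fwd$geom$L2, 2L * 8L)                   # stride 32 tokens
  expect_length(fwd$r, cfg$dR)
  expect_true(all(is.finite(fwd$r)))
  r2 <- extractShared(m, s@stmap)
  expect_identical(dim(r2), c(1L, cfg$dR))
})

test_that("parameter count is independent of the input size", {
  base <- modelConfig(H = 32L, W = 64L, cEmbed = 4L, n1 = 1L, n2 = 1L,
                      nMp = 2L, nHeads = 2L, sState = 4L, dR = 16L,
                      bvpLen = 64L)
  big <- modelConfig(H = 64L, W = 128L, cEmbed = 4L, n1 = 1L, n2 = 1L,
                     nMp = 2L, nHeads = 2L, sState = 4L, dR = 16L,
                     bvpLen = 64L)
  nSmall <- nParams(rppgModel(base, seed = 1))
  nBig <- nParams(rppgModel(big, seed = 1))
  # global average pooling makes the backbone size-independent; only the
  # BVP head (which reads the pre-pool token sequence) scales with H, W
  bvpSmall <- length(rppgModel(base, seed = 1)@state$modules[["head.BVP"]]$par$W)
  bvpBig <- length(rppgModel(big, seed = 1)@state$modules[["head.BVP"]]$par$W)
  expect_identical(nSmall - bvpSmall, nBig - bvpBig)
})

test_that("a random conv layer matches a direct-loop convolution oracle", {
  set.seed(13)
  for (case in list(list(k = 3L, st = 1L, p = 1L), list(k = 3L, st = 2L, p = 1L))) {
    mod <- rppgmamba:::nnConv2d(2L, 3L, k = case$k, stride = case$st,
                                pad = case$p)
    h <- 6L; w <- 8L
    x <- matrix(rnorm(h * w * 2), h * w, 2)
    out <- rppgmamba:::conv2dForward(mod, x, h, w, 1L)
    ref <- naiveConv2d(x, h, w, mod$par$W, mod$par$b, case$k, case$st, case$p)
    expect_equal(out$x, ref$y, tolerance = 1e-12)
    expect_equal(c(out$h, out$w), c(ref$h, ref$w))
  }
})

test_that("a residual conv layer matches the straight-line two-conv formula", {
  set.seed(14)
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 14)
  M <- m@state$modules
  h <- 8L; w <- 16L
  x <- matrix(rnorm(h * w * cfg$cEmbed), h * w, cfg$cEmbed)
  out <- rppgmamba:::resconvForward(M, "rc1", 1L, x, h, w, 1L, FALSE)
  # independent evaluation: conv -> BN(eval) -> GELU -> conv -> BN + input
  bnEval <- function(z, mod)
    t((t(z) - mod$runMean) / sqrt(mod$runVar + 1e-5) * mod$par$gamma +
        mod$par$beta)
  c1 <- M[["rc1.l1.conv1"]]
  c2 <- M[["rc1.l1.conv2"]]
  a <- naiveConv2d(x, h, w, c1$par$W, c1$par$b, 3L, 1L, 1L)$y
  a <- bnEval(a, M[["rc1.l1.bn1"]])
  a <- a * pnorm(a)
  b <- naiveConv2d(a, h, w, c2$par$W, c2$par$b, 3L, 1L, 1L)$y
  ref <- bnEval(b, M[["rc1.l1.bn2"]]) + x
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("zeroing non-residual weights reduces residual layers to identity", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 21)
  zeroResidualWeights(m)
  M <- m@state$modules
  set.seed(3)
  h <- 8L; w <- 16L
  x <- matrix(rnorm(h * w * cfg$cEmbed), h * w, cfg$cEmbed)
  expect_equal(rppgmamba:::resconvForward(M, "rc1", 1L, x, h, w, 1L, FALSE),
               x, tolerance = 1e-12)
  tok <- matrix(rnorm(8 * 4 * cfg$cEmbed), 8, 4 * cfg$cEmbed)
  for (j in 1:cfg$nMp) {
    p <- sprintf("stage1.l%d", j)
    out <- rppgmamba:::hybridLayerForward(m@state, p, m@state$kinds[j],
                                          tok, 1L, 8L)
    expect_equal(out, tok, tolerance = 1e-12)
  }
})

test_that("the integrator collapses to a shared-path projection when the scan is the identity", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 31)
  m@state$scanIdentity <- TRUE
  M <- m@state$modules
  C <- 4L * cfg$cEmbed
  set.seed(7)
  x <- matrix(rnorm(8 * C), 8, C)
  out <- rppgmamba:::integratorForward(M, "stage1.l1", x, 1L, 8L, TRUE)
  # main path == vice path, so Linear(concat(v, v)) = v (W1 + W2) + b
  v <- rppgmamba:::actForward(M[["stage1.l1.int.silu"]],
         rppgmamba:::dwconv1dForward(M[["stage1.l1.int.dwc"]],
           rppgmamba:::linearForward(M[["stage1.l1.int.lin"]], x), 1L, 8L))
  W <- M[["stage1.l1.int.proj"]]$par$W
  Ch <- C %/% 2L
  ref <- v %*% (W[seq_len(Ch), ] + W[Ch + seq_len(Ch), ])
  ref <- t(t(ref) + M[["stage1.l1.int.proj"]]$par$b)
  expect_equal(out, ref, tolerance = 1e-12)
  m@state$scanIdentity <- FALSE
})

test_that("the integrator composition matches an independent straight-line evaluation", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 8)
  M <- m@state$modules
  C <- 4L * cfg$cEmbed
  set.seed(9)
  x <- matrix(rnorm(8 * C), 8, C)
  out <- rppgmamba:::integratorForward(M, "stage1.l1", x, 1L, 8L, FALSE)
  # straight-line oracle: Linear -> regular depthwise conv -> SiLU -> scan
  # (naive loops) for the main path, same pre-scan values for the vice path,
  # concatenated and projected
  lin <- M[["stage1.l1.int.lin"]]
  u <- t(t(x %*% lin$par$W) + lin$par$b)
  dwc <- M[["stage1.l1.int.dwc"]]
  vconv <- u * 0
  for (l in 1:8) for (c in seq_len(ncol(u))) {
    acc <- dwc$par$b[c]
    for (j in 1:3) {
      src <- l + j - 2
      if (src >= 1 && src <= 8) acc <- acc + dwc$par$W[j, c] * u[src, c]
    }
    vconv[l, c] <- acc
  }
  v <- vconv * plogis(vconv)
  main <- naiveSelectiveScanLayer(M[["stage1.l1.int.scan"]], v, 1L, 8L)
  proj <- M[["stage1.l1.int.proj"]]
  ref <- t(t(cbind(main, v) %*% proj$par$W) + proj$par$b)
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("the selective scan layer reduces to the time-invariant recurrence", {
  set.seed(16)
  mod <- rppgmamba:::nnSelectiveSSM(3L, 4L)
  mod$par$Wd[] <- 0
  mod$par$Wb[] <- 0
  mod$par$Wc[] <- 0
  # constant per-token parameters: Delta = softplus(bd), B = C = 0 gives
  # zero output; pin nonzero constant B, C through the bias-free maps by
  # feeding a constant input channel instead
  x <- matrix(rnorm(10 * 3), 10, 3)
  yZero <- rppgmamba:::sssmForward(mod, x, 1L, 10L)
  expect_equal(yZero, x * 0)
  # non-degenerate constant case via the naive reference
  mod2 <- rppgmamba:::nnSelectiveSSM(3L, 4L)
  y <- rppgmamba:::sssmForward(mod2, x, 2L, 5L)
  ref <- naiveSelectiveScanLayer(mod2, x, 2L, 5L)
  expect_equal(y, ref, tolerance = 1e-10)
  expect_equal(rppgmamba:::sssmForward(mod2, x * 0, 2L, 5L), x * 0)
})

test_that("attention rows normalize, single tokens pass through, and order equivaries", {
  set.seed(18)
  mod <- rppgmamba:::nnAttention(8L, 2L, "t")
  x <- matrix(rnorm(6 * 8), 6, 8)
  y <- rppgmamba:::attnForward(mod, x, 1L, 6L)
  for (A in mod$cache$As)
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-6)
  # single token: softmax over one element is 1, so output is the value
  # projection of that token
  x1 <- x[1, , drop = FALSE]
  y1 <- rppgmamba:::attnForward(mod, x1, 1L, 1L)
  v1 <- (x1 %*% mod$par$Wv + mod$par$bv) %*% mod$par$Wo
  expect_equal(y1, t(t(v1) + mod$par$bo), tolerance = 1e-10)
  # no positional encoding: permuting tokens permutes the output
  perm <- sample(6)
  yp <- rppgmamba:::attnForward(mod, x[perm, ], 1L, 6L)
  expect_equal(yp, y[perm, ], tolerance = 1e-10)
})

test_that("forward passes are deterministic and finite end to end", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 5)
  s <- makeStmapSample(tinySynthConfig(seed = 6), 1)
  X <- rppgmamba:::stmapsToInput(list(s@stmap), cfg)
  f1 <- rppgmamba:::modelForward(m, X, 1L, training = FALSE)
  f2 <- rppgmamba:::modelForward(m, X, 1L, training = FALSE)
  expect_identical(f1$r, f2$r)
  expect_identical(f1$bvp, f2$bvp)
  expect_true(all(vapply(f1$sigma, function(s) all(s > 0 & s < 1), TRUE)))
})

test_that("backpropagated gradients match finite differences across layer types", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 3)
  ss <- tinySamples(3, seed = 5)
  X <- rppgmamba:::stmapsToInput(lapply(ss, function(s) s@stmap), cfg)
  set.seed(11)
  goldZ <- list(hr = rnorm(3), spo2 = rnorm(3), rr = rnorm(3),
                bvp = matrix(rnorm(3 * 64), 3, 64))
  lcfg <- lossConfig(w1 = 1, w2 = 1, w3 = 1, normStats = NULL)
  lossOf <- function() {
    fwd <- rppgmamba:::modelForward(m, X, 3L, training = TRUE)
    rppgmamba:::lossWithGrad(list(hr = fwd$hr, spo2 = fwd$spo2,
                                  rr = fwd$rr, bvp = fwd$bvp),
                             goldZ, 1, lcfg)
  }
  lw <- lossOf()
  for (mm in m@state$modules) rppgmamba:::nnZeroGrad(mm)
  rppgmamba:::modelBackward(m, lw$grads)
  M <- m@state$modules
  checks <- list(
    c("stem.conv1", "W", 5), c("stem.bn1", "gamma", 2),
    c("rc2.l1.conv2", "W", 10), c("down1.conv", "W", 3),
    c("stage1.l1.int.scan", "Alog", 2), c("stage1.l1.int.scan", "Wd", 3),
    c("stage1.l1.int.scan", "Wb", 4), c("stage1.l1.int.dwc", "W", 2),
    c("stage1.l2.attn", "Wq", 8), c("stage2.l1.mlp.fc1", "W", 3),
    c("sampler.conv", "W", 6), c("projR", "W", 9),
    c("gate.HR.lin1", "W", 11), c("gate.RR.ln2", "gamma", 4),
    c("head.SpO2", "W", 1), c("head.BVP", "W", 100))
  eps <- 1e-5
  for (ck in checks) {
    nm <- ck[1]; pn <- ck[2]; i <- as.integer(ck[3])
    g <- M[[nm]]$grad[[pn]][i]
    orig <- M[[nm]]$par[[pn]][i]
    M[[nm]]$par[[pn]][i] <- orig + eps
    lp <- lossOf()$total
    M[[nm]]$par[[pn]][i] <- orig - eps
    lm <- lossOf()$total
    M[[nm]]$par[[pn]][i] <- orig
    fd <- (lp - lm) / (2 * eps)
    expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-8), 1e-4,
              label = sprintf("gradient deviation for %s$%s", nm, pn))
  }
})

test_that("model checkpoints round-trip through save and load", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 9)
  m@state$normStats <- list(hr = c(100, 30), spo2 = c(92, 4), rr = c(16, 5))
  s <- makeStmapSample(tinySynthConfig(seed = 2), 1)
  r1 <- extractShared(m, s@stmap)
  p1 <- predictVitals(m, list(s))
  path <- file.path(tempdir(), "model.ckpt")
  saveModel(m, path, metrics = list(note = "unit"))
  m2 <- loadModel(path)
  expect_equal(extractShared(m2, s@stmap), r1, tolerance = 1e-12)
  expect_identical(m2@config$cEmbed, cfg$cEmbed)
  # target-normalization statistics travel with the checkpoint, so raw-scale
  # predictions survive the round trip
  p2 <- predictVitals(m2, list(s))
  expect_equal(p2@hr, p1@hr, tolerance = 1e-12)
  expect_equal(p2@spo2, p1@spo2, tolerance = 1e-12)
  unlink(path)
})

test_that("configuration validation enforces architectural constraints", {
  expect_error(modelConfig(H = 60L), "divisible by 32")
  expect_error(modelConfig(cEmbed = 6L, nHeads = 7L), "nHeads")
  expect_error(modelConfig(nMp = 0L), "nMp")
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 1)
  bad <- array(0.5, c(16, 64, 3))
  expect_error(extractShared(m, bad), "expects")
})
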