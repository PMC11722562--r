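# State-space core: zero-order-hold discretization, recurrent scan,
# structured kernel, convolutional scan, selective scan.

test_that("scalar zero-order hold matches the closed form", {
  dp <- discretizeSSM(ssmParams(-1, 1, 1, log(2)))
  expect_equal(drop(dp@Abar), 0.5, tolerance = 1e-12)
  expect_equal(drop(dp@Bbar), 0.5, tolerance = 1e-12)
  expect_equal(drop(dp@Cbar), 1)
  expect_identical(dp@branch, "inverse")
})

test_that("small-delta discretization approaches I + delta*A", {
  set.seed(7)
  A <- matrix(rnorm(16), 4, 4)
  d <- 1e-6
  dp <- discretizeSSM(ssmParams(A, rnorm(4), rnorm(4), d))
  expect_lt(max(abs(dp@Abar - (diag(4) + d * A))), 1e-9)
})

test_that("discrete input matrix matches a quadrature oracle", {
  set.seed(42)
  p <- randomStableParams(4)
  dp <- discretizeSSM(p)
  # independent oracle: Bbar = (int_0^Delta exp(sA) ds) B by fine Riemann sum
  nStep <- 1e4
  h <- p@delta / nStep
  acc <- matrix(0, 4, 4)
  for (i in seq_len(nStep)) {
    s <- (i - 0.5) * h
    acc <- acc + as.matrix(Matrix::expm(Matrix::Matrix(s * p@A))) * h
  }
  expect_lt(max(abs(dp@Bbar - acc %*% p@B)), 1e-6)
})

test_that("singular delta*A falls back to the series branch and stays exact", {
  # A = 0: the inverse formula is singular; the ZOH limit is Bbar = delta*B
  dp <- discretizeSSM(ssmParams(matrix(0, 2, 2), c(1, 2), c(1, 0), 0.3))
  expect_identical(dp@branch, "series")
  expect_equal(dp@Bbar, matrix(0.3 * c(1, 2), 2, 1), tolerance = 1e-12)
  expect_equal(dp@Abar, diag(2), tolerance = 1e-12)
})

test_that("recurrent scan reproduces hand-computed and degenerate cases", {
  dp <- discretizeSSM(ssmParams(log(0.5), 1, 2, 1))  # Abar = 0.5
  expect_equal(dp@Abar[1, 1], 0.5, tolerance = 1e-12)
  dp@Bbar[1, 1] <- 1  # pin Bbar for the hand-computed case
  expect_equal(scanRecurrent(dp, c(1, 1)), c(2, 3), tolerance = 1e-12)
  expect_equal(scanRecurrent(dp, numeric(5)), numeric(5))
  expect_equal(scanRecurrent(dp, c(1, 0, 0)), buildKernel(dp, 3),
               tolerance = 1e-12)
})

test_that("structured kernel matches powers of Abar and the impulse response", {
  dp <- new("DiscreteSSMParams", Abar = matrix(0.5), Bbar = matrix(1),
            Cbar = matrix(2), branch = "inverse")
  expect_equal(buildKernel(dp, 3), c(2, 1, 0.5))
  dp0 <- new("DiscreteSSMParams", Abar = matrix(0, 2, 2),
             Bbar = matrix(c(1, 1)), Cbar = matrix(c(1, 2), 1), branch = "inverse")
  expect_equal(buildKernel(dp0, 4), c(3, 0, 0, 0))
  set.seed(3)
  dpr <- discretizeSSM(randomStableParams(3))
  imp <- scanRecurrent(dpr, c(1, numeric(15)))
  expect_equal(imp, buildKernel(dpr, 16), tolerance = 1e-6)
})

test_that("convolutional scan equals the recurrence and is linear", {
  set.seed(11)
  for (i in 1:20) {
    dp <- discretizeSSM(randomStableParams(sample(1:6, 1)))
    L <- sample(2:40, 1)
    rho <- rnorm(L)
    yr <- scanRecurrent(dp, rho)
    yc <- scanConvolutional(dp, rho)
    expect_rel_equal(yc, yr, 1e-5)
  }
  dp <- discretizeSSM(randomStableParams(4))
  expect_equal(scanConvolutional(dp, c(1, numeric(9))), buildKernel(dp, 10),
               tolerance = 1e-10)
  r1 <- rnorm(16); r2 <- rnorm(16)
  lhs <- scanConvolutional(dp, 2 * r1 - 3 * r2)
  rhs <- 2 * scanConvolutional(dp, r1) - 3 * scanConvolutional(dp, r2)
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("stable diagonal systems discretize inside the unit interval", {
  set.seed(5)
  for (i in 1:20) {
    s <- sample(1:6, 1)
    A <- diag(runif(s, -5, -0.1), s)
    d <- runif(1, 1e-3, 1)
    dp <- discretizeSSM(ssmParams(A, rnorm(s), rnorm(s), d))
    expect_true(all(diag(dp@Abar) > 0 & diag(dp@Abar) < 1))
    expect_lt(max(Mod(eigen(dp@Abar, only.values = TRUE)$values)), 1)
  }
})

test_that("halving delta while holding the input reproduces the scan", {
  # ZOH is exact for piecewise-constant inputs, so two half-steps of the
  # held input compose to one full step
  set.seed(4)
  p <- randomStableParams(3)
  rho <- rnorm(20)
  y1 <- scanRecurrent(discretizeSSM(p), rho)
  pHalf <- ssmParams(p@A, p@B, p@C, p@delta / 2)
  y2 <- scanRecurrent(discretizeSSM(pHalf), rep(rho, each = 2))
  expect_lt(max(abs(y1 - y2[seq(2, 40, by = 2)])), 1e-10)
})

test_that("selective scan reduces to the time-invariant scan and matches a naive loop", {
  set.seed(21)
  s <- 3; L <- 12; nc <- 4
  A <- diag(runif(s, -3, -0.5), s)
  Bv <- rnorm(s); Cv <- rnorm(s); d <- 0.4
  x <- matrix(rnorm(L * nc), L, nc)
  sel <- selectiveParams(A, rep(d, L), matrix(Bv, L, s, byrow = TRUE),
                         matrix(Cv, L, s, byrow = TRUE))
  y <- selectiveScan(x, sel)
  dp <- discretizeSSM(ssmParams(A, Bv, Cv, d))
  for (c in seq_len(nc))
    expect_equal(y[, c], scanRecurrent(dp, x[, c]), tolerance = 1e-10)
  expect_equal(selectiveScan(x * 0, sel), x * 0)
  # time-varying case vs an independent step-by-step loop
  L2 <- 8
  x2 <- matrix(rnorm(L2 * nc), L2, nc)
  delta <- runif(L2, 0.1, 0.8)
  Bm <- matrix(rnorm(L2 * s), L2, s)
  Cm <- matrix(rnorm(L2 * s), L2, s)
  sel2 <- selectiveParams(A, delta, Bm, Cm)
  y2 <- selectiveScan(x2, sel2)
  ref <- x2 * 0
  for (c in seq_len(nc)) {
    psi <- numeric(s)
    for (t in seq_len(L2)) {
      dpt <- discretizeSSM(ssmParams(A, Bm[t, ], Cm[t, ], delta[t]))
      psi <- drop(dpt@Abar %*% psi) + dpt@Bbar[, 1] * x2[t, c]
      ref[t, c] <- sum(dpt@Cbar[1, ] * psi)
    }
  }
  expect_equal(y2, ref, tolerance = 1e-10)
  expect_error(selectiveParams(A, c(delta[-1], -0.1), Bm, Cm), "positive")
})

test_that("validation rejects malformed or non-finite systems", {
  expect_error(ssmParams(matrix(1, 2, 2), 1, c(1, 2), -0.5), "delta")
  expect_error(ssmParams(matrix(NaN, 1, 1), 1, 1, 0.5), "finite")
  dp <- new("DiscreteSSMParams", Abar = matrix(2), Bbar = matrix(1),
            Cbar = matrix(1), branch = "inverse")
  # divergent system eventually overflows into non-finite state
  expect_error(scanRecurrent(dp, rep(1e308, 10)), "non-finite state at scan step")
})
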