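# Gates, task feature selection, estimation heads, and the multi-task loss.

test_that("gates map zero weights to 0.5 and always stay inside (0,1)", {
  m <- rppgModel(tinyModelConfig(), seed = 2)
  M <- m@state$modules
  for (pn in c("lin1", "lin2")) {
    M[[paste0("gate.HR.", pn)]]$par$W[] <- 0
    M[[paste0("gate.HR.", pn)]]$par$b[] <- 0
  }
  r <- matrix(rnorm(2 * 16), 2, 16)
  sig0 <- gateActivations(m, r, "HR")
  expect_equal(as.vector(sig0), rep(0.5, 32))
  set.seed(8)
  for (task in c("HR", "SpO2", "RR")) {
    sig <- gateActivations(m, matrix(rnorm(3 * 16, sd = 3), 3, 16), task)
    expect_true(all(sig > 0 & sig < 1))
  }
})

test_that("gate output matches a straight-line composition of its chain", {
  m <- rppgModel(tinyModelConfig(), seed = 4)
  M <- m@state$modules
  set.seed(5)
  r <- matrix(rnorm(16), 1, 16)
  ln <- function(x, mod) {
    mu <- mean(x); v <- mean(x^2) - mu^2
    (x - mu) / sqrt(v + 1e-5) * mod$par$gamma + mod$par$beta
  }
  h <- drop(r %*% M[["gate.RR.lin1"]]$par$W) + M[["gate.RR.lin1"]]$par$b
  h <- pmax(ln(h, M[["gate.RR.ln1"]]), 0)
  h <- drop(h %*% M[["gate.RR.lin2"]]$par$W) + M[["gate.RR.lin2"]]$par$b
  h <- plogis(ln(h, M[["gate.RR.ln2"]]))
  expect_equal(as.vector(gateActivations(m, r, "RR")), h, tolerance = 1e-10)
})

test_that("feature selection is elementwise gating bounded by the input", {
  r <- rnorm(16)
  expect_equal(selectFeatures(r, rep(0.5, 16)), r / 2)
  expect_equal(selectFeatures(numeric(16), runif(16)), numeric(16))
  set.seed(10)
  for (i in 1:100) {
    r <- rnorm(16, sd = 2)
    s <- runif(16)
    expect_true(all(abs(selectFeatures(r, s)) <= abs(r)))
  }
  expect_error(selectFeatures(rnorm(4), runif(5)), "length")
})

test_that("heads produce the declared prediction shapes and constant-bias case", {
  cfg <- tinyModelConfig()
  m <- rppgModel(cfg, seed = 6)
  M <- m@state$modules
  for (task in c("HR", "SpO2", "RR")) {
    M[[paste0("head.", task)]]$par$W[] <- 0
    M[[paste0("head.", task)]]$par$b[] <- 0.7
  }
  ss <- tinySamples(2, seed = 3)
  X <- rppgmamba:::stmapsToInput(lapply(ss, function(s) s@stmap), cfg)
  fwd <- rppgmamba:::modelForward(m, X, 2, training = FALSE)
  expect_equal(fwd$hr, rep(0.7, 2))
  expect_equal(fwd$spo2, rep(0.7, 2))
  expect_equal(fwd$rr, rep(0.7, 2))
  expect_identical(dim(fwd$bvp), c(2L, cfg$bvpLen))
  expect_true(all(is.finite(fwd$bvp)))
})

test_that("negative Pearson loss identities and affine invariance hold", {
  expect_equal(negPearson(1:4, 1:4), 0)
  expect_equal(negPearson(-(1:4), 1:4), 2)
  expect_equal(negPearson(c(1, 2, 1, 2), c(0, 1, 0, 1)), 0)
  set.seed(2)
  p <- rnorm(50); g <- rnorm(50)
  expect_equal(negPearson(3.2 * p + 1, g), negPearson(p, g), tolerance = 1e-12)
  expect_error(negPearson(rep(1, 5), rnorm(5)), "constant")
  expect_error(negPearson(rnorm(5), rep(2, 5)), "constant")
  expect_error(negPearson(1:3, 1:4), "length")
})

test_that("theta ramps linearly from zero and saturates at one", {
  expect_equal(thetaSchedule(0, 1000), 0)
  expect_equal(thetaSchedule(100, 1000, 0.1), 1)
  expect_equal(thetaSchedule(500, 1000, 0.1), 1)
  expect_equal(thetaSchedule(50, 1000, 0.1), 0.5)
  expect_equal(thetaSchedule(10, 1000, 0), 1)
  expect_error(thetaSchedule(1, 0), "positive")
  th <- vapply(0:200, thetaSchedule, 0, total = 200, warmupFraction = 0.25)
  expect_true(all(diff(th) >= 0))
})

test_that("overall loss follows the weighted theta-gated structure", {
  mk <- function(hr, spo2, rr, bvp) vitalsBundle(hr, spo2, rr, bvp)
  bvp <- matrix(sin(seq(0, 6 * pi, length.out = 64)), 1)
  gold <- mk(72, 97, 15, bvp)
  cfg <- lossConfig(w1 = 1e-4, w2 = 1e-4, w3 = 1e-4, normStats = NULL)
  perfect <- totalLoss(gold, gold, step = 100, total = 100, cfg = cfg)
  expect_equal(perfect$total, 0)
  # theta = 0 suppresses everything but the HR term
  pred <- mk(70, 95, 17, -bvp)
  early <- totalLoss(pred, gold, step = 0, total = 100, cfg = cfg)
  expect_equal(early$theta, 0)
  expect_equal(early$total, early$hr)
  # printed arithmetic case: errors 2/1/1, theta 1, weights 1e-4, no BVP term
  cfg2 <- lossConfig(w1 = 1e-4, w2 = 1e-4, includeBvp = FALSE,
                     normStats = NULL)
  pred2 <- mk(74, 96, 16, bvp)
  lt <- totalLoss(pred2, gold, step = 100, total = 100, cfg = cfg2)
  expect_equal(lt$total, 2 + 2e-4, tolerance = 1e-12)
  # nonnegativity and the total >= L_HR bound
  set.seed(9)
  for (i in 1:20) {
    pr <- mk(runif(1, 40, 180), runif(1, 70, 100), runif(1, 6, 30),
             matrix(rnorm(64), 1))
    lt <- totalLoss(pr, gold, step = sample(0:100, 1), total = 100, cfg = cfg)
    expect_true(all(unlist(lt[c("hr", "spo2", "rr", "bvp")]) >= 0))
    expect_gte(lt$total, lt$hr)
  }
})

test_that("theta zero makes the auxiliary-task gradients vanish at step zero", {
  set.seed(3)
  predZ <- list(hr = rnorm(4), spo2 = rnorm(4), rr = rnorm(4),
                bvp = matrix(rnorm(4 * 32), 4))
  goldZ <- list(hr = rnorm(4), spo2 = rnorm(4), rr = rnorm(4),
                bvp = matrix(rnorm(4 * 32), 4))
  lw <- rppgmamba:::lossWithGrad(predZ, goldZ, theta = 0,
                                 lossConfig(w1 = 1, w2 = 1, w3 = 1,
                                            normStats = NULL))
  expect_equal(lw$grads$spo2, numeric(4))
  expect_equal(lw$grads$rr, numeric(4))
  expect_equal(lw$grads$bvp, matrix(0, 4, 32))
  expect_false(all(lw$grads$hr == 0))
})
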