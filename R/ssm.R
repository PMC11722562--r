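# State-space core: continuous model, zero-order-hold discretization, and the
# three equivalent views of the discrete system (recurrence, structured
# convolution kernel, selective time-varying scan).

#' Construct continuous state-space parameters
#'
#' @param A state-evolution matrix (scalar or S x S matrix).
#' @param B input projection (scalar or S x 1).
#' @param C output projection (scalar or 1 x S).
#' @param delta positive time-scale used by the zero-order hold.
#' @return an [SSMParams-class] object.
#' @examples
#' p <- ssmParams(-1, 1, 1, log(2))
#' discretizeSSM(p)
#' @export
ssmParams <- function(A, B, C, delta) {
  # slot assignment rather than new(..., C = ): an argument named `C` would
  # partially match new()'s `Class` formal
  p <- new("SSMParams")
  p@A <- as.matrix(A)
  p@B <- matrix(as.numeric(B), ncol = 1L)
  p@C <- matrix(as.numeric(C), nrow = 1L)
  p@delta <- as.numeric(delta)
  validObject(p)
  p
}

#' Zero-order-hold discretization
#'
#' Converts the continuous system (A, B, C) with time-scale `delta` into the
#' discrete system: \eqn{\bar{A} = \exp(\Delta A)},
#' \eqn{\bar{B} = (\Delta A)^{-1}(\exp(\Delta A) - I)\,\Delta B},
#' \eqn{\bar{C} = C}. When \eqn{\Delta A} is (near-)singular the inverse
#' formula is replaced by the equivalent integral series
#' \eqn{\bar{B} = \Delta (I + \Delta A/2! + (\Delta A)^2/3! + \dots) B},
#' which is finite at \eqn{A \to 0}; the `branch` slot records which formula
#' was used.
#'
#' @param params an [SSMParams-class] object.
#' @param seriesTol switch to the series branch when the Frobenius norm of
#'   \eqn{\Delta A} falls below this value, or when the inversion is
#'   numerically singular.
#' @return a [DiscreteSSMParams-class] object.
#' @export
discretizeSSM <- function(params, seriesTol = 1e-6) {
  stopifnot(is(params, "SSMParams"))
  validObject(params)
  s <- nrow(params@A)
  dA <- params@delta * params@A
  Abar <- as.matrix(Matrix::expm(Matrix::Matrix(dA)))
  I <- diag(s)
  useSeries <- norm(dA, "F") < seriesTol
  branch <- "inverse"
  if (!useSeries) {
    Bbar <- tryCatch(
      solve(dA, (Abar - I) %*% (params@delta * params@B)),
      error = function(e) NULL)
    if (is.null(Bbar)) useSeries <- TRUE
  }
  if (useSeries) {
    branch <- "series"
    # integral form: (1/Delta) * int_0^Delta exp(sA) ds = sum dA^k/(k+1)!
    term <- I
    acc <- I
    for (k in 1:12) {
      term <- term %*% dA / (k + 1)
      acc <- acc + term
      if (max(abs(term)) < 1e-18) break
    }
    Bbar <- acc %*% (params@delta * params@B)
  }
  new("DiscreteSSMParams", Abar = Abar, Bbar = as.matrix(Bbar),
      Cbar = params@C, branch = branch)
}

#' Recurrent scan of a discrete state-space system
#'
#' Runs \eqn{\psi(t) = \bar{A}\psi(t-1) + \bar{B}\rho(t)},
#' \eqn{\phi(t) = \bar{C}\psi(t)} with \eqn{\psi(0) = 0}.
#'
#' @param dparams a [DiscreteSSMParams-class] object.
#' @param rho numeric input sequence of length L.
#' @return numeric output sequence \eqn{\phi} of length L.
#' @export
scanRecurrent <- function(dparams, rho) {
  stopifnot(is(dparams, "DiscreteSSMParams"), length(rho) >= 1L)
  s <- nrow(dparams@Abar)
  psi <- numeric(s)
  phi <- numeric(length(rho))
  for (t in seq_along(rho)) {
    psi <- drop(dparams@Abar %*% psi) + dparams@Bbar[, 1L] * rho[t]
    if (!all(is.finite(psi)))
      stop("non-finite state at scan step ", t)
    phi[t] <- drop(dparams@Cbar %*% psi)
  }
  phi
}

#' Structured convolution kernel of a discrete state-space system
#'
#' The impulse response
#' \eqn{\bar{K} = (\bar{C}\bar{B},\ \bar{C}\bar{A}\bar{B},\ \dots,\
#' \bar{C}\bar{A}^{L-1}\bar{B})}.
#'
#' @param dparams a [DiscreteSSMParams-class] object.
#' @param L kernel length (positive integer).
#' @return numeric vector of length L.
#' @export
buildKernel <- function(dparams, L) {
  stopifnot(is(dparams, "DiscreteSSMParams"), L >= 1L)
  v <- dparams@Bbar
  k <- numeric(L)
  for (t in seq_len(L)) {
    k[t] <- drop(dparams@Cbar %*% v)
    if (t < L) v <- dparams@Abar %*% v
  }
  k
}

#' Convolutional scan of a discrete state-space system
#'
#' Computes the same output as [scanRecurrent()] through the causal
#' convolution \eqn{\phi(t) = \sum_{s} \bar{K}(s)\,\rho(t-s)} with the
#' structured kernel from [buildKernel()].
#'
#' @inheritParams scanRecurrent
#' @return numeric output sequence of length `length(rho)`.
#' @export
scanConvolutional <- function(dparams, rho) {
  stopifnot(is(dparams, "DiscreteSSMParams"), length(rho) >= 1L)
  L <- length(rho)
  k <- buildKernel(dparams, L)
  full <- stats::convolve(rho, rev(k), type = "open")
  full[seq_len(L)]
}

#' Per-token parameters of the selective (input-dependent) scan
#'
#' @param A shared state matrix (S x S), typically with negative-real
#'   eigenvalues.
#' @param delta positive time-scale per token (length L).
#' @param B matrix L x S; row t is the input projection at token t.
#' @param C matrix L x S; row t is the output projection at token t.
#' @return a validated list of class `selectiveParams`.
#' @export
selectiveParams <- function(A, delta, B, C) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  C <- as.matrix(C)
  L <- length(delta)
  if (any(!is.finite(delta)) || any(delta <= 0))
    stop("all delta_t must be positive and finite")
  if (nrow(B) != L || nrow(C) != L)
    stop("B and C must have one row per token")
  if (ncol(B) != nrow(A) || ncol(C) != nrow(A))
    stop("B and C rows must have length S_state")
  structure(list(A = A, delta = as.numeric(delta), B = B, C = C),
            class = "selectiveParams")
}

#' Selective scan over a token sequence
#'
#' Time-varying state-space scan: each token t is integrated with its own
#' zero-order-hold discretization \eqn{\bar{A}_t = \exp(\Delta_t A)} and
#' \eqn{\bar{B}_t}, then
#' \eqn{\psi_t = \bar{A}_t \psi_{t-1} + \bar{B}_t x_t},
#' \eqn{y_t = C_t \psi_t}. Channels are scanned independently with shared
#' parameters. With constant \eqn{\Delta_t, B_t, C_t} this reduces exactly
#' to [scanRecurrent()] applied per channel.
#'
#' @param x numeric matrix L x C_model (tokens in rows).
#' @param sel a [selectiveParams()] object with sequence length L.
#' @return numeric matrix L x C_model.
#' @export
selectiveScan <- function(x, sel) {
  stopifnot(inherits(sel, "selectiveParams"))
  x <- as.matrix(x)
  L <- nrow(x)
  if (length(sel$delta) != L)
    stop("sequence length of sel does not match x")
  s <- nrow(sel$A)
  psi <- matrix(0, s, ncol(x))
  y <- matrix(0, L, ncol(x))
  for (t in seq_len(L)) {
    dp <- discretizeSSM(ssmParams(sel$A, sel$B[t, ], sel$C[t, ], sel$delta[t]))
    psi <- dp@Abar %*% psi + dp@Bbar %*% x[t, , drop = FALSE]
    y[t, ] <- drop(dp@Cbar %*% psi)
  }
  y
}

#' State-space equivalence self-check
#'
#' Draws random stable systems and measures the maximum relative deviation
#' between the recurrent and convolutional scans, and between the recurrent
#' impulse response and the structured kernel. Used by the `ssm-check` CLI
#' subcommand and the test suite.
#'
#' @param nDraws number of random systems.
#' @param maxState maximum state size (drawn uniformly from 1..maxState).
#' @param maxLen maximum sequence length.
#' @param seed RNG seed.
#' @return list with `maxRelDeviation` (recurrent vs convolutional) and
#'   `maxKernelDeviation` (impulse response vs kernel).
#' @export
ssmEquivalenceCheck <- function(nDraws = 50, maxState = 8, maxLen = 64,
                                seed = 1) {
  set.seed(seed)
  worstScan <- 0
  worstKernel <- 0
  for (i in seq_len(nDraws)) {
    s <- sample.int(maxState, 1L)
    L <- sample(2:maxLen, 1L)
    # stable A: random matrix shifted to negative-definite symmetric part
    M <- matrix(stats::rnorm(s * s, sd = 0.5), s, s)
    A <- M - diag(s) * (max(abs(eigen(M, only.values = TRUE)$values)) + 0.2)
    p <- ssmParams(A, stats::rnorm(s), stats::rnorm(s),
                   stats::runif(1, 0.05, 1))
    dp <- discretizeSSM(p)
    rho <- stats::rnorm(L)
    phiR <- scanRecurrent(dp, rho)
    phiC <- scanConvolutional(dp, rho)
    scale <- max(abs(phiR), 1e-12)
    worstScan <- max(worstScan, max(abs(phiR - phiC)) / scale)
    imp <- scanRecurrent(dp, c(1, numeric(L - 1L)))
    k <- buildKernel(dp, L)
    worstKernel <- max(worstKernel,
                       max(abs(imp - k)) / max(abs(k), 1e-12))
  }
  list(maxRelDeviation = worstScan, maxKernelDeviation = worstKernel,
       nDraws = nDraws)
}
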