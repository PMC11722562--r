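#' @import methods
NULL

#' Continuous state-space parameters
#'
#' Holds the continuous-time linear state-space model
#' \eqn{\psi'(t) = A\psi(t) + B\rho(t)}, \eqn{\phi(t) = C\psi(t)} together
#' with the time-scale \eqn{\Delta} used for zero-order-hold discretization.
#'
#' @slot A square state-evolution matrix (S_state x S_state), units 1/time.
#' @slot B input-projection column matrix (S_state x 1).
#' @slot C output-projection row matrix (1 x S_state).
#' @slot delta positive time-scale scalar.
#' @seealso [ssmParams()], [discretizeSSM()]
#' @export
setClass("SSMParams",
  representation(A = "matrix", B = "matrix", C = "matrix", delta = "numeric"),
  validity = function(object) {
    msg <- character()
    s <- nrow(object@A)
    if (!all(is.finite(object@A), is.finite(object@B), is.finite(object@C)))
      msg <- c(msg, "A, B, C must be finite")
    if (ncol(object@A) != s) msg <- c(msg, "A must be square")
    if (!identical(dim(object@B), c(s, 1L)))
      msg <- c(msg, "B must be S_state x 1")
    if (!identical(dim(object@C), c(1L, s)))
      msg <- c(msg, "C must be 1 x S_state")
    if (length(object@delta) != 1L || !is.finite(object@delta) ||
        object@delta <= 0)
      msg <- c(msg, "delta must be a positive finite scalar")
    if (length(msg)) msg else TRUE
  })

#' Zero-order-hold discretized state-space parameters
#'
#' The discrete system \eqn{\psi(t) = \bar{A}\psi(t-1) + \bar{B}\rho(t)},
#' \eqn{\phi(t) = \bar{C}\psi(t)} obtained from [discretizeSSM()].
#'
#' @slot Abar discrete state matrix \eqn{\bar{A} = \exp(\Delta A)}.
#' @slot Bbar discrete input column \eqn{\bar{B}}.
#' @slot Cbar output row, equal to the continuous C.
#' @slot branch `"inverse"` or `"series"` — which formula computed Bbar.
#' @export
setClass("DiscreteSSMParams",
  representation(Abar = "matrix", Bbar = "matrix", Cbar = "matrix",
                 branch = "character"),
  validity = function(object) {
    s <- nrow(object@Abar)
    msg <- character()
    if (ncol(object@Abar) != s) msg <- c(msg, "Abar must be square")
    if (!identical(dim(object@Bbar), c(s, 1L)))
      msg <- c(msg, "Bbar must be S_state x 1")
    if (!identical(dim(object@Cbar), c(1L, s)))
      msg <- c(msg, "Cbar must be 1 x S_state")
    if (!all(is.finite(object@Abar), is.finite(object@Bbar),
             is.finite(object@Cbar)))
      msg <- c(msg, "discrete parameters must be finite")
    if (length(msg)) msg else TRUE
  })

#' Spatial-temporal map of a facial video clip
#'
#' An STMap stacks the per-frame spatial means of facial ROI blocks as rows,
#' so each row is a colour time series; the horizontal axis is time. Values
#' are scaled to [0, 1] per row and channel.
#'
#' @slot values numeric array H x W x 3 in [0, 1].
#' @slot rate sampling rate of the temporal axis in frames per second.
#' @slot roiCount number of spatial ROI rows before any resizing.
#' @export
setClass("STMap",
  representation(values = "array", rate = "numeric", roiCount = "integer"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 3L || d[3] != 3L)
      msg <- c(msg, "values must be an H x W x 3 array")
    if (!all(is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Bundle of vital-sign values
#'
#' Container for heart rate (beats/min), blood-oxygen saturation (percent),
#' respiration rate (breaths/min) and blood-volume-pulse waveforms
#' (arbitrary units), for one or more samples. Used both for ground truth
#' and for model predictions.
#'
#' @slot hr numeric vector, beats per minute.
#' @slot spo2 numeric vector, percent.
#' @slot rr numeric vector, breaths per minute.
#' @slot bvp numeric matrix, one waveform per row (n x T).
#' @export
setClass("VitalsBundle",
  representation(hr = "numeric", spo2 = "numeric", rr = "numeric",
                 bvp = "matrix"),
  validity = function(object) {
    n <- length(object@hr)
    msg <- character()
    if (length(object@spo2) != n || length(object@rr) != n)
      msg <- c(msg, "hr, spo2, rr must have equal length")
    if (nrow(object@bvp) != n)
      msg <- c(msg, "bvp must have one row per sample")
    if (length(msg)) msg else TRUE
  })

#' A synthetic STMap sample with known ground truth
#'
#' @slot stmap the generated [STMap-class].
#' @slot truth a single-sample [VitalsBundle-class] with the generating vitals.
#' @slot seed integer seed the sample was drawn under.
#' @slot configHash hash of the generator configuration (provenance).
#' @export
setClass("SyntheticSample",
  representation(stmap = "STMap", truth = "VitalsBundle", seed = "integer",
                 configHash = "character"))

#' Multi-task vitals estimation model
#'
#' The full network: convolutional stem and residual blocks, two hybrid
#' stages of selective-state-space integrator layers and attention layers,
#' per-task gates and estimation heads. Parameters live in the `state`
#' environment so training can update them in place.
#'
#' @slot config list of architecture hyperparameters, see [modelConfig()].
#' @slot state environment holding layer parameter stores and optimizer state.
#' @export
setClass("RppgModel",
  representation(config = "list", state = "environment"))

setMethod("show", "SSMParams", function(object) {
  cat(sprintf("SSMParams: S_state = %d, delta = %g\n",
              nrow(object@A), object@delta))
})

setMethod("show", "DiscreteSSMParams", function(object) {
  cat(sprintf("DiscreteSSMParams: S_state = %d, spectral radius = %.4f (%s)\n",
              nrow(object@Abar), max(Mod(eigen(object@Abar,
                                              only.values = TRUE)$values)),
              object@branch))
})

setMethod("show", "STMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("STMap: %d x %d x 3 @ %g Hz (%d ROI rows)\n",
              d[1], d[2], object@rate, object@roiCount))
})

setMethod("show", "VitalsBundle", function(object) {
  cat(sprintf(
    "VitalsBundle: %d sample(s); HR %s bpm, SpO2 %s%%, RR %s /min, BVP T=%d\n",
    length(object@hr),
    paste(signif(utils::head(object@hr, 3), 4), collapse = ", "),
    paste(signif(utils::head(object@spo2, 3), 4), collapse = ", "),
    paste(signif(utils::head(object@rr, 3), 4), collapse = ", "),
    ncol(object@bvp)))
})

setMethod("show", "SyntheticSample", function(object) {
  cat("SyntheticSample (seed", object@seed, ")\n")
  show(object@stmap)
  show(object@truth)
})

setMethod("show", "RppgModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "RppgModel: input %dx%dx3, C_embed %d, stages %d+%d hybrid layers, %d params\n",
    cfg$H, cfg$W, cfg$cEmbed, cfg$nMp, cfg$nMp, nParams(object)))
})

# ---- accessors -------------------------------------------------------------

#' @describeIn STMap-class the raw H x W x 3 array.
#' @param x object.
#' @export
stmapValues <- function(x) x@values

#' @describeIn STMap-class sampling rate (frames/second).
#' @export
stmapRate <- function(x) x@rate

#' Build a vitals bundle
#'
#' @param hr heart rate(s), beats/min.
#' @param spo2 oxygen saturation(s), percent.
#' @param rr respiration rate(s), breaths/min.
#' @param bvp waveform matrix (n x T) or a single numeric vector.
#' @return a [VitalsBundle-class].
#' @export
vitalsBundle <- function(hr, spo2, rr, bvp) {
  if (is.null(dim(bvp))) bvp <- matrix(bvp, nrow = 1L)
  new("VitalsBundle", hr = as.numeric(hr), spo2 = as.numeric(spo2),
      rr = as.numeric(rr), bvp = bvp)
}

#' @describeIn VitalsBundle-class heart rates (beats/min).
#' @param x object.
#' @export
vitalsHR <- function(x) x@hr

#' @describeIn VitalsBundle-class oxygen saturations (percent).
#' @export
vitalsSpO2 <- function(x) x@spo2

#' @describeIn VitalsBundle-class respiration rates (breaths/min).
#' @export
vitalsRR <- function(x) x@rr

#' @describeIn VitalsBundle-class BVP waveform matrix (n x T).
#' @export
vitalsBVP <- function(x) x@bvp

#' Construct an STMap object
#'
#' @param values H x W x 3 array in [0,1].
#' @param rate temporal sampling rate, frames/second.
#' @param roiCount number of ROI rows before resizing (defaults to H).
#' @return an [STMap-class].
#' @export
stmap <- function(values, rate = 30, roiCount = dim(values)[1]) {
  new("STMap", values = values, rate = rate, roiCount = as.integer(roiCount))
}
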