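# Multi-task loss: L1 on the scalar vitals, negative-Pearson on the BVP
# waveform, an early-training adaptation ramp theta, and trade-off weights.
# L = theta * (w1*L_SpO2 + w2*L_RR [+ w3*L_BVP]) + L_HR.

#' Negative Pearson correlation loss
#'
#' Returns \eqn{1 - \rho(pred, gold)} where \eqn{\rho} is the Pearson
#' correlation; 0 for perfectly correlated waveforms, 2 for perfectly
#' anti-correlated ones. Invariant under positive affine rescaling of either
#' argument.
#'
#' @param pred,gold numeric sequences of equal length >= 2.
#' @return scalar in [0, 2].
#' @export
negPearson <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold must have equal length")
  if (length(pred) < 2L) stop("sequences must have length >= 2")
  if (stats::sd(gold) == 0) stop("gold sequence is constant; correlation undefined")
  if (stats::sd(pred) == 0) stop("pred sequence is constant; correlation undefined")
  1 - stats::cor(pred, gold)
}

# gradient of negPearson w.r.t. pred, numerically stabilized for training
negPearsonGrad <- function(pred, gold, eps = 1e-12) {
  n <- length(pred)
  p <- pred - mean(pred)
  g <- gold - mean(gold)
  np <- sqrt(sum(p^2)) + eps
  ng <- sqrt(sum(g^2)) + eps
  rho <- sum(p * g) / (np * ng)
  v <- g / (np * ng) - rho * p / np^2
  -(v - mean(v))
}

#' Early-training adaptation parameter
#'
#' Linear warm-up ramp suppressing the auxiliary regularization terms early
#' in training: \eqn{\theta = \min(1, step / (warmupFraction \cdot total))}.
#' With `warmupFraction = 0` the ramp is disabled and \eqn{\theta = 1}
#' throughout.
#'
#' @param step current training step (0-based).
#' @param total total number of training steps (> 0).
#' @param warmupFraction fraction of `total` over which theta ramps 0 to 1.
#' @return scalar in [0, 1], nondecreasing in `step`.
#' @export
thetaSchedule <- function(step, total, warmupFraction = 0.1) {
  if (length(total) != 1L || total <= 0) stop("total must be a positive integer")
  if (step < 0 || step > total) stop("step must lie in [0, total]")
  if (warmupFraction <= 0) return(1)
  min(1, step / (warmupFraction * total))
}

#' Loss configuration
#'
#' @param w1,w2,w3 nonnegative trade-off weights for the SpO2, RR and BVP
#'   terms. Defaults are the raw-scale settings (1e-4); the desk-scale
#'   training configuration overrides them to 1 because it z-scores targets.
#' @param warmupFraction theta ramp length as a fraction of training.
#' @param includeBvp include the negative-Pearson BVP term.
#' @param normStats optional list with elements `hr`, `spo2`, `rr`, each
#'   `c(mean, sd)`; scalar targets are z-scored by these before the L1 loss
#'   and predictions un-scaled for metrics. `NULL` means no normalization.
#' @return list of class `lossConfig`.
#' @export
lossConfig <- function(w1 = 1e-4, w2 = 1e-4, w3 = 1e-4,
                       warmupFraction = 0.1, includeBvp = TRUE,
                       normStats = NULL) {
  stopifnot(all(is.finite(c(w1, w2, w3))), all(c(w1, w2, w3) >= 0))
  structure(list(w1 = w1, w2 = w2, w3 = w3,
                 warmupFraction = warmupFraction,
                 includeBvp = isTRUE(includeBvp), normStats = normStats),
            class = "lossConfig")
}

zscore <- function(x, stats) if (is.null(stats)) x else (x - stats[1]) / stats[2]
unzscore <- function(z, stats) if (is.null(stats)) z else z * stats[2] + stats[1]

#' Overall multi-task training loss
#'
#' \eqn{L = \theta (w_1 L_{SpO2} + w_2 L_{RR} [+ w_3 L_{BVP}]) + L_{HR}}
#' where the scalar terms are mean absolute errors (after optional
#' z-scoring per `cfg$normStats`) and the BVP term is the mean
#' [negPearson()] across waveforms.
#'
#' @param pred,gold [VitalsBundle-class] objects with equal sample counts.
#' @param step,total training position for the theta ramp.
#' @param cfg a [lossConfig()].
#' @return list with `total`, `theta`, and the per-term breakdown
#'   `hr`, `spo2`, `rr`, `bvp`.
#' @export
totalLoss <- function(pred, gold, step, total, cfg = lossConfig()) {
  stopifnot(is(pred, "VitalsBundle"), is(gold, "VitalsBundle"))
  ns <- cfg$normStats
  lhr <- mean(abs(zscore(pred@hr, ns$hr) - zscore(gold@hr, ns$hr)))
  lsp <- mean(abs(zscore(pred@spo2, ns$spo2) - zscore(gold@spo2, ns$spo2)))
  lrr <- mean(abs(zscore(pred@rr, ns$rr) - zscore(gold@rr, ns$rr)))
  lbvp <- if (cfg$includeBvp)
    mean(vapply(seq_len(nrow(pred@bvp)),
                function(i) negPearson(pred@bvp[i, ], gold@bvp[i, ]), 0))
  else NA_real_
  th <- thetaSchedule(step, total, cfg$warmupFraction)
  aux <- cfg$w1 * lsp + cfg$w2 * lrr +
    if (cfg$includeBvp) cfg$w3 * lbvp else 0
  list(total = th * aux + lhr, theta = th,
       hr = lhr, spo2 = lsp, rr = lrr, bvp = lbvp)
}

# loss + gradients w.r.t. the model's normalized-scale outputs; used by the
# training loop. predZ: list(hr, spo2, rr, bvp) on the z scale; goldZ same.
lossWithGrad <- function(predZ, goldZ, theta, cfg) {
  B <- length(predZ$hr)
  ehr <- predZ$hr - goldZ$hr
  esp <- predZ$spo2 - goldZ$spo2
  err <- predZ$rr - goldZ$rr
  lhr <- mean(abs(ehr)); lsp <- mean(abs(esp)); lrr <- mean(abs(err))
  dhr <- sign(ehr) / B
  dsp <- theta * cfg$w1 * sign(esp) / B
  drr <- theta * cfg$w2 * sign(err) / B
  if (cfg$includeBvp) {
    lb <- numeric(B)
    dbvp <- predZ$bvp * 0
    for (i in seq_len(B)) {
      p <- predZ$bvp[i, ]; g <- goldZ$bvp[i, ]
      pc <- p - mean(p); gc <- g - mean(g)
      np <- sqrt(sum(pc^2)) + 1e-12
      ng <- sqrt(sum(gc^2)) + 1e-12
      lb[i] <- 1 - sum(pc * gc) / (np * ng)
      dbvp[i, ] <- theta * cfg$w3 * negPearsonGrad(p, g) / B
    }
    lbvp <- mean(lb)
  } else {
    lbvp <- NA_real_
    dbvp <- predZ$bvp * 0
  }
  aux <- cfg$w1 * lsp + cfg$w2 * lrr + if (cfg$includeBvp) cfg$w3 * lbvp else 0
  list(total = theta * aux + lhr, theta = theta,
       hr = lhr, spo2 = lsp, rr = lrr, bvp = lbvp,
       grads = list(hr = dhr, spo2 = dsp, rr = drr, bvp = dbvp))
}
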