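# Feature-extraction backbone: convolutional stem, residual conv blocks with
# downsamplers, then two hybrid stages in which the first half of the layers
# are selective-SSM integrator layers and the second half are multi-head
# attention layers; global average pooling and a linear projection produce
# the task-shared representation. Channel width doubles at every spatial
# downsampling (C, 2C, 4C, 8C at strides 4, 8, 16, 32).

#' Model architecture configuration
#'
#' @param H,W input STMap height and width; both must be divisible by 32
#'   (two stem strides, two conv-block downsamplers, one inter-stage sampler).
#' @param cEmbed embedding channels C after the stem; widths are C, 2C, 4C,
#'   8C at strides 4, 8, 16, 32.
#' @param n1,n2 residual conv layers in the first/second ResConv block.
#' @param nMp layers per hybrid stage; the first `ceiling(nMp/2)` are
#'   integrator layers, the rest attention layers (odd values allowed).
#' @param nHeads attention heads; must divide both stage widths (4C, 8C).
#' @param mlpRatio hidden-width expansion of the MLP sublayers.
#' @param sState state size of the selective scan.
#' @param dR length of the task-shared representation r.
#' @param bvpLen length T of the predicted BVP waveform.
#' @return a validated list of class `modelConfig`.
#' @export
modelConfig <- function(H = 64L, W = 256L, cEmbed = 32L, n1 = 2L, n2 = 2L,
                        nMp = 4L, nHeads = 4L, mlpRatio = 4L, sState = 16L,
                        dR = 128L, bvpLen = W) {
  cfg <- list(H = as.integer(H), W = as.integer(W),
              cEmbed = as.integer(cEmbed), n1 = as.integer(n1),
              n2 = as.integer(n2), nMp = as.integer(nMp),
              nHeads = as.integer(nHeads), mlpRatio = as.integer(mlpRatio),
              sState = as.integer(sState), dR = as.integer(dR),
              bvpLen = as.integer(bvpLen))
  if (cfg$H %% 32L != 0L || cfg$W %% 32L != 0L)
    stop("H and W must be divisible by 32")
  if ((4L * cfg$cEmbed) %% cfg$nHeads != 0L)
    stop("nHeads must divide the stage channel widths")
  if (cfg$cEmbed %% 2L != 0L)
    stop("cEmbed must be even (integrator halves the width)")
  if (cfg$nMp < 1L) stop("nMp must be >= 1")
  class(cfg) <- "modelConfig"
  cfg
}

# token flatten order: the STMap's horizontal axis is physiological time, so
# tokens scan along W fastest; perm maps token index -> spatial flat index
tokenPerm <- function(h, w) {
  l <- seq_len(h * w)
  hh <- (l - 1L) %/% w + 1L
  ww <- (l - 1L) %% w + 1L
  hh + h * (ww - 1L)
}

buildHybridLayer <- function(mods, prefix, C, kind, cfg) {
  mods[[paste0(prefix, ".ln1")]] <- nnLayerNorm(C)
  if (kind == "integrator") {
    Ch <- C %/% 2L
    mods[[paste0(prefix, ".int.lin")]] <- nnLinear(C, Ch, sd = sqrt(1 / C))
    mods[[paste0(prefix, ".int.dwc")]] <- nnDWConv1d(Ch)
    mods[[paste0(prefix, ".int.silu")]] <- nnAct("silu")
    mods[[paste0(prefix, ".int.scan")]] <- nnSelectiveSSM(Ch, cfg$sState)
    mods[[paste0(prefix, ".int.proj")]] <- nnLinear(C, C, sd = sqrt(1 / C))
  } else {
    mods[[paste0(prefix, ".attn")]] <- nnAttention(C, cfg$nHeads, prefix)
  }
  mods[[paste0(prefix, ".ln2")]] <- nnLayerNorm(C)
  hid <- C * cfg$mlpRatio
  mods[[paste0(prefix, ".mlp.fc1")]] <- nnLinear(C, hid, sd = sqrt(1 / C))
  mods[[paste0(prefix, ".mlp.act")]] <- nnAct("gelu")
  mods[[paste0(prefix, ".mlp.fc2")]] <- nnLinear(hid, C, sd = sqrt(1 / hid))
  mods
}

#' Build the multi-task vitals estimation model
#'
#' Assembles the full network (backbone, per-task gates, estimation heads)
#' with freshly initialized parameters.
#'
#' @param cfg a [modelConfig()].
#' @param seed integer seed for weight initialization.
#' @return an [RppgModel-class].
#' @export
rppgModel <- function(cfg = modelConfig(), seed = 1L) {
  stopifnot(inherits(cfg, "modelConfig"))
  set.seed(seed)
  C0 <- cfg$cEmbed
  mods <- list()
  mods[["stem.conv1"]] <- nnConv2d(3L, C0, stride = 2L)
  mods[["stem.bn1"]] <- nnBatchNorm(C0)
  mods[["stem.act1"]] <- nnAct("gelu")
  mods[["stem.conv2"]] <- nnConv2d(C0, C0, stride = 2L)
  mods[["stem.bn2"]] <- nnBatchNorm(C0)
  mods[["stem.act2"]] <- nnAct("gelu")
  for (i in seq_len(cfg$n1)) {
    p <- sprintf("rc1.l%d", i)
    mods[[paste0(p, ".conv1")]] <- nnConv2d(C0, C0)
    mods[[paste0(p, ".bn1")]] <- nnBatchNorm(C0)
    mods[[paste0(p, ".act")]] <- nnAct("gelu")
    mods[[paste0(p, ".conv2")]] <- nnConv2d(C0, C0)
    mods[[paste0(p, ".bn2")]] <- nnBatchNorm(C0)
  }
  mods[["down1.conv"]] <- nnConv2d(C0, 2L * C0, stride = 2L)
  mods[["down1.bn"]] <- nnBatchNorm(2L * C0)
  for (i in seq_len(cfg$n2)) {
    p <- sprintf("rc2.l%d", i)
    mods[[paste0(p, ".conv1")]] <- nnConv2d(2L * C0, 2L * C0)
    mods[[paste0(p, ".bn1")]] <- nnBatchNorm(2L * C0)
    mods[[paste0(p, ".act")]] <- nnAct("gelu")
    mods[[paste0(p, ".conv2")]] <- nnConv2d(2L * C0, 2L * C0)
    mods[[paste0(p, ".bn2")]] <- nnBatchNorm(2L * C0)
  }
  mods[["down2.conv"]] <- nnConv2d(2L * C0, 4L * C0, stride = 2L)
  mods[["down2.bn"]] <- nnBatchNorm(4L * C0)
  nInt <- as.integer(ceiling(cfg$nMp / 2))
  kinds <- c(rep("integrator", nInt), rep("attention", cfg$nMp - nInt))
  for (j in seq_len(cfg$nMp))
    mods <- buildHybridLayer(mods, sprintf("stage1.l%d", j), 4L * C0,
                             kinds[j], cfg)
  mods[["sampler.conv"]] <- nnConv2d(4L * C0, 8L * C0, stride = 2L)
  mods[["sampler.bn"]] <- nnBatchNorm(8L * C0)
  for (j in seq_len(cfg$nMp))
    mods <- buildHybridLayer(mods, sprintf("stage2.l%d", j), 8L * C0,
                             kinds[j], cfg)
  mods[["pool"]] <- nnMeanPool()
  mods[["projR"]] <- nnLinear(8L * C0, cfg$dR, sd = sqrt(1 / (8L * C0)))
  for (task in c("HR", "SpO2", "RR")) {
    p <- paste0("gate.", task)
    mods[[paste0(p, ".lin1")]] <- nnLinear(cfg$dR, cfg$dR, sd = sqrt(1 / cfg$dR))
    mods[[paste0(p, ".ln1")]] <- nnLayerNorm(cfg$dR)
    mods[[paste0(p, ".relu")]] <- nnAct("relu")
    mods[[paste0(p, ".lin2")]] <- nnLinear(cfg$dR, cfg$dR, sd = sqrt(1 / cfg$dR))
    mods[[paste0(p, ".ln2")]] <- nnLayerNorm(cfg$dR)
    mods[[paste0(p, ".sig")]] <- nnAct("sigmoid")
    mods[[paste0("head.", task)]] <- nnLinear(cfg$dR, 1L, sd = 0.01)
  }
  L2 <- (cfg$H %/% 32L) * (cfg$W %/% 32L)
  mods[["head.BVP"]] <- nnLinear(L2 * 8L * C0, cfg$bvpLen,
                                 sd = sqrt(1 / (L2 * 8L * C0)))
  state <- new.env(parent = emptyenv())
  state$modules <- mods
  state$kinds <- kinds
  state$scanIdentity <- FALSE
  new("RppgModel", config = unclass(cfg), state = state)
}

#' Number of trainable parameters
#' @param model an [RppgModel-class].
#' @return integer count.
#' @export
nParams <- function(model) {
  sum(vapply(model@state$modules,
             function(m) sum(vapply(m$par, length, 1L)), 1))
}

# ---- sub-block forward/backward -------------------------------------------

stemForward <- function(M, x, h, w, B, training) {
  o <- conv2dForward(M[["stem.conv1"]], x, h, w, B)
  v <- actForward(M[["stem.act1"]], bnForward(M[["stem.bn1"]], o$x, training))
  o2 <- conv2dForward(M[["stem.conv2"]], v, o$h, o$w, B)
  v2 <- actForward(M[["stem.act2"]], bnForward(M[["stem.bn2"]], o2$x, training))
  list(x = v2, h = o2$h, w = o2$w)
}

stemBackward <- function(M, dy) {
  d <- bnBackward(M[["stem.bn2"]], actBackward(M[["stem.act2"]], dy))
  d <- conv2dBackward(M[["stem.conv2"]], d)
  d <- bnBackward(M[["stem.bn1"]], actBackward(M[["stem.act1"]], d))
  conv2dBackward(M[["stem.conv1"]], d)
}

resconvForward <- function(M, prefix, n, x, h, w, B, training) {
  for (i in seq_len(n)) {
    p <- sprintf("%s.l%d", prefix, i)
    o <- conv2dForward(M[[paste0(p, ".conv1")]], x, h, w, B)
    v <- actForward(M[[paste0(p, ".act")]],
                    bnForward(M[[paste0(p, ".bn1")]], o$x, training))
    o2 <- conv2dForward(M[[paste0(p, ".conv2")]], v, h, w, B)
    x <- bnForward(M[[paste0(p, ".bn2")]], o2$x, training) + x
  }
  x
}

resconvBackward <- function(M, prefix, n, dy) {
  for (i in rev(seq_len(n))) {
    p <- sprintf("%s.l%d", prefix, i)
    d <- bnBackward(M[[paste0(p, ".bn2")]], dy)
    d <- conv2dBackward(M[[paste0(p, ".conv2")]], d)
    d <- bnBackward(M[[paste0(p, ".bn1")]],
                    actBackward(M[[paste0(p, ".act")]], d))
    dy <- dy + conv2dBackward(M[[paste0(p, ".conv1")]], d)
  }
  dy
}

integratorForward <- function(M, p, x, B, L, scanIdentity) {
  v <- actForward(M[[paste0(p, ".int.silu")]],
         dwconv1dForward(M[[paste0(p, ".int.dwc")]],
           linearForward(M[[paste0(p, ".int.lin")]], x), B, L))
  main <- if (scanIdentity) v else
    sssmForward(M[[paste0(p, ".int.scan")]], v, B, L)
  linearForward(M[[paste0(p, ".int.proj")]], cbind(main, v))
}

integratorBackward <- function(M, p, dy, scanIdentity) {
  dcat <- linearBackward(M[[paste0(p, ".int.proj")]], dy)
  Ch <- ncol(dcat) %/% 2L
  dmain <- dcat[, seq_len(Ch), drop = FALSE]
  dv <- dcat[, Ch + seq_len(Ch), drop = FALSE]
  if (scanIdentity) dv <- dv + dmain
  else dv <- dv + sssmBackward(M[[paste0(p, ".int.scan")]], dmain)
  d <- dwconv1dBackward(M[[paste0(p, ".int.dwc")]],
         actBackward(M[[paste0(p, ".int.silu")]], dv))
  linearBackward(M[[paste0(p, ".int.lin")]], d)
}

hybridLayerForward <- function(state, p, kind, x, B, L) {
  M <- state$modules
  t1 <- lnForward(M[[paste0(p, ".ln1")]], x)
  br <- if (kind == "integrator")
    integratorForward(M, p, t1, B, L, state$scanIdentity)
  else attnForward(M[[paste0(p, ".attn")]], t1, B, L)
  x2 <- x + br
  t2 <- lnForward(M[[paste0(p, ".ln2")]], x2)
  m <- linearForward(M[[paste0(p, ".mlp.fc2")]],
         actForward(M[[paste0(p, ".mlp.act")]],
           linearForward(M[[paste0(p, ".mlp.fc1")]], t2)))
  x2 + m
}

hybridLayerBackward <- function(state, p, kind, dy) {
  M <- state$modules
  d <- linearBackward(M[[paste0(p, ".mlp.fc1")]],
         actBackward(M[[paste0(p, ".mlp.act")]],
           linearBackward(M[[paste0(p, ".mlp.fc2")]], dy)))
  dx2 <- dy + lnBackward(M[[paste0(p, ".ln2")]], d)
  dbr <- if (kind == "integrator")
    integratorBackward(M, p, dx2, state$scanIdentity)
  else attnBackward(M[[paste0(p, ".attn")]], dx2)
  dx2 + lnBackward(M[[paste0(p, ".ln1")]], dbr)
}

gateForward <- function(M, task, r) {
  p <- paste0("gate.", task)
  actForward(M[[paste0(p, ".sig")]],
    lnForward(M[[paste0(p, ".ln2")]],
      linearForward(M[[paste0(p, ".lin2")]],
        actForward(M[[paste0(p, ".relu")]],
          lnForward(M[[paste0(p, ".ln1")]],
            linearForward(M[[paste0(p, ".lin1")]], r))))))
}

gateBackward <- function(M, task, dsigma) {
  p <- paste0("gate.", task)
  linearBackward(M[[paste0(p, ".lin1")]],
    lnBackward(M[[paste0(p, ".ln1")]],
      actBackward(M[[paste0(p, ".relu")]],
        linearBackward(M[[paste0(p, ".lin2")]],
          lnBackward(M[[paste0(p, ".ln2")]],
            actBackward(M[[paste0(p, ".sig")]], dsigma))))))
}

# ---- full model forward/backward ------------------------------------------

# x: matrix (B*H*W, 3), spatial index h fastest. Returns predictions on the
# normalized (z-score) scale plus intermediates needed for the backward pass.
modelForward <- function(model, x, B, training = FALSE) {
  state <- model@state
  M <- state$modules
  cfg <- model@config
  st <- stemForward(M, x, cfg$H, cfg$W, B, training)
  v <- resconvForward(M, "rc1", cfg$n1, st$x, st$h, st$w, B, training)
  o <- conv2dForward(M[["down1.conv"]], v, st$h, st$w, B)
  v <- bnForward(M[["down1.bn"]], o$x, training)
  v <- resconvForward(M, "rc2", cfg$n2, v, o$h, o$w, B, training)
  o2 <- conv2dForward(M[["down2.conv"]], v, o$h, o$w, B)
  v <- bnForward(M[["down2.bn"]], o2$x, training)
  h3 <- o2$h; w3 <- o2$w
  perm1 <- tokenPerm(h3, w3)
  L1 <- h3 * w3
  gidx1 <- rep((seq_len(B) - 1L) * L1, each = L1) + perm1
  tok <- v[gidx1, , drop = FALSE]
  for (j in seq_len(cfg$nMp))
    tok <- hybridLayerForward(state, sprintf("stage1.l%d", j),
                              state$kinds[j], tok, B, L1)
  # unflatten, sampler, reflatten
  inv1 <- integer(L1); inv1[perm1] <- seq_len(L1)
  ginv1 <- rep((seq_len(B) - 1L) * L1, each = L1) + inv1
  vmap <- tok[ginv1, , drop = FALSE]
  o3 <- conv2dForward(M[["sampler.conv"]], vmap, h3, w3, B)
  v2 <- bnForward(M[["sampler.bn"]], o3$x, training)
  h4 <- o3$h; w4 <- o3$w
  perm2 <- tokenPerm(h4, w4)
  L2 <- h4 * w4
  gidx2 <- rep((seq_len(B) - 1L) * L2, each = L2) + perm2
  tok2 <- v2[gidx2, , drop = FALSE]
  for (j in seq_len(cfg$nMp))
    tok2 <- hybridLayerForward(state, sprintf("stage2.l%d", j),
                               state$kinds[j], tok2, B, L2)
  pooled <- meanPoolForward(M[["pool"]], tok2, B, L2)
  r <- linearForward(M[["projR"]], pooled)
  sigma <- list()
  rp <- list()
  yhat <- list()
  for (task in c("HR", "SpO2", "RR")) {
    sigma[[task]] <- gateForward(M, task, r)
    rp[[task]] <- sigma[[task]] * r
    yhat[[task]] <- linearForward(M[[paste0("head.", task)]], rp[[task]])
  }
  C4 <- ncol(tok2)
  Z <- matrix(0, B, L2 * C4)
  for (b in seq_len(B))
    Z[b, ] <- as.vector(tok2[(b - 1L) * L2 + seq_len(L2), , drop = FALSE])
  bvp <- linearForward(M[["head.BVP"]], Z)
  fwd <- list(hr = drop(yhat$HR), spo2 = drop(yhat$SpO2), rr = drop(yhat$RR),
              bvp = bvp, r = r, sigma = sigma, rp = rp,
              geom = list(B = B, L1 = L1, L2 = L2, C4 = C4,
                          gidx1 = gidx1, ginv1 = ginv1, gidx2 = gidx2,
                          h3 = h3, w3 = w3))
  state$lastFwd <- fwd
  fwd
}

# douts: list(hr, spo2, rr: length-B vectors; bvp: B x T matrix) of loss
# gradients w.r.t. the normalized-scale outputs.
modelBackward <- function(model, douts) {
  state <- model@state
  M <- state$modules
  cfg <- model@config
  fwd <- state$lastFwd
  g <- fwd$geom
  B <- g$B
  dr <- matrix(0, B, cfg$dR)
  for (task in c("HR", "SpO2", "RR")) {
    dyt <- matrix(switch(task, HR = douts$hr, SpO2 = douts$spo2,
                         RR = douts$rr), B, 1L)
    drp <- linearBackward(M[[paste0("head.", task)]], dyt)
    dsigma <- drp * fwd$r
    dr <- dr + drp * fwd$sigma[[task]]
    dr <- dr + gateBackward(M, task, dsigma)
  }
  dZ <- linearBackward(M[["head.BVP"]], douts$bvp)
  dtok2 <- matrix(0, B * g$L2, g$C4)
  for (b in seq_len(B))
    dtok2[(b - 1L) * g$L2 + seq_len(g$L2), ] <-
      matrix(dZ[b, ], g$L2, g$C4)
  dpooled <- linearBackward(M[["projR"]], dr)
  dtok2 <- dtok2 + meanPoolBackward(M[["pool"]], dpooled)
  for (j in rev(seq_len(cfg$nMp)))
    dtok2 <- hybridLayerBackward(state, sprintf("stage2.l%d", j),
                                 state$kinds[j], dtok2)
  # gidx2 is a permutation of rows; invert it directly
  dv2 <- matrix(0, nrow(dtok2), ncol(dtok2))
  dv2[g$gidx2, ] <- dtok2
  d <- bnBackward(M[["sampler.bn"]], dv2)
  dvmap <- conv2dBackward(M[["sampler.conv"]], d)
  dtok <- matrix(0, nrow(dvmap), ncol(dvmap))
  dtok[g$ginv1, ] <- dvmap
  for (j in rev(seq_len(cfg$nMp)))
    dtok <- hybridLayerBackward(state, sprintf("stage1.l%d", j),
                                state$kinds[j], dtok)
  dvflat <- matrix(0, nrow(dtok), ncol(dtok))
  dvflat[g$gidx1, ] <- dtok
  d <- bnBackward(M[["down2.bn"]], dvflat)
  d <- conv2dBackward(M[["down2.conv"]], d)
  d <- resconvBackward(M, "rc2", cfg$n2, d)
  d <- bnBackward(M[["down1.bn"]], d)
  d <- conv2dBackward(M[["down1.conv"]], d)
  d <- resconvBackward(M, "rc1", cfg$n1, d)
  stemBackward(M, d)
}

# ---- public API ------------------------------------------------------------

# convert a list of STMap objects (or H x W x 3 arrays) to the input matrix
stmapsToInput <- function(stmaps, cfg) {
  if (is(stmaps, "STMap")) stmaps <- list(stmaps)
  B <- length(stmaps)
  X <- matrix(0, B * cfg$H * cfg$W, 3L)
  for (b in seq_len(B)) {
    v <- if (is(stmaps[[b]], "STMap")) stmaps[[b]]@values else stmaps[[b]]
    d <- dim(v)
    if (d[1] != cfg$H || d[2] != cfg$W)
      stop(sprintf("STMap is %dx%d but the model expects %dx%d",
                   d[1], d[2], cfg$H, cfg$W))
    X[(b - 1L) * cfg$H * cfg$W + seq_len(cfg$H * cfg$W), ] <-
      matrix(v, cfg$H * cfg$W, 3L)
  }
  X
}

#' Task-shared representation of one or more STMaps
#'
#' Runs the backbone in evaluation mode and returns the pooled, linearly
#' projected shared representation r that feeds the per-task gates.
#'
#' @param model an [RppgModel-class].
#' @param stmaps an [STMap-class], a list of them, or H x W x 3 arrays.
#' @return numeric matrix (n samples x dR).
#' @export
extractShared <- function(model, stmaps) {
  if (is(stmaps, "STMap") || is.array(stmaps)) stmaps <- list(stmaps)
  X <- stmapsToInput(stmaps, model@config)
  fwd <- modelForward(model, X, length(stmaps), training = FALSE)
  fwd$r
}

#' Per-task gate activations
#'
#' Applies one task's gate chain (Linear, LayerNorm, ReLU, Linear,
#' LayerNorm, Sigmoid) to shared representations. All outputs are strictly
#' inside (0, 1).
#'
#' @param model an [RppgModel-class].
#' @param r matrix of shared representations (n x dR), e.g. from
#'   [extractShared()].
#' @param task one of `"HR"`, `"SpO2"`, `"RR"`.
#' @return matrix of gate values in (0, 1), same shape as `r`.
#' @export
gateActivations <- function(model, r, task = c("HR", "SpO2", "RR")) {
  task <- match.arg(task)
  if (is.null(dim(r))) r <- matrix(r, nrow = 1L)
  gateForward(model@state$modules, task, r)
}

#' Gated task-specific features
#'
#' Elementwise selection r' = sigma * r of the shared representation by a
#' gate output.
#'
#' @param r shared representation (vector or matrix).
#' @param sigma gate output of matching shape, entries in (0, 1).
#' @return task-specific features, same shape.
#' @export
selectFeatures <- function(r, sigma) {
  if (length(r) != length(sigma))
    stop("r and sigma must have the same length")
  r * sigma
}

#' Zero all non-residual branch weights (diagnostic)
#'
#' Sets the closing projection of every residual branch to zero (second conv
#' + batch norm of each residual conv layer, integrator output projection,
#' attention output projection, second MLP linear), which reduces every
#' residual layer to the identity map. Used to verify gradient/identity
#' properties.
#'
#' @param model an [RppgModel-class]; modified in place.
#' @return the model, invisibly.
#' @export
zeroResidualWeights <- function(model) {
  M <- model@state$modules
  for (nm in names(M)) {
    if (grepl("\\.(conv2)$", nm) && grepl("^rc", nm)) {
      M[[nm]]$par$W[] <- 0; M[[nm]]$par$b[] <- 0
    }
    if (grepl("\\.bn2$", nm) && grepl("^rc", nm)) {
      M[[nm]]$par$gamma[] <- 0; M[[nm]]$par$beta[] <- 0
    }
    if (grepl("\\.int\\.proj$", nm) || grepl("\\.mlp\\.fc2$", nm)) {
      M[[nm]]$par$W[] <- 0; M[[nm]]$par$b[] <- 0
    }
    if (grepl("\\.attn$", nm)) {
      M[[nm]]$par$Wo[] <- 0; M[[nm]]$par$bo[] <- 0
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single-file archive holding a JSON manifest
#' (architecture config, package version, optional metric snapshot) and all
#' parameter arrays plus batch-norm running statistics.
#'
#' @param model an [RppgModel-class].
#' @param path file path.
#' @param metrics optional named list stored in the manifest.
#' @return `saveModel` the path invisibly; `loadModel` the restored model.
#' @export
saveModel <- function(model, path, metrics = NULL) {
  M <- model@state$modules
  pars <- lapply(M, function(m) m$par)
  running <- lapply(M, function(m)
    if (m$type == "bn") list(runMean = m$runMean, runVar = m$runVar) else NULL)
  manifest <- jsonlite::toJSON(
    list(config = model@config,
         version = as.character(utils::packageVersion("rppgmamba")),
         normStats = model@state$normStats,
         metrics = metrics),
    auto_unbox = TRUE, digits = NA)
  saveRDS(list(manifest = as.character(manifest), params = pars,
               running = running), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  ck <- readRDS(path)
  manifest <- jsonlite::fromJSON(ck$manifest)
  cfg <- do.call(modelConfig, manifest$config[names(formals(modelConfig))[
    names(formals(modelConfig)) %in% names(manifest$config)]])
  model <- rppgModel(cfg, seed = 1L)
  M <- model@state$modules
  for (nm in names(ck$params)) {
    for (pn in names(ck$params[[nm]])) M[[nm]]$par[[pn]] <- ck$params[[nm]][[pn]]
    if (!is.null(ck$running[[nm]])) {
      M[[nm]]$runMean <- ck$running[[nm]]$runMean
      M[[nm]]$runVar <- ck$running[[nm]]$runVar
    }
  }
  if (!is.null(manifest$normStats))
    model@state$normStats <- lapply(manifest$normStats, as.numeric)
  model
}
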