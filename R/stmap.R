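# STMap construction from frame sequences, 30 Hz resampling, augmentation,
# and plain-text container I/O. Face detection is out of scope: the caller
# supplies the ROI rectangle (the synthetic generator bypasses video).

#' Build an STMap from a frame sequence
#'
#' Partitions the face ROI of every frame into a `grid` of blocks, takes
#' each block's per-channel spatial mean per frame, and stacks the resulting
#' time series as rows: an array (rows*cols) x T x 3. Each row is min-max
#' normalized to [0, 1] per channel over the temporal window; a constant
#' (zero-range) row is set to 0.5 and recorded in the `degenerateRows`
#' attribute.
#'
#' @param frames list of H x W x 3 numeric arrays (same size), or a
#'   directory containing PNG frames in lexical order.
#' @param timestamps per-frame times in seconds, strictly increasing;
#'   defaults to a uniform grid at `rate`.
#' @param roi ROI rectangle `c(top, left, height, width)` in pixels;
#'   defaults to the full frame. Must be divisible by the grid.
#' @param grid `c(rows, cols)` block partition of the ROI.
#' @param rate nominal frame rate stored in the result.
#' @return an [STMap-class] with `(rows*cols)` rows and T = number of frames
#'   columns; attribute `degenerateRows` lists zero-range (row, channel)
#'   pairs.
#' @export
framesToSTMap <- function(frames, timestamps = NULL, roi = NULL,
                          grid = c(8L, 8L), rate = 30) {
  if (is.character(frames) && length(frames) == 1L) {
    files <- sort(list.files(frames, pattern = "\\.png$", full.names = TRUE))
    if (length(files) < 2L) stop("need at least 2 frames")
    frames <- lapply(files, png::readPNG)
  }
  nT <- length(frames)
  if (nT < 2L) stop("need at least 2 frames")
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("all frames must share dimensions")
  if (!is.null(timestamps)) {
    if (length(timestamps) != nT) stop("one timestamp per frame required")
    if (any(diff(timestamps) <= 0))
      stop("timestamps must be strictly increasing")
  }
  if (is.null(roi)) roi <- c(1L, 1L, d[1L], d[2L])
  rows <- grid[1L]; cols <- grid[2L]
  if (roi[3L] %% rows != 0L || roi[4L] %% cols != 0L)
    stop("grid must divide the ROI dimensions")
  bh <- roi[3L] %/% rows; bw <- roi[4L] %/% cols
  H <- rows * cols
  vals <- array(0, c(H, nT, 3L))
  for (t in seq_len(nT)) {
    f <- frames[[t]]
    for (gr in seq_len(rows)) for (gc in seq_len(cols)) {
      ri <- roi[1L] + (gr - 1L) * bh + seq_len(bh) - 1L
      ci <- roi[2L] + (gc - 1L) * bw + seq_len(bw) - 1L
      blk <- f[ri, ci, , drop = FALSE]
      r <- gc + cols * (gr - 1L)
      vals[r, t, ] <- apply(blk, 3L, mean)
    }
  }
  degenerate <- NULL
  for (r in seq_len(H)) for (c in 1:3) {
    rng <- range(vals[r, , c])
    if (diff(rng) == 0) {
      vals[r, , c] <- 0.5
      degenerate <- rbind(degenerate, c(row = r, channel = c))
      warning(sprintf("constant block: row %d channel %d set to 0.5", r, c))
    } else {
      vals[r, , c] <- (vals[r, , c] - rng[1L]) / diff(rng)
    }
  }
  out <- stmap(vals, rate = rate, roiCount = H)
  attr(out, "degenerateRows") <- degenerate
  out
}

#' Resample a timestamped signal to a uniform 30 Hz grid
#'
#' Natural cubic-spline interpolation onto a uniform grid spanning the
#' original time range; the first sample time is preserved exactly.
#'
#' @param t strictly increasing timestamps (seconds), length >= 4.
#' @param y signal values at `t`.
#' @param rate target rate in Hz (default 30).
#' @return list with `t` (the uniform grid) and `y` (the resampled signal).
#' @export
resample30Hz <- function(t, y, rate = 30) {
  if (length(t) != length(y)) stop("t and y must have equal length")
  if (length(t) < 4L) stop("cubic spline needs at least 4 samples")
  if (anyDuplicated(t) || any(diff(t) <= 0))
    stop("timestamps must be strictly increasing without duplicates")
  f <- stats::splinefun(t, y, method = "natural")
  grid <- seq(t[1L], t[length(t)], by = 1 / rate)
  list(t = grid, y = f(grid))
}

#' Augmentation configuration
#'
#' @param jitterBrightness,jitterContrast,jitterSaturation maximum relative
#'   perturbation of each colour-jitter factor, in [0, 0.5].
#' @param blurSigmaRange interval from which the Gaussian blur sigma is
#'   drawn (pixels); `c(0, 0)` disables blur.
#' @param seed RNG seed making the augmentation reproducible.
#' @return list of class `augmentConfig`.
#' @export
augmentConfig <- function(jitterBrightness = 0.1, jitterContrast = 0.1,
                          jitterSaturation = 0.1, blurSigmaRange = c(0, 1),
                          seed = 1L) {
  j <- c(jitterBrightness, jitterContrast, jitterSaturation)
  if (any(j < 0) || any(j > 0.5)) stop("jitter perturbations must be in [0, 0.5]")
  if (any(blurSigmaRange < 0)) stop("blur sigma must be >= 0")
  structure(list(jitterBrightness = jitterBrightness,
                 jitterContrast = jitterContrast,
                 jitterSaturation = jitterSaturation,
                 blurSigmaRange = blurSigmaRange, seed = as.integer(seed)),
            class = "augmentConfig")
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Colour-jitter and blur augmentation of an STMap
#'
#' Applies random brightness, contrast and saturation factors within the
#' configured bounds, then a Gaussian blur with sigma drawn from
#' `blurSigmaRange`, and clips to [0, 1]. Fully reproducible from
#' `cfg$seed`; shape and rate metadata are never altered.
#'
#' @param x an [STMap-class].
#' @param cfg an [augmentConfig()].
#' @return the augmented [STMap-class].
#' @export
augmentSTMap <- function(x, cfg) {
  stopifnot(is(x, "STMap"), inherits(cfg, "augmentConfig"))
  v <- x@values
  withSeed(cfg$seed, {
    fb <- 1 + stats::runif(1, -cfg$jitterBrightness, cfg$jitterBrightness)
    fc <- 1 + stats::runif(1, -cfg$jitterContrast, cfg$jitterContrast)
    fs <- 1 + stats::runif(1, -cfg$jitterSaturation, cfg$jitterSaturation)
    sigma <- stats::runif(1, cfg$blurSigmaRange[1L], cfg$blurSigmaRange[2L])
    v <- v * fb
    m <- mean(v)
    v <- (v - m) * fc + m
    gray <- (v[, , 1L] + v[, , 2L] + v[, , 3L]) / 3
    for (c in 1:3) v[, , c] <- gray + fs * (v[, , c] - gray)
    if (sigma > 0)
      for (c in 1:3) v[, , c] <- EBImage::gblur(v[, , c], sigma = sigma)
  })
  v[v < 0] <- 0
  v[v > 1] <- 1
  stmap(v, rate = x@rate, roiCount = x@roiCount)
}

#' Bilinear resize of an STMap
#'
#' Optional geometry adapter resizing an STMap to the input size the model
#' expects.
#'
#' @param x an [STMap-class].
#' @param H,W target height and width.
#' @return the resized [STMap-class].
#' @export
resizeSTMap <- function(x, H, W) {
  v <- array(0, c(H, W, 3L))
  for (c in 1:3)
    v[, , c] <- EBImage::resize(x@values[, , c], w = H, h = W)
  v[v < 0] <- 0; v[v > 1] <- 1
  stmap(v, rate = x@rate * W / dim(x@values)[2L], roiCount = x@roiCount)
}

# ---- container I/O ---------------------------------------------------------

#' Write / read an STMap container
#'
#' Plain-text directory bundle: `stmap_R.csv`, `stmap_G.csv`, `stmap_B.csv`
#' (H x W matrices), `bvp.csv`, and `meta.json` holding the labels
#' (hr, spo2, rr), sampling rate and generator seed.
#'
#' @param x an [STMap-class] or [SyntheticSample-class].
#' @param dir directory to create/read.
#' @return `writeSTMapBundle` the directory invisibly; `readSTMapBundle` a
#'   [SyntheticSample-class] (labels NA when absent).
#' @export
writeSTMapBundle <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is(x, "SyntheticSample")) {
    sm <- x@stmap
    meta <- list(hr = x@truth@hr, spo2 = x@truth@spo2, rr = x@truth@rr,
                 rate = sm@rate, seed = x@seed, configHash = x@configHash)
    utils::write.csv(data.frame(bvp = as.numeric(x@truth@bvp[1L, ])),
                     file.path(dir, "bvp.csv"), row.names = FALSE)
  } else {
    sm <- x
    meta <- list(hr = NA, spo2 = NA, rr = NA, rate = sm@rate,
                 seed = NA, configHash = NA)
  }
  for (c in 1:3) {
    ch <- c("R", "G", "B")[c]
    utils::write.table(sm@values[, , c],
                       file.path(dir, sprintf("stmap_%s.csv", ch)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname writeSTMapBundle
#' @export
readSTMapBundle <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  chans <- lapply(c("R", "G", "B"), function(ch)
    as.matrix(utils::read.table(file.path(dir, sprintf("stmap_%s.csv", ch)),
                                sep = ",")))
  v <- array(0, c(nrow(chans[[1L]]), ncol(chans[[1L]]), 3L))
  for (c in 1:3) v[, , c] <- chans[[c]]
  sm <- stmap(v, rate = meta$rate)
  bvpPath <- file.path(dir, "bvp.csv")
  bvp <- if (file.exists(bvpPath))
    utils::read.csv(bvpPath)$bvp else rep(NA_real_, ncol(chans[[1L]]))
  truth <- vitalsBundle(hr = meta$hr, spo2 = meta$spo2, rr = meta$rr,
                        bvp = bvp)
  new("SyntheticSample", stmap = sm, truth = truth,
      seed = as.integer(if (is.null(meta$seed) || is.na(meta$seed)) 0L
                        else meta$seed),
      configHash = as.character(meta$configHash))
}

#' Export an STMap as an 8-bit PNG for visual inspection
#'
#' @param x an [STMap-class].
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
stmapToPNG <- function(x, path) {
  png::writePNG(x@values, path)
  invisible(path)
}

#' Read / write a vitals CSV time series
#'
#' Columns `t_sec`, `bvp` and optionally `hr`, `spo2`, `rr`.
#'
#' @param path CSV path.
#' @param df data frame with at least `t_sec` and `bvp`.
#' @return `readVitalsCSV` a data frame; `writeVitalsCSV` the path invisibly.
#' @export
readVitalsCSV <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("t_sec", "bvp") %in% names(df)))
    stop("vitals CSV must have columns t_sec and bvp")
  df
}

#' @rdname readVitalsCSV
#' @export
writeVitalsCSV <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
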