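# Synthetic STMap generator: pulsatile colour signal at a known heart rate,
# respiratory amplitude+frequency modulation at a known respiration rate,
# red/blue channel-ratio structure encoding a known SpO2 via the classical
# ratio-of-ratios calibration, plus illumination drift and Gaussian noise.
# Includes an independent Welch-spectrum oracle for validating labels.

#' Synthetic generator configuration
#'
#' Defaults define the study conditions used throughout the package:
#' physiological uniform ranges, a three-harmonic pulse, mild respiratory
#' amplitude/frequency modulation, and noise expressed in units of the
#' green-channel pulse (AC) amplitude.
#'
#' @param nSamples number of samples a dataset draw will contain.
#' @param durationS clip duration in seconds.
#' @param rate sampling rate (Hz).
#' @param hrRange,rrRange,spo2Range uniform label ranges (beats/min,
#'   breaths/min, percent); must lie inside 40-180, 6-30, 70-100.
#' @param pulseHarmonicWeights amplitudes of the pulse harmonics.
#' @param amDepth respiratory amplitude-modulation depth (fraction).
#' @param fmDepth respiratory frequency-modulation depth (fraction).
#' @param noiseSd i.i.d. Gaussian noise standard deviation, in units of the
#'   green AC amplitude.
#' @param driftAmplitude relative amplitude of the sinusoidal illumination
#'   drift (0.05-0.15 Hz).
#' @param rows number of STMap rows.
#' @param width STMap width (temporal samples fed to the model).
#' @param seed base RNG seed; sample i uses `seed + i`.
#' @return list of class `synthConfig`.
#' @export
synthConfig <- function(nSamples = 10L, durationS = 256 / 30, rate = 30,
                        hrRange = c(50, 150), rrRange = c(8, 24),
                        spo2Range = c(85, 100),
                        pulseHarmonicWeights = c(1, 0.4, 0.15),
                        amDepth = 0.15, fmDepth = 0.05, noiseSd = 0.1,
                        driftAmplitude = 0.5, rows = 64L, width = 256L,
                        seed = 1L) {
  stopifnot(hrRange[1] >= 40, hrRange[2] <= 180,
            rrRange[1] >= 6, rrRange[2] <= 30,
            spo2Range[1] >= 70, spo2Range[2] <= 100,
            rate * durationS >= width)
  structure(list(nSamples = as.integer(nSamples), durationS = durationS,
                 rate = rate, hrRange = hrRange, rrRange = rrRange,
                 spo2Range = spo2Range,
                 pulseHarmonicWeights = pulseHarmonicWeights,
                 amDepth = amDepth, fmDepth = fmDepth, noiseSd = noiseSd,
                 driftAmplitude = driftAmplitude, rows = as.integer(rows),
                 width = as.integer(width), seed = as.integer(seed)),
            class = "synthConfig")
}

#' Synthetic blood-volume-pulse waveform
#'
#' Harmonic pulse at `hr` with respiratory coupling: the instantaneous
#' pulse frequency is modulated by `fmDepth` at the respiration frequency
#' (through the integrated phase), and the amplitude by `amDepth`. The
#' output is standardized to zero mean and unit (sample) standard
#' deviation.
#'
#' @param hr heart rate, beats/min.
#' @param rr respiration rate, breaths/min.
#' @param cfg a [synthConfig()].
#' @param t optional time vector (seconds); defaults to the config grid.
#' @param delay waveform delay in seconds (spatial propagation).
#' @return numeric vector of samples.
#' @export
makeBVP <- function(hr, rr, cfg = synthConfig(), t = NULL, delay = 0) {
  if (is.null(t))
    t <- seq(0, by = 1 / cfg$rate, length.out = round(cfg$rate * cfg$durationS))
  tt <- t - delay
  fhr <- hr / 60
  frr <- rr / 60
  # integrated instantaneous frequency: int_0^t (1 + fm sin(2 pi frr s)) ds
  phase <- tt + cfg$fmDepth * (1 - cos(2 * pi * frr * tt)) / (2 * pi * frr)
  phis <- c(0, -pi / 2, -pi)
  w <- cfg$pulseHarmonicWeights
  x <- numeric(length(tt))
  for (k in seq_along(w))
    x <- x + w[k] * sin(2 * pi * k * fhr * phase + phis[min(k, length(phis))])
  x <- x * (1 + cfg$amDepth * sin(2 * pi * frr * tt))
  (x - mean(x)) / stats::sd(x)
}

# raw (pre-normalization) channel signals for one sample; the test suite
# uses this to recompute the ratio-of-ratios from the generated signals
synthRawSignals <- function(cfg, drawIndex, hr = NULL, rr = NULL,
                            spo2 = NULL) {
  seed <- cfg$seed + as.integer(drawIndex)
  withSeed(seed, {
    if (is.null(hr)) hr <- stats::runif(1, cfg$hrRange[1], cfg$hrRange[2])
    if (is.null(rr)) rr <- stats::runif(1, cfg$rrRange[1], cfg$rrRange[2])
    if (is.null(spo2))
      spo2 <- stats::runif(1, cfg$spo2Range[1], cfg$spo2Range[2])
    nT <- round(cfg$rate * cfg$durationS)
    t <- seq(0, by = 1 / cfg$rate, length.out = nT)
    # ratio-of-ratios encoding: spo2 = 110 - 25 * R  =>  R = (110 - spo2)/25
    R <- (110 - spo2) / 25
    if (R <= 0) stop("spo2 outside the ratio-of-ratios mapping range")
    dc <- c(R = 0.45, G = 0.50, B = 0.35)
    acdcB <- 0.03
    acdc <- c(R = R * acdcB, G = 0.03, B = acdcB)
    rows <- cfg$rows
    delays <- (seq_len(rows) - 1L) / rows * 0.04  # ~40 ms propagation
    pulse <- t(vapply(delays, function(d) makeBVP(hr, rr, cfg, t, delay = d),
                      numeric(nT)))
    frrHz <- rr / 60
    resp <- sin(2 * pi * frrHz * t)                      # baseline respiration
    fdrift <- stats::runif(1, 0.05, 0.15)
    drift <- cfg$driftAmplitude * acdc["G"] *
      sin(2 * pi * fdrift * t + stats::runif(1, 0, 2 * pi))
    raw <- array(0, c(rows, nT, 3L))
    noiseScale <- cfg$noiseSd * dc["G"] * acdc["G"]
    for (c in 1:3) {
      base <- dc[c] * (1 + 0.2 * acdc["G"] * resp) + dc[c] * drift
      ac <- dc[c] * acdc[c]
      raw[, , c] <- matrix(base, rows, nT, byrow = TRUE) + ac * pulse +
        matrix(stats::rnorm(rows * nT, sd = noiseScale), rows, nT)
    }
    list(raw = raw, pulse = pulse, t = t, hr = hr, rr = rr, spo2 = spo2,
         dc = dc, acdc = acdc, R = R, seed = seed)
  })
}

#' Generate one synthetic STMap sample
#'
#' Draws (hr, rr, spo2) uniformly from the configured ranges, builds
#' per-row channel signals carrying the pulse, respiration and SpO2
#' structure, normalizes each row to [0, 1], and crops to the configured
#' width. Deterministic in `(cfg, drawIndex)`.
#'
#' @param cfg a [synthConfig()].
#' @param drawIndex sample index (determines the seed `cfg$seed + drawIndex`).
#' @param hr,rr,spo2 optional fixed labels overriding the random draw.
#' @return a [SyntheticSample-class].
#' @export
makeStmapSample <- function(cfg = synthConfig(), drawIndex = 1L,
                            hr = NULL, rr = NULL, spo2 = NULL) {
  rs <- synthRawSignals(cfg, drawIndex, hr, rr, spo2)
  W <- cfg$width
  v <- array(0, c(cfg$rows, W, 3L))
  for (r in seq_len(cfg$rows)) for (c in 1:3) {
    x <- rs$raw[r, seq_len(W), c]
    rng <- range(x)
    v[r, , c] <- if (diff(rng) == 0) 0.5 else (x - rng[1]) / diff(rng)
  }
  sm <- stmap(v, rate = cfg$rate, roiCount = cfg$rows)
  bvp <- makeBVP(rs$hr, rs$rr, cfg, rs$t[seq_len(W)])
  truth <- vitalsBundle(hr = rs$hr, spo2 = rs$spo2, rr = rs$rr, bvp = bvp)
  new("SyntheticSample", stmap = sm, truth = truth,
      seed = as.integer(rs$seed), configHash = synthConfigHash(cfg))
}

synthConfigHash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x)
    paste(format(x, digits = 12), collapse = ","), ""), collapse = ";")
  # small rolling hash; provenance only
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}

#' Generate a synthetic dataset
#'
#' @param cfg a [synthConfig()].
#' @return list with `samples` (list of [SyntheticSample-class]) and
#'   `manifest` (data frame sample_id, hr, spo2, rr, seed).
#' @export
makeSyntheticDataset <- function(cfg = synthConfig()) {
  samples <- lapply(seq_len(cfg$nSamples), function(i)
    makeStmapSample(cfg, i))
  manifest <- data.frame(
    sample_id = seq_len(cfg$nSamples),
    hr = vapply(samples, function(s) s@truth@hr, 0),
    spo2 = vapply(samples, function(s) s@truth@spo2, 0),
    rr = vapply(samples, function(s) s@truth@rr, 0),
    seed = vapply(samples, function(s) s@seed, 0L))
  list(samples = samples, manifest = manifest)
}

#' Write a synthetic dataset to disk
#'
#' One STMap container directory per sample plus `manifest.csv`.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
writeSyntheticDataset <- function(cfg, dir) {
  ds <- makeSyntheticDataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(ds$samples))
    writeSTMapBundle(ds$samples[[i]], file.path(dir, sprintf("sample_%04d", i)))
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(ds$manifest)
}

#' Welch power spectral density
#'
#' Hann-windowed, mean-detrended, 50\%-overlapping segment-averaged
#' periodogram.
#'
#' @param x numeric signal.
#' @param rate sampling rate (Hz).
#' @param nseg segment length (defaults to `min(256, length(x))`).
#' @return list with `freq` (Hz) and `power`.
#' @export
welchPSD <- function(x, rate, nseg = min(256L, length(x))) {
  n <- length(x)
  nseg <- min(nseg, n)
  hop <- max(1L, nseg %/% 2L)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nseg) - 1L) / (nseg - 1L))
  starts <- seq(1L, n - nseg + 1L, by = hop)
  acc <- numeric(nseg %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s + seq_len(nseg) - 1L]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nseg %/% 2L + 1L)]
  }
  list(freq = (seq_len(nseg %/% 2L + 1L) - 1L) * rate / nseg,
       power = acc / length(starts))
}

#' Spectral heart-rate oracle
#'
#' Estimates heart rate as 60 times the frequency of the Welch-spectrum
#' maximum inside `band`. For an STMap input the row spectra are averaged
#' first. Independent of the neural network; used to validate generator
#' labels and sanity-check predictions.
#'
#' @param x numeric signal (e.g. a BVP waveform) or an [STMap-class].
#' @param rate sampling rate (Hz); taken from the STMap when omitted.
#' @param band frequency band in Hz searched for the pulse peak.
#' @param refine parabolic (quadratic log-power) interpolation of the peak
#'   position between bins; `FALSE` returns the raw bin frequency.
#' @return estimated heart rate, beats/min.
#' @export
spectralOracleHR <- function(x, rate = NULL, band = c(0.7, 3.0),
                             refine = FALSE) {
  if (is(x, "STMap")) {
    if (is.null(rate)) rate <- x@rate
    v <- x@values
    acc <- NULL
    for (r in seq_len(dim(v)[1L])) {
      ps <- welchPSD(v[r, , 2L], rate)   # green channel rows
      acc <- if (is.null(acc)) ps$power else acc + ps$power
    }
    freq <- welchPSD(v[1L, , 2L], rate)$freq
    power <- acc
  } else {
    if (length(x) < 64L) stop("sequence too short for the spectral oracle")
    ps <- welchPSD(x, rate)
    freq <- ps$freq
    power <- ps$power
  }
  keep <- which(freq >= band[1L] & freq <= band[2L])
  if (!length(keep)) stop("no spectral bins inside the requested band")
  ipk <- keep[which.max(power[keep])]
  fpk <- freq[ipk]
  if (refine && ipk > 1L && ipk < length(freq)) {
    lp <- log(pmax(power[(ipk - 1L):(ipk + 1L)], 1e-300))
    denom <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (denom < 0) {
      shift <- 0.5 * (lp[1L] - lp[3L]) / denom
      fpk <- fpk + shift * (freq[2L] - freq[1L])
    }
  }
  60 * fpk
}
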