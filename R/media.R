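# Algorithmic context measures: perceived brightness, A-weighted sound
# level, and person counting from short clips.

.rec601 <- c(0.299, 0.587, 0.114)

# Collapse an H x W x T or H x W x 3 x T stack to grayscale H x W x T.
.toGray <- function(frames) {
  d <- dim(frames)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("frames must be an H x W x T or H x W x 3 x T array")
  if (length(d) == 4L) {
    if (d[3L] != 3L) stop("RGB frames must have 3 channels")
    g <- .rec601[1L] * frames[, , 1L, , drop = FALSE] +
      .rec601[2L] * frames[, , 2L, , drop = FALSE] +
      .rec601[3L] * frames[, , 3L, , drop = FALSE]
    dim(g) <- d[c(1L, 2L, 4L)]
    g
  } else frames
}

#' Mean luminance of a frame stack
#'
#' Averages pixel intensity over all pixels of all frames and rescales
#' from the 0--255 intensity range to a 0--100 luminance scale. RGB
#' stacks are first reduced to luma with Rec.601 weights
#' (0.299, 0.587, 0.114).
#'
#' @param frames numeric array, H x W x T (grayscale) or H x W x 3 x T
#'   (RGB), intensities in [0, 255].
#' @return luminance in [0, 100].
#' @export
meanLuminance <- function(frames) {
  g <- .toGray(frames)
  if (length(g) == 0L) stop("empty frame stack")
  r <- range(g)
  if (r[1L] < 0 || r[2L] > 255)
    stop("pixel intensities must lie in [0, 255]")
  mean(g) / 2.55
}

#' Cube-root perceived lightness (Glasser's formula)
#'
#' Transforms physical luminance on a 0--100 scale into perceived
#' lightness, L = 25.29 * Y^(1/3) - 18.38, clamped to [0, 100]. The
#' cube-root form reflects the compressive nonlinearity of human
#' brightness perception.
#'
#' @param Y luminance in [0, 100] (vectorized).
#' @param a,b the two constants of the formula; defaults 25.29 and
#'   -18.38.
#' @return perceived lightness in [0, 100].
#' @export
glasserLightness <- function(Y, a = 25.29, b = -18.38) {
  if (any(Y < 0 | Y > 100)) stop("Y must lie in [0, 100]")
  pmin(pmax(a * Y^(1 / 3) + b, 0), 100)
}

#' Ordinal bins for brightness and loudness
#'
#' `brightnessBin()` maps perceived lightness to the 0--4 scale with
#' 20-point half-open increments [0,20), [20,40), [40,60), [60,80),
#' [80,100]; `loudnessBin()` maps a sound level in dB to 0--4 using the
#' ranges (-Inf,40), [40,50), [50,70), [70,85), [85,Inf).
#'
#' @param L perceived lightness in [0, 100] (vectorized).
#' @return integer bin in 0..4.
#' @export
brightnessBin <- function(L) {
  if (any(L < 0 | L > 100)) stop("lightness must lie in [0, 100]")
  pmin(as.integer(floor(L / 20)), 4L)
}

#' @rdname brightnessBin
#' @param db sound level in dB (vectorized); must be finite.
#' @export
loudnessBin <- function(db) {
  if (any(!is.finite(db))) stop("dB values must be finite")
  as.integer(findInterval(db, c(40, 50, 70, 85)))
}

#' A-weighting gain
#'
#' `aWeightingDb()` evaluates the standard analog A-weighting magnitude
#' response (IEC 61672 pole frequencies 20.6, 107.7, 737.9 and 12194 Hz)
#' normalized to 0 dB at 1 kHz. `aWeight()` applies the weighting to a
#' waveform in the FFT domain, which reproduces the analytic curve
#' exactly at each DFT bin.
#'
#' @param freq frequency in Hz (vectorized).
#' @return `aWeightingDb()`: gain in dB (0 at 1 kHz); `aWeight()`: the
#'   weighted waveform.
#' @export
aWeightingDb <- function(freq) {
  20 * log10(.aWeightLinear(freq) / .aWeightLinear(1000))
}

.aWeightLinear <- function(f) {
  f2 <- f^2
  (12194^2 * f2^2) /
    ((f2 + 20.6^2) * sqrt((f2 + 107.7^2) * (f2 + 737.9^2)) *
       (f2 + 12194^2))
}

#' @rdname aWeightingDb
#' @param audio numeric waveform.
#' @param sampleRate sampling rate in Hz (>= 8000).
#' @export
aWeight <- function(audio, sampleRate) {
  if (sampleRate < 8000) stop("sampleRate must be at least 8 kHz")
  if (length(audio) < 0.05 * sampleRate)
    stop("audio shorter than 50 ms; too short for the weighting filter")
  n <- length(audio)
  f <- (seq_len(n) - 1) * sampleRate / n
  f <- pmin(f, sampleRate - f)             # fold to [0, Nyquist]
  w <- .aWeightLinear(f) / .aWeightLinear(1000)
  Re(stats::fft(stats::fft(audio) * w, inverse = TRUE) / n)
}

#' Temporally smoothed A-weighted sound level
#'
#' Computes the clip-level sound level: samples are A-weighted, squared
#' to instantaneous power, smoothed with an exponential moving average
#' (time constant `windowS`, the "fast" sound-level-meter convention),
#' averaged over the clip, and converted to decibels as
#' 10*log10(power) + `calib`. With the default calibration constant 94,
#' a waveform with RMS 1 reads 94 dB. Digital silence (mean power below
#' 1e-12) returns the floor value 0 dB.
#'
#' @param audio numeric waveform, samples in [-1, 1].
#' @param sampleRate sampling rate in Hz.
#' @param windowS smoothing time constant in seconds (default 0.125).
#' @param calib calibration constant in dB (default 94).
#' @param weighting apply A-weighting first (default TRUE).
#' @return sound level in dB.
#' @export
smoothedPowerDb <- function(audio, sampleRate, windowS = 0.125,
                            calib = 94, weighting = TRUE) {
  if (!length(audio)) stop("empty audio")
  x <- if (weighting) aWeight(audio, sampleRate) else audio
  p <- x^2
  alpha <- 1 - exp(-1 / (sampleRate * windowS))
  sm <- stats::filter(alpha * p, 1 - alpha, method = "recursive")
  pw <- mean(sm)
  if (pw < 1e-12) return(0)
  10 * log10(pw) + calib
}

#' Count people in a clip by background subtraction and tracking
#'
#' Deterministic person-counting surrogate with the same contract as a
#' detector-plus-tracker chain: it reports the number of identity
#' clusters (tracks) found across frames. Steps: (1) per-pixel temporal
#' median background; (2) foreground where |frame - background| exceeds
#' `k` times a robust spread (median absolute deviation of the residuals,
#' scaled, floored at `minDiff` intensity units); (3) connected
#' components with at least `minArea` pixels are detections;
#' (4) detections are linked across frames by greedy nearest-centroid
#' matching gated at `maxDisp` pixels; (5) tracks observed in at least
#' `minTrackFrames` frames are counted.
#'
#' @param frames numeric array as in [meanLuminance()]; at least 2 frames.
#' @param k foreground threshold multiplier (default 3).
#' @param minArea minimum component area in pixels (default 15).
#' @param maxDisp matching gate in pixels per frame (default 12).
#' @param minTrackFrames minimum track length (default 3).
#' @param minDiff absolute floor of the foreground threshold in intensity
#'   units (default 10), guarding against zero spread in noise-free
#'   scenes.
#' @param maxGap frames a track may go unseen and still be extended
#'   (default 2).
#' @return integer person count.
#' @export
countPeople <- function(frames, k = 3, minArea = 15L, maxDisp = 12,
                        minTrackFrames = 3L, minDiff = 10, maxGap = 2L) {
  g <- .toGray(frames)
  d <- dim(g)
  if (d[3L] < 2L) stop("need at least 2 frames")
  H <- d[1L]; W <- d[2L]; nT <- d[3L]
  X <- matrix(g, H * W, nT)
  bg <- matrixStats::rowMedians(X)
  dev <- abs(X - bg)
  spread <- 1.4826 * stats::median(dev)
  thr <- max(k * spread, minDiff)

  rowIdx <- rep.int(seq_len(H), W)
  colIdx <- rep(seq_len(W), each = H)

  tracks <- list()   # each: c(y, x, lastSeen, len)
  for (t in seq_len(nT)) {
    mask <- matrix(dev[, t] > thr, H, W)
    dets <- NULL
    if (any(mask)) {
      lab <- EBImage::bwlabel(mask)
      lv <- as.vector(lab)
      sel <- lv > 0L
      if (any(sel)) {
        areas <- tabulate(lv[sel])
        keep <- which(areas >= minArea)
        if (length(keep)) {
          ys <- rowsum(rowIdx[sel], lv[sel])[, 1L]
          xs <- rowsum(colIdx[sel], lv[sel])[, 1L]
          dets <- cbind(y = ys[keep] / areas[keep],
                        x = xs[keep] / areas[keep])
        }
      }
    }
    nd <- if (is.null(dets)) 0L else nrow(dets)
    active <- which(vapply(tracks, function(tr) t - tr[3L] <= maxGap,
                           logical(1L)))
    usedDet <- rep(FALSE, nd)
    if (nd && length(active)) {
      last <- t(vapply(tracks[active], function(tr) tr[1:2], numeric(2L)))
      dm <- outer(last[, 1L], dets[, "y"], "-")^2 +
        outer(last[, 2L], dets[, "x"], "-")^2
      gate2 <- maxDisp^2
      ord <- order(dm)
      usedTr <- rep(FALSE, length(active))
      for (o in ord) {
        if (dm[o] > gate2) break
        i <- (o - 1L) %% length(active) + 1L
        j <- (o - 1L) %/% length(active) + 1L
        if (usedTr[i] || usedDet[j]) next
        usedTr[i] <- TRUE; usedDet[j] <- TRUE
        id <- active[i]
        tracks[[id]] <- c(dets[j, "y"], dets[j, "x"], t,
                          tracks[[id]][4L] + 1)
      }
    }
    if (nd) {
      for (j in which(!usedDet))
        tracks[[length(tracks) + 1L]] <-
          c(dets[j, "y"], dets[j, "x"], t, 1)
    }
  }
  sum(vapply(tracks, function(tr) tr[4L] >= minTrackFrames, logical(1L)))
}

#' @describeIn rateClip extract all algorithmic measures from one clip:
#'   raw luminance, perceived lightness, brightness bin, A-weighted dB
#'   level, loudness bin and person count, as a one-row data.frame.
#' @param calib dB calibration constant (default 94).
#' @param windowS loudness smoothing time constant in seconds.
#' @param k,minArea,maxDisp,minTrackFrames detector/tracker knobs passed
#'   to [countPeople()].
#' @export
setMethod("rateClip", "Clip", function(clip, calib = 94, windowS = 0.125,
                                       k = 3, minArea = 15L, maxDisp = 12,
                                       minTrackFrames = 3L, ...) {
  Y <- meanLuminance(clip@frames)
  L <- glasserLightness(Y)
  db <- smoothedPowerDb(clip@audio, clip@sampleRate, windowS = windowS,
                        calib = calib)
  data.frame(
    situation_id = clip@situationId,
    raw_luminance = Y,
    lightness = L,
    brightness_bin = brightnessBin(L),
    raw_db = db,
    loudness_bin = loudnessBin(db),
    person_count = countPeople(clip@frames, k = k, minArea = minArea,
                               maxDisp = maxDisp,
                               minTrackFrames = minTrackFrames),
    stringsAsFactors = FALSE
  )
})
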