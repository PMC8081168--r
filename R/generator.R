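# Synthetic-study generator: multilevel situation structure, ground-truth
# context per location type, rendered clips, and simulated participant and
# annotator rating channels.

.locationLevels <- c("bars_pubs", "nightclubs", "restaurants", "events",
                     "streets_parks", "travelling", "private")
.coarseLevels <- c("commercial", "public", "private")

#' Coarse location of a fine location type
#'
#' Deterministic mapping of the seven fine location types to the three
#' coarse ones: bars/pubs, nightclubs, restaurants and events are
#' commercial venues; streets/parks and travelling are public spaces;
#' private places map to private.
#'
#' @param fine character vector of fine location labels.
#' @return character vector of coarse labels.
#' @export
coarseLocation <- function(fine) {
  map <- c(bars_pubs = "commercial", nightclubs = "commercial",
           restaurants = "commercial", events = "commercial",
           streets_parks = "public", travelling = "public",
           private = "private")
  out <- map[as.character(fine)]
  if (any(is.na(out)))
    stop("unknown location type: ",
         paste(unique(fine[is.na(out)]), collapse = ", "))
  unname(out)
}

# deterministic sub-seed derivation from one root seed (kept below 2^31)
.subSeed <- function(root, k) {
  as.integer((as.numeric(root) * 48271 + k * 1234567) %% 2147483629 + 1)
}

#' Configuration of the synthetic-study generator
#'
#' Returns a validated configuration list. The defaults encode the study
#' conditions the generator emulates: 210 participants contributing a
#' heavy-tailed number of situations each (truncated negative binomial,
#' so that roughly 20% of participants contribute about half of the
#' situations), seven location types with source-specific luminance,
#' sound-level and attendance distributions, alcohol choice from a
#' random-intercept logistic model with location-specific context
#' effects, per-location clip probabilities, and modest media parameters
#' for rendered clips.
#'
#' @param nParticipants number of participants (default 210).
#' @param situationsPerParticipant list with `mu`, `size` (negative
#'   binomial) and `min` (truncation, default 1).
#' @param locations data.frame with one row per fine location type and
#'   columns location, prob, lumMean, lumSd, dbMean, dbSd, attMu,
#'   attSize, clipProb.
#' @param alcoholModel list with `intercepts` (named by coarse location),
#'   `beta` (3 x 4 matrix of log-odds per unit of true brightness bin,
#'   loudness bin, attendance count and prior drinks, rows named by
#'   coarse location) and `sigmaU` (random-intercept SD).
#' @param ratingNoise list with `participant` and `annotator` components;
#'   each has `bias`, `sd` (on the 0--4 bin scale) and `attendanceSd`
#'   (relative noise on counts).
#' @param media list with fps, duration (s), height, width, sampleRate.
#' @param calib dB calibration constant used throughout (default 94).
#' @param dbRange feasible range for true sound levels (clips must be
#'   renderable without clipping; default c(20, 85)).
#' @param lumRange feasible range for true luminance (default
#'   c(0.5, 95)).
#' @param seed root seed; all stage randomness derives from it.
#' @return a list of class "GeneratorConfig".
#' @export
generatorConfig <- function(
    nParticipants = 210L,
    situationsPerParticipant = list(mu = 11.2, size = 1, min = 1L),
    locations = NULL,
    alcoholModel = NULL,
    ratingNoise = NULL,
    media = list(fps = 4, duration = 10, height = 90, width = 120,
                 sampleRate = 8000),
    calib = 94,
    dbRange = c(20, 85),
    lumRange = c(0.5, 95),
    seed = 1L) {
  if (is.null(locations)) {
    locations <- data.frame(
      location = .locationLevels,
      prob = c(0.1463, 0.0365, 0.0547, 0.0314, 0.1374, 0.0483, 0.5454),
      lumMean = c(10, 6, 30, 26, 8, 28, 26),
      lumSd = c(6, 4, 12, 12, 6, 12, 14),
      dbMean = c(75, 84, 66, 76, 63, 63, 48),
      dbSd = c(6, 4, 7, 7, 8, 8, 10),
      attMu = c(7, 10, 5, 14, 5, 3, 4),
      attSize = c(2, 2, 3, 1.5, 1.5, 1.5, 1.2),
      clipProb = c(0.36, 0.50, 0.32, 0.40, 0.40, 0.56, 0.31),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(alcoholModel)) {
    beta <- rbind(
      commercial = c(-0.40, 0.34, 0.000, 0.13),
      public     = c(-0.40, 0.00, 0.150, 0.11),
      private    = c(-0.10, 0.55, 0.095, 0.02)
    )
    colnames(beta) <- c("brightness", "loudness", "attendance",
                        "prior_drinks")
    alcoholModel <- list(
      intercepts = c(commercial = 2.8, public = 1.75, private = -0.6),
      beta = beta,
      sigmaU = 1.0
    )
  }
  if (is.null(ratingNoise)) {
    ratingNoise <- list(
      participant = list(bias = 0, sd = 0.8, attendanceSd = 0.35),
      annotator = list(bias = -0.3, sd = 0.45, attendanceSd = 0.15)
    )
  }
  cfg <- list(nParticipants = as.integer(nParticipants),
              situationsPerParticipant = situationsPerParticipant,
              locations = locations, alcoholModel = alcoholModel,
              ratingNoise = ratingNoise, media = media, calib = calib,
              dbRange = dbRange, lumRange = lumRange,
              seed = as.integer(seed))
  class(cfg) <- "GeneratorConfig"
  validateGeneratorConfig(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants: location probabilities sum to 1
#' (within 1e-9), all SDs are non-negative, clip probabilities lie in
#' [0, 1], and the clip duration is positive.
#'
#' @param cfg a "GeneratorConfig" list.
#' @return `cfg`, invisibly; stops on violation.
#' @export
validateGeneratorConfig <- function(cfg) {
  loc <- cfg$locations
  if (!setequal(loc$location, .locationLevels))
    stop("locations must cover exactly the 7 location types")
  if (abs(sum(loc$prob) - 1) > 1e-9)
    stop("location probabilities must sum to 1 (within 1e-9)")
  if (any(c(loc$lumSd, loc$dbSd) < 0))
    stop("location SDs must be non-negative")
  if (any(loc$clipProb < 0 | loc$clipProb > 1))
    stop("clip probabilities must lie in [0, 1]")
  if (cfg$media$duration <= 0) stop("clip duration must be positive")
  if (cfg$alcoholModel$sigmaU < 0) stop("sigmaU must be non-negative")
  ns <- vapply(cfg$ratingNoise,
               function(x) min(x$sd, x$attendanceSd), numeric(1))
  if (any(ns < 0)) stop("rating-noise SDs must be non-negative")
  invisible(cfg)
}

#' Simulate participants' in-situ ratings from the ground truth
#'
#' Participant ratings are the algorithmic bins of the true context plus
#' a bias and Gaussian noise, rounded and clamped to the 0--4 scale;
#' reported attendance is the true head count under multiplicative
#' noise. With zero noise and zero bias the ratings reproduce the
#' algorithmic bins exactly.
#'
#' @param luminance,db,nPeople vectors of true luminance (0--100), sound
#'   level (dB) and head count.
#' @param bias additive rating bias on the bin scale.
#' @param sd rating noise SD on the bin scale.
#' @param attendanceSd relative noise SD on counts.
#' @param seed optional seed set before drawing.
#' @return data.frame with integer columns brightness, loudness (0--4)
#'   and attendance (>= 0).
#' @export
simulateParticipantRatings <- function(luminance, db, nPeople, bias = 0,
                                       sd = 0, attendanceSd = 0,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(luminance)
  stopifnot(length(db) == n, length(nPeople) == n)
  bBin <- brightnessBin(glasserLightness(luminance))
  lBin <- loudnessBin(db)
  clamp04 <- function(x) pmin(pmax(as.integer(round(x)), 0L), 4L)
  data.frame(
    brightness = clamp04(bBin + bias + stats::rnorm(n, 0, sd)),
    loudness = clamp04(lBin + bias + stats::rnorm(n, 0, sd)),
    attendance = pmax(0L, as.integer(round(
      nPeople * (1 + stats::rnorm(n, 0, attendanceSd)))))
  )
}

#' Simulate a five-annotator rating panel for one clip
#'
#' Each annotator rates brightness, music loudness and chatter loudness
#' on the 0--4 scale and places the visible head count into one of the
#' five attendance categories. Music and chatter are generated so that
#' the per-rater maximum tracks the true loudness bin: one of the two
#' channels carries the bin, the other sits 0--2 points below. With all
#' rater noise and bias at zero the fused panel reproduces the
#' algorithmic bins and the true attendance category exactly.
#'
#' @param luminance,db,nPeople scalars of clip ground truth.
#' @param raterBias,raterSd numeric length-5 bias and noise SD per rater
#'   (scalars are recycled).
#' @param attendanceSd relative noise SD on the perceived count.
#' @param seed optional seed.
#' @param situationId id copied into the output.
#' @return 5-row data.frame: situation_id, rater_id, brightness, music,
#'   chatter, attendance_cat.
#' @export
simulateAnnotatorPanel <- function(luminance, db, nPeople,
                                   raterBias = 0, raterSd = 0,
                                   attendanceSd = 0, seed = NULL,
                                   situationId = "s1") {
  if (!is.null(seed)) set.seed(seed)
  raterBias <- rep_len(raterBias, 5L)
  raterSd <- rep_len(raterSd, 5L)
  bBin <- brightnessBin(glasserLightness(luminance))
  lBin <- loudnessBin(db)
  clamp04 <- function(x) pmin(pmax(as.integer(round(x)), 0L), 4L)
  musicDominates <- stats::runif(1) < 0.5
  gap <- sample(0:2, 1L)
  dom <- lBin
  oth <- max(0L, lBin - gap)
  musicBase <- if (musicDominates) dom else oth
  chatterBase <- if (musicDominates) oth else dom
  noise <- function(base) clamp04(base + raterBias +
                                    stats::rnorm(5L, 0, raterSd))
  perceived <- pmax(0, round(nPeople *
                               (1 + stats::rnorm(5L, 0, attendanceSd))))
  data.frame(
    situation_id = situationId,
    rater_id = seq_len(5L),
    brightness = noise(bBin),
    music = noise(musicBase),
    chatter = noise(chatterBase),
    attendance_cat = attendanceCategory(perceived),
    stringsAsFactors = FALSE
  )
}

# pixel-offset template of an ellipse blob; returns dy/dx offsets
.blobTemplate <- function(rx, ry) {
  dx <- rep(-rx:rx, times = 2L * ry + 1L)
  dy <- rep(-ry:ry, each = 2L * rx + 1L)
  keep <- (dx / rx)^2 + (dy / ry)^2 <= 1
  cbind(dy = dy[keep], dx = dx[keep])
}

#' Render a synthetic clip with known context
#'
#' Produces a [Clip-class] whose algorithmic measurements match the
#' generating targets: frames are a constant background at the pixel
#' value whose mean luminance equals `luminanceTarget` (compensated for
#' the blob pixels), with `nPeople` moving elliptical blobs at a fixed
#' contrast margin; the audio is band-limited pink noise (>= 200 Hz,
#' 14 dB below the carrier) plus a 1 kHz tone, scaled so the A-weighted
#' smoothed level equals `levelDb` exactly. When each blob can be given
#' its own cell of a lane grid the trajectories never overlap (and the
#' tracker recovers the exact count); in very crowded scenes
#' trajectories are random and may transiently overlap.
#'
#' @param luminanceTarget target mean luminance in [0, 100].
#' @param levelDb target A-weighted level in dB (under `calib`).
#' @param nPeople number of rendered blobs (>= 0).
#' @param media list with fps, duration, height, width, sampleRate.
#' @param seed seed for trajectories and noise.
#' @param calib dB calibration constant (default 94).
#' @param contrastMargin blob-background contrast in intensity units
#'   (default 60).
#' @param situationId id stored in the clip.
#' @return a [Clip-class]. Errors if `levelDb` cannot be reached without
#'   clipping the audio to [-1, 1].
#' @export
renderClip <- function(luminanceTarget, levelDb, nPeople,
                       media = list(fps = 4, duration = 10, height = 90,
                                    width = 120, sampleRate = 8000),
                       seed = 1L, calib = 94, contrastMargin = 60,
                       situationId = "s1") {
  if (luminanceTarget < 0 || luminanceTarget > 100)
    stop("luminanceTarget must lie in [0, 100]")
  if (nPeople < 0) stop("nPeople must be non-negative")
  set.seed(seed)
  H <- media$height; W <- media$width
  nT <- round(media$fps * media$duration)
  nS <- round(media$sampleRate * media$duration)

  rx <- max(4L, round(W / 40)); ry <- max(3L, round(H / 40))
  tmpl <- .blobTemplate(rx, ry)
  blobArea <- nrow(tmpl)

  bg0 <- 2.55 * luminanceTarget
  blobVal <- if (bg0 <= 255 - contrastMargin) bg0 + contrastMargin
             else bg0 - contrastMargin
  nPix <- H * W
  bg <- if (nPeople > 0)
    (2.55 * luminanceTarget * nPix - nPeople * blobArea * blobVal) /
      (nPix - nPeople * blobArea)
  else bg0
  bg <- min(max(bg, 0), 255)

  # trajectories: disjoint cells of a lane grid when they fit, else
  # random; each blob ping-pongs horizontally inside its own cell so
  # components never merge and tracks never cross
  laneH <- 2L * ry + 2L
  nLanes <- (H - 2L) %/% laneH
  # a cell must leave enough travel range to keep pixel dwell low
  maxCols <- max(1L, (W - 2L) %/% (4L * (2L * rx + 1L)))
  nCols <- if (nPeople > 0) ceiling(nPeople / nLanes) else 1L
  lanes <- nPeople > 0 && nCols <= maxCols
  xlim <- c(rx + 1, W - rx); ylim <- c(ry + 1, H - ry)
  xlo <- rep(xlim[1L], nPeople); xhi <- rep(xlim[2L], nPeople)
  if (nPeople > 0) {
    # keep every pixel's blob dwell under half the clip so the temporal
    # median stays uncontaminated even around trajectory reversals
    spMin <- max(2.5, 5 * (2 * rx + 1) / nT)
    spMax <- spMin + 2
    if (lanes) {
      cell <- sample(nLanes * nCols, nPeople)
      laneIdx <- (cell - 1L) %/% nCols + 1L
      colIdx <- (cell - 1L) %% nCols + 1L
      py <- 1 + (laneIdx - 0.5) * laneH
      cw <- (W - 2) / nCols
      xlo <- 1 + (colIdx - 1) * cw + rx + 1
      xhi <- 1 + colIdx * cw - rx - 1
      px <- stats::runif(nPeople, xlo, xhi)
      vx <- sample(c(-1, 1), nPeople, TRUE) *
        stats::runif(nPeople, spMin, spMax)
      vy <- rep(0, nPeople)
    } else {
      px <- stats::runif(nPeople, xlim[1L], xlim[2L])
      py <- stats::runif(nPeople, ylim[1L], ylim[2L])
      sp <- stats::runif(nPeople, spMin, spMax)
      an <- stats::runif(nPeople, 0, 2 * pi)
      vx <- sp * cos(an); vy <- sp * sin(an)
    }
  }

  frames <- array(bg, dim = c(H, W, nT))
  if (nPeople > 0) {
    for (t in seq_len(nT)) {
      fr <- matrix(bg, H, W)
      for (b in seq_len(nPeople)) {
        cy <- round(py[b]); cx <- round(px[b])
        idx <- cbind(tmpl[, "dy"] + cy, tmpl[, "dx"] + cx)
        fr[idx] <- blobVal
        # advance with reflection keeping the full blob in frame
        px[b] <- px[b] + vx[b]; py[b] <- py[b] + vy[b]
        if (px[b] < xlo[b]) { px[b] <- 2 * xlo[b] - px[b]; vx[b] <- -vx[b] }
        if (px[b] > xhi[b]) { px[b] <- 2 * xhi[b] - px[b]; vx[b] <- -vx[b] }
        if (py[b] < ylim[1L]) { py[b] <- 2 * ylim[1L] - py[b]; vy[b] <- -vy[b] }
        if (py[b] > ylim[2L]) { py[b] <- 2 * ylim[2L] - py[b]; vy[b] <- -vy[b] }
      }
      frames[, , t] <- fr
    }
  }
  frames <- round(frames)   # 8-bit storage so file round-trips are exact

  # audio: 1 kHz carrier + band-limited pink noise 14 dB down, scaled to the target
  tt <- seq_len(nS) / media$sampleRate
  sine <- sin(2 * pi * 1000 * tt)
  white <- stats::rnorm(nS)
  f <- (seq_len(nS) - 1) * media$sampleRate / nS
  f <- pmin(f, media$sampleRate - f)
  shape <- ifelse(f >= 200, 1 / sqrt(f), 0)   # band-limited pink
  pink <- Re(stats::fft(stats::fft(white) * shape, inverse = TRUE) / nS)
  pA <- mean(aWeight(pink, media$sampleRate)^2)
  sA <- mean(aWeight(sine, media$sampleRate)^2)
  pink <- pink * sqrt(10^(-1.4) * sA / pA)    # 14 dB below the carrier
  mix <- sine + pink
  L0 <- smoothedPowerDb(mix, media$sampleRate, calib = calib)
  gain <- 10^((levelDb - L0) / 20)
  audio <- gain * mix
  if (max(abs(audio)) > 1)
    stop(sprintf(
      "sound level target %.1f dB unreachable without clipping (max |sample| = %.2f)",
      levelDb, max(abs(audio))))
  new("Clip", frames = frames, fps = media$fps, audio = audio,
      sampleRate = media$sampleRate, situationId = situationId)
}

#' Generate a complete synthetic study
#'
#' Draws participants and their situations (heavy-tailed counts),
#' samples a location and ground-truth context per situation, draws the
#' alcohol outcome from the random-intercept logistic model, simulates
#' the participant rating channel, renders clips for situations that
#' have one, and simulates the five-annotator panels on those clips.
#' Identical seed and configuration give identical output.
#'
#' @param cfg a [generatorConfig()] list.
#' @param renderClips render media for has_clip situations (default
#'   TRUE); when FALSE only the tables are produced and the annotator
#'   panels are simulated from the ground truth directly.
#' @return a [DrinkingStudy-class].
#' @export
generateStudy <- function(cfg = generatorConfig(), renderClips = TRUE) {
  validateGeneratorConfig(cfg)
  root <- cfg$seed
  loc <- cfg$locations

  set.seed(.subSeed(root, 1L))
  spp <- cfg$situationsPerParticipant
  counts <- integer(cfg$nParticipants)
  for (j in seq_len(cfg$nParticipants)) {
    repeat {
      cnt <- stats::rnbinom(1L, mu = spp$mu, size = spp$size)
      if (cnt >= spp$min) { counts[j] <- cnt; break }
    }
  }
  n <- sum(counts)
  pid <- rep(seq_len(cfg$nParticipants), counts)

  set.seed(.subSeed(root, 2L))
  li <- sample(nrow(loc), n, replace = TRUE, prob = loc$prob)
  lum <- pmin(pmax(stats::rnorm(n, loc$lumMean[li], loc$lumSd[li]),
                   cfg$lumRange[1L]), cfg$lumRange[2L])
  db <- pmin(pmax(stats::rnorm(n, loc$dbMean[li], loc$dbSd[li]),
                  cfg$dbRange[1L]), cfg$dbRange[2L])
  nPeople <- stats::rnbinom(n, mu = loc$attMu[li], size = loc$attSize[li])
  prior <- round(stats::rgamma(n, shape = 1.2, scale = 1.8), 1)

  fine <- loc$location[li]
  coarse <- coarseLocation(fine)
  am <- cfg$alcoholModel
  u <- stats::rnorm(cfg$nParticipants, 0, am$sigmaU)
  bBin <- brightnessBin(glasserLightness(lum))
  lBin <- loudnessBin(db)
  Xc <- cbind(bBin, lBin, nPeople, prior)
  eta <- am$intercepts[coarse] +
    rowSums(Xc * am$beta[coarse, , drop = FALSE]) + u[pid]
  alcohol <- stats::rbinom(n, 1L, stats::plogis(eta))
  hasClip <- stats::rbinom(n, 1L, loc$clipProb[li])

  pr <- simulateParticipantRatings(
    lum, db, nPeople,
    bias = cfg$ratingNoise$participant$bias,
    sd = cfg$ratingNoise$participant$sd,
    attendanceSd = cfg$ratingNoise$participant$attendanceSd,
    seed = .subSeed(root, 3L))

  situ <- data.frame(
    situation_id = sprintf("s%05d", seq_len(n)),
    participant_id = sprintf("p%03d", pid),
    location_fine = fine,
    location_coarse = coarse,
    alcohol = alcohol,
    prior_drinks = prior,
    p_brightness = pr$brightness,
    p_loudness = pr$loudness,
    p_attendance = pr$attendance,
    has_clip = hasClip,
    true_luminance = lum,
    true_db = db,
    true_n_people = nPeople,
    stringsAsFactors = FALSE
  )

  clipIdx <- which(hasClip == 1L)
  clipList <- list()
  if (renderClips && length(clipIdx)) {
    clipList <- lapply(clipIdx, function(i) {
      renderClip(lum[i], db[i], nPeople[i], media = cfg$media,
                 seed = .subSeed(root, 1000L + i), calib = cfg$calib,
                 situationId = situ$situation_id[i])
    })
    names(clipList) <- situ$situation_id[clipIdx]
  }

  ann <- list()
  anN <- cfg$ratingNoise$annotator
  for (i in clipIdx) {
    ann[[length(ann) + 1L]] <- simulateAnnotatorPanel(
      lum[i], db[i], nPeople[i],
      raterBias = anN$bias, raterSd = anN$sd,
      attendanceSd = anN$attendanceSd,
      seed = .subSeed(root, 2000000L + i),
      situationId = situ$situation_id[i])
  }
  annotationsDf <- if (length(ann)) do.call(rbind, ann) else
    data.frame(situation_id = character(), rater_id = integer(),
               brightness = integer(), music = integer(),
               chatter = integer(), attendance_cat = character(),
               stringsAsFactors = FALSE)

  new("DrinkingStudy", situations = situ, annotations = annotationsDf,
      clips = clipList, config = unclass(cfg))
}

#' Write a study to disk as plain files
#'
#' Writes situations.csv and annotations.csv, one folder per clip with a
#' PNG frame sequence and a PCM 16-bit mono audio.wav, and a JSON
#' manifest echoing the configuration and the root seed. Integer table
#' values and 8-bit frames round-trip exactly; audio round-trips to
#' 16-bit quantization precision.
#'
#' @param study a [DrinkingStudy-class].
#' @param outDir output directory (must exist or be creatable).
#' @return `outDir`, invisibly.
#' @export
writeDataset <- function(study, outDir) {
  parent <- dirname(outDir)
  if (!dir.exists(parent))
    stop("parent directory does not exist: ", parent)
  dir.create(outDir, showWarnings = FALSE)
  utils::write.csv(situations(study),
                   file.path(outDir, "situations.csv"), row.names = FALSE)
  utils::write.csv(annotations(study),
                   file.path(outDir, "annotations.csv"), row.names = FALSE)
  cl <- clips(study)
  if (length(cl)) {
    clipRoot <- file.path(outDir, "clips")
    dir.create(clipRoot, showWarnings = FALSE)
    for (nm in names(cl)) {
      cdir <- file.path(clipRoot, nm)
      dir.create(cdir, showWarnings = FALSE)
      fr <- cl[[nm]]@frames
      for (t in seq_len(dim(fr)[3L]))
        png::writePNG(fr[, , t] / 255,
                      file.path(cdir, sprintf("frame_%04d.png", t)))
      writeWav(cl[[nm]]@audio, cl[[nm]]@sampleRate,
               file.path(cdir, "audio.wav"))
      writeLines(jsonlite::toJSON(list(fps = cl[[nm]]@fps), auto_unbox = TRUE),
                 file.path(cdir, "meta.json"))
    }
  }
  cfg <- studyConfig(study)
  manifest <- list(config = cfg,
                   seed = cfg$seed,
                   n_situations = nrow(situations(study)),
                   n_clips = length(cl))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outDir, "manifest.json"))
  invisible(outDir)
}

#' Read a study written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @return a [DrinkingStudy-class].
#' @export
readDataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir)
  situ <- utils::read.csv(file.path(dir, "situations.csv"),
                          stringsAsFactors = FALSE)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"),
                         stringsAsFactors = FALSE,
                         colClasses = c(attendance_cat = "character"))
  clipRoot <- file.path(dir, "clips")
  clipList <- list()
  if (dir.exists(clipRoot)) {
    for (nm in list.dirs(clipRoot, recursive = FALSE, full.names = FALSE)) {
      cdir <- file.path(clipRoot, nm)
      pngs <- sort(list.files(cdir, pattern = "^frame_.*\\.png$",
                              full.names = TRUE))
      fr <- vapply(pngs, function(p) png::readPNG(p) * 255,
                   matrix(0, nrow = dim(png::readPNG(pngs[1L]))[1L],
                          ncol = dim(png::readPNG(pngs[1L]))[2L]))
      dimnames(fr) <- NULL
      wav <- readWav(file.path(cdir, "audio.wav"))
      meta <- jsonlite::fromJSON(file.path(cdir, "meta.json"))
      clipList[[nm]] <- new("Clip", frames = fr, fps = meta$fps,
                            audio = wav$samples,
                            sampleRate = wav$sampleRate,
                            situationId = nm)
    }
  }
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  new("DrinkingStudy", situations = situ, annotations = ann,
      clips = clipList, config = as.list(manifest$config))
}
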