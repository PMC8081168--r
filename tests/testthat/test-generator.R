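test_that("coarseLocation maps the seven fine types deterministically", {
  expect_identical(coarseLocation(c("bars_pubs", "nightclubs",
                                    "restaurants", "events")),
                   rep("commercial", 4))
  expect_identical(coarseLocation(c("streets_parks", "travelling")),
                   rep("public", 2))
  expect_identical(coarseLocation("private"), "private")
  expect_error(coarseLocation("moon"), "unknown location")
})

test_that("generatorConfig validates its structural invariants", {
  cfg <- generatorConfig()
  expect_s3_class(cfg, "GeneratorConfig")
  bad <- cfg
  bad$locations$prob[1] <- bad$locations$prob[1] + 0.5
  expect_error(validateGeneratorConfig(bad), "sum to 1")
  bad <- cfg
  bad$locations$lumSd[2] <- -1
  expect_error(validateGeneratorConfig(bad), "non-negative")
  bad <- cfg
  bad$locations$clipProb[3] <- 1.5
  expect_error(validateGeneratorConfig(bad), "\\[0, 1\\]")
  bad <- cfg
  bad$media$duration <- 0
  expect_error(validateGeneratorConfig(bad), "duration")
})

test_that("zero-noise participant ratings equal the algorithmic bins", {
  lum <- c(5, 20, 50, 80, 95)
  db <- c(30, 45, 60, 75, 88)
  np <- c(0, 2, 5, 9, 20)
  r <- simulateParticipantRatings(lum, db, np)
  expect_identical(r$brightness, brightnessBin(glasserLightness(lum)))
  expect_identical(r$loudness, loudnessBin(db))
  expect_identical(r$attendance, as.integer(np))
})

test_that("participant rating noise stays on the 0-4 scale", {
  set.seed(1)
  r <- simulateParticipantRatings(runif(500, 0, 100), runif(500, 20, 88),
                                  rpois(500, 5), bias = 0.3, sd = 2,
                                  attendanceSd = 0.5, seed = 4)
  expect_true(all(r$brightness %in% 0:4))
  expect_true(all(r$loudness %in% 0:4))
  expect_true(all(r$attendance >= 0))
})

test_that("zero-noise annotator panels agree with the truth bins", {
  p <- simulateAnnotatorPanel(50, 60, 3, seed = 2, situationId = "sZ")
  expect_identical(nrow(p), 5L)
  expect_identical(unique(p$situation_id), "sZ")
  expect_true(all(p$brightness ==
                    brightnessBin(glasserLightness(50))))
  # overall loudness (max of music/chatter) reproduces the truth bin
  expect_identical(overallLoudness(p$music, p$chatter), loudnessBin(60))
  expect_identical(unique(p$attendance_cat), attendanceCategory(3))
})

test_that("renderClip meets its measurement contract", {
  cl <- renderClip(50, 60, 0, media = smallMedia(), seed = 3)
  r <- rateClip(cl)
  expect_gte(r$raw_luminance, 49); expect_lte(r$raw_luminance, 51)
  expect_gte(r$raw_db, 59.5); expect_lte(r$raw_db, 60.5)
  expect_identical(r$person_count, 0L)
})

test_that("renderClip keeps blobs detectable on a black background", {
  cl <- renderClip(0, 40, 3, media = smallMedia(), seed = 4)
  expect_identical(countPeople(cl@frames), 3L)
})

test_that("15 people are recovered exactly on the default frame", {
  cl <- renderClip(30, 60, 15, media = defaultMedia(), seed = 6)
  expect_identical(countPeople(cl@frames), 15L)
})

test_that("renderClip errors on unreachable dB targets", {
  expect_error(renderClip(50, 95, 0, media = smallMedia(), seed = 1),
               "clipping")
})

test_that("generateStudy is reproducible and structurally sound", {
  cfg <- smallConfig(nParticipants = 15, seed = 21)
  s1 <- generateStudy(cfg)
  s2 <- generateStudy(cfg)
  expect_identical(situations(s1), situations(s2))
  expect_identical(annotations(s1), annotations(s2))
  expect_identical(lapply(clips(s1), slot, "frames"),
                   lapply(clips(s2), slot, "frames"))
  situ <- situations(s1)
  expect_true(all(situ$location_fine %in%
                    c("bars_pubs", "nightclubs", "restaurants", "events",
                      "streets_parks", "travelling", "private")))
  expect_identical(coarseLocation(situ$location_fine),
                   situ$location_coarse)
  expect_true(all(situ$alcohol %in% 0:1))
  expect_true(all(situ$prior_drinks >= 0))
  expect_true(all(situ$p_brightness %in% 0:4))
  expect_true(all(situ$p_loudness %in% 0:4))
  expect_true(all(situ$p_attendance >= 0))
  expect_identical(sort(names(clips(s1))),
                   sort(situ$situation_id[situ$has_clip == 1L]))
  # every annotated clip has exactly 5 raters
  expect_true(all(table(annotations(s1)$situation_id) == 5L))
  expect_identical(nrow(validateStudy(s1)), 0L)
})

test_that("different seeds give different studies", {
  a <- situations(generateStudy(smallConfig(nParticipants = 10, seed = 1),
                                renderClips = FALSE))
  b <- situations(generateStudy(smallConfig(nParticipants = 10, seed = 2),
                                renderClips = FALSE))
  expect_false(identical(a, b))
})

test_that("the situation load per participant is heavy-tailed", {
  cfg <- generatorConfig(seed = 9)
  situ <- situations(generateStudy(cfg, renderClips = FALSE))
  counts <- sort(table(situ$participant_id), decreasing = TRUE)
  top20 <- sum(counts[seq_len(ceiling(0.2 * length(counts)))])
  share <- top20 / sum(counts)
  expect_gt(share, 0.40)
  expect_lt(share, 0.65)
})

test_that("writeDataset/readDataset round-trips the study", {
  cfg <- generatorConfig(nParticipants = 4, media = smallMedia(),
                        seed = 31)
  study <- generateStudy(cfg)
  dir <- file.path(tempdir(), "ds_roundtrip")
  unlink(dir, recursive = TRUE)
  writeDataset(study, dir)
  back <- readDataset(dir)
  s0 <- situations(study); s1 <- situations(back)
  expect_identical(s0$situation_id, s1$situation_id)
  for (col in c("alcohol", "has_clip", "p_brightness", "p_loudness",
                "p_attendance"))
    expect_identical(as.integer(s0[[col]]), as.integer(s1[[col]]))
  expect_equal(s0$prior_drinks, s1$prior_drinks, tolerance = 1e-12)
  a0 <- annotations(study); a1 <- annotations(back)
  expect_identical(a0$brightness, as.integer(a1$brightness))
  expect_identical(gsub("–", "-", a0$attendance_cat), a1$attendance_cat)
  # frames round-trip exactly (8-bit), audio to 16-bit quantization
  for (nm in names(clips(study))) {
    expect_equal(clips(back)[[nm]]@frames, clips(study)[[nm]]@frames,
                 tolerance = 1e-9)
    expect_lt(max(abs(clips(back)[[nm]]@audio - clips(study)[[nm]]@audio)),
              1e-4)
  }
  unlink(dir, recursive = TRUE)
})

test_that("WAV files round-trip at 16 and 24 bits and downmix stereo", {
  x <- referenceSine(duration = 0.2) * 0.9
  f <- tempfile(fileext = ".wav")
  writeWav(x, 8000, f, bits = 16L)
  r <- readWav(f)
  expect_identical(r$sampleRate, 8000L)
  expect_lt(max(abs(r$samples - x)), 2^-15 + 1e-9)
  writeWav(x, 8000, f, bits = 24L)
  expect_lt(max(abs(readWav(f)$samples - x)), 2^-23 + 1e-9)
  unlink(f)
})
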