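test_that("meanLuminance averages pixels and rescales to 0-100", {
  fr <- array(127.5, dim = c(4, 5, 3))
  expect_equal(meanLuminance(fr), 50)
  fr[] <- 0
  expect_equal(meanLuminance(fr), 0)
  fr[] <- 255
  expect_equal(meanLuminance(fr), 100)
  # RGB input is converted by the luma weights before averaging
  rgb <- array(0, dim = c(2, 2, 3, 2))
  rgb[, , 1, ] <- 255   # pure red
  expect_equal(meanLuminance(rgb), 100 * 0.299, tolerance = 1e-12)
})

test_that("glasserLightness matches the cube-root law and clamps", {
  expect_equal(glasserLightness(100), 25.29 * 100^(1 / 3) - 18.38)
  expect_equal(glasserLightness(0), 0)      # raw value -18.38, clamped
  expect_true(all(diff(glasserLightness(seq(0.5, 100, by = 0.5))) > 0))
  expect_true(all(glasserLightness(c(0, 1e-9, 100)) >= 0))
  expect_true(all(glasserLightness(c(0, 100)) <= 100))
  expect_error(glasserLightness(101), "0, 100")
})

test_that("brightness bins are 20-point bins of lightness with top cap", {
  expect_equal(brightnessBin(c(0, 19.99, 20, 39.9, 40, 60, 80, 99, 100)),
               c(0, 0, 1, 1, 2, 3, 4, 4, 4))
})

test_that("loudness bins use the 40/50/70/85 dB boundaries", {
  expect_equal(loudnessBin(c(0, 39.9, 40, 49.9, 50, 69.9, 70, 84.9, 85, 120)),
               c(0, 0, 1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("A-weighting is 0 dB at 1 kHz and matches tabulated values", {
  expect_equal(aWeightingDb(1000), 0, tolerance = 1e-9)
  expect_equal(aWeightingDb(100), -19.1, tolerance = 0.05)
  expect_equal(aWeightingDb(2000), 1.2, tolerance = 0.05)
  # low frequencies are strongly attenuated
  expect_lt(aWeightingDb(20), -50)
})

test_that("aWeight leaves a 1 kHz tone essentially unchanged", {
  sr <- 8000
  x <- sin(2 * pi * 1000 * seq_len(sr) / sr)
  w <- aWeight(x, sr)
  expect_equal(mean(w^2), mean(x^2), tolerance = 1e-6)
})

test_that("smoothedPowerDb calibrates a full-scale sine near C - 3.01", {
  sr <- 8000
  x <- referenceSine(duration = 2, sampleRate = sr)
  expect_equal(smoothedPowerDb(x, sr, calib = 94), 94 - 3.0103,
               tolerance = 0.2)
  # calibration constant shifts the scale one-for-one
  expect_equal(smoothedPowerDb(x, sr, calib = 100) -
                 smoothedPowerDb(x, sr, calib = 94), 6)
})

test_that("silence reports the 0 dB floor", {
  expect_equal(smoothedPowerDb(numeric(8000), 8000), 0)
})

test_that("halving amplitude lowers the level by about 6 dB", {
  sr <- 8000
  x <- referenceSine(duration = 2, sampleRate = sr)
  expect_equal(smoothedPowerDb(x, sr) - smoothedPowerDb(x / 2, sr),
               20 * log10(2), tolerance = 0.05)
})

test_that("countPeople is exact on static and rendered scenes", {
  # a completely static scene has no moving components
  fr <- array(40, dim = c(60, 80, 20))
  expect_identical(countPeople(fr), 0L)
  for (np in c(1L, 4L, 9L)) {
    cl <- renderClip(30, 60, np, media = smallMedia(), seed = 100 + np)
    expect_identical(countPeople(cl@frames), np)
  }
})

test_that("blobs stay detectable at the luminance extremes", {
  for (lum in c(0, 95)) {
    cl <- renderClip(lum, 60, 3, media = smallMedia(), seed = 5)
    expect_identical(countPeople(cl@frames), 3L)
  }
})

test_that("rateClip fills every field and is deterministic", {
  cl <- renderClip(50, 60, 2, media = smallMedia(), seed = 9,
                   situationId = "sX")
  r1 <- rateClip(cl)
  r2 <- rateClip(cl)
  expect_identical(r1, r2)
  expect_identical(r1$situation_id, "sX")
  expect_equal(r1$raw_luminance, 50, tolerance = 0.5)
  expect_equal(r1$lightness, glasserLightness(r1$raw_luminance))
  expect_identical(r1$brightness_bin, 3L)   # L(50) = 74.8 -> bin 3
  expect_identical(r1$loudness_bin, 2L)
  expect_identical(r1$person_count, 2L)
})

test_that("a dark silent clip rates as all zeros", {
  cl <- new("Clip",
            frames = array(0, dim = c(30, 40, 8)), fps = 2,
            audio = numeric(8000), sampleRate = 8000,
            situationId = "dark")
  r <- rateClip(cl)
  expect_identical(r$brightness_bin, 0L)
  expect_identical(r$loudness_bin, 0L)
  expect_identical(r$person_count, 0L)
})
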