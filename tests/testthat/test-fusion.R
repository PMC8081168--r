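test_that("attendanceCategory maps counts to the five bands", {
  expect_identical(attendanceCategory(c(0, 1, 2, 4, 5, 10, 11, 40)),
                   c("0", "1", "2-4", "2-4", "5-10", "5-10", ">10", ">10"))
  expect_error(attendanceCategory(-1), "non-negative")
})

test_that("fuseOrdinal takes the mode at >= 3 votes, else rounded mean", {
  expect_identical(fuseOrdinal(c(2, 2, 2, 0, 4)), 2L)   # majority
  expect_identical(fuseOrdinal(c(3, 3, 3, 3, 3)), 3L)   # unanimity
  expect_identical(fuseOrdinal(c(0, 1, 2, 3, 4)), 2L)   # mean 2
  expect_identical(fuseOrdinal(c(0, 0, 1, 1, 4)), 1L)   # mean 1.2 -> 1
  expect_identical(fuseOrdinal(c(0, 0, 1, 1, 2)), 1L)   # mean 0.8 -> 1
  expect_error(fuseOrdinal(c(1, 2, 3)), "5 ratings")
  expect_error(fuseOrdinal(c(0, 1, 2, 3, 5)), "0..4")
})

test_that("overallLoudness is the fused per-rater max of music/chatter", {
  expect_identical(overallLoudness(c(4, 0, 0, 0, 0), c(0, 4, 4, 4, 0)),
                   4L)   # maxima 4,4,4,4,0 -> majority 4
  expect_identical(overallLoudness(rep(1L, 5), rep(2L, 5)), 2L)
})

test_that("fuseAttendance averages the recoded category values", {
  # recode 0,1,2-4,5-10,>10 -> 0,1,3,7.5,15
  expect_equal(fuseAttendance(c("0", "1", "2-4", "5-10", ">10")),
               mean(c(0, 1, 3, 7.5, 15)))
  expect_equal(fuseAttendance(rep(">10", 5)), 15)
  # en-dash spelling is normalized
  expect_equal(fuseAttendance(rep("2–4", 5)), 3)
  expect_error(fuseAttendance(rep("lots", 5)), "unknown")
})

test_that("participantAttendanceTotal sums recoded company counts", {
  expect_identical(participantAttendanceTotal(1, 2, 0, 3, 0), 6L)
  expect_identical(participantAttendanceTotal(0, ">10", 10, 0, ">10"), 40L)
  expect_error(participantAttendanceTotal(2, 0, 0, 0, 0), "partner")
  expect_error(participantAttendanceTotal(0, 11, 0, 0, 0), "0..10")
})

test_that("icc2k matches the two-way mean-square formula on a toy set", {
  # Shrout & Fleiss two-way layout, computed against direct anova sums
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  n <- nrow(m); k <- ncol(m)
  rowM <- rowMeans(m); colM <- colMeans(m); g <- mean(m)
  msr <- k * sum((rowM - g)^2) / (n - 1)
  msc <- n * sum((colM - g)^2) / (k - 1)
  mse <- (sum((m - outer(rowM, rep(1, k)) - outer(rep(1, n), colM) + g)^2)) /
    ((n - 1) * (k - 1))
  expect_equal(icc2k(m), (msr - mse) / (msr + (msc - mse) / n))
  expect_equal(icc2k(m, "ICC21"),
               (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
  # average-of-k agreement is never below single-rater agreement here
  expect_gte(icc2k(m), icc2k(m, "ICC21"))
})

test_that("icc2k recovers high agreement for low-noise raters", {
  set.seed(42)
  truth <- rnorm(200, 0, 2)
  m <- sapply(1:5, function(r) truth + rnorm(200, 0, 1))
  k <- 5; varE <- 1; varT <- 4
  expected <- varT / (varT + varE / k)   # ~0.952 population value
  expect_equal(icc2k(m), expected, tolerance = 0.03)
})

test_that("agreementLabel applies the Cicchetti bands", {
  expect_identical(as.character(agreementLabel(c(0.1, 0.45, 0.70, 0.9))),
                   c("poor", "fair", "good", "excellent"))
  expect_identical(as.character(agreementLabel(c(0.40, 0.60, 0.75))),
                   c("fair", "good", "excellent"))
})

test_that("fuseAnnotations fuses per situation and keeps one row each", {
  ann <- do.call(rbind, lapply(c("sA", "sB"), function(id)
    data.frame(situation_id = id, rater_id = paste0("r", 1:5),
               brightness = c(2, 2, 2, 1, 4),
               music = c(0, 0, 1, 1, 0),
               chatter = c(3, 3, 3, 0, 0),
               attendance_cat = c("0", "1", "1", "2-4", ">10"),
               stringsAsFactors = FALSE)))
  f <- fuseAnnotations(ann)
  expect_identical(nrow(f), 2L)
  expect_identical(f$a_brightness, c(2L, 2L))
  # per-rater maxima 3,3,3,1,0 -> majority 3
  expect_identical(f$a_loudness, c(3L, 3L))
  expect_equal(f$a_attendance, rep(mean(c(0, 1, 1, 3, 15)), 2))
  expect_error(fuseAnnotations(ann[, -3]), "missing columns")
})
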