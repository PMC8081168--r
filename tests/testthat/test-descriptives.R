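test_that("correspondenceMatrix tallies pairs and preserves the total", {
  x <- c(0, 0, 1, 2, 4, 4, 3)
  y <- c(0, 1, 1, 2, 4, 3, 3)
  m <- correspondenceMatrix(x, y)
  expect_identical(dim(m), c(5L, 5L))
  expect_identical(sum(m), length(x))
  # brute-force tally oracle
  for (i in 0:4) for (j in 0:4)
    expect_identical(m[i + 1, j + 1], sum(x == i & y == j))
  expect_error(correspondenceMatrix(x, y[-1]), "equal length")
  expect_error(correspondenceMatrix(c(0, 5), c(0, 1)), "0..4")
})

test_that("clusterPearson reproduces cor() and widens inference", {
  set.seed(3)
  cl <- rep(1:20, each = 10)
  u <- rnorm(20)[cl]
  x <- u + rnorm(200)
  y <- 0.5 * x + u + rnorm(200)
  res <- clusterPearson(x, y, cl)
  expect_equal(res$r, cor(x, y))
  expect_true(res$p >= 0 && res$p <= 1)
  # with cluster-level confounding, the naive iid p-value is smaller
  naive <- cor.test(x, y)$p.value
  expect_gte(res$p, naive)
  expect_error(clusterPearson(x, y, rep(1, 200)), "3 clusters")
  expect_error(clusterPearson(rep(1, 200), y, cl), "zero variance")
})

test_that("clusterPairedTtest detects shifts and handles identical input", {
  set.seed(4)
  cl <- rep(1:25, each = 8)
  x <- rnorm(200)
  res0 <- clusterPairedTtest(x, x, cl)
  expect_identical(res0$p, 1)
  expect_identical(res0$meanDiff, 0)
  res1 <- clusterPairedTtest(x + 1, x, cl)
  expect_equal(res1$meanDiff, 1)
  expect_lt(res1$p, 1e-6)
})

test_that("cohensD matches hand-computed pooled-SD effect sizes", {
  # equal group SDs: d is just the mean difference over the common SD
  r <- cohensD(50, 10, 2, 50, 12, 2)
  expect_equal(r$d, 1)
  v <- (50 + 50) / (50 * 50) + 1 / (2 * 100)
  expect_equal(r$ciHi - r$ciLo, 2 * qnorm(0.975) * sqrt(v))
  expect_lt(r$ciLo, r$d); expect_gt(r$ciHi, r$d)
  # direction: group 2 below group 1 gives negative d
  expect_lt(cohensD(30, 5, 1, 30, 4, 1)$d, 0)
  expect_error(cohensD(1, 0, 1, 30, 0, 1), "n >= 2")
  expect_error(cohensD(10, 0, 0, 10, 0, 0), "pooled SD")
})

test_that("table1Report summarizes means, letters and correlations", {
  cfg <- smallConfig(nParticipants = 25, seed = 13)
  study <- generateStudy(cfg)
  stab <- buildSourceTable(study)
  t1 <- table1Report(stab)
  expect_identical(nrow(t1$means), 9L)            # 3 measures x 3 sources
  expect_identical(nrow(t1$correlations), 9L)     # 3 measures x 3 pairs
  expect_true(all(t1$correlations$r >= -1 & t1$correlations$r <= 1))
  expect_true(all(t1$correlations$label %in%
                    c("poor", "fair", "good", "excellent")))
  expect_identical(nrow(t1$letters), 9L)
  expect_true(all(nchar(t1$letters$letter) >= 1))
  # simulated sources track the same truth, so agreement is high
  expect_gt(mean(t1$correlations$r), 0.5)
})

test_that("table2Report contrasts drink groups within locations", {
  cfg <- smallConfig(nParticipants = 40, seed = 17)
  study <- generateStudy(cfg, renderClips = FALSE)
  situ <- situations(study)
  t2 <- table2Report(situ[0L, ], situ)
  t2p <- t2[t2$source == "participants", ]
  expect_identical(nrow(t2p), 21L)                # 7 locations x 3 measures
  expect_true(all(t2p$pct_alc >= 0 & t2p$pct_alc <= 100, na.rm = TRUE))
  # group Ns are consistent within each location
  for (loc in unique(t2p$location)) {
    sub <- t2p[t2p$location == loc, ]
    expect_identical(length(unique(sub$n)), 1L)
  }
  # where both drink groups exist, d matches the closed form
  row <- t2p[!is.na(t2p$d), ][1L, ]
  sl <- situ[situ$location_fine == row$location, ]
  v <- sl[[paste0("p_", row$measure)]]
  a <- sl$alcohol
  dd <- cohensD(sum(a == 0), mean(v[a == 0]), sd(v[a == 0]),
                sum(a == 1), mean(v[a == 1]), sd(v[a == 1]))
  expect_equal(row$d, dd$d)
  expect_equal(row$ci_lo, dd$ciLo)
})
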