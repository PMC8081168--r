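# simulate a random-intercept logistic dataset
simRiData <- function(nCluster = 60, perCluster = 25, beta0 = -0.5,
                      beta1 = 0.8, sigmaU = 1, seed = 1) {
  set.seed(seed)
  cl <- rep(seq_len(nCluster), each = perCluster)
  u <- rnorm(nCluster, 0, sigmaU)
  x <- rnorm(nCluster * perCluster)
  eta <- beta0 + beta1 * x + u[cl]
  y <- rbinom(length(x), 1, plogis(eta))
  list(y = y, X = cbind(x = x), cl = cl)
}

test_that("fitRandomInterceptLogit agrees with lme4::glmer", {
  d <- simRiData(seed = 7)
  fit <- fitRandomInterceptLogit(d$y, d$X, d$cl)
  df <- data.frame(y = d$y, x = d$X[, 1], cl = d$cl)
  ref <- lme4::glmer(y ~ x + (1 | cl), data = df,
                     family = binomial, nAGQ = 15)
  expect_equal(unname(coef(fit)), unname(lme4::fixef(ref)),
               tolerance = 5e-3)
  expect_equal(fit@sigmaU,
               sqrt(unname(lme4::VarCorr(ref)[["cl"]][1])),
               tolerance = 1e-2)
  expect_equal(fit@logLik, as.numeric(logLik(ref)), tolerance = 1e-3)
  expect_true(fit@converged)
  expect_identical(fit@nClusters, 60L)
})

test_that("the fit collapses to plain glm when sigma_u is zero", {
  d <- simRiData(sigmaU = 0, nCluster = 40, perCluster = 30, seed = 3)
  fit <- fitRandomInterceptLogit(d$y, d$X, d$cl)
  ref <- glm(d$y ~ d$X[, 1], family = binomial)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 0.02)
  expect_lt(fit@sigmaU, 0.15)
})

test_that("input validation catches malformed fitting problems", {
  d <- simRiData(nCluster = 12, perCluster = 10)
  expect_error(fitRandomInterceptLogit(rep(1, 120), d$X, d$cl),
               "constant")
  expect_error(fitRandomInterceptLogit(d$y, d$X, rep(1:5, 24)),
               "10 clusters")
  expect_error(
    fitRandomInterceptLogit(c(2, d$y[-1]), d$X, d$cl), "binary")
  Xbad <- d$X; Xbad[1] <- NA
  expect_error(fitRandomInterceptLogit(d$y, Xbad, d$cl), "finite")
})

test_that("orTable exponentiates coefficients with robust Wald CIs", {
  d <- simRiData(seed = 11)
  fit <- fitRandomInterceptLogit(d$y, d$X, d$cl)
  ot <- orTable(fit)
  expect_identical(ot$term, names(coef(fit)))
  expect_equal(ot$OR, unname(exp(coef(fit))))
  se <- sqrt(diag(vcov(fit)))
  expect_equal(ot$ci_lo, unname(exp(coef(fit) - qnorm(0.975) * se)))
  expect_true(all(ot$ci_lo < ot$OR & ot$OR < ot$ci_hi))
})

test_that("mzR2Fixed implements the latent-scale variance ratio", {
  d <- simRiData(seed = 5)
  fit <- fitRandomInterceptLogit(d$y, d$X, d$cl)
  eta <- drop(fit@X %*% coef(fit))
  expect_equal(mzR2Fixed(fit),
               var(eta) / (var(eta) + fit@sigmaU^2 + pi^2 / 3))
  expect_gt(mzR2Fixed(fit, dropRandom = TRUE), mzR2Fixed(fit))
  expect_true(mzR2Fixed(fit) >= 0 && mzR2Fixed(fit) < 1)
})

test_that("hosmerLemeshow matches a hand-built decile computation", {
  set.seed(8)
  x <- rnorm(400)
  p <- plogis(-0.3 + x)
  y <- rbinom(400, 1, p)
  hl <- hosmerLemeshow(y, p, g = 10)
  expect_identical(hl$g, 10L)
  expect_identical(hl$df, 8L)
  expect_true(hl$p >= 0 && hl$p <= 1)
  # direct recomputation with the same decile grouping
  br <- unique(quantile(p, probs = seq(0, 1, length.out = 11), type = 2))
  grp <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  O <- tapply(y, grp, sum)
  E <- tapply(p, grp, sum)
  ng <- tabulate(grp)
  chi <- sum((O - E)^2 / (E * (1 - E / ng)))
  expect_equal(hl$chi2, chi)
  expect_equal(hl$p, pchisq(chi, 8, lower.tail = FALSE))
})

test_that("hosmerLemeshow flags a badly misspecified model", {
  set.seed(9)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(2 * x^2 - 2))   # quadratic truth
  pLin <- fitted(glm(y ~ x, family = binomial))
  expect_lt(hosmerLemeshow(y, pLin, g = 10)$p, 0.01)
})

test_that("table3Report fits per source and location and skips absent sources", {
  cfg <- smallConfig(nParticipants = 60, seed = 23)
  study <- generateStudy(cfg, renderClips = FALSE)
  situ <- situations(study)
  t3 <- table3Report(situ)
  expect_true(all(t3$table$source == "participants"))
  expect_true(any(grepl("annotators: source columns absent", t3$skipped)))
  expect_true(all(t3$table$term %in%
                    c("brightness", "loudness", "attendance",
                      "prior_drinks")))
  expect_true(all(t3$table$OR > 0))
  expect_true(all(t3$table$ci_lo <= t3$table$OR &
                    t3$table$OR <= t3$table$ci_hi))
  expect_true(all(t3$table$r2_mz >= 0 & t3$table$r2_mz < 1))
})
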