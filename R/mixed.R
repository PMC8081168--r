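# Random-intercept logistic regression by adaptive Gauss-Hermite
# quadrature, with cluster-level sandwich standard errors, the
# McKelvey-Zavoina fixed-effects pseudo R-squared, and a fixed-part
# Hosmer-Lemeshow goodness-of-fit test.

# per-cluster marginal log-likelihood at (beta, sigma), adaptive GHQ.
# cl must be a factor-coded integer vector 1..J. Returns length-J vector.
.riLogLikByCluster <- function(beta, sigma, X, y, cl, J, gh,
                               warm = NULL) {
  eta0 <- drop(X %*% beta)
  s <- 2 * y - 1
  if (sigma < 1e-6) {
    # boundary: no random effect, likelihood factorizes over clusters
    ll <- -log1p(exp(-s * eta0))
    return(rowsum(ll, cl)[, 1L])
  }
  u <- if (is.null(warm)) numeric(J) else warm
  inv2 <- 1 / sigma^2
  for (it in seq_len(50L)) {
    p <- stats::plogis(eta0 + u[cl])
    g <- rowsum(y - p, cl)[, 1L] - u * inv2
    h <- rowsum(p * (1 - p), cl)[, 1L] + inv2
    step <- g / h
    step <- pmax(pmin(step, 2), -2)
    u <- u + step
    if (max(abs(step)) < 1e-9) break
  }
  p <- stats::plogis(eta0 + u[cl])
  h <- rowsum(p * (1 - p), cl)[, 1L] + inv2
  tau <- 1 / sqrt(h)
  Q <- length(gh$x)
  # n x Q matrix of linear predictors at the adapted nodes
  uq <- outer(u, rep(1, Q)) + sqrt(2) * outer(tau, gh$x)   # J x Q
  A <- matrix(0, J, Q)
  for (q in seq_len(Q)) {
    llq <- -log1p(exp(-s * (eta0 + uq[cl, q])))
    A[, q] <- rowsum(llq, cl)[, 1L] +
      stats::dnorm(uq[, q], 0, sigma, log = TRUE)
  }
  A <- A + outer(rep(1, J), log(gh$w) + gh$x^2)
  amax <- apply(A, 1L, max)
  ll <- amax + log(rowSums(exp(A - amax))) + log(sqrt(2) * tau)
  attr(ll, "umode") <- u
  ll
}

#' Fit a random-intercept logistic regression
#'
#' Maximizes the marginal likelihood of a logistic regression with a
#' Gaussian random intercept per cluster, using adaptive Gauss-Hermite
#' quadrature (nodes centered and scaled at each cluster's posterior
#' mode). Standard errors come from a cluster-level sandwich estimator,
#' the analogue of "robust maximum likelihood" estimation: the bread is
#' the observed information of the marginal likelihood, the meat the
#' outer product of per-cluster scores with the J/(J-1) small-sample
#' correction.
#'
#' @param y binary outcome (0/1).
#' @param X numeric predictor matrix (an intercept column is added
#'   unless one is present).
#' @param clusterIds cluster membership, at least 10 clusters.
#' @param nNodes quadrature nodes (default 15, minimum 12).
#' @param gradTol gradient-norm tolerance used for the convergence flag.
#' @param source,location labels carried into report tables.
#' @return a [MixedFit-class].
#' @export
fitRandomInterceptLogit <- function(y, X, clusterIds, nNodes = 15L,
                                    gradTol = 1e-4, source = "",
                                    location = "") {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("predictors must be finite")
  if (length(unique(y)) < 2L) stop("y must not be constant")
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  clF <- factor(clusterIds)
  J <- nlevels(clF)
  if (J < 10L) stop("need at least 10 clusters")
  cl <- as.integer(clF)
  if (nNodes < 12L) stop("use at least 12 quadrature nodes")
  if (!("(Intercept)" %in% colnames(X)) &&
      !any(apply(X, 2L, function(c) all(c == 1))))
    X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  gh <- pracma::gaussHermite(nNodes)

  glm0 <- suppressWarnings(stats::glm.fit(X, y,
                                          family = stats::binomial()))
  sep <- any(abs(glm0$coefficients) > 15) ||
    any(glm0$fitted.values > 1 - 1e-10 & y == 1) &&
    any(glm0$fitted.values < 1e-10 & y == 0)
  start <- c(glm0$coefficients, log(0.8))

  warmEnv <- new.env()
  warmEnv$u <- NULL
  negll <- function(theta) {
    ll <- .riLogLikByCluster(theta[seq_len(p)], exp(theta[p + 1L]),
                             X, y, cl, J, gh, warm = warmEnv$u)
    warmEnv$u <- attr(ll, "umode")
    -sum(ll)
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 400L, reltol = 1e-12))
  # one restart from the optimum; BFGS occasionally stalls with a
  # stale curvature approximation and a fresh start clears it
  opt2 <- stats::optim(opt$par, negll, method = "BFGS",
                       control = list(maxit = 400L, reltol = 1e-12))
  if (opt2$value <= opt$value) opt <- opt2
  theta <- opt$par
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- unname(exp(theta[p + 1L]))

  # numerical gradient/Hessian of the total log-likelihood
  fn <- function(th) -negll(th)
  gr <- pracma::grad(fn, theta)
  Hs <- pracma::hessian(fn, theta)
  Ainf <- -Hs                                     # observed information

  # per-cluster scores by central differences
  hstep <- pmax(1e-5, 1e-5 * abs(theta))
  S <- matrix(0, J, p + 1L)
  for (k in seq_len(p + 1L)) {
    tp <- theta; tp[k] <- tp[k] + hstep[k]
    tm <- theta; tm[k] <- tm[k] - hstep[k]
    lp <- .riLogLikByCluster(tp[seq_len(p)], exp(tp[p + 1L]), X, y, cl,
                             J, gh, warm = warmEnv$u)
    lm <- .riLogLikByCluster(tm[seq_len(p)], exp(tm[p + 1L]), X, y, cl,
                             J, gh, warm = warmEnv$u)
    S[, k] <- (lp - lm) / (2 * hstep[k])
  }
  meat <- crossprod(S) * J / (J - 1)   # CR1 small-sample correction
  bread <- tryCatch(solve(Ainf), error = function(e)
    .pinv(Ainf))
  vcovAll <- bread %*% meat %*% bread
  vcovBeta <- vcovAll[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(vcovBeta) <- list(names(beta), names(beta))

  converged <- opt$convergence == 0 &&
    sqrt(sum(gr^2)) < gradTol * max(1, abs(opt$value))
  if (!converged)
    warning(sprintf(
      "fit may not have converged (gradient norm %.3g)", sqrt(sum(gr^2))))

  new("MixedFit",
      coefficients = beta, vcov = vcovBeta, sigmaU = sigma,
      logLik = -opt$value, nObs = length(y), nClusters = J,
      converged = converged, gradNorm = sqrt(sum(gr^2)),
      separation = sep, source = source, location = location,
      X = X, y = as.numeric(y), clusterIds = as.character(clusterIds))
}

# small pseudo-inverse fallback without extra deps
.pinv <- function(M) {
  s <- svd(M)
  tol <- max(dim(M)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Odds-ratio table of a mixed fit
#'
#' @param fit a [MixedFit-class].
#' @param level confidence level (default 0.95).
#' @return data.frame with term, OR, ci_lo, ci_hi (Wald intervals on the
#'   log-odds scale with the cluster-robust SEs, exponentiated).
#' @export
orTable <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit@vcov))
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit@coefficients
  data.frame(term = names(b), OR = exp(b),
             ci_lo = exp(b - z * se), ci_hi = exp(b + z * se),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' McKelvey-Zavoina pseudo R-squared, fixed effects only
#'
#' On the latent-variable scale the logistic model has residual variance
#' pi^2/3; the fixed-effects R-squared is Var(X beta) divided by
#' Var(X beta) + sigma_u^2 + pi^2/3 -- the random-intercept variance is
#' kept in the denominator but excluded from the numerator, so the
#' statistic estimates the share of latent variance the measured context
#' would explain in a new sample. Setting `dropRandom = TRUE` removes
#' sigma_u^2 from the denominator entirely.
#'
#' @param fit a [MixedFit-class].
#' @param X optional predictor matrix; defaults to the fit's.
#' @param dropRandom drop sigma_u^2 from the denominator (default FALSE).
#' @return R-squared in [0, 1).
#' @export
mzR2Fixed <- function(fit, X = NULL, dropRandom = FALSE) {
  if (is.null(X)) X <- fit@X
  eta <- drop(as.matrix(X) %*% fit@coefficients)
  vf <- stats::var(eta)
  denom <- vf + (if (dropRandom) 0 else fit@sigmaU^2) + pi^2 / 3
  vf / denom
}

#' Hosmer-Lemeshow goodness-of-fit test on fixed-part probabilities
#'
#' Splits observations into `g` groups by deciles of the predicted
#' probability (ties kept together in the lower group; empty groups are
#' merged, reducing the degrees of freedom), then compares observed and
#' expected event counts: chi^2 = sum (O - E)^2 / (E (1 - E/n)). The
#' p-value uses g_effective - 2 degrees of freedom; p below .05 flags a
#' poor fit. For a [MixedFit-class] the probabilities are the fixed-part
#' ones, plogis(X beta).
#'
#' @param y binary outcomes.
#' @param phat predicted probabilities.
#' @param g number of groups (default 10); requires n >= 10 g.
#' @return list with `chi2`, `p`, `df`, `g`.
#' @export
hosmerLemeshow <- function(y, phat, g = 10L) {
  n <- length(y)
  if (length(phat) != n) stop("y and phat must have equal length")
  if (n < 10L * g) stop("need at least 10 observations per group")
  if (all(phat %in% c(0, 1)) && all(phat == y))
    return(list(chi2 = 0, p = 1, df = g - 2L, g = g))
  br <- unique(stats::quantile(phat, probs = seq(0, 1, length.out = g + 1L),
                               type = 2))
  grp <- cut(phat, breaks = br, include.lowest = TRUE, labels = FALSE)
  ng <- tabulate(grp)
  keep <- ng > 0L
  O <- rowsum(y, grp)[, 1L]
  E <- rowsum(phat, grp)[, 1L]
  ng <- ng[keep]
  denom <- E * (1 - E / ng)
  term <- ifelse(denom <= 0, ifelse(O == E, 0, Inf), (O - E)^2 / denom)
  chi2 <- sum(term)
  geff <- length(ng)
  df <- max(geff - 2L, 1L)
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, g = geff)
}

#' @rdname hosmerLemeshow
#' @param fit a [MixedFit-class]; `y` and the fixed-part probabilities
#'   are taken from it.
#' @export
hosmerLemeshowMl <- function(fit, g = 10L) {
  phat <- stats::plogis(drop(fit@X %*% fit@coefficients))
  hosmerLemeshow(fit@y, phat, g = g)
}

#' Fit the nine source-by-location models
#'
#' Fits the random-intercept logistic regression of alcohol use on
#' brightness, loudness, attendance and prior drinks, separately for
#' each data source (participants, annotators, algorithm) and each
#' coarse location type, and attaches the McKelvey-Zavoina fixed-effects
#' R-squared and the Hosmer-Lemeshow fit test. Strata with a constant
#' outcome, too few observations or clusters are flagged and skipped;
#' one failed model does not abort the report.
#'
#' @param sourceTable as built by [buildSourceTable()].
#' @param g Hosmer-Lemeshow group count (default 10).
#' @param nNodes quadrature nodes.
#' @return list with `fits` (named list of [MixedFit-class]), `table`
#'   (tidy data.frame: source, location, term, OR, ci_lo, ci_hi, r2_mz,
#'   hl_chi2, hl_p, n) and `skipped` (character log of skipped strata).
#' @export
table3Report <- function(sourceTable, g = 10L, nNodes = 15L) {
  srcCols <- list(participants = c("p_brightness", "p_loudness",
                                   "p_attendance"),
                  annotators = c("a_brightness", "a_loudness",
                                 "a_attendance"),
                  algorithm = c("g_brightness", "g_loudness",
                                "g_attendance"))
  fits <- list(); rows <- list(); skipped <- character()
  for (src in names(srcCols)) {
    if (!all(srcCols[[src]] %in% names(sourceTable))) {
      skipped <- c(skipped, paste0(src, ": source columns absent"))
      next
    }
    for (locLab in .coarseLevels) {
      st <- sourceTable[sourceTable$location_coarse == locLab, ]
      key <- paste(src, locLab, sep = ".")
      if (nrow(st) < 10L * g || length(unique(st$alcohol)) < 2L ||
          length(unique(st$participant_id)) < 10L) {
        skipped <- c(skipped, paste0(key, ": stratum too small or outcome constant"))
        next
      }
      X <- cbind(brightness = st[[srcCols[[src]][1L]]],
                 loudness = st[[srcCols[[src]][2L]]],
                 attendance = st[[srcCols[[src]][3L]]],
                 prior_drinks = st$prior_drinks)
      fit <- tryCatch(
        fitRandomInterceptLogit(st$alcohol, X, st$participant_id,
                                nNodes = nNodes, source = src,
                                location = locLab),
        error = function(e) e)
      if (inherits(fit, "error")) {
        skipped <- c(skipped, paste0(key, ": ", conditionMessage(fit)))
        next
      }
      fit@r2mz <- mzR2Fixed(fit)
      hl <- hosmerLemeshowMl(fit, g = g)
      fit@hlChi2 <- hl$chi2; fit@hlP <- hl$p
      fits[[key]] <- fit
      ot <- orTable(fit)
      ot <- ot[ot$term != "(Intercept)", ]
      rows[[key]] <- data.frame(source = src, location = locLab,
                                term = ot$term, OR = ot$OR,
                                ci_lo = ot$ci_lo, ci_hi = ot$ci_hi,
                                r2_mz = fit@r2mz, hl_chi2 = fit@hlChi2,
                                hl_p = fit@hlP, n = fit@nObs,
                                stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), location = character(),
               term = character(), OR = numeric(), ci_lo = numeric(),
               ci_hi = numeric(), r2_mz = numeric(), hl_chi2 = numeric(),
               hl_p = numeric(), n = integer())
  rownames(tab) <- NULL
  list(fits = fits, table = tab, skipped = skipped)
}
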