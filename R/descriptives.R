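# Source comparison and location-by-drink contrasts: correspondence
# matrices, cluster-adjusted correlations and paired t-tests, Cohen's d.

#' Correspondence matrix of two ordinal rating vectors
#'
#' Cross-tabulates two 0--4 ordinal ratings of the same situations into
#' a 5 x 5 count matrix; the total count is preserved. Attendance
#' measures should first be binned to the five annotator categories
#' (see [attendanceCategory()]).
#'
#' @param x,y integer vectors with values in 0..4, equal length.
#' @return 5 x 5 matrix of counts; rows index `x`, columns `y`.
#' @export
correspondenceMatrix <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (any(c(x, y) < 0 | c(x, y) > 4) || any(c(x, y) %% 1 != 0))
    stop("values must be integers in 0..4")
  m <- table(factor(x, levels = 0:4), factor(y, levels = 0:4))
  unclass(as.matrix(m))
}

# cluster-robust variance of a linear model, clustered on cluster_ids
.clusterP <- function(fit, clusterIds, term) {
  v <- sandwich::vcovCL(fit, cluster = clusterIds)
  est <- stats::coef(fit)[term]
  se <- sqrt(v[term, term])
  stat <- est / se
  df <- length(unique(clusterIds)) - 1L
  c(stat = unname(stat), p = unname(2 * stats::pt(-abs(stat), df)))
}

#' Pearson correlation with cluster-robust inference
#'
#' The point estimate is the ordinary Pearson correlation; its p-value
#' accounts for situations being nested within participants, via a
#' regression of the standardized y on the standardized x with
#' cluster-robust (sandwich) standard errors clustered on
#' `clusterIds`.
#'
#' @param x,y numeric vectors.
#' @param clusterIds cluster membership (e.g. participant ids); at
#'   least 3 distinct clusters.
#' @return list with `r`, `p`, and `stat` (the robust t statistic).
#' @export
clusterPearson <- function(x, y, clusterIds) {
  if (length(unique(clusterIds)) < 3L) stop("need at least 3 clusters")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y")
  r <- stats::cor(x, y)
  fit <- stats::lm(scale(y) ~ scale(x))
  cp <- .clusterP(fit, clusterIds, "scale(x)")
  list(r = r, p = cp["p"], stat = cp["stat"])
}

#' Paired t-test with cluster-robust inference
#'
#' Tests the mean of the paired differences x - y against zero with a
#' cluster-robust standard error (clustered on participants).
#'
#' @inheritParams clusterPearson
#' @return list with `t`, `p` and `meanDiff`.
#' @export
clusterPairedTtest <- function(x, y, clusterIds) {
  if (length(unique(clusterIds)) < 3L) stop("need at least 3 clusters")
  d <- x - y
  if (all(d == d[1L]) && d[1L] == 0)
    return(list(t = 0, p = 1, meanDiff = 0))
  fit <- stats::lm(d ~ 1)
  cp <- .clusterP(fit, clusterIds, "(Intercept)")
  list(t = unname(cp["stat"]), p = unname(cp["p"]), meanDiff = mean(d))
}

#' Cohen's d from summary statistics, with 95% confidence interval
#'
#' Standardized mean difference d = (m2 - m1) / s_pooled with the
#' pooled standard deviation, and the Hedges-Olkin normal-approximation
#' confidence interval with variance (n1+n2)/(n1*n2) + d^2/(2(n1+n2)).
#' An effect is read as significant when the interval excludes zero.
#'
#' @param n1,m1,s1 size, mean and SD of group 1.
#' @param n2,m2,s2 size, mean and SD of group 2.
#' @return list with `d`, `ciLo`, `ciHi`.
#' @export
cohensD <- function(n1, m1, s1, n2, m2, s2) {
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled SD")
  d <- (m2 - m1) / sqrt(sp2)
  v <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  z <- stats::qnorm(0.975)
  list(d = d, ciLo = d - z * sqrt(v), ciHi = d + z * sqrt(v))
}

# compact letter display: groups are sorted by mean; every maximal run
# of consecutive groups that are mutually non-different (p >= alpha)
# shares one letter
.letterDisplay <- function(means, pMatrix, alpha = 0.05) {
  k <- length(means)
  ord <- order(means)
  ns <- pMatrix >= alpha
  diag(ns) <- TRUE
  ends <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(ns[ord[i:(j + 1L)], ord[i:(j + 1L)]])) j <- j + 1L
    ends[i] <- j
  }
  # keep intervals not contained in an earlier (wider) one
  runs <- list()
  for (i in seq_len(k)) {
    contained <- any(vapply(seq_len(i - 1L),
                            function(h) ends[h] >= ends[i], logical(1L)))
    if (!contained) runs[[length(runs) + 1L]] <- ord[i:ends[i]]
  }
  letts <- character(k)
  for (r in seq_along(runs))
    letts[runs[[r]]] <- paste0(letts[runs[[r]]], letters[r])
  letts
}

#' Per-source means with cluster-adjusted pairwise contrasts
#'
#' For each measure (brightness, loudness, attendance) compares the
#' three sources on the clip subsample: means and SDs, all-pairs
#' cluster-robust paired t-tests with a compact letter display (shared
#' letters mean no detectable difference at p < .05), and cluster-
#' adjusted Pearson correlations between sources.
#'
#' @param sourceTable per-situation aligned measurements of the three
#'   sources, as built by [buildSourceTable()].
#' @return list with components `means` (data.frame), `letters`
#'   (data.frame) and `correlations` (data.frame).
#' @export
table1Report <- function(sourceTable) {
  st <- sourceTable
  meas <- c("brightness", "loudness", "attendance")
  srcCols <- list(participants = c("p_brightness", "p_loudness",
                                   "p_attendance"),
                  annotators = c("a_brightness", "a_loudness",
                                 "a_attendance"),
                  algorithm = c("g_brightness", "g_loudness",
                                "g_attendance"))
  means <- do.call(rbind, lapply(seq_along(meas), function(m) {
    do.call(rbind, lapply(names(srcCols), function(s) {
      v <- st[[srcCols[[s]][m]]]
      data.frame(measure = meas[m], source = s, mean = mean(v),
                 sd = stats::sd(v), stringsAsFactors = FALSE)
    }))
  }))
  letterRows <- list(); corRows <- list()
  for (m in seq_along(meas)) {
    cols <- vapply(srcCols, `[`, character(1L), m)
    pm <- matrix(1, 3L, 3L)
    for (a in 1:2) for (b in (a + 1L):3L) {
      tt <- clusterPairedTtest(st[[cols[a]]], st[[cols[b]]],
                               st$participant_id)
      pm[a, b] <- pm[b, a] <- tt$p
      cp <- clusterPearson(st[[cols[a]]], st[[cols[b]]],
                           st$participant_id)
      corRows[[length(corRows) + 1L]] <- data.frame(
        measure = meas[m], source1 = names(srcCols)[a],
        source2 = names(srcCols)[b], r = cp$r, p = cp$p,
        label = as.character(agreementLabel(cp$r)),
        stringsAsFactors = FALSE)
    }
    mu <- vapply(cols, function(cc) mean(st[[cc]]), numeric(1L))
    letterRows[[length(letterRows) + 1L]] <- data.frame(
      measure = meas[m], source = names(srcCols),
      mean = unname(mu), letter = .letterDisplay(mu, pm),
      stringsAsFactors = FALSE)
  }
  list(means = means,
       letters = do.call(rbind, letterRows),
       correlations = do.call(rbind, corRows))
}

#' Location-by-drink summary with effect sizes
#'
#' For every location type, measure and source: group sizes and alcohol
#' percentages, means and SDs overall and split by drink type, and
#' Cohen's d (with 95% CI) for the alcohol vs no-alcohol contrast.
#' Cells where either drink group has fewer than 2 observations omit
#' the effect size rather than failing.
#'
#' @param sourceTable as built by [buildSourceTable()] (annotator and
#'   algorithm sources; clip subsample).
#' @param situationsAll the full situation table (participant source).
#' @return long data.frame, one row per location x source x measure.
#' @export
table2Report <- function(sourceTable, situationsAll) {
  meas <- c("brightness", "loudness", "attendance")
  out <- list()
  cell <- function(df, col, locLab, src, m) {
    v <- df[[col]]; alc <- df$alcohol
    n0 <- sum(alc == 0); n1 <- sum(alc == 1)
    row <- data.frame(
      location = locLab, source = src, measure = m,
      n = length(v), n_alc = n1,
      pct_alc = if (length(v)) 100 * n1 / length(v) else NA_real_,
      mean_total = if (length(v)) mean(v) else NA_real_,
      sd_total = if (length(v) > 1L) stats::sd(v) else NA_real_,
      mean_nonalc = if (n0) mean(v[alc == 0]) else NA_real_,
      mean_alc = if (n1) mean(v[alc == 1]) else NA_real_,
      d = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      stringsAsFactors = FALSE)
    if (n0 >= 2L && n1 >= 2L) {
      s0 <- stats::sd(v[alc == 0]); s1 <- stats::sd(v[alc == 1])
      if (!(s0 == 0 && s1 == 0)) {
        dd <- cohensD(n0, mean(v[alc == 0]), s0, n1, mean(v[alc == 1]), s1)
        row$d <- dd$d; row$ci_lo <- dd$ciLo; row$ci_hi <- dd$ciHi
      }
    }
    row
  }
  for (locLab in .locationLevels) {
    sAll <- situationsAll[situationsAll$location_fine == locLab, ]
    sClip <- sourceTable[sourceTable$location_fine == locLab, ]
    for (m in seq_along(meas)) {
      out[[length(out) + 1L]] <-
        cell(sAll, paste0("p_", meas[m]), locLab, "participants", meas[m])
      out[[length(out) + 1L]] <-
        cell(sClip, paste0("a_", meas[m]), locLab, "annotators", meas[m])
      out[[length(out) + 1L]] <-
        cell(sClip, paste0("g_", meas[m]), locLab, "algorithm", meas[m])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
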