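# Two-class alcohol inference: minority oversampling, 10-fold
# cross-validation, random forests, 10 iterations.

#' Oversample the minority class
#'
#' Duplicates rows of the minority class, drawn with replacement, until
#' both classes have equal counts; the majority class is untouched and
#' no synthetic feature values are created.
#'
#' @param X feature matrix or data.frame.
#' @param y binary labels (two classes present).
#' @param seed seed for the resampling.
#' @return list with `X` and `y` of the balanced data.
#' @export
oversampleMinority <- function(X, y, seed = 1L) {
  X <- as.data.frame(X)
  tab <- table(y)
  if (length(tab) < 2L) stop("both classes must be present")
  if (tab[1L] == tab[2L]) return(list(X = X, y = y))
  minLab <- names(tab)[which.min(tab)]
  idxMin <- which(y == minLab)
  need <- max(tab) - min(tab)
  set.seed(seed)
  extra <- sample(idxMin, need, replace = TRUE)
  list(X = rbind(X, X[extra, , drop = FALSE]),
       y = c(y, y[extra]))
}

# stratified fold assignment on the original labels
.stratifiedFolds <- function(y, folds) {
  f <- integer(length(y))
  for (lab in unique(y)) {
    idx <- sample(which(y == lab))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated random-forest inference of alcohol use
#'
#' Runs the two-class inference task ("drinking alcohol" vs "drinking no
#' alcohol"): class balancing by minority oversampling, 10-fold
#' cross-validation with a random forest, repeated over 10 iterations,
#' reporting the mean accuracy. Two orderings of balancing and splitting
#' are available: `leakage_safe` (the default) oversamples inside each
#' training fold only, so duplicated minority rows can never sit on both
#' sides of a split; `paper_mode` balances the full dataset first and
#' then cross-validates the balanced data.
#'
#' @param X feature matrix/data.frame (the three context ratings plus
#'   prior drinks of one source).
#' @param y binary labels; n >= 50.
#' @param nTrees trees per forest (default 300; the useful range is
#'   roughly 200--500).
#' @param folds,iterations cross-validation shape (defaults 10 and 10).
#' @param mode "leakage_safe" or "paper_mode".
#' @param seed governs fold draws, oversampling and forest randomness.
#' @return list of class "InferenceReport": mode, nTrees, seed,
#'   `accuracy` (overall mean), `perFold` (iterations x folds matrix),
#'   `nBefore`, `nAfter`.
#' @export
cvInference <- function(X, y, nTrees = 300L, folds = 10L,
                        iterations = 10L, mode = c("leakage_safe",
                                                   "paper_mode"),
                        seed = 1L) {
  mode <- match.arg(mode)
  X <- as.data.frame(X)
  if (length(y) < 50L) stop("need at least 50 observations")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  yf <- factor(y)
  acc <- matrix(NA_real_, iterations, folds)
  nAfter <- NA_integer_
  for (it in seq_len(iterations)) {
    itSeed <- seed + 7919L * it
    set.seed(itSeed)
    if (mode == "paper_mode") {
      os <- oversampleMinority(X, as.character(yf), seed = itSeed)
      Xb <- os$X; yb <- factor(os$y)
      nAfter <- length(yb)
      set.seed(itSeed + 1L)
      fold <- .stratifiedFolds(as.character(yb), folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        if (length(unique(yb[tr])) < 2L) next
        rf <- ranger::ranger(y = yb[tr], x = Xb[tr, , drop = FALSE],
                             num.trees = nTrees,
                             seed = itSeed + 100L + k)
        pred <- stats::predict(rf, data = Xb[!tr, , drop = FALSE])
        acc[it, k] <- mean(pred$predictions == yb[!tr])
      }
    } else {
      fold <- .stratifiedFolds(as.character(yf), folds)
      for (k in seq_len(folds)) {
        tr <- fold != k
        if (length(unique(yf[tr])) < 2L) next
        os <- oversampleMinority(X[tr, , drop = FALSE],
                                 as.character(yf[tr]),
                                 seed = itSeed + 10L + k)
        nAfter <- length(os$y)
        rf <- ranger::ranger(y = factor(os$y), x = os$X,
                             num.trees = nTrees,
                             seed = itSeed + 100L + k)
        pred <- stats::predict(rf, data = X[!tr, , drop = FALSE])
        acc[it, k] <- mean(pred$predictions == as.character(yf[!tr]))
      }
    }
  }
  out <- list(mode = mode, nTrees = nTrees, seed = seed,
              folds = folds, iterations = iterations,
              accuracy = mean(acc, na.rm = TRUE), perFold = acc,
              nBefore = length(y), nAfter = nAfter)
  class(out) <- "InferenceReport"
  out
}

#' @export
print.InferenceReport <- function(x, ...) {
  cat(sprintf(
    "InferenceReport: %d-fold CV x %d iterations, %d trees, mode = %s\n",
    x$folds, x$iterations, x$nTrees, x$mode))
  cat(sprintf("  mean accuracy = %.3f (n = %d before balancing)\n",
              x$accuracy, x$nBefore))
  invisible(x)
}

#' Inference accuracy for each source and location type
#'
#' Runs [cvInference()] for the 3 sources x 3 coarse location types on
#' a source table; strata too small for the task are flagged and
#' skipped.
#'
#' @param sourceTable as built by [buildSourceTable()].
#' @param mode,nTrees,seed passed to [cvInference()].
#' @return list with `table` (data.frame source, location, accuracy, n)
#'   and `skipped`.
#' @export
inferenceReport <- function(sourceTable, mode = "leakage_safe",
                            nTrees = 300L, seed = 1L) {
  srcCols <- list(participants = c("p_brightness", "p_loudness",
                                   "p_attendance"),
                  annotators = c("a_brightness", "a_loudness",
                                 "a_attendance"),
                  algorithm = c("g_brightness", "g_loudness",
                                "g_attendance"))
  rows <- list(); skipped <- character()
  i <- 0L
  for (src in names(srcCols)) {
    if (!all(srcCols[[src]] %in% names(sourceTable))) {
      skipped <- c(skipped, paste0(src, ": source columns absent"))
      i <- i + length(.coarseLevels)
      next
    }
    for (locLab in .coarseLevels) {
      i <- i + 1L
      st <- sourceTable[sourceTable$location_coarse == locLab, ]
      key <- paste(src, locLab, sep = ".")
      if (nrow(st) < 50L || length(unique(st$alcohol)) < 2L ||
          min(table(st$alcohol)) < 10L) {
        skipped <- c(skipped, paste0(key, ": stratum too small"))
        next
      }
      X <- data.frame(brightness = st[[srcCols[[src]][1L]]],
                      loudness = st[[srcCols[[src]][2L]]],
                      attendance = st[[srcCols[[src]][3L]]],
                      prior_drinks = st$prior_drinks)
      rep <- cvInference(X, st$alcohol, nTrees = nTrees, mode = mode,
                         seed = seed + 31L * i)
      rows[[key]] <- data.frame(source = src, location = locLab,
                                accuracy = rep$accuracy, n = nrow(st),
                                stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source = character(), location = character(),
               accuracy = numeric(), n = integer())
  rownames(tab) <- NULL
  list(table = tab, skipped = skipped)
}
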