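#' Accessors for DrinkingStudy
#'
#' @param object a [DrinkingStudy-class].
#' @return `situations()` and `annotations()` return data.frames;
#'   `clips()` a named list of [Clip-class] objects; `studyConfig()` the
#'   configuration list.
#' @export
setGeneric("situations", function(object) standardGeneric("situations"))

#' @rdname situations
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @rdname situations
#' @export
setGeneric("clips", function(object) standardGeneric("clips"))

#' @rdname situations
#' @export
setGeneric("studyConfig", function(object) standardGeneric("studyConfig"))

#' Extract algorithmic context measures from a clip
#'
#' @param clip a [Clip-class].
#' @param ... passed on to the individual extractors (see [countPeople()]
#'   and [smoothedPowerDb()]).
#' @return a one-row data.frame (see [rateClip,Clip-method]).
#' @export
setGeneric("rateClip", function(clip, ...) standardGeneric("rateClip"))

#' @rdname situations
#' @export
setMethod("situations", "DrinkingStudy", function(object) object@situations)

#' @rdname situations
#' @export
setMethod("annotations", "DrinkingStudy", function(object) object@annotations)

#' @rdname situations
#' @export
setMethod("clips", "DrinkingStudy", function(object) object@clips)

#' @rdname situations
#' @export
setMethod("studyConfig", "DrinkingStudy", function(object) object@config)

setMethod("show", "Clip", function(object) {
  d <- dim(object@frames)
  nT <- d[length(d)]
  cat("Clip", if (nzchar(object@situationId))
    paste0("<", object@situationId, ">") else "", "\n")
  cat(sprintf("  frames: %d x %d%s, %d frames @ %g fps\n",
              d[1L], d[2L], if (length(d) == 4L) " x 3 (RGB)" else "",
              nT, object@fps))
  cat(sprintf("  audio : %d samples @ %g Hz (%.2f s)\n",
              length(object@audio), object@sampleRate,
              length(object@audio) / object@sampleRate))
})

setMethod("show", "DrinkingStudy", function(object) {
  s <- object@situations
  cat("DrinkingStudy\n")
  cat(sprintf("  %d situations in %d participants; %d with a clip\n",
              nrow(s), length(unique(s$participant_id)), sum(s$has_clip)))
  cat(sprintf("  %d rendered clips held; %d annotator rows\n",
              length(object@clips), nrow(object@annotations)))
  if (nrow(s))
    cat(sprintf("  alcohol in %.1f%% of situations\n",
                100 * mean(s$alcohol)))
})

setMethod("show", "MixedFit", function(object) {
  cat("MixedFit: random-intercept logistic regression\n")
  if (nzchar(object@source) || nzchar(object@location))
    cat(sprintf("  source = %s, location = %s\n",
                object@source, object@location))
  cat(sprintf("  n = %d observations in %d clusters\n",
              object@nObs, object@nClusters))
  cat(sprintf("  sigma_u = %.3f, logLik = %.2f, converged = %s\n",
              object@sigmaU, object@logLik, object@converged))
  if (object@separation)
    cat("  WARNING: (quasi-)separation detected; estimates unreliable\n")
  print(orTable(object))
})

#' @describeIn fitRandomInterceptLogit fixed-effect coefficients.
#' @param object a [MixedFit-class].
#' @export
setMethod("coef", "MixedFit", function(object) object@coefficients)

#' @describeIn fitRandomInterceptLogit cluster-robust covariance matrix.
#' @export
setMethod("vcov", "MixedFit", function(object) object@vcov)
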