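#' @import methods
NULL

#' Clip: rendered or loaded media for one drinking situation
#'
#' A `Clip` holds the frame stack and mono audio track of one 10-second
#' context recording, together with its timing metadata. Frames are stored
#' as a numeric array with dimensions height x width x T (grayscale) or
#' height x width x 3 x T (RGB), with pixel intensities on the 0--255
#' scale. Audio samples lie in [-1, 1].
#'
#' @slot frames numeric array, H x W x T or H x W x 3 x T, values in [0, 255].
#' @slot fps frames per second.
#' @slot audio numeric vector of mono samples in [-1, 1].
#' @slot sampleRate audio sampling rate in Hz.
#' @slot situationId identifier of the situation the clip documents.
#'
#' @seealso [renderClip()], [rateClip()]
#' @export
setClass("Clip",
  representation(
    frames = "array",
    fps = "numeric",
    audio = "numeric",
    sampleRate = "numeric",
    situationId = "character"
  )
)

setValidity("Clip", function(object) {
  msg <- character()
  d <- dim(object@frames)
  if (!(length(d) %in% c(3L, 4L)))
    msg <- c(msg, "frames must be an H x W x T or H x W x 3 x T array")
  if (length(d) == 4L && d[3L] != 3L)
    msg <- c(msg, "RGB frames must have 3 channels in the third dimension")
  rng <- range(object@frames)
  if (rng[1L] < 0 || rng[2L] > 255)
    msg <- c(msg, "frame intensities must lie in [0, 255]")
  if (length(object@audio) &&
      max(abs(object@audio)) > 1 + 1e-9)
    msg <- c(msg, "audio samples must lie in [-1, 1]")
  if (object@fps <= 0) msg <- c(msg, "fps must be positive")
  if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be positive")
  if (length(msg)) msg else TRUE
})

#' DrinkingStudy: a complete (synthetic or loaded) study
#'
#' Container for one study: the situation table (one row per drinking
#' event, nested in participants), the long annotator rating table
#' (5 raters x 4 items per clip), the rendered/loaded clips, and the
#' generator or run configuration that produced them.
#'
#' @slot situations data.frame, one row per situation (see
#'   [generateStudy()] for the column contract).
#' @slot annotations data.frame with columns situation_id, rater_id,
#'   brightness, music, chatter, attendance_cat.
#' @slot clips named list of [Clip-class] objects keyed by situation id.
#' @slot config list echoing the configuration used to build the study.
#' @export
setClass("DrinkingStudy",
  representation(
    situations = "data.frame",
    annotations = "data.frame",
    clips = "list",
    config = "list"
  )
)

setValidity("DrinkingStudy", function(object) {
  msg <- character()
  need <- c("situation_id", "participant_id", "location_fine",
            "location_coarse", "alcohol", "prior_drinks",
            "p_brightness", "p_loudness", "p_attendance", "has_clip")
  miss <- setdiff(need, names(object@situations))
  if (length(miss))
    msg <- c(msg, paste("situations is missing columns:",
                        paste(miss, collapse = ", ")))
  if (nrow(object@annotations)) {
    needA <- c("situation_id", "rater_id", "brightness", "music",
               "chatter", "attendance_cat")
    missA <- setdiff(needA, names(object@annotations))
    if (length(missA))
      msg <- c(msg, paste("annotations is missing columns:",
                          paste(missA, collapse = ", ")))
  }
  if (length(object@clips) &&
      !all(vapply(object@clips, is, logical(1L), class2 = "Clip")))
    msg <- c(msg, "clips must all be Clip objects")
  if (length(msg)) msg else TRUE
})

#' MixedFit: a fitted random-intercept logistic regression
#'
#' Result of [fitRandomInterceptLogit()]: maximum-likelihood estimates of
#' the fixed effects and the participant-level random-intercept SD, a
#' cluster-robust (sandwich) covariance matrix, odds ratios with 95%
#' confidence intervals, and the model-fit indices used to compare data
#' sources (McKelvey-Zavoina fixed-effects pseudo R-squared and a
#' fixed-part Hosmer-Lemeshow test).
#'
#' @slot coefficients named numeric vector of fixed effects (log-odds).
#' @slot vcov cluster-robust covariance of the fixed effects.
#' @slot sigmaU random-intercept standard deviation (>= 0).
#' @slot logLik maximized marginal log-likelihood.
#' @slot nObs,nClusters problem size.
#' @slot converged logical; `gradNorm` records the final gradient norm.
#' @slot gradNorm numeric gradient norm at the solution.
#' @slot separation logical flag for (quasi-)separated data.
#' @slot source,location free-text labels for report tables.
#' @slot r2mz McKelvey-Zavoina fixed-effects R-squared (filled by
#'   [mzR2Fixed()] when built through [table3Report()]).
#' @slot hlChi2,hlP Hosmer-Lemeshow statistic and p-value.
#' @slot X,y,clusterIds the model frame kept for fit indices.
#' @export
setClass("MixedFit",
  representation(
    coefficients = "numeric",
    vcov = "matrix",
    sigmaU = "numeric",
    logLik = "numeric",
    nObs = "integer",
    nClusters = "integer",
    converged = "logical",
    gradNorm = "numeric",
    separation = "logical",
    source = "character",
    location = "character",
    r2mz = "numeric",
    hlChi2 = "numeric",
    hlP = "numeric",
    X = "matrix",
    y = "numeric",
    clusterIds = "character"
  ),
  prototype(
    sigmaU = NA_real_, r2mz = NA_real_, hlChi2 = NA_real_, hlP = NA_real_,
    source = "", location = "", separation = FALSE
  )
)

setValidity("MixedFit", function(object) {
  if (!is.na(object@sigmaU) && object@sigmaU < 0)
    "sigmaU must be non-negative" else TRUE
})
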