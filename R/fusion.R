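# Annotator-side measures: ordinal fusion across 5 raters, overall
# loudness, attendance recoding, and ICC(2,k) agreement.

#' Attendance categories and their recoded values
#'
#' The five annotator attendance categories and the numeric values they
#' are recoded to: '0' -> 0, '1' -> 1, '2-4' -> 3, '5-10' -> 7.5,
#' '>10' -> 15.
#' @export
attendanceLevels <- c("0", "1", "2-4", "5-10", ">10")

.attendanceValues <- c(`0` = 0, `1` = 1, `2-4` = 3, `5-10` = 7.5,
                       `>10` = 15)

# tolerate the typographic en dash in loaded data
.normCat <- function(cats) gsub("–", "-", as.character(cats))

#' Category containing a person count
#'
#' @param n non-negative count (vectorized).
#' @return one of [attendanceLevels].
#' @export
attendanceCategory <- function(n) {
  if (any(n < 0)) stop("counts must be non-negative")
  attendanceLevels[findInterval(n, c(0, 1, 2, 5, 11)) ]
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Fuse five ordinal ratings into one
#'
#' If three or more of the five raters agree on one value, that value is
#' selected; otherwise the mean of the five ratings is rounded to the
#' closest integer (half away from zero; with five integer ratings the
#' mean is a multiple of 0.2, so exact .5 ties cannot occur).
#'
#' @param ratings integer vector of length 5 with values in 0..4.
#' @return integer in 0..4.
#' @export
fuseOrdinal <- function(ratings) {
  if (length(ratings) != 5L) stop("exactly 5 ratings are required")
  if (any(is.na(ratings)) || any(ratings %% 1 != 0) ||
      any(ratings < 0 | ratings > 4))
    stop("ratings must be integers in 0..4")
  tab <- tabulate(ratings + 1L, nbins = 5L)
  if (max(tab) >= 3L) return(which.max(tab) - 1L)
  as.integer(.roundHalfAway(mean(ratings)))
}

#' Overall loudness from music and chatter ratings
#'
#' Each rater's overall loudness is the maximum of their music-loudness
#' and chatter-loudness ratings; the five per-rater maxima are then
#' fused with [fuseOrdinal()].
#'
#' @param music,chatter integer vectors of length 5, values in 0..4.
#' @return integer in 0..4.
#' @export
overallLoudness <- function(music, chatter) {
  if (length(music) != 5L || length(chatter) != 5L)
    stop("exactly 5 ratings per dimension are required")
  fuseOrdinal(pmax(music, chatter))
}

#' Average recoded attendance categories
#'
#' @param cats character vector of length 5 with values among
#'   [attendanceLevels].
#' @return mean of the recoded values, in [0, 15].
#' @export
fuseAttendance <- function(cats) {
  if (length(cats) != 5L) stop("exactly 5 ratings are required")
  v <- .attendanceValues[.normCat(cats)]
  if (any(is.na(v)))
    stop("unknown attendance category: ",
         paste(unique(cats[is.na(v)]), collapse = ", "))
  mean(v)
}

#' Total attendance from a participant's company report
#'
#' Participants report how many of five types of company are present
#' (partner 0/1; family, male friends, female friends and others each
#' 0..10 or '>10', the latter recoded to 15); the total attendance is
#' the sum of the recoded counts.
#'
#' @param partner 0 or 1.
#' @param family,maleFriends,femaleFriends,others each an integer 0..10
#'   or the string '>10'.
#' @return integer total.
#' @export
participantAttendanceTotal <- function(partner, family, maleFriends,
                                       femaleFriends, others) {
  if (!partner %in% c(0, 1)) stop("partner must be 0 or 1")
  rec <- function(x) {
    if (identical(as.character(x), ">10")) return(15)
    x <- suppressWarnings(as.numeric(x))
    if (is.na(x) || x %% 1 != 0 || x < 0 || x > 10)
      stop("company codes must be integers 0..10 or '>10'")
    x
  }
  as.integer(partner + rec(family) + rec(maleFriends) +
               rec(femaleFriends) + rec(others))
}

#' Intraclass correlation, two-way random effects
#'
#' Shrout-Fleiss ICC(2,k) (absolute agreement, average of k raters) and
#' ICC(2,1) (single rater) from a complete subjects x raters matrix,
#' computed from the two-way mean squares: ICC(2,k) =
#' (MS_R - MS_E) / (MS_R + (MS_C - MS_E)/n).
#'
#' Degenerate inputs (zero between-subject variance) give a defined
#' value <= 0 rather than an error.
#'
#' @param ratings numeric matrix, n subjects x k raters, complete.
#' @param type "ICC2k" (default) or "ICC21".
#' @return the intraclass correlation coefficient.
#' @export
icc2k <- function(ratings, type = c("ICC2k", "ICC21")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 raters")
  if (any(is.na(ratings))) stop("ratings matrix must be complete")
  rowM <- rowMeans(ratings); colM <- colMeans(ratings)
  grand <- mean(ratings)
  msr <- k * sum((rowM - grand)^2) / (n - 1)
  msc <- n * sum((colM - grand)^2) / (k - 1)
  sse <- sum((ratings - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC2k") {
    (msr - mse) / (msr + (msc - mse) / n)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  }
}

#' Cicchetti interpretation band of an agreement coefficient
#'
#' Labels a correlation or ICC: below .40 'poor', .40--.59 'fair',
#' .60--.74 'good', .75 and above 'excellent'. Used for report labelling
#' only.
#'
#' @param r coefficient (vectorized).
#' @return character label.
#' @export
agreementLabel <- function(r) {
  cut(r, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf),
      labels = c("poor", "fair", "good", "excellent"),
      right = FALSE)
}

#' Fuse a full annotator table
#'
#' Applies the fusion rules per situation to a long annotation table
#' (columns situation_id, rater_id, brightness, music, chatter,
#' attendance_cat) and returns one row per situation with the fused
#' annotator measures.
#'
#' @param annotations long-format annotation data.frame.
#' @return data.frame with columns situation_id, a_brightness,
#'   a_loudness, a_attendance.
#' @export
fuseAnnotations <- function(annotations) {
  need <- c("situation_id", "rater_id", "brightness", "music", "chatter",
            "attendance_cat")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("annotations is missing columns: ", paste(miss, collapse = ", "))
  sp <- split(annotations, annotations$situation_id)
  out <- lapply(sp, function(a) {
    a <- a[order(a$rater_id), ]
    data.frame(
      situation_id = a$situation_id[1L],
      a_brightness = fuseOrdinal(a$brightness),
      a_loudness = overallLoudness(a$music, a$chatter),
      a_attendance = fuseAttendance(a$attendance_cat),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
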