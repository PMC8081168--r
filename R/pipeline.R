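# Orchestration: source-table assembly, full pipeline runs, and study
# validation.

#' Extract algorithmic ratings for every clip of a study
#'
#' @param study a [DrinkingStudy-class] holding rendered clips.
#' @param ... detector/loudness knobs passed to [rateClip()].
#' @return data.frame, one row per clip (see [rateClip()]).
#' @export
extractAlgoRatings <- function(study, ...) {
  cl <- clips(study)
  if (!length(cl)) stop("study holds no clips")
  res <- do.call(rbind, lapply(cl, rateClip, ...))
  rownames(res) <- NULL
  res
}

#' Assemble the aligned three-source measurement table
#'
#' Joins, for every situation that has a clip, the participant ratings
#' (p_*), the fused annotator measures (a_*, via [fuseAnnotations()])
#' and the algorithmic measures (g_*, via [extractAlgoRatings()] unless
#' supplied), together with the outcome and design columns.
#'
#' @param study a [DrinkingStudy-class].
#' @param algoRatings optional precomputed algorithmic ratings
#'   data.frame (with situation_id, brightness_bin, loudness_bin,
#'   person_count).
#' @return data.frame with one row per clip situation.
#' @export
buildSourceTable <- function(study, algoRatings = NULL) {
  situ <- situations(study)
  st <- situ[situ$has_clip == 1L, ]
  fused <- fuseAnnotations(annotations(study))
  if (is.null(algoRatings)) algoRatings <- extractAlgoRatings(study)
  g <- data.frame(situation_id = algoRatings$situation_id,
                  g_brightness = algoRatings$brightness_bin,
                  g_loudness = algoRatings$loudness_bin,
                  g_attendance = algoRatings$person_count,
                  stringsAsFactors = FALSE)
  out <- merge(merge(st, fused, by = "situation_id"), g,
               by = "situation_id")
  out[order(out$situation_id), ]
}

#' Validate a study's tables and cross-references
#'
#' Checks the schema, value ranges (ordinal ratings in 0..4,
#' non-negative attendance), five raters per annotated clip, known
#' attendance categories, and the cross-reference between has_clip rows
#' and held clips. Issues are returned as data, not raised.
#'
#' @param study a [DrinkingStudy-class].
#' @return data.frame of issues (kind, id, message); zero rows when the
#'   study is clean.
#' @export
validateStudy <- function(study) {
  issues <- list()
  add <- function(kind, id, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      kind = kind, id = id, message = msg, stringsAsFactors = FALSE)
  s <- situations(study)
  for (col in c("p_brightness", "p_loudness")) {
    bad <- which(s[[col]] < 0 | s[[col]] > 4 | s[[col]] %% 1 != 0)
    for (i in bad) add("range", s$situation_id[i],
                       sprintf("%s = %s outside 0..4", col, s[[col]][i]))
  }
  bad <- which(s$p_attendance < 0)
  for (i in bad) add("range", s$situation_id[i], "negative attendance")
  bad <- which(!s$location_fine %in% .locationLevels)
  for (i in bad) add("schema", s$situation_id[i],
                     paste("unknown location", s$location_fine[i]))
  bad <- which(coarseLocation(
    ifelse(s$location_fine %in% .locationLevels, s$location_fine,
           "private")) != s$location_coarse &
      s$location_fine %in% .locationLevels)
  for (i in bad) add("schema", s$situation_id[i],
                     "location_coarse does not match location_fine")
  a <- annotations(study)
  if (nrow(a)) {
    byClip <- table(a$situation_id)
    for (id in names(byClip)[byClip != 5L])
      add("arity", id, sprintf("%d raters instead of 5", byClip[[id]]))
    for (col in c("brightness", "music", "chatter")) {
      bad <- which(a[[col]] < 0 | a[[col]] > 4 | a[[col]] %% 1 != 0)
      for (i in bad) add("range", a$situation_id[i],
                         sprintf("annotator %s = %s outside 0..4",
                                 col, a[[col]][i]))
    }
    bad <- which(!gsub("–", "-", a$attendance_cat) %in%
                   attendanceLevels)
    for (i in bad) add("range", a$situation_id[i],
                       paste("unknown attendance category",
                             a$attendance_cat[i]))
  }
  if (length(clips(study))) {
    want <- s$situation_id[s$has_clip == 1L]
    for (id in setdiff(want, names(clips(study))))
      add("crossref", id, "has_clip situation without a clip")
    for (id in setdiff(names(clips(study)), want))
      add("crossref", id, "clip without a has_clip situation")
  }
  if (!length(issues))
    return(data.frame(kind = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, issues)
  rownames(res) <- NULL
  res
}

#' Run the full pipeline
#'
#' generate -> extract -> fuse -> describe -> model -> infer, writing
#' the report tables as CSV with a manifest and a structured log.
#' Re-running with the same configuration reproduces identical CSVs.
#' When the study carries no clips, the stages that need the annotator
#' or algorithm source are restricted to the participant source.
#'
#' @param cfg a [generatorConfig()].
#' @param outDir report directory (created if missing).
#' @param renderClips render media (default TRUE).
#' @param mode,nTrees inference parameters.
#' @param hlGroups Hosmer-Lemeshow group count.
#' @return invisibly, a list with the in-memory results (study,
#'   sourceTable, table1, table2, table3, inference, issues).
#' @export
runAll <- function(cfg = generatorConfig(), outDir,
                   renderClips = TRUE, mode = "leakage_safe",
                   nTrees = 300L, hlGroups = 10L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outDir, "run.log")
  logLines <- character()
  note <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    logLines <<- c(logLines, line)
  }

  study <- generateStudy(cfg, renderClips = renderClips)
  note("generate", sprintf("%d situations, %d clips",
                           nrow(situations(study)),
                           length(clips(study))))
  issues <- validateStudy(study)
  note("validate", sprintf("%d issues", nrow(issues)))

  results <- list(study = study, issues = issues)
  haveClips <- length(clips(study)) > 0L

  if (haveClips) {
    algo <- extractAlgoRatings(study, calib = cfg$calib)
    note("extract", sprintf("%d clips rated", nrow(algo)))
    stab <- buildSourceTable(study, algoRatings = algo)
    note("fuse", sprintf("%d aligned situations", nrow(stab)))
    utils::write.csv(algo, file.path(outDir, "algo_ratings.csv"),
                     row.names = FALSE)
    t1 <- table1Report(stab)
    utils::write.csv(t1$means, file.path(outDir, "table1_means.csv"),
                     row.names = FALSE)
    utils::write.csv(t1$correlations,
                     file.path(outDir, "table1_correlations.csv"),
                     row.names = FALSE)
    # correspondence matrices, attendance binned to categories
    cm <- list(
      brightness = correspondenceMatrix(stab$p_brightness,
                                        stab$a_brightness),
      loudness = correspondenceMatrix(stab$p_loudness, stab$a_loudness),
      attendance = correspondenceMatrix(
        match(attendanceCategory(stab$p_attendance), attendanceLevels) - 1L,
        match(attendanceCategory(round(stab$a_attendance)),
              attendanceLevels) - 1L))
    for (nm in names(cm))
      utils::write.csv(cm[[nm]],
                       file.path(outDir,
                                 sprintf("correspondence_%s.csv", nm)),
                       row.names = TRUE)
    note("describe", "table1 + correspondence matrices written")
    t2 <- table2Report(stab, situations(study))
    utils::write.csv(t2, file.path(outDir, "table2.csv"),
                     row.names = FALSE)
    t3 <- table3Report(stab, g = hlGroups)
    utils::write.csv(t3$table, file.path(outDir, "table3.csv"),
                     row.names = FALSE)
    note("model", sprintf("%d models fitted, %d skipped",
                          length(t3$fits), length(t3$skipped)))
    inf <- inferenceReport(stab, mode = mode, nTrees = nTrees,
                           seed = cfg$seed)
    utils::write.csv(inf$table, file.path(outDir, "inference.csv"),
                     row.names = FALSE)
    note("infer", sprintf("%d strata", nrow(inf$table)))
    results <- c(results, list(sourceTable = stab, table1 = t1,
                               correspondence = cm, table2 = t2,
                               table3 = t3, inference = inf))
  } else {
    note("extract", "skipped: no clips in study")
    # downstream stages restricted to the participant source, run on
    # all situations (no clip alignment possible)
    situ <- situations(study)
    t2 <- table2Report(situ[0L, ], situ)
    t2 <- t2[t2$source == "participants", ]
    utils::write.csv(t2, file.path(outDir, "table2.csv"),
                     row.names = FALSE)
    note("describe", "participant source only")
    t3 <- table3Report(situ, g = hlGroups)
    utils::write.csv(t3$table, file.path(outDir, "table3.csv"),
                     row.names = FALSE)
    note("model", sprintf("%d models fitted, %d skipped (participant source only)",
                          length(t3$fits), length(t3$skipped)))
    inf <- inferenceReport(situ, mode = mode, nTrees = nTrees,
                           seed = cfg$seed)
    utils::write.csv(inf$table, file.path(outDir, "inference.csv"),
                     row.names = FALSE)
    note("infer", sprintf("%d strata (participant source only)",
                          nrow(inf$table)))
    results <- c(results, list(table2 = t2, table3 = t3,
                               inference = inf))
  }

  manifest <- list(config = unclass(cfg), mode = mode, nTrees = nTrees,
                   hlGroups = hlGroups, renderClips = renderClips)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(outDir, "manifest.json"))
  writeLines(logLines, logFile)
  invisible(results)
}
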