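#' Write and read a cohort as plain-text files
#'
#' Persists a synthetic cohort in the package's interchange layout under
#' `dir`:
#' \itemize{
#' \item `fixations.csv` — columns `subject_id, x, y` (one row per point);
#' \item `expressions.csv` — columns `subject_id, frame, label`;
#' \item `eeg/<subject_id>.csv` — one column per channel (header = channel
#'   names), one row per sample, plus a JSON sidecar
#'   `eeg/<subject_id>.json` holding the sampling rate;
#' \item `manifest.json` — subject ids, labels, and file inventory.
#' }
#'
#' @param cohort a [generate_cohort()] cohort.
#' @param dir output directory (created if absent).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` a
#'   `"cohort"` object (with a `NULL` spec).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort") || is.list(cohort))
  dir.create(file.path(dir, "eeg"), recursive = TRUE, showWarnings = FALSE)
  fix <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id, x = s$fixations[, 1],
               y = s$fixations[, 2])))
  utils::write.csv(fix, file.path(dir, "fixations.csv"), row.names = FALSE)
  expr <- do.call(rbind, lapply(cohort$subjects, function(s)
    data.frame(subject_id = s$subject_id,
               frame = seq_along(s$expressions), label = s$expressions)))
  utils::write.csv(expr, file.path(dir, "expressions.csv"),
                   row.names = FALSE)
  for (s in cohort$subjects) {
    utils::write.csv(as.data.frame(t(s$eeg$data)),
                     file.path(dir, "eeg", paste0(s$subject_id, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(list(fs = s$eeg$fs, subject_id = s$subject_id,
                              channels = s$eeg$channels),
                         file.path(dir, "eeg",
                                   paste0(s$subject_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    subjects = lapply(cohort$subjects, function(s)
      list(subject_id = s$subject_id, label = s$label)),
    files = list(fixations = "fixations.csv",
                 expressions = "expressions.csv", eeg_dir = "eeg"),
    target_label = if (!is.null(cohort$spec)) cohort$spec$target_label
                   else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  fix <- utils::read.csv(file.path(dir, "fixations.csv"))
  expr <- utils::read.csv(file.path(dir, "expressions.csv"),
                          colClasses = c(label = "character"))
  subjects <- lapply(manifest$subjects, function(m) {
    id <- m$subject_id
    side <- jsonlite::read_json(file.path(dir, "eeg",
                                          paste0(id, ".json")),
                                simplifyVector = TRUE)
    eeg_df <- utils::read.csv(file.path(dir, "eeg", paste0(id, ".csv")))
    fx <- fix[fix$subject_id == id, c("x", "y")]
    list(subject_id = id, label = m$label,
         fixations = as.matrix(fx),
         expressions = expr$label[expr$subject_id == id][
           order(expr$frame[expr$subject_id == id])],
         eeg = eeg_recording(t(as.matrix(eeg_df)), fs = side$fs,
                             channels = colnames(eeg_df),
                             subject_id = id))
  })
  names(subjects) <- vapply(subjects, `[[`, character(1), "subject_id")
  spec <- NULL
  if (!is.null(manifest$target_label))
    spec <- list(target_label = manifest$target_label)
  structure(list(subjects = subjects, spec = spec), class = "cohort")
}

#' Write a feature matrix or evaluation report as CSV
#'
#' `write_features` writes a subjects x features matrix with a leading
#' `subject_id` column. `write_eval` writes the per-subject predictions
#' and the column-normalized confusion matrix of a [fusion_loocv()]
#' report to `<stem>_predictions.csv` and `<stem>_confusion.csv`.
#'
#' @param features numeric matrix with subject row names.
#' @param path,stem output paths.
#' @param eval a `"fusion_eval"` object.
#' @return The written path(s), invisibly.
#' @export
write_features <- function(features, path) {
  df <- data.frame(subject_id = rownames(features), features,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
write_eval <- function(eval, stem) {
  stopifnot(inherits(eval, "fusion_eval"))
  p1 <- paste0(stem, "_predictions.csv")
  p2 <- paste0(stem, "_confusion.csv")
  utils::write.csv(eval$predictions, p1, row.names = FALSE)
  cm <- as.data.frame(eval$confusion$matrix)
  cm <- cbind(predicted = rownames(cm), cm)
  utils::write.csv(cm, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write a band/region t-test screening report as CSV
#'
#' The tabular analogue of the band-power group-comparison table: one row
#' per band x region feature with Levene's F, the t statistic, p-value,
#' mean difference (ASD minus TD) and its standard error.
#'
#' @param screen a [ttest_screen()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(screen, path) {
  utils::write.csv(screen[, c("band", "region", "F", "t", "p",
                              "mean_diff", "se", "selected")],
                   path, row.names = FALSE)
  invisible(path)
}
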