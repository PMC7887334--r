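#' Reader-study harness (three-class comparison)
#'
#' Compares readers (physicians) and the model on a balanced three-class case
#' set: hip-fracture, pelvic-fracture and normal images (50 each in the
#' reference design). Each fracture task is scored one-vs-rest on its 100
#' relevant cases (the 50 target-class cases plus the 50 normals); balanced
#' accuracy is the mean of the three per-class recalls; each reader is
#' compared with the model by McNemar's test on the task's correctness
#' indicators; "misdiagnoses detected" counts target-class cases the reader
#' missed but the model called correctly.
#'
#' @param study data frame with columns `case_id`, `truth` (one of
#'   `"hip_fracture"`, `"pelvic_fracture"`, `"normal"`), a `model` column, and
#'   one column per reader, each holding predicted classes from the same set.
#' @param model_col name of the model's column (default `"model"`).
#' @return A `reader_study_report`: `tasks` tibble (one row per rater x task
#'   with accuracy/sensitivity/specificity, McNemar p vs the model, and
#'   misdiagnoses-detected counts) and `balanced` tibble (per-rater balanced
#'   accuracy over the three classes). [tidy()] returns the tasks table.
#' @export
reader_study_report <- function(study, model_col = "model") {
  classes <- c("hip_fracture", "pelvic_fracture", "normal")
  need <- c("case_id", "truth", model_col)
  if (!all(need %in% names(study))) {
    abort(paste("reader study needs columns:", paste(need, collapse = ", ")))
  }
  raters <- setdiff(names(study), c("case_id", "truth"))
  for (col in c("truth", raters)) {
    vals <- study[[col]]
    if (anyNA(vals) || any(!nzchar(as.character(vals)))) {
      bad <- study$case_id[is.na(vals) | !nzchar(as.character(vals))]
      abort(paste0("missing responses in `", col, "` for cases: ",
                   paste(bad, collapse = ", ")))
    }
    if (!all(vals %in% classes)) {
      abort(paste0("`", col, "` contains classes outside {",
                   paste(classes, collapse = ", "), "}."))
    }
  }
  tasks <- c(hip_fracture = "hip", pelvic_fracture = "pelvic")
  task_rows <- list()
  for (target in names(tasks)) {
    rel <- study$truth %in% c(target, "normal")
    truth_bin <- as.integer(study$truth[rel] == target)
    model_bin <- as.integer(study[[model_col]][rel] == target)
    for (rt in raters) {
      calls <- as.integer(study[[rt]][rel] == target)
      tp <- sum(calls & truth_bin); fn <- sum(!calls & truth_bin)
      tn <- sum(!calls & !truth_bin); fp <- sum(calls & !truth_bin)
      mc <- mcnemar_test(calls, model_bin, truth_bin)
      missed_idx <- truth_bin == 1 & calls == 0
      md <- sum(missed_idx & model_bin == 1)
      task_rows[[length(task_rows) + 1]] <- tibble(
        rater = rt, task = tasks[[target]],
        accuracy = (tp + tn) / length(truth_bin),
        sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
        mcnemar_p_vs_model = mc$p_value,
        misdiagnoses_detected = md,
        misdiagnoses_detected_pct = md / sum(truth_bin))
    }
  }
  balanced <- dplyr::bind_rows(lapply(raters, function(rt) {
    rec <- vapply(classes, function(cl) {
      mean(study[[rt]][study$truth == cl] == cl)
    }, numeric(1))
    tibble(rater = rt, balanced_accuracy = mean(rec))
  }))
  structure(list(tasks = dplyr::bind_rows(task_rows), balanced = balanced,
                 n_cases = nrow(study)),
            class = "reader_study_report")
}

#' @export
print.reader_study_report <- function(x, ...) {
  cat(sprintf("<reader_study_report> %d cases, %d raters\n", x$n_cases,
              nrow(x$balanced)))
  print(x$tasks)
  invisible(x)
}

#' @export
tidy.reader_study_report <- function(x, ...) x$tasks

#' @export
glance.reader_study_report <- function(x, ...) {
  dplyr::summarise(dplyr::group_by(x$tasks, .data$task),
                   mean_accuracy = mean(.data$accuracy),
                   mean_sensitivity = mean(.data$sensitivity),
                   mean_specificity = mean(.data$specificity),
                   .groups = "drop")
}

#' Read a reader-study response matrix
#'
#' CSV with columns `case_id`, `truth`, one column per reader, and `model`.
#'
#' @param path CSV path.
#' @return Tibble suitable for [reader_study_report()].
#' @export
read_reader_study <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a reader-study report as JSON and Markdown
#'
#' @param report a `reader_study_report`.
#' @param json_path,md_path output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_reader_study_report <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(tasks = report$tasks, balanced = report$balanced,
                              n_cases = report$n_cases),
                         json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(md_path)) {
    t <- report$tasks
    lines <- c(
      "| rater | task | acc | sen | spe | McNemar p | misdiagnoses detected |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %.3f | %.3f | %.3f | %.4g | %d (%.0f%%) |",
              t$rater, t$task, t$accuracy, t$sensitivity, t$specificity,
              t$mcnemar_p_vs_model, t$misdiagnoses_detected,
              100 * t$misdiagnoses_detected_pct),
      "", "| rater | balanced accuracy |", "|---|---|",
      sprintf("| %s | %.3f |", report$balanced$rater,
              report$balanced$balanced_accuracy))
    writeLines(lines, md_path)
  }
  invisible(c(json_path, md_path))
}
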