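#' Behavioral dataset of binary choices and confidence ratings
#'
#' A `behavioral_dataset` is the canonical container for one
#' two-alternative forced-choice (2AFC) task: a complete participants x
#' questions table in long format, one row per (participant, question)
#' cell, holding a binary correctness indicator (`correct`, 1 = chose the
#' true alternative) and a continuous confidence rating (`confidence`, on
#' a 0-100 visual-analog scale). The design is forced-choice: every cell
#' must be present exactly once.
#'
#' @param records a data frame with columns `participant_id`,
#'   `question_id`, `correct` and `confidence`.
#' @param task_name optional label for the task.
#'
#' @details Participant and question identifiers are opaque strings.
#'   Unless the input carries an explicit order (factor levels), they are
#'   ordered lexicographically for reproducibility.
#'
#' @return A tibble of class `behavioral_dataset` with attributes
#'   `task_name`, `participants` and `questions`.
#' @seealso [read_dataset()], [generate_dataset()]
#' @export
behavioral_dataset <- function(records, task_name = "task") {
  required <- c("participant_id", "question_id", "correct", "confidence")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stopf("records are missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  records <- tibble::as_tibble(records[required])
  records$participant_id <- as.character(records$participant_id)
  records$question_id <- as.character(records$question_id)

  if (!all(records$correct %in% c(0, 1))) {
    stopf("`correct` must be 0 or 1 for every record.")
  }
  if (!is.numeric(records$confidence) ||
      any(!is.finite(records$confidence)) ||
      any(records$confidence < 0 | records$confidence > 100)) {
    bad <- which(!is.finite(records$confidence) |
                   records$confidence < 0 | records$confidence > 100)[1]
    stopf("`confidence` must lie in [0, 100]; offending value %s at row %d.",
          records$confidence[bad], bad)
  }

  participants <- sort(unique(records$participant_id))
  questions <- sort(unique(records$question_id))

  key <- paste(records$participant_id, records$question_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- records[dup, ][1, ]
    stopf("duplicate cell for participant '%s', question '%s'.",
          d$participant_id, d$question_id)
  }
  expected <- as.vector(outer(participants, questions, paste, sep = "\r"))
  absent <- setdiff(expected, key)
  if (length(absent) > 0) {
    pq <- strsplit(absent[1], "\r", fixed = TRUE)[[1]]
    stopf(paste0("incomplete design: missing cell for participant '%s', ",
                 "question '%s' (%d cell(s) absent in total)."),
          pq[1], pq[2], length(absent))
  }

  records <- records[order(records$participant_id, records$question_id), ]
  structure(records,
            task_name = task_name,
            participants = participants,
            questions = questions,
            class = c("behavioral_dataset", class(tibble::tibble())))
}

#' @export
print.behavioral_dataset <- function(x, ...) {
  cat(sprintf("<behavioral_dataset> task '%s': %d participants x %d questions\n",
              attr(x, "task_name"), length(attr(x, "participants")),
              length(attr(x, "questions"))))
  NextMethod()
}

#' Accessors for a behavioral dataset
#'
#' @param data a [behavioral_dataset()].
#' @return `participants()` and `questions()` return character vectors of
#'   ids in canonical order; `task_name()` the task label.
#' @export
participants <- function(data) attr(data, "participants")

#' @rdname participants
#' @export
questions <- function(data) attr(data, "questions")

#' @rdname participants
#' @export
task_name <- function(data) attr(data, "task_name")

#' Participants x questions matrix of one response field
#'
#' Reshapes the long-format records into a numeric matrix with one row
#' per participant and one column per question, in canonical order. Used
#' internally by the simulation drivers, and handy for inspection.
#'
#' @param data a [behavioral_dataset()].
#' @param field `"correct"` or `"confidence"`.
#' @return numeric matrix with dimnames (participants, questions).
#' @export
response_matrix <- function(data, field = c("correct", "confidence")) {
  field <- match.arg(field)
  p <- participants(data)
  q <- questions(data)
  m <- matrix(NA_real_, length(p), length(q), dimnames = list(p, q))
  m[cbind(match(data$participant_id, p), match(data$question_id, q))] <-
    data[[field]]
  m
}

#' Read a behavioral dataset from a long-format CSV file
#'
#' The canonical layout is a UTF-8 CSV with a header and exactly the four
#' columns `participant_id`, `question_id`, `correct`, `confidence`, one
#' row per (participant, question) cell. Row order in the file is
#' irrelevant; the dataset is stored in lexicographic id order.
#'
#' @param path path to the CSV file.
#' @param layout file layout; only `"long"` is supported.
#' @param task_name optional task label; defaults to the file name.
#' @return a [behavioral_dataset()].
#' @export
read_dataset <- function(path, layout = "long", task_name = NULL) {
  layout <- match.arg(layout, "long")
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  if (is.null(task_name)) {
    task_name <- sub("\\.[^.]*$", "", basename(path))
  }
  behavioral_dataset(df, task_name = task_name)
}

#' Write a behavioral dataset to the canonical long-format CSV
#'
#' Inverse of [read_dataset()]: `read_dataset(write_dataset(x, p))`
#' reproduces `x` on the four canonical columns.
#'
#' @param data a [behavioral_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a summary table to CSV
#'
#' Summary tables carry condition labels plus numeric columns (means, CI
#' bounds, proportions, effect sizes). Numeric columns are written with 6
#' significant digits, so values round-trip through a generic CSV reader
#' to 1e-6 relative accuracy.
#'
#' @param table a non-empty data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stopf("`table` must be a non-empty data frame.")
  }
  out <- as.data.frame(table)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
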