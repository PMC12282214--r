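#' Read and write epoch-level accelerometer CSV files
#'
#' The epoch interchange format has one row per worker per 60-s epoch with
#' columns `worker_id, date, time, met, steps`; `time` is the epoch start
#' on the local clock and the working window is half-open.
#'
#' @param path file path.
#' @param epochs data.table/data.frame in the epoch layout.
#' @return `read_epoch_csv` returns a data.table.
#' @export
read_epoch_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "time"))
  need <- c("worker_id", "date", "time", "met", "steps")
  if (!all(need %in% names(dt)))
    stop("epoch file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dt$date <- as.Date(dt$date)
  dt
}

#' @rdname read_epoch_csv
#' @export
write_epoch_csv <- function(epochs, path) {
  data.table::fwrite(epochs, path)
  invisible(path)
}

#' Read and write the subject-level CSV
#'
#' One row per subject with covariates, item-level questionnaire responses
#' at both visits and adherence recalls; empty cells are missing values.
#'
#' @param path file path.
#' @param subjects subject data.frame.
#' @return `read_subject_csv` returns a data.frame.
#' @export
read_subject_csv <- function(path) {
  d <- as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
  if ("group" %in% names(d))
    d$group <- factor(d$group, levels = c("intervention", "control"))
  d
}

#' @rdname read_subject_csv
#' @export
write_subject_csv <- function(subjects, path) {
  data.table::fwrite(subjects, path)
  invisible(path)
}

#' Load a study configuration from a YAML file
#'
#' Recognized keys (all optional; omitted keys keep package defaults):
#' `n_intervention`, `n_control`, `seed`, `confounding`, `epoch_mode`,
#' `work_window` (two-element list), `m`, `n_iterations`, `k_donors`,
#' `outcomes` (list), `complete_case`, `variance`, `pa_long_runs`.
#'
#' @param path YAML file path.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files",
         call. = FALSE)
  y <- yaml::yaml.load_file(path)
  pick <- function(keys) y[intersect(keys, names(y))]
  cohort <- do.call(cohort_config,
                    pick(c("n_intervention", "n_control", "seed",
                           "confounding", "epoch_mode", "work_window")))
  imp <- do.call(imputation_spec, pick(c("m", "n_iterations", "k_donors")))
  args <- pick(c("outcomes", "complete_case", "variance", "pa_long_runs",
                 "seed"))
  args$outcomes <- unlist(args$outcomes)
  if (length(args$outcomes) == 0) args$outcomes <- NULL
  do.call(study_config, c(list(cohort = cohort, imputation = imp), args))
}
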