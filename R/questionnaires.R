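#' Score the K6 psychological-distress scale
#'
#' Sum of six items each scored 0-4, giving 0-24 points; higher is worse.
#' Any missing item makes the score missing (no prorating) so that whole
#' scores are handled by imputation.
#'
#' @param items numeric vector of 6 items, or a matrix/data.frame with 6
#'   columns (one row per respondent).
#' @return integer score(s) in 0-24, `NA` where any item is missing.
#' @export
#' @examples
#' score_k6(c(1, 2, 0, 3, 1, 1))  # 8
score_k6 <- function(items) {
  m <- as.matrix(items)
  if (is.null(dim(items))) m <- matrix(m, nrow = 1)
  if (ncol(m) != 6) stop("K6 requires 6 items", call. = FALSE)
  if (any(m < 0 | m > 4, na.rm = TRUE))
    stop("K6 items must be in 0-4", call. = FALSE)
  out <- rowSums(m)
  if (is.null(dim(items))) out[[1]] else out
}

#' Score the work-engagement scale
#'
#' Arithmetic mean of the items, each rated 0-6; higher is better
#' engagement. Any missing item makes the score missing.
#'
#' @param items numeric vector, or matrix/data.frame with one row per
#'   respondent.
#' @return mean score(s) in 0-6.
#' @export
#' @examples
#' score_uwes(c(3, 3, 3, 3, 3, 3, 0, 6, 3))  # 3
score_uwes <- function(items) {
  m <- as.matrix(items)
  if (is.null(dim(items))) m <- matrix(m, nrow = 1)
  if (any(m < 0 | m > 6, na.rm = TRUE))
    stop("work-engagement items must be in 0-6", call. = FALSE)
  out <- rowMeans(m)
  if (is.null(dim(items))) out[[1]] else out
}

#' Score absolute presenteeism
#'
#' Single 0-10 self-rating of overall job performance; higher is better.
#'
#' @param rating numeric vector of ratings.
#' @return the rating(s), validated.
#' @export
score_presenteeism <- function(rating) {
  if (any(rating < 0 | rating > 10, na.rm = TRUE))
    stop("presenteeism rating must be in 0-10", call. = FALSE)
  rating
}

#' Summarize adherence over the three recall points
#'
#' Computes the share of each response category at each recall point among
#' complete cases (subjects with all three recalls observed), matching how
#' program-adherence figures are reported.
#'
#' @param responses data.frame with integer columns `adh_1`, `adh_2`,
#'   `adh_3` (1 = "almost never" ... 4 = "almost always"); intervention-arm
#'   rows.
#' @return data.frame with columns `time_point`, `category`, `share`, plus
#'   attribute `"n_complete"`; shares sum to 1 per time point. Zero rows
#'   (with a warning) when no complete cases exist.
#' @export
summarize_adherence <- function(responses) {
  cols <- paste0("adh_", 1:3)
  stopifnot(all(cols %in% names(responses)))
  cc <- stats::complete.cases(responses[, cols])
  if (!any(cc)) {
    warning("no complete adherence cases", call. = FALSE)
    out <- data.frame(time_point = integer(), category = integer(),
                      share = numeric())
    attr(out, "n_complete") <- 0L
    return(out)
  }
  r <- responses[cc, cols]
  out <- do.call(rbind, lapply(1:3, function(t) {
    tab <- tabulate(r[[cols[t]]], nbins = 4)
    data.frame(time_point = t, category = 1:4, share = tab / sum(tab))
  }))
  attr(out, "n_complete") <- sum(cc)
  out
}

# score all instruments in a subject table -> per-visit score columns
score_questionnaires <- function(subjects, config) {
  for (inst in c("k6", "uwes", "hpq")) {
    q <- config$questionnaires[[inst]]
    for (v in c("b", "f")) {
      if (q$items == 1L) {
        score <- score_presenteeism(subjects[[paste0(inst, "_", v)]])
      } else {
        cols <- paste0(inst, "_", v, "_", seq_len(q$items))
        m <- as.matrix(subjects[, cols])
        score <- if (inst == "k6") score_k6(m) else score_uwes(m)
      }
      subjects[[paste0(inst, "_", v, "_score")]] <- score
    }
  }
  subjects
}
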