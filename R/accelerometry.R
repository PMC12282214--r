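#' Classify a 60-s epoch by MET value
#'
#' Cut-points: sedentary behavior (SB) for MET in `(0, 1.5]`,
#' light-intensity activity (LPA) for `(1.5, 3.0)`, moderate-to-vigorous
#' activity (MVPA) for `>= 3.0`. A MET of exactly 0 is the device's
#' below-detection signal and is returned as `"nonwear_candidate"`; whether
#' such epochs are non-wear is decided by [detect_nonwear()] (isolated zero
#' runs shorter than 60 min count as wear and are treated as sedentary
#' downstream). The printed cut-points leave a nominal gap between 1.5 and
#' 1.6; the half-open intervals close it so every non-negative MET value is
#' classified.
#'
#' @param met numeric vector of MET values (>= 0).
#' @return character vector in
#'   `c("SB", "LPA", "MVPA", "nonwear_candidate")`.
#' @export
#' @examples
#' classify_epoch(c(0, 1.5, 1.55, 3.0))
classify_epoch <- function(met) {
  if (any(is.na(met)) || any(met < 0))
    stop("MET values must be non-negative and non-missing", call. = FALSE)
  out <- character(length(met))
  out[met == 0] <- "nonwear_candidate"
  out[met > 0 & met <= 1.5] <- "SB"
  out[met > 1.5 & met < 3.0] <- "LPA"
  out[met >= 3.0] <- "MVPA"
  out
}

#' Flag non-wear epochs in one worker-day
#'
#' Non-wear time is any maximal run of at least 60 consecutive
#' below-detection (MET = 0) epochs; shorter zero runs count as wear. No
#' tolerance epochs are allowed inside a run.
#'
#' @param met numeric MET vector for one contiguous worker-day (one value
#'   per 60-s epoch, in time order).
#' @param min_run minimum run length (epochs) that counts as non-wear.
#' @return logical vector, `TRUE` where the epoch is worn.
#' @export
#' @examples
#' detect_nonwear(c(rep(0, 59), 1.2))  # 59 zeros: all wear
detect_nonwear <- function(met, min_run = 60L) {
  if (any(met < 0)) stop("MET values must be non-negative", call. = FALSE)
  r <- rle(met == 0)
  nonwear <- rep(r$values & r$lengths >= min_run, r$lengths)
  !nonwear
}

#' Extract the working-hours window from an epoch stream
#'
#' Keeps epochs whose start time lies in the half-open interval
#' `[start, end)`; the default 09:00-17:00 window yields 480 epoch slots.
#'
#' @param stream data.frame/data.table with columns `time` (`"HH:MM"` or
#'   `"HH:MM:SS"` clock time of the epoch start) and any others.
#' @param window character `c(start, end)` clock times.
#' @return the filtered stream (possibly zero rows).
#' @export
extract_working_window <- function(stream, window = c("09:00", "17:00")) {
  win <- parse_window(window)
  tm <- time_to_min(stream$time)
  stream[tm >= win[1] & tm < win[2], , drop = FALSE]
}

time_to_min <- function(time) {
  u <- unique(time)
  p <- strsplit(u, ":")
  mins <- vapply(p, function(x) as.integer(x[1]) * 60L + as.integer(x[2]),
                 integer(1))
  mins[match(time, u)]
}

#' Valid-day rule
#'
#' A workday is valid when the device was worn for at least 75% of the
#' working window (360 of 480 minutes by default).
#'
#' @param wear_min worn minutes in the window.
#' @param window_min total window length in minutes.
#' @param frac required wear fraction.
#' @return logical.
#' @export
is_valid_day <- function(wear_min, window_min = 480, frac = 0.75) {
  wear_min >= frac * window_min
}

#' Bout metrics for one classified day
#'
#' Prolonged sedentary bouts are maximal runs of consecutive worn SB epochs
#' lasting at least `sb_bout_min` (30) minutes; bouted physical activity
#' comprises maximal runs of consecutive worn activity epochs (LPA or MVPA,
#' intensities may mix) lasting between `pa_bout_range[1]` and
#' `pa_bout_range[2]` minutes — the span from a typical single break
#' session (3 min) to the daily break goal (10 min). Non-wear epochs break
#' any run. Activity runs longer than the upper bound are excluded by
#' default (`long_runs = "exclude"`); `"truncate"` counts each as one bout
#' of the maximum length instead.
#'
#' @param classes character vector of epoch classes (`"SB"`, `"LPA"`,
#'   `"MVPA"`, `"nonwear_candidate"`).
#' @param wear logical wear flags from [detect_nonwear()].
#' @param sb_bout_min minimum prolonged-SB run length (min).
#' @param pa_bout_range inclusive activity-bout length band (min).
#' @param long_runs `"exclude"` or `"truncate"` for activity runs longer
#'   than the band.
#' @return list with `prolonged_sb_min`, `prolonged_sb_count`,
#'   `bouted_pa_min`, `bouted_pa_count`.
#' @export
#' @examples
#' cls <- rep(c("SB", "LPA"), c(35, 5))
#' compute_bouts(cls, rep(TRUE, 40))
compute_bouts <- function(classes, wear = rep(TRUE, length(classes)),
                          sb_bout_min = 30L, pa_bout_range = c(3L, 10L),
                          long_runs = c("exclude", "truncate")) {
  long_runs <- match.arg(long_runs)
  ok <- classes %in% c("SB", "LPA", "MVPA", "nonwear_candidate")
  if (!all(ok)) stop("unclassified epoch at position ", which(!ok)[1],
                     call. = FALSE)
  # wear SB (incl. below-detection wear epochs) vs wear PA vs break
  state <- ifelse(!wear, "NW",
                  ifelse(classes %in% c("LPA", "MVPA"), "PA", "SB"))
  r <- rle(state)
  sb <- r$values == "SB" & r$lengths >= sb_bout_min
  pa_all <- r$values == "PA"
  pa_in <- pa_all & r$lengths >= pa_bout_range[1] & r$lengths <= pa_bout_range[2]
  pa_long <- pa_all & r$lengths > pa_bout_range[2]
  bouted_min <- sum(r$lengths[pa_in])
  bouted_count <- sum(pa_in)
  if (long_runs == "truncate" && any(pa_long)) {
    bouted_min <- bouted_min + sum(pa_long) * pa_bout_range[2]
    bouted_count <- bouted_count + sum(pa_long)
  }
  list(prolonged_sb_min = sum(r$lengths[sb]),
       prolonged_sb_count = sum(sb),
       bouted_pa_min = bouted_min,
       bouted_pa_count = bouted_count)
}

#' Standardize a behavior quantity to an 8-hour workday
#'
#' `standardized = raw * 480 / wear_min`, applied alike to minutes, bout
#' counts and steps so days with different wear times are comparable.
#'
#' @param raw observed quantity over the worn part of the day.
#' @param wear_min worn minutes (> 0; `NA` returned when 0).
#' @return standardized quantity per 480 worn minutes.
#' @export
#' @examples
#' standardize(150, 400)  # 180
standardize <- function(raw, wear_min) {
  out <- raw * 480 / wear_min
  out[wear_min <= 0] <- NA_real_
  out
}

#' Summarize a subject's daily metrics
#'
#' Averages each standardized metric over valid days. Subjects with fewer
#' than `min_valid_days` valid days do not meet the inclusion rule: their
#' metrics are set missing (for downstream imputation) but the record is
#' retained.
#'
#' @param daily data.frame of per-day metrics for one subject (layout of
#'   [process_accelerometry()]`$daily`).
#' @param min_valid_days inclusion threshold (default 4).
#' @return one-row data.frame of subject-level standardized means.
#' @export
summarize_subject <- function(daily, min_valid_days = 4L) {
  stopifnot(nrow(daily) >= 1)
  metrics <- c("wear_min", "sb", "lpa", "mvpa", "prolonged_sb_min",
               "prolonged_sb_count", "bouted_pa_min", "bouted_pa_count",
               "steps")
  v <- daily[daily$valid, , drop = FALSE]
  n_valid <- nrow(v)
  meets <- n_valid >= min_valid_days
  out <- data.frame(id = daily$worker_id[1], n_valid_days = n_valid,
                    meets_inclusion = meets)
  for (m in metrics) {
    col <- if (m == "wear_min") "wear_min" else paste0("std_", m)
    out[[m]] <- if (meets) mean(v[[col]]) else NA_real_
  }
  out
}

#' Process epoch streams into daily and subject behavior metrics
#'
#' Full device pipeline: working-window extraction, MET classification,
#' non-wear detection (60-min zero runs), valid-day rule (>= 75% wear),
#' bout detection, standardization to 480 worn minutes, and per-subject
#' averaging over valid days with the >= 4 valid-day inclusion rule.
#' Below-detection epochs that fall outside a non-wear run are counted as
#' sedentary, so worn SB + LPA + MVPA minutes always equal wear time.
#'
#' @param epochs data.frame/data.table with columns `worker_id`, `date`,
#'   `time`, `met`, `steps` (one row per 60-s epoch).
#' @param window working window `c(start, end)`.
#' @param pa_long_runs treatment of long activity runs, see
#'   [compute_bouts()].
#' @param min_valid_days subject inclusion threshold.
#' @return list with `daily` (per worker-day raw and standardized metrics
#'   and validity flag) and `subjects` (per-worker standardized means;
#'   metrics `NA` when the inclusion rule fails).
#' @export
process_accelerometry <- function(epochs, window = c("09:00", "17:00"),
                                  pa_long_runs = c("exclude", "truncate"),
                                  min_valid_days = 4L) {
  pa_long_runs <- match.arg(pa_long_runs)
  win <- parse_window(window)
  window_len <- win[2] - win[1]
  dt <- data.table::as.data.table(epochs)
  if (any(dt$met < 0)) stop("negative MET value in input", call. = FALSE)

  dt[, time_min := time_to_min(time)]
  dt <- dt[time_min >= win[1] & time_min < win[2]]
  if (nrow(dt) == 0)
    return(list(daily = dt[0], subjects = dt[0]))
  data.table::setorder(dt, worker_id, date, time_min)

  dt[, day := .GRP, by = .(worker_id, date)]
  gap <- dt[, any(diff(time_min) != 1L), by = day]$V1
  if (any(gap))
    stop("gap in epoch sequence: streams must be contiguous over the window",
         call. = FALSE)

  n <- nrow(dt)
  new_day <- c(TRUE, dt$day[-1] != dt$day[-n])

  zero <- dt$met == 0
  zrun <- cumsum(new_day | c(FALSE, zero[-1] != zero[-n]))
  zlen <- tabulate(zrun)
  dt[, wear := !(zero & zlen[zrun] >= 60L)]

  # worn zero epochs are sedentary; class 1=SB, 2=PA, 0=non-wear
  state <- integer(n)
  state[dt$wear & dt$met < 1.5 + 1e-9] <- 1L
  state[dt$wear & dt$met > 1.5] <- 2L
  mvpa <- dt$wear & dt$met >= 3.0

  # run-length structure for bout metrics
  rrun <- cumsum(new_day | c(FALSE, state[-1] != state[-n]))
  rlen <- tabulate(rrun)
  run_state <- state[!duplicated(rrun)]
  run_day <- dt$day[!duplicated(rrun)]
  run_len <- rlen[unique(rrun)]

  sb_sel <- run_state == 1L & run_len >= 30L
  pa_in <- run_state == 2L & run_len >= 3L & run_len <= 10L
  pa_long <- run_state == 2L & run_len > 10L

  nd <- max(dt$day)
  agg_runs <- function(sel, val) {
    out <- numeric(nd)
    if (any(sel)) {
      s <- rowsum(val[sel], run_day[sel])
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  prolonged_min <- agg_runs(sb_sel, run_len)
  prolonged_cnt <- agg_runs(sb_sel, rep(1, length(run_len)))
  bouted_min <- agg_runs(pa_in, run_len)
  bouted_cnt <- agg_runs(pa_in, rep(1, length(run_len)))
  if (pa_long_runs == "truncate") {
    bouted_min <- bouted_min + 10 * agg_runs(pa_long, rep(1, length(run_len)))
    bouted_cnt <- bouted_cnt + agg_runs(pa_long, rep(1, length(run_len)))
  }

  daily <- dt[, .(
    wear_min = sum(wear),
    sb_min = sum(wear & met <= 1.5),
    lpa_min = sum(wear & met > 1.5 & met < 3.0),
    mvpa_min = sum(wear & met >= 3.0),
    steps = sum(steps[wear])
  ), by = .(worker_id, date, day)]
  daily[, `:=`(prolonged_sb_min = prolonged_min[day],
               prolonged_sb_count = prolonged_cnt[day],
               bouted_pa_min = bouted_min[day],
               bouted_pa_count = bouted_cnt[day])]
  daily[, valid := is_valid_day(wear_min, window_len)]
  for (m in c("sb_min", "lpa_min", "mvpa_min", "prolonged_sb_min",
              "prolonged_sb_count", "bouted_pa_min", "bouted_pa_count",
              "steps")) {
    std_name <- paste0("std_", sub("_min$", "", m))
    std_name <- c(sb_min = "std_sb", lpa_min = "std_lpa", mvpa_min = "std_mvpa",
                  prolonged_sb_min = "std_prolonged_sb_min",
                  prolonged_sb_count = "std_prolonged_sb_count",
                  bouted_pa_min = "std_bouted_pa_min",
                  bouted_pa_count = "std_bouted_pa_count",
                  steps = "std_steps")[[m]]
    daily[, (std_name) := standardize(get(m), wear_min)]
  }
  daily[, day := NULL]

  subjects <- daily[, {
    v <- .SD[valid == TRUE]
    meets <- nrow(v) >= min_valid_days
    if (meets) {
      list(n_valid_days = nrow(v), meets_inclusion = TRUE,
           wear_min = mean(v$wear_min),
           sb = mean(v$std_sb), lpa = mean(v$std_lpa),
           mvpa = mean(v$std_mvpa),
           prolonged_sb_min = mean(v$std_prolonged_sb_min),
           prolonged_sb_count = mean(v$std_prolonged_sb_count),
           bouted_pa_min = mean(v$std_bouted_pa_min),
           bouted_pa_count = mean(v$std_bouted_pa_count),
           steps = mean(v$std_steps))
    } else {
      list(n_valid_days = nrow(v), meets_inclusion = FALSE,
           wear_min = NA_real_, sb = NA_real_, lpa = NA_real_,
           mvpa = NA_real_, prolonged_sb_min = NA_real_,
           prolonged_sb_count = NA_real_, bouted_pa_min = NA_real_,
           bouted_pa_count = NA_real_, steps = NA_real_)
    }
  }, by = worker_id]
  data.table::setnames(subjects, "worker_id", "id")

  list(daily = daily[], subjects = subjects[])
}
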