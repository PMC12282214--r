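test_that("MET cut-points classify every non-negative value", {
  expect_identical(classify_epoch(c(0, 1.5, 1.55, 3.0, 0.9, 2.9, 10)),
                   c("nonwear_candidate", "SB", "LPA", "MVPA", "SB", "LPA",
                     "MVPA"))
  expect_error(classify_epoch(-0.1), "non-negative")
  # exhaustive 0.1 grid: classes are exclusive and exhaustive
  grid <- seq(0, 12, by = 0.1)
  cls <- classify_epoch(grid)
  expect_identical(cls[grid == 0], "nonwear_candidate")
  expect_true(all(cls[grid > 0 & grid <= 1.5] == "SB"))
  expect_true(all(cls[grid > 1.5 & grid < 3.0] == "LPA"))
  expect_true(all(cls[grid >= 3.0] == "MVPA"))
})

test_that("non-wear detection flags 60-minute zero runs exactly", {
  expect_true(all(!detect_nonwear(rep(0, 60))))
  met59 <- c(1, rep(0, 59), 1)
  expect_true(all(detect_nonwear(met59)))
  # random streams vs the brute-force sliding-window oracle
  set.seed(77)
  for (i in 1:30) {
    met <- ifelse(runif(480) < 0.4, 0, round(runif(480, 0.9, 3.5), 1))
    # implant a guaranteed long zero run occasionally
    if (i %% 3 == 0) met[100:170] <- 0
    expect_identical(detect_nonwear(met), nonwear_oracle(met))
  }
})

test_that("working-window extraction uses the half-open boundary", {
  mins <- 535:1025
  stream <- data.frame(
    time = sprintf("%02d:%02d", mins %/% 60, mins %% 60), met = 1)
  kept <- extract_working_window(stream)
  expect_equal(nrow(kept), 480L)
  expect_true("16:59" %in% kept$time)
  expect_false("17:00" %in% kept$time)
  none <- extract_working_window(
    data.frame(time = c("07:00", "08:59"), met = 1))
  expect_equal(nrow(none), 0L)
})

test_that("the valid-day rule is a 75 percent wear threshold", {
  expect_true(is_valid_day(360, 480))
  expect_false(is_valid_day(359, 480))
  expect_true(is_valid_day(480, 480))
})

test_that("bout metrics match the run-length oracle on random sequences", {
  expect_equal(compute_bouts(rep("SB", 30))$prolonged_sb_min, 30)
  expect_equal(compute_bouts(rep("SB", 30))$prolonged_sb_count, 1)
  broken <- c(rep("SB", 20), "LPA", rep("SB", 20))
  expect_equal(compute_bouts(broken)$prolonged_sb_count, 0)
  expect_error(compute_bouts(c("SB", "???")), "unclassified")

  set.seed(101)
  for (i in 1:200) {
    classes <- sample(c("SB", "LPA", "MVPA"), 480, replace = TRUE,
                      prob = c(0.8, 0.15, 0.05))
    wear <- runif(480) > 0.02
    mode <- if (i %% 2 == 0) "exclude" else "truncate"
    expect_equal(compute_bouts(classes, wear, long_runs = mode),
                 bouts_oracle(classes, wear, long_runs = mode),
                 ignore_attr = TRUE)
  }
})

test_that("standardization follows the x480/wear rule and conserves time", {
  expect_equal(standardize(150, 400), 180)
  expect_equal(standardize(123, 480), 123)
  expect_true(is.na(standardize(10, 0)))
  sb <- 200; lpa <- 150; mvpa <- 50
  wear <- sb + lpa + mvpa
  expect_equal(standardize(sb, wear) + standardize(lpa, wear) +
                 standardize(mvpa, wear), 480, tolerance = 1e-9)
})

test_that("epoch pipeline metrics agree with the per-day reference path", {
  set.seed(55)
  met <- ifelse(runif(480) < 0.05, 0, round(runif(480, 0.9, 4.0), 1))
  met[200:275] <- 0   # a detectable device-off block
  ep <- met_to_epochs(met)
  proc <- process_accelerometry(ep)
  d <- proc$daily

  wear <- detect_nonwear(met)
  classes <- classify_epoch(met)
  oracle <- bouts_oracle(classes, wear)
  expect_equal(d$wear_min, sum(wear))
  expect_equal(d$sb_min, sum(wear & met <= 1.5))
  expect_equal(d$lpa_min, sum(wear & met > 1.5 & met < 3))
  expect_equal(d$mvpa_min, sum(wear & met >= 3))
  expect_equal(d$prolonged_sb_min, oracle$prolonged_sb_min)
  expect_equal(d$bouted_pa_min, oracle$bouted_pa_min)
  expect_equal(d$bouted_pa_count, oracle$bouted_pa_count)
  expect_equal(d$std_sb + d$std_lpa + d$std_mvpa, 480, tolerance = 1e-9)

  # idempotence: processing the same stream twice is identical
  expect_identical(proc$daily, process_accelerometry(ep)$daily)

  # gaps are rejected
  expect_error(process_accelerometry(ep[-10]), "contiguous")
})

test_that("extending a 29-minute sitting run to 30 adds exactly one bout", {
  classes <- c(rep("SB", 29), rep("LPA", 10))
  b29 <- compute_bouts(classes)
  classes30 <- c(rep("SB", 30), rep("LPA", 10))
  b30 <- compute_bouts(classes30)
  expect_equal(b29$prolonged_sb_count, 0)
  expect_equal(b30$prolonged_sb_count, 1)
  expect_equal(b30$prolonged_sb_min, 30)
})

test_that("long activity runs are excluded or truncated per configuration", {
  classes <- c(rep("LPA", 12), rep("SB", 30))
  expect_equal(compute_bouts(classes, long_runs = "exclude")$bouted_pa_min, 0)
  tr <- compute_bouts(classes, long_runs = "truncate")
  expect_equal(tr$bouted_pa_min, 10)
  expect_equal(tr$bouted_pa_count, 1)
})

test_that("subject summaries enforce the four-valid-day inclusion rule", {
  set.seed(66)
  base_met <- round(runif(480, 0.9, 3.2), 1)
  days <- lapply(1:4, function(d)
    met_to_epochs(base_met, date = as.Date("2019-01-07") + d))
  ep4 <- data.table::rbindlist(days)
  s4 <- process_accelerometry(ep4)$subjects
  expect_true(s4$meets_inclusion)
  expect_equal(s4$n_valid_days, 4L)

  s3 <- process_accelerometry(data.table::rbindlist(days[1:3]))$subjects
  expect_false(s3$meets_inclusion)
  expect_true(is.na(s3$sb))
  expect_equal(nrow(s3), 1L)   # record retained for imputation

  # identical days: the summary equals any single day
  d1 <- process_accelerometry(days[[1]])$daily
  expect_equal(s4$sb, d1$std_sb)
  expect_equal(s4$steps, d1$std_steps)

  # summarize_subject agrees with the pipeline aggregation
  ss <- summarize_subject(as.data.frame(process_accelerometry(ep4)$daily))
  expect_equal(ss$sb, s4$sb)
  expect_equal(ss$n_valid_days, s4$n_valid_days)
})
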