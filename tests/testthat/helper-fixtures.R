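# Small configurations and independent oracles shared across test files.

small_config <- function(n_int = 12, n_ctl = 16, seed = 1,
                         epoch_mode = "markov") {
  cohort_config(n_intervention = n_int, n_control = n_ctl, seed = seed,
                wear_days = list(intervention = c(4.5, 0.5),
                                 control = c(4.5, 0.5)),
                epoch_mode = epoch_mode)
}

no_missing <- function(cfg) {
  for (v in c("age", "sex", "bmi", "manager", "accel", "k6", "uwes", "hpq",
              "attrition"))
    cfg$missingness[[v]] <- c(intervention = 0, control = 0)
  cfg$missingness$adherence <- 0
  cfg
}

# brute-force non-wear oracle: an epoch is non-wear iff some window of
# `w` consecutive zero epochs covers it (O(n * w) scan)
nonwear_oracle <- function(met, w = 60L) {
  n <- length(met)
  nonwear <- rep(FALSE, n)
  zero <- met == 0
  if (n >= w) {
    for (s in seq_len(n - w + 1L)) {
      if (all(zero[s:(s + w - 1L)])) nonwear[s:(s + w - 1L)] <- TRUE
    }
  }
  !nonwear
}

# run-length-encoding bout oracle over wear-state classes
bouts_oracle <- function(classes, wear, long_runs = "exclude") {
  state <- ifelse(!wear, "NW",
                  ifelse(classes %in% c("LPA", "MVPA"), "PA", "SB"))
  prolonged_min <- 0; prolonged_count <- 0
  bouted_min <- 0; bouted_count <- 0
  i <- 1L
  n <- length(state)
  while (i <= n) {
    j <- i
    while (j < n && state[j + 1L] == state[i]) j <- j + 1L
    len <- j - i + 1L
    if (state[i] == "SB" && len >= 30) {
      prolonged_min <- prolonged_min + len
      prolonged_count <- prolonged_count + 1
    }
    if (state[i] == "PA") {
      if (len >= 3 && len <= 10) {
        bouted_min <- bouted_min + len
        bouted_count <- bouted_count + 1
      } else if (len > 10 && long_runs == "truncate") {
        bouted_min <- bouted_min + 10
        bouted_count <- bouted_count + 1
      }
    }
    i <- j + 1L
  }
  list(prolonged_sb_min = prolonged_min, prolonged_sb_count = prolonged_count,
       bouted_pa_min = bouted_min, bouted_pa_count = bouted_count)
}

# build an epoch data.table for one worker-day from a MET vector
met_to_epochs <- function(met, worker_id = 1L, date = as.Date("2019-01-07"),
                          start_min = 540L) {
  mins <- start_min + seq_along(met) - 1L
  data.table::data.table(
    worker_id = worker_id, date = date,
    time = sprintf("%02d:%02d:00", mins %/% 60L, mins %% 60L),
    met = met, steps = 0L)
}
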