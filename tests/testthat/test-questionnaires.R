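test_that("K6 scoring sums six 0-4 items into 0-24", {
  expect_equal(score_k6(rep(4, 6)), 24)
  expect_equal(score_k6(rep(0, 6)), 0)
  expect_equal(score_k6(c(1, 2, 0, 3, 1, 1)), 8)
  expect_error(score_k6(c(5, 0, 0, 0, 0, 0)), "0-4")
  expect_error(score_k6(rep(1, 5)), "6 items")
  expect_true(is.na(score_k6(c(NA, 1, 1, 1, 1, 1))))
  # permutation invariance, matrix input
  m <- rbind(c(1, 2, 0, 3, 1, 1), c(3, 1, 1, 0, 2, 1))
  expect_equal(score_k6(m), c(8, 8))
})

test_that("work-engagement scoring is the item mean on the 0-6 scale", {
  expect_equal(score_uwes(rep(6, 9)), 6)
  expect_equal(score_uwes(rep(0, 9)), 0)
  expect_equal(score_uwes(c(3, 3, 3, 3, 3, 3, 0, 6, 3)), 3)
  expect_error(score_uwes(c(7, 1)), "0-6")
  expect_true(is.na(score_uwes(c(NA, rep(3, 8)))))
})

test_that("absolute presenteeism is a validated identity map", {
  expect_equal(score_presenteeism(10), 10)
  expect_equal(score_presenteeism(0), 0)
  expect_equal(score_presenteeism(7), 7)
  expect_error(score_presenteeism(11), "0-10")
})

test_that("adherence summaries use complete cases and normalize per time point", {
  r <- data.frame(adh_1 = c(4, 4, 1, NA), adh_2 = c(4, 3, 1, 2),
                  adh_3 = c(4, 4, 2, 4))
  s <- summarize_adherence(r)
  expect_equal(attr(s, "n_complete"), 3L)
  for (t in 1:3)
    expect_equal(sum(s$share[s$time_point == t]), 1)
  expect_equal(s$share[s$time_point == 1 & s$category == 4], 2 / 3)

  same <- data.frame(adh_1 = rep(2, 5), adh_2 = rep(2, 5), adh_3 = rep(2, 5))
  s <- summarize_adherence(same)
  expect_equal(s$share[s$category == 2], rep(1, 3))

  empty <- data.frame(adh_1 = NA, adh_2 = 1, adh_3 = 1)
  expect_warning(s0 <- summarize_adherence(empty), "no complete")
  expect_equal(nrow(s0), 0L)
})
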