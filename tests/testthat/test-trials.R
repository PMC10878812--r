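test_that("trial parsing validates the schema and rejects bad rows", {
  sched <- simulate_task_schedule(seed = 5, n_blocks = 8)
  trials <- simulate_behaviour(behaviour_params(n_per_group = 2, seed = 5),
                               sched)
  ok <- parse_trials(trials)
  expect_equal(nrow(ok), nrow(trials))
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(trials, f)
  expect_equal(nrow(parse_trials(f)), nrow(trials))
  # violations: NoGo in AllGo block, RT beyond the window, RT without response
  bad <- trials
  bad$trial_type[which(bad$block_type == "AllGo")[1]] <- "NoGo"
  i <- which(bad$responded & bad$block_type == "Mixed")[1]
  bad$rt[i] <- 1500
  j <- which(!bad$responded & bad$block_type == "Mixed")[1]
  bad$rt[j] <- 400
  expect_warning(out <- parse_trials(bad), "rejected 3")
  expect_equal(nrow(out), nrow(trials) - 3)
  expect_equal(nrow(attr(out, "rejected")), 3)
  expect_error(parse_trials(trials[, -1]), "missing column")
})

test_that("questionnaire scoring reverses negative items correctly", {
  resp <- tibble::tibble(
    scale = rep(c("extraversion", "self_esteem"), each = 10),
    item = c(1:10, 1:10),
    reversed = rep(c(rep(FALSE, 5), rep(TRUE, 5)), 2),
    value = c(rep(5, 5), rep(1, 5), rep(3, 5), rep(0, 5))
  )
  expect_equal(score_extraversion(resp), 80L)  # scale maximum
  # all-neutral extraversion alone scores 30 whatever the reversal pattern
  neut <- resp[resp$scale == "extraversion", ]
  neut$value <- 3
  expect_equal(score_extraversion(neut), 30L)
  # reversing a reversed item twice restores the original score
  twice <- resp
  twice$value[twice$reversed & twice$scale == "extraversion"] <-
    6 - (6 - twice$value[twice$reversed & twice$scale == "extraversion"])
  expect_equal(score_extraversion(twice), score_extraversion(resp))
  # violations
  miss <- resp; miss$value[3] <- NA
  expect_error(score_extraversion(miss), "missing")
  oob <- resp; oob$value[1] <- 7
  expect_error(score_extraversion(oob), "1..5")
})

test_that("descriptive statistics match hand computation", {
  tr <- tibble::tibble(
    participant_id = "P1", group = "Control",
    block_index = c(1, 1, 2, 2), block_type = c("AllGo", "AllGo", "Mixed", "Mixed"),
    trial_index = c(1, 2, 1, 2), trial_type = c("Go", "Go", "Go", "NoGo"),
    responded = c(TRUE, TRUE, FALSE, FALSE),
    rt = c(300, 500, NA, NA)
  )
  d <- descriptive_stats(tr)
  rt_row <- d[d$measure == "reaction_time_ms" & d$block_type == "AllGo", ]
  expect_equal(rt_row$mean, 400)
  expect_equal(rt_row$sd, sd(c(300, 500)))
  ce_row <- d[d$measure == "commission_errors", ]
  expect_equal(ce_row$mean, 0)  # no NoGo responses -> zero commission errors
})

test_that("commission errors never exceed the NoGo trial count", {
  sched <- simulate_task_schedule(seed = 9)
  tr <- simulate_behaviour(behaviour_params(n_per_group = 3, seed = 9,
                                            ce_means = c(Control = 70,
                                                         Synchronized = 70)),
                           sched)
  ce <- tr |>
    dplyr::filter(block_type == "Mixed", trial_type == "NoGo") |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(errors = sum(responded))
  expect_true(all(ce$errors <= 80))
})
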