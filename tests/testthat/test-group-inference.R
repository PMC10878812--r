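test_that("HbO-HbR differences and correlation classes follow the definitions", {
  est <- tidyr::expand_grid(
    participant_id = "P1", group = "Control",
    roi = c("LIFG", "RPFC"), block_type = c("AllGo", "Mixed")
  )
  vals <- tibble::tribble(
    ~roi, ~block_type, ~hbo, ~hbr,
    "LIFG", "AllGo", 2, -1,   # canonical -> d = 3, negative class
    "LIFG", "Mixed", 1.5, 1.5, # equal -> d = 0, positive class
    "RPFC", "AllGo", -2, 1,   # inverted -> d = -3, negative class
    "RPFC", "Mixed", 1, 0.5   # concordant -> positive class
  )
  est <- dplyr::left_join(est, vals, by = c("roi", "block_type")) |>
    tidyr::pivot_longer(c("hbo", "hbr"), names_to = "chromophore",
                        values_to = "beta")
  d <- hbo_hbr_difference(est)
  get <- function(r, b) d[d$roi == r & d$block_type == b, ]
  expect_equal(get("LIFG", "AllGo")$diff, 3)
  expect_equal(get("LIFG", "AllGo")$corr_class, "negative")
  expect_equal(get("LIFG", "Mixed")$diff, 0)
  expect_equal(get("LIFG", "Mixed")$corr_class, "positive")
  expect_equal(get("RPFC", "AllGo")$diff, -3)
  expect_equal(get("RPFC", "AllGo")$corr_class, "negative")
  expect_equal(get("RPFC", "Mixed")$corr_class, "positive")
  # unpaired estimates refused
  expect_error(hbo_hbr_difference(est[-1, ]), "unpaired")
  # the negative-only filter never increases the row count
  expect_lte(nrow(d[d$corr_class == "negative", ]), nrow(d))
  props <- difference_class_proportions(d)
  expect_equal(props$negative_fraction[props$roi == "LIFG" &
                                         props$block_type == "AllGo"], 1)
})

test_that("marginal contrasts match a hand-computed oracle on toy draws", {
  cells <- tidyr::expand_grid(block_type = c("AllGo", "Mixed"),
                              roi = "LIFG",
                              group = c("Control", "Synchronized")) |>
    dplyr::mutate(cell_id = dplyr::row_number())
  set.seed(12)
  draws <- tibble::tibble(
    `cellmean[1].diff` = rnorm(500, 1.0, 0.1),  # AllGo Control
    `cellmean[2].diff` = rnorm(500, 0.6, 0.1),  # AllGo Synchronized
    `cellmean[3].diff` = rnorm(500, 0.2, 0.1),  # Mixed Control
    `cellmean[4].diff` = rnorm(500, 0.1, 0.1)   # Mixed Synchronized
  )
  fit <- structure(
    list(draws = draws, effects = tibble::tibble(),
         model_info = list(cells = cells, outcomes = "diff",
                           beta_col = dyadsync:::cellmean_col)),
    class = "dyad_fit")
  cb <- contrast_marginal(fit, "block")
  m <- as.matrix(draws)
  oracle <- mean((m[, 1] - m[, 3] + m[, 2] - m[, 4]) / 2)
  expect_equal(cb$beta, oracle, tolerance = 1e-12)
  expect_equal(cb$flag, "substantial")
  cg <- contrast_marginal(fit, "group")
  oracle_allgo <- mean(m[, 1] - m[, 2])
  expect_equal(cg$beta[cg$block_type == "AllGo"], oracle_allgo,
               tolerance = 1e-12)
  expect_error(contrast_marginal(fit, "nope"))
})

test_that("multivariate model recovers cell means and flips signs under label swap", {
  est <- toy_roi_estimates(n_per_group = 8, seed = 3)
  fit <- do.call(fit_multivariate_model, c(list(est, seed = 4), fast_mcmc))
  expect_true(glance(fit)$converged)
  cb <- contrast_marginal(fit, "block")
  # generating block gap: hbo 0.8 - 1.2 = -0.4, hbr +0.4/3
  hbo <- cb[cb$outcome == "hbo", ]
  expect_lt(max(abs(hbo$beta - (-0.4))), 0.12)
  hbr <- cb[cb$outcome == "hbr", ]
  expect_lt(max(abs(hbr$beta - 0.4 / 3)), 0.12)
  # no group difference was generated
  cg <- contrast_marginal(fit, "group")
  expect_true(all(abs(cg$beta) < 0.3))
  # label swap flips group-contrast signs
  swapped <- est
  swapped$group <- ifelse(est$group == "Control", "Synchronized", "Control")
  fit2 <- do.call(fit_multivariate_model, c(list(swapped, seed = 4), fast_mcmc))
  cg2 <- contrast_marginal(fit2, "group")
  j <- dplyr::inner_join(cg, cg2, by = c("roi", "block_type", "outcome"))
  expect_equal(j$beta.x, -j$beta.y, tolerance = 0.15)
  # independent outcomes: residual-correlation posterior covers zero
  rc <- tidy(fit)[tidy(fit)$effect == "residual_cor_hbo_hbr", ]
  expect_true(rc$hpd_lo <= 0 && rc$hpd_hi >= 0)
})

test_that("contrasts are invariant to ROI level ordering", {
  est <- toy_roi_estimates(n_per_group = 6, seed = 8)
  fit <- do.call(fit_multivariate_model, c(list(est, seed = 9), fast_mcmc))
  est_rev <- est[order(est$roi, decreasing = TRUE), ]
  fit_rev <- do.call(fit_multivariate_model, c(list(est_rev, seed = 9),
                                               fast_mcmc))
  a <- contrast_marginal(fit, "block") |> dplyr::arrange(roi, outcome)
  b <- contrast_marginal(fit_rev, "block") |> dplyr::arrange(roi, outcome)
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
})

test_that("difference model filter isolates cortical truth under contamination", {
  # cortical rows generated around the true cell means; contaminated rows
  # (sign-concordant "systemic" pairs) pushed far positive
  est <- toy_roi_estimates(n_per_group = 10, seed = 5, sd_id = 0.1)
  d <- hbo_hbr_difference(est)
  contam <- d[d$participant_id %in% sprintf("T%03d", 1:4), ]
  contam$hbo <- 4 + 0.1 * contam$hbo
  contam$hbr <- 0.5 + 0.1 * abs(contam$hbr)  # concordant signs, unequal size
  contam$diff <- contam$hbo - contam$hbr
  contam$corr_class <- "positive"
  mixed <- dplyr::bind_rows(d[!(d$participant_id %in% contam$participant_id), ],
                            contam)
  f_all <- do.call(fit_difference_model,
                   c(list(mixed, filter = "all", seed = 6), fast_mcmc))
  f_neg <- do.call(fit_difference_model,
                   c(list(mixed, filter = "negative_only", seed = 6),
                     fast_mcmc))
  truth_allgo <- 0.8 + 0.8 / 3  # generating hbo - hbr, AllGo cells
  cells <- f_neg$model_info$cells
  cell_est <- function(fit) {
    e <- tidy(fit)
    mean(e$estimate[grepl("AllGo", e$effect)])
  }
  err_neg <- abs(cell_est(f_neg) - truth_allgo)
  err_all <- abs(cell_est(f_all) - truth_allgo)
  expect_lt(err_neg, err_all)
  # with all rows negative-class the two filters coincide
  dneg <- d[d$corr_class == "negative", ]
  f1 <- do.call(fit_difference_model, c(list(dneg, filter = "all", seed = 7),
                                        fast_mcmc))
  f2 <- do.call(fit_difference_model, c(list(dneg, filter = "negative_only",
                                             seed = 7), fast_mcmc))
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-9)
})

test_that("brain-behaviour model recovers a localized RT slope", {
  est <- toy_roi_estimates(n_per_group = 12, seed = 10, sd_id = 0.1,
                           sd_resid = 0.1)
  d <- hbo_hbr_difference(est)
  set.seed(10)
  beh <- tibble::tibble(
    participant_id = unique(d$participant_id),
    mean_rt = rnorm(dplyr::n_distinct(d$participant_id), 375, 30),
    commission_errors = rpois(dplyr::n_distinct(d$participant_id), 15)
  )
  # inject a positive RT slope only in (LIFG, Mixed, Synchronized)
  d2 <- dplyr::left_join(d, beh, by = "participant_id")
  sel <- d2$roi == "LIFG" & d2$block_type == "Mixed" &
    d2$group == "Synchronized"
  d2$diff[sel] <- d2$diff[sel] + 0.02 * (d2$mean_rt[sel] - 375)
  fit <- do.call(fit_brain_behaviour_model,
                 c(list(d2[, names(d)], beh, seed = 11), fast_mcmc))
  eff <- tidy(fit)
  slopes <- eff[grepl("rt_slope_per_ms$", eff$effect), ]
  hot <- slopes[grepl("LIFG.Mixed.Synchronized", slopes$effect), ]
  expect_lt(abs(hot$estimate - 0.02), 0.01)
  cold <- slopes[!grepl("LIFG.Mixed.Synchronized", slopes$effect), ]
  expect_true(all(abs(cold$estimate) < 0.01))
  # sign convention: larger RT with larger difference gives a positive slope
  expect_gt(hot$estimate, 0)
})
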