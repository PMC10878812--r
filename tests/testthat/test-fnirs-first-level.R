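test_that("downsampling preserves the passband and kills the stopband", {
  rate <- 4.5
  t <- (0:4499) / rate  # 1000 s
  slow <- sin(2 * pi * 0.05 * t)
  fast <- sin(2 * pi * 1.5 * t)
  s <- bare_series(cbind(1 + 0.1 * slow, 1 + 0.1 * fast, rep(2, length(t))),
                   rate)
  ds <- downsample_fnirs(s, 0.6)
  expect_equal(ds$rate, 0.6)
  mid <- ds$time > 100 & ds$time < 900  # away from edges
  amp_slow <- (max(ds$values[mid, 1]) - min(ds$values[mid, 1])) / 2
  amp_fast <- (max(ds$values[mid, 2]) - min(ds$values[mid, 2])) / 2
  expect_equal(amp_slow, 0.1, tolerance = 0.01)   # below target Nyquist
  expect_lt(amp_fast, 0.1 * 0.1)                  # attenuated > 90%
  expect_equal(unique(ds$values[, 3]), 2, tolerance = 1e-9)  # constant
  expect_error(downsample_fnirs(ds, 0.6), "below the current rate")
})

test_that("optical density conversion matches the log-ratio closed form", {
  set.seed(6)
  v <- matrix(exp(rnorm(400, 0, 0.05)), 100, 4)
  s <- bare_series(v, 4.5)
  od <- intensity_to_od(s)
  expect_equal(od$values, -log(sweep(v, 2, colMeans(v), "/")),
               tolerance = 1e-12)
  # constant intensity gives OD identically zero
  s0 <- bare_series(matrix(3, 50, 4), 4.5)
  expect_true(all(intensity_to_od(s0)$values == 0))
  # a doubled sample maps to -ln 2 up to the mean shift
  v2 <- matrix(1, 60, 4); v2[30, 1] <- 2
  od2 <- intensity_to_od(bare_series(v2, 4.5))
  expect_equal(od2$values[30, 1] - od2$values[1, 1], -log(2),
               tolerance = 1e-12)
  vneg <- v; vneg[5, 2] <- -1
  expect_error(intensity_to_od(bare_series(vneg, 4.5)), "non-positive")
})

test_that("Beer-Lambert inversion round-trips and matches manual elimination", {
  mont <- tiny_montage()
  ev <- tibble::tibble(onset = 30, condition = "AllGo", duration = 16)
  raw <- simulate_fnirs(fnirs_params(systemic_amplitude = 0.5, noise_sd = 0.2,
                                     seed = 4), ev, mont, duration_s = 120)
  h <- od_to_haemoglobin(intensity_to_od(downsample_fnirs(raw)))
  expect_true(all(is.finite(h$values)))
  # forward-generate OD from known concentrations and invert exactly
  E <- dyadsync:::EXTINCTION
  hbo <- 1.3; hbr <- -0.4  # uM
  L_cm <- 3; ppf <- 0.1
  od760 <- (E["760", "hbo"] * hbo + E["760", "hbr"] * hbr) * 1e-6 * L_cm * ppf
  od850 <- (E["850", "hbo"] * hbo + E["850", "hbr"] * hbr) * 1e-6 * L_cm * ppf
  # manual 2x2 elimination (Cramer's rule)
  det <- E["760", "hbo"] * E["850", "hbr"] - E["760", "hbr"] * E["850", "hbo"]
  hbo_hat <- (od760 * E["850", "hbr"] - od850 * E["760", "hbr"]) /
    det / (L_cm * ppf) * 1e6
  hbr_hat <- (E["760", "hbo"] * od850 - E["850", "hbo"] * od760) /
    det / (L_cm * ppf) * 1e6
  expect_equal(hbo_hat, hbo, tolerance = 1e-9)
  expect_equal(hbr_hat, hbr, tolerance = 1e-9)
  # and the packaged inversion agrees on a constructed series
  odv <- matrix(c(od760, od850), nrow = 10, ncol = 2, byrow = TRUE)
  info <- tibble::tibble(channel = "LIFG_L01", wavelength = c(760L, 850L)) |>
    dplyr::left_join(mont, by = "channel")
  od_s <- dyadsync:::new_fnirs_series(
    odv, info, (1:10) / 4.5, 4.5, mont,
    tibble::tibble(onset = numeric(0), condition = character(0)), "od")
  hh <- od_to_haemoglobin(od_s)
  expect_equal(unique(hh$values[, 1]), hbo, tolerance = 1e-9)
  expect_equal(unique(hh$values[, 2]), hbr, tolerance = 1e-9)
})

test_that("design matrix has the documented structure", {
  ev <- tibble::tibble(onset = c(40, 120), condition = c("AllGo", "Mixed"))
  n <- 240; rate <- 0.6
  X <- build_design_matrix(ev, n, rate)
  expect_true(all(c("task_AllGo", "task_Mixed", "const") %in% colnames(X)))
  # drift columns span frequencies at or below 0.01 Hz: K = floor(0.01*2n/rate)
  expect_equal(sum(grepl("^drift_", colnames(X))), floor(0.01 * 2 * n / rate))
  # single-event regressor peaks after the boxcar + HRF lag, then returns
  tk <- X[, "task_AllGo"]
  pk <- which.max(tk)
  peak_t <- (pk - 1) / rate
  expect_gt(peak_t, 40 + 10); expect_lt(peak_t, 40 + 30)
  expect_lt(abs(tk[n]), 0.05)
  expect_equal(max(tk), 1, tolerance = 0.05)  # isolated block peaks near 1
  # no events: only drift + constant
  X0 <- build_design_matrix(ev[0, ], n, rate)
  expect_true(all(grepl("^drift_|^const", colnames(X0))))
  expect_error(build_design_matrix(tibble::tibble(onset = 1e4,
                                                  condition = "AllGo"),
                                   n, rate), "beyond the end")
  # short-channel PCs: at most one per series, orthogonal columns
  set.seed(3)
  sc <- matrix(rnorm(n * 4), n, 4)
  colnames(sc) <- c("S1.hbo", "S2.hbo", "S1.hbr", "S2.hbr")
  Xs <- build_design_matrix(ev, n, rate, short_channels = sc)
  pcs <- Xs[, grepl("^shortpc_", colnames(Xs)), drop = FALSE]
  expect_equal(ncol(pcs), 4)
  hbo_pcs <- pcs[, grepl("hbo", colnames(pcs))]
  expect_equal(crossprod(hbo_pcs)[1, 2], 0, tolerance = 1e-8)
})

test_that("AR(1) GLM recovers noise-free amplitudes exactly through the pipeline", {
  mont <- tiny_montage()
  sched <- simulate_task_schedule(41, n_blocks = 6)
  ev <- schedule_events(sched)
  amp <- dyadsync:::default_amplitudes(unique(mont$roi))
  raw <- simulate_fnirs(fnirs_params(systemic_amplitude = 0, ar1_rho = 0,
                                     noise_sd = 0, seed = 1), ev, mont)
  fl <- fnirs_first_level(raw)
  m <- dplyr::inner_join(
    fl$roi_estimates, amp,
    by = c("roi", "condition" = "block_type", "chromophore"))
  expect_equal(m$beta, m$amplitude, tolerance = 1e-6)
  # end-to-end linearity: doubling the amplitude doubles the estimate
  amp2 <- amp; amp2$amplitude <- amp2$amplitude * 2
  raw2 <- simulate_fnirs(fnirs_params(true_amplitude = amp2,
                                      systemic_amplitude = 0, ar1_rho = 0,
                                      noise_sd = 0, seed = 1), ev, mont)
  fl2 <- fnirs_first_level(raw2)
  expect_equal(fl2$roi_estimates$beta, 2 * fl$roi_estimates$beta,
               tolerance = 1e-6)
})

test_that("AR(1) standard errors are calibrated where OLS underestimates", {
  mont <- default_montage(long_per_roi = c(LIFG = 1), n_short = 0)
  ev <- schedule_events(simulate_task_schedule(5, n_blocks = 6))
  res <- vapply(1:150, function(r) {
    raw <- simulate_fnirs(fnirs_params(systemic_amplitude = 0, ar1_rho = 0.8,
                                       noise_sd = 0.8, seed = r), ev, mont)
    h <- od_to_haemoglobin(intensity_to_od(downsample_fnirs(raw)))
    X <- build_design_matrix(h$events, nrow(h$values), h$rate,
                             native_rate = h$native_rate,
                             native_n = h$native_n)
    b <- fit_glm_ar1(h, X)
    b1 <- b[b$chromophore == "hbo" & b$condition == "AllGo", ]
    y <- h$values[, which(h$info$chromophore == "hbo")[1]]
    ols <- stats::lm.fit(X, y)
    s2 <- sum(ols$residuals^2) / (length(y) - ncol(X))
    se_ols <- sqrt(diag(solve(crossprod(X)) * s2))[1]
    c(b1$beta, b1$se, se_ols)
  }, numeric(3))
  truth <- 0.8
  cover_ar1 <- mean(abs(res[1, ] - truth) <= 1.96 * res[2, ])
  cover_ols <- mean(abs(res[1, ] - truth) <= 1.96 * res[3, ])
  expect_gt(cover_ar1, 0.87)
  expect_lt(cover_ols, cover_ar1)
  # rho ~ 0 data: AR(1) fit agrees with OLS
  raw0 <- simulate_fnirs(fnirs_params(systemic_amplitude = 0, ar1_rho = 0,
                                      noise_sd = 0.5, seed = 7), ev, mont)
  h0 <- od_to_haemoglobin(intensity_to_od(downsample_fnirs(raw0)))
  X0 <- build_design_matrix(h0$events, nrow(h0$values), h0$rate,
                            native_rate = h0$native_rate,
                            native_n = h0$native_n)
  b0 <- fit_glm_ar1(h0, X0)
  y0 <- h0$values[, 1]
  ols0 <- stats::lm.fit(X0, y0)
  expect_equal(b0$beta[b0$chromophore == "hbo" & b0$condition == "AllGo"][1],
               unname(ols0$coefficients["task_AllGo"]), tolerance = 0.05)
})

test_that("channel selection and ROI pooling follow the stated rules", {
  betas <- tibble::tibble(
    channel = c("a", "b", "c"), chromophore = "hbo",
    roi = "LIFG", separation_mm = c(8, 30, 45), is_short = c(TRUE, FALSE, FALSE),
    condition = "AllGo", beta = 1:3, se = 1, rho = 0
  )
  kept <- select_long_channels(betas)
  expect_equal(kept$channel, "b")
  # inverse-variance pooling hand example: beta {2, 4}, SE {1, 2} -> 2.4
  two <- tibble::tibble(
    channel = c("x", "y"), chromophore = "hbo", roi = "LIFG",
    separation_mm = 30, is_short = FALSE, condition = "AllGo",
    beta = c(2, 4), se = c(1, 2), rho = 0
  )
  pooled <- roi_average(two)
  expect_equal(pooled$beta, 2.4)
  expect_equal(pooled$se, 1 / sqrt(1 + 0.25))
  # equal SEs reduce to the arithmetic mean, and a huge-SE channel vanishes
  two$se <- c(1, 1)
  expect_equal(roi_average(two)$beta, 3)
  two$se <- c(1, 1e6)
  expect_equal(roi_average(two)$beta, 2, tolerance = 1e-6)
  # pooled SE decreases monotonically as channels accumulate
  many <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(two[1, ], channel = paste0("c", i))
  }))
  ses <- vapply(1:4, function(k) roi_average(many[1:k, ])$se, numeric(1))
  expect_true(all(diff(ses) < 0))
  # an ROI with no channels is flagged missing, not zero
  mont <- tiny_montage()
  expect_warning(full <- roi_average(two[1, ], mont), "RPFC")
  expect_true(is.na(full$beta[full$roi == "RPFC"][1]))
})

test_that("drift regressors absorb sub-0.01 Hz components", {
  mont <- default_montage(long_per_roi = c(LIFG = 1), n_short = 0)
  ev <- schedule_events(simulate_task_schedule(6, n_blocks = 6))
  raw <- simulate_fnirs(fnirs_params(systemic_amplitude = 0, ar1_rho = 0,
                                     noise_sd = 0, seed = 2), ev, mont)
  beta0 <- fnirs_first_level(raw)$roi_estimates
  # inject a slow additive component into the intensity-domain signal
  # (0.0012 OD ~ a 2 uM haemoglobin excursion at 30 mm separation)
  slow <- 0.0012 * sin(2 * pi * 0.004 * raw$time)
  raw2 <- raw
  raw2$values <- raw$values * exp(-slow)  # multiplicative in intensity = additive in OD
  beta1 <- fnirs_first_level(raw2)$roi_estimates
  expect_equal(beta1$beta, beta0$beta, tolerance = 0.02)
})
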