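test_that("median imputation fills missing keypoints and leaves the rest", {
  x <- matrix(rep(c(1, 2, 3, 4, 100), 7), ncol = 7)
  y <- x + 10
  conf <- matrix(0.9, 5, 7)
  conf[3, 2] <- 0  # l_shoulder missing in frame 3
  s <- kp_series(x, y, conf)
  out <- impute_missing(s)
  # median of the observed {1, 2, 4, 100} is 3
  expect_equal(out$x[out$frame == 3 & out$joint == "l_shoulder"], 3)
  expect_equal(out$y[out$frame == 3 & out$joint == "l_shoulder"], 13)
  untouched <- out[!(out$frame == 3 & out$joint == "l_shoulder"), ]
  orig <- s[!(s$frame == 3 & s$joint == "l_shoulder"), ]
  expect_equal(untouched$x, orig$x)
  # no missing values: identity
  s2 <- kp_series(x, y)
  expect_equal(impute_missing(s2)$x, s2$x)
  # all but one missing: every frame takes the single observed value
  conf3 <- matrix(0.9, 5, 7); conf3[2:5, 1] <- 0
  out3 <- impute_missing(kp_series(x, y, conf3))
  expect_true(all(out3$x[out3$joint == "neck"] == x[1, 1]))
  # never-observed joint errors with its name
  conf4 <- matrix(0.9, 5, 7); conf4[, 4] <- 0
  expect_error(impute_missing(kp_series(x, y, conf4)), "l_elbow")
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  t <- 1:40
  quad <- 2 + 0.5 * t - 0.01 * t^2
  x <- matrix(rep(quad, 7), ncol = 7)
  s <- kp_series(x, x)
  out <- smooth_series(s)
  expect_equal(out$x, s$x, tolerance = 1e-10)
  # constant series unchanged
  s0 <- kp_series(matrix(5, 40, 7), matrix(7, 40, 7))
  expect_equal(smooth_series(s0)$x, s0$x, tolerance = 1e-12)
  # smoothing a noisy sinusoid reduces variance about the clean signal
  set.seed(1)
  clean <- 100 + 30 * sin(2 * pi * (1:200) / 80)
  noisy <- clean + rnorm(200, 0, 5)
  sn <- kp_series(matrix(rep(noisy, 7), ncol = 7),
                  matrix(rep(clean, 7), ncol = 7))
  sm <- smooth_series(sn)
  v_in <- mean((noisy - clean)^2)
  v_out <- mean((sm$x[sm$joint == "neck"] - clean)^2)
  expect_lt(v_out, v_in)
  # series shorter than the window errors
  expect_error(smooth_series(kp_series(matrix(1, 5, 7), matrix(1, 5, 7))),
               "shorter")
})

test_that("pose matrix matches the brute-force pairwise distances", {
  p <- toy_pose(seed = 42, jitter = 20)
  D <- pose_matrix(p)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:7) for (j in 1:7) {
    expect_equal(D[i, j], sqrt(sum((p[i, ] - p[j, ])^2)))
  }
  # 3-4-5 triangle
  p2 <- matrix(0, 7, 2); p2[2, ] <- c(3, 4)
  expect_equal(pose_matrix(p2)[1, 2], 5)
  # degenerate pose gives the zero matrix
  expect_true(all(pose_matrix(matrix(1, 7, 2)) == 0))
  expect_error(pose_matrix(matrix(c(NA, rep(1, 13)), 7, 2)), "non-finite")
})

test_that("laplacian similarity agrees with an independent oracle", {
  set.seed(99)
  for (k in 1:20) {
    A <- pose_matrix(toy_pose(jitter = 40))
    B <- pose_matrix(toy_pose(jitter = 40))
    expect_equal(laplacian_similarity(A, B),
                 oracle_laplacian_score(A, B, similarity_gain()),
                 tolerance = 1e-12)
  }
})

test_that("similarity score has the documented identities and invariances", {
  set.seed(7)
  A <- pose_matrix(toy_pose(jitter = 30))
  B <- pose_matrix(toy_pose(jitter = 30))
  expect_equal(laplacian_similarity(A, A), 1)
  expect_equal(laplacian_similarity(A, 2 * A), 1)  # isotropic scaling
  expect_equal(laplacian_similarity(A, B), laplacian_similarity(B, A))
  s <- laplacian_similarity(A, B)
  expect_gt(s, 0); expect_lte(s, 1)
  # rotation + translation of the underlying pose leaves the score unchanged
  p <- toy_pose(jitter = 30)
  s_ref <- laplacian_similarity(pose_matrix(p), B)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  p_rot <- sweep(p %*% R, 2, c(55, -20), "+")
  expect_equal(laplacian_similarity(pose_matrix(p_rot), B), s_ref,
               tolerance = 1e-9)
  # degenerate poses
  Z <- pose_matrix(matrix(3, 7, 2))
  expect_warning(s0 <- laplacian_similarity(A, Z), "degenerate")
  expect_equal(s0, 0)
  expect_equal(laplacian_similarity(Z, Z), 1)
})

test_that("expected similarity degrades monotonically with added noise", {
  set.seed(31)
  n <- 120
  base <- simulate_dyad_motion(motion_params(
    duration_s = n / 30, kinematic_noise_sd = 0, dropout_rate = 0,
    mirror_lag_s = 0, seed = 5))
  means <- vapply(c(0, 5, 15, 40), function(sd_px) {
    b <- base$confederate
    b$x <- b$x + rnorm(nrow(b), 0, sd_px)
    b$y <- b$y + rnorm(nrow(b), 0, sd_px)
    attr(dyad_similarity(base$participant, b), "mean")
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("dyad similarity trace matches per-frame scoring and handles length mismatch", {
  dm <- simulate_dyad_motion(motion_params(duration_s = 3, dropout_rate = 0,
                                           seed = 8))
  tr <- dyad_similarity(dm$participant, dm$confederate)
  expect_true(all(tr$score >= 0 & tr$score <= 1))
  expect_equal(attr(tr, "mean"), mean(tr$score))
  # identical series give mean exactly 1
  tr_same <- dyad_similarity(dm$participant, dm$participant)
  expect_equal(attr(tr_same, "mean"), 1)
  # per-frame scores equal the public single-frame operation after the same
  # preprocessing (vectorised path vs matrix path)
  pa <- impute_missing(dm$participant) |> smooth_series()
  pb <- impute_missing(dm$confederate) |> smooth_series()
  f <- 37
  A <- pose_matrix(pa[pa$frame == f, c("joint", "x", "y")])
  B <- pose_matrix(pb[pb$frame == f, c("joint", "x", "y")])
  expect_equal(tr$score[tr$frame == f], laplacian_similarity(A, B),
               tolerance = 1e-12)
  # truncation warning on unequal frame counts
  short <- dm$confederate[dm$confederate$frame <= 60, ]
  expect_warning(tr2 <- dyad_similarity(dm$participant, short), "truncating")
  expect_equal(attr(tr2, "n_frames"), 60)
})
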