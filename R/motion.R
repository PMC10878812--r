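# Synthetic dyadic upper-body motion in keypoint form.

# Upper-body joints tracked throughout the package, in fixed order.
pose_joints <- function() {
  c("neck", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
    "l_wrist", "r_wrist")
}

#' Parameters for the dyad motion generator
#'
#' The `synchronized` regime emulates a mirror game: the confederate's
#' trajectory is a horizontally mirrored, lagged, noise-perturbed copy of the
#' participant's smooth random arm movement. The `control` regime emulates a
#' movement-observation activity: the two people move independently, each
#' taking one turn as the sole mover while the other sits near-still.
#' Defaults (lag, kinematic noise, movement amplitude) are packaged
#' calibration constants, tuned once against the similarity scorer so the
#' regimes reproduce the study-level mean similarity scores; they are not
#' meant to be retuned per run.
#'
#' @param regime `"synchronized"` or `"control"`.
#' @param duration_s recording duration, seconds (default 300 = two 2:30
#'   leadership turns).
#' @param fps video frame rate, frames/s.
#' @param mirror_lag_s follower lag in the synchronized regime, seconds.
#' @param kinematic_noise_sd keypoint measurement noise SD, pixels, applied
#'   to both people.
#' @param dropout_rate fraction of keypoints emitted as missing
#'   (confidence 0).
#' @param move_amp arm angular excursion SD, radians (movement vigour).
#' @param seed integer seed.
#' @return A list of class `motion_params`.
#' @export
motion_params <- function(regime = c("synchronized", "control"),
                          duration_s = 300, fps = 30,
                          mirror_lag_s = 0.1,
                          kinematic_noise_sd = 4,
                          dropout_rate = 0.02,
                          move_amp = 0.55,
                          seed = 1L) {
  regime <- match.arg(regime)
  vals <- c(duration_s, fps, mirror_lag_s, kinematic_noise_sd, dropout_rate,
            move_amp)
  if (!all(is.finite(vals))) stop("motion_params(): non-finite parameter")
  stopifnot(duration_s > 0, fps > 0, dropout_rate >= 0, dropout_rate < 1,
            mirror_lag_s >= 0, kinematic_noise_sd >= 0, move_amp >= 0)
  structure(
    list(regime = regime, duration_s = duration_s, fps = fps,
         mirror_lag_s = mirror_lag_s, kinematic_noise_sd = kinematic_noise_sd,
         dropout_rate = dropout_rate, move_amp = move_amp,
         seed = as.integer(seed)),
    class = "motion_params"
  )
}

# Smooth band-limited angle trajectory: sum of 2-4 random-phase sinusoids,
# rescaled to standard deviation `amp`.
angle_trajectory <- function(t, amp, f_lo = 0.05, f_hi = 0.4) {
  k <- sample(2:4, 1)
  f <- runif(k, f_lo, f_hi)
  ph <- runif(k, 0, 2 * pi)
  a <- runif(k, 0.5, 1)
  x <- colSums(a * sin(outer(2 * pi * f, t) + ph))
  if (stats::sd(x) > 0) x <- x * (amp / stats::sd(x))
  x
}

# One person's joint coordinates (n x 7 matrices x/y) from arm angle
# trajectories. Angles are measured from straight-down; y grows downward
# (image convention). `sway` adds slight whole-body motion.
pose_from_angles <- function(th_l, th_r, ph_l, ph_r, cx = 320, sway = 2) {
  n <- length(th_l)
  t_idx <- seq_len(n)
  sway_x <- sway * sin(2 * pi * 0.05 * t_idx / 30)
  neck <- cbind(cx + sway_x, 140 + 0.5 * sway_x)
  lsho <- cbind(neck[, 1] - 85, neck[, 2] + 30)
  rsho <- cbind(neck[, 1] + 85, neck[, 2] + 30)
  lelb <- lsho + 120 * cbind(sin(th_l - 0.2), cos(th_l - 0.2))
  relb <- rsho + 120 * cbind(sin(th_r + 0.2), cos(th_r + 0.2))
  lwri <- lelb + 110 * cbind(sin(ph_l - 0.2), cos(ph_l - 0.2))
  rwri <- relb + 110 * cbind(sin(ph_r + 0.2), cos(ph_r + 0.2))
  xs <- cbind(neck[, 1], lsho[, 1], rsho[, 1], lelb[, 1], relb[, 1],
              lwri[, 1], rwri[, 1])
  ys <- cbind(neck[, 2], lsho[, 2], rsho[, 2], lelb[, 2], relb[, 2],
              lwri[, 2], rwri[, 2])
  colnames(xs) <- colnames(ys) <- pose_joints()
  list(x = xs, y = ys)
}

# Random moving-arm angle set for one person over frames `t` (seconds).
moving_angles <- function(t, amp) {
  list(
    th_l = -angle_trajectory(t, amp), th_r = angle_trajectory(t, amp),
    ph_l = -angle_trajectory(t, amp * 1.3), ph_r = angle_trajectory(t, amp * 1.3)
  )
}

# Near-still resting angles (tiny sway only).
resting_angles <- function(t) {
  list(
    th_l = -angle_trajectory(t, 0.02), th_r = angle_trajectory(t, 0.02),
    ph_l = -angle_trajectory(t, 0.03), ph_r = angle_trajectory(t, 0.03)
  )
}

coords_to_series <- function(xy, person_id, fps, noise_sd, dropout_rate) {
  n <- nrow(xy$x)
  jn <- pose_joints()
  x <- xy$x + matrix(rnorm(n * 7, 0, noise_sd), n, 7)
  y <- xy$y + matrix(rnorm(n * 7, 0, noise_sd), n, 7)
  conf <- matrix(runif(n * 7, 0.5, 0.95), n, 7)
  if (dropout_rate > 0) {
    drop <- matrix(runif(n * 7) < dropout_rate, n, 7)
    x[drop] <- 0; y[drop] <- 0; conf[drop] <- 0
  }
  out <- tibble::tibble(
    frame = rep(seq_len(n), times = 7),
    joint = rep(jn, each = n),
    x = as.vector(x), y = as.vector(y), confidence = as.vector(conf)
  ) |>
    dplyr::arrange(.data$frame, match(.data$joint, jn))
  attr(out, "person_id") <- person_id
  attr(out, "fps") <- fps
  class(out) <- c("keypoint_series", class(out))
  out
}

#' Simulate dyadic upper-body motion
#'
#' Generates two keypoint series (participant and confederate) under the
#' regime described in [motion_params()]. In the synchronized regime the
#' confederate reproduces the participant's pose reflected about the
#' inter-person axis after `mirror_lag_s`; the reflected copy keeps the same
#' joint names, so with zero lag and zero noise the two pose-distance
#' matrices are identical frame by frame (reflection is an isometry) and the
#' similarity score is exactly 1.
#'
#' @param params a [motion_params()] object.
#' @return List of class `dyad_motion` with elements `participant` and
#'   `confederate` (keypoint tibbles: `frame`, `joint`, `x`, `y`,
#'   `confidence`), `fps`, and the generating `params`.
#' @examples
#' dm <- simulate_dyad_motion(motion_params(duration_s = 4, seed = 2))
#' @export
simulate_dyad_motion <- function(params = motion_params()) {
  stopifnot(inherits(params, "motion_params"))
  with_seed(params$seed, {
    n <- round(params$duration_s * params$fps)
    if (n < 2) stop("duration_s * fps must give at least 2 frames")
    t <- seq_len(n) / params$fps
    if (params$regime == "synchronized") {
      ang <- moving_angles(t, params$move_amp)
      p <- pose_from_angles(ang$th_l, ang$th_r, ang$ph_l, ang$ph_r)
      lag <- round(params$mirror_lag_s * params$fps)
      shift <- function(m) m[pmax(seq_len(n) - lag, 1), , drop = FALSE]
      # reflect about the participant's centreline, then seat the
      # confederate in the right half of the combined frame
      cx <- 320
      c_xy <- list(x = 2 * cx - shift(p$x) + 640, y = shift(p$y))
    } else {
      half <- floor(n / 2)
      seg <- c(rep(1L, half), rep(2L, n - half))
      # confederate moves first, participant second (control protocol)
      conf_ang <- moving_angles(t, params$move_amp)
      part_ang <- moving_angles(t, params$move_amp)
      conf_rest <- resting_angles(t)
      part_rest <- resting_angles(t)
      pick <- function(mov, rest, active) {
        lapply(setNames(names(mov), names(mov)), function(nm) {
          ifelse(seg == active, mov[[nm]], rest[[nm]])
        })
      }
      ca <- pick(conf_ang, conf_rest, 1L)
      pa <- pick(part_ang, part_rest, 2L)
      p <- pose_from_angles(pa$th_l, pa$th_r, pa$ph_l, pa$ph_r)
      c_xy <- pose_from_angles(ca$th_l, ca$th_r, ca$ph_l, ca$ph_r, cx = 960)
    }
    structure(
      list(
        participant = coords_to_series(p, "participant", params$fps,
                                       params$kinematic_noise_sd,
                                       params$dropout_rate),
        confederate = coords_to_series(c_xy, "confederate", params$fps,
                                       params$kinematic_noise_sd,
                                       params$dropout_rate),
        fps = params$fps, params = params
      ),
      class = "dyad_motion"
    )
  })
}
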