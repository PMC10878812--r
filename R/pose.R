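# Pose-similarity scoring: imputation, smoothing, pose matrices and the
# graph-Laplacian similarity score.

# Packaged sensitivity constant of the similarity map (see
# laplacian_similarity). Calibrated once against the motion generator so the
# two movement regimes reproduce the study-level mean scores; frozen.
SIMILARITY_GAIN <- 3.9

#' Sensitivity constant of the Laplacian similarity score
#'
#' @return The packaged gain constant `k` used in
#'   `score = 1 / (1 + k * ||L_a - L_b||_F)`.
#' @export
similarity_gain <- function() SIMILARITY_GAIN

# ---- keypoint series helpers -----------------------------------------------

as_keypoint_matrixes <- function(series) {
  jn <- pose_joints()
  stopifnot(all(c("frame", "joint", "x", "y", "confidence") %in% names(series)))
  frames <- sort(unique(series$frame))
  get <- function(col) {
    m <- matrix(NA_real_, length(frames), length(jn),
                dimnames = list(NULL, jn))
    idx <- cbind(match(series$frame, frames), match(series$joint, jn))
    m[idx] <- series[[col]]
    m
  }
  list(frames = frames, x = get("x"), y = get("y"), conf = get("confidence"))
}

matrixes_to_series <- function(km, template) {
  jn <- pose_joints()
  out <- tibble::tibble(
    frame = rep(km$frames, times = length(jn)),
    joint = rep(jn, each = length(km$frames)),
    x = as.vector(km$x), y = as.vector(km$y),
    confidence = as.vector(km$conf)
  ) |>
    dplyr::arrange(.data$frame, match(.data$joint, jn))
  attr(out, "person_id") <- attr(template, "person_id")
  attr(out, "fps") <- attr(template, "fps")
  class(out) <- c("keypoint_series", class(out))
  out
}

# Missing = confidence 0 or non-finite coordinates.
missing_mask <- function(km) {
  (!is.finite(km$x)) | (!is.finite(km$y)) | km$conf == 0 | is.na(km$conf)
}

#' Impute missing keypoints with the per-joint median
#'
#' Replaces every missing coordinate (confidence 0 or `NA`) by the median of
#' that joint's observed values over the whole recording; observed values
#' are untouched.
#'
#' @param series a keypoint tibble (`frame`, `joint`, `x`, `y`,
#'   `confidence`).
#' @return The series with missing coordinates filled in (their confidence
#'   left at 0 for provenance).
#' @export
impute_missing <- function(series) {
  km <- as_keypoint_matrixes(series)
  miss <- missing_mask(km)
  for (j in seq_len(ncol(km$x))) {
    mj <- miss[, j]
    if (all(mj)) {
      stop(sprintf("impute_missing(): joint '%s' is never observed",
                   colnames(km$x)[j]))
    }
    if (any(mj)) {
      km$x[mj, j] <- median(km$x[!mj, j])
      km$y[mj, j] <- median(km$y[!mj, j])
    }
  }
  matrixes_to_series(km, series)
}

#' Savitzky-Golay smoothing of joint trajectories
#'
#' Applies a Savitzky-Golay filter (default window 13 frames, polynomial
#' order 2) independently to each joint's x and y timeseries. Polynomials of
#' degree at most `polyorder` pass through unchanged.
#'
#' @param series a keypoint tibble with no missing coordinates (run
#'   [impute_missing()] first).
#' @param window odd filter window length, frames.
#' @param polyorder polynomial order, less than `window`.
#' @return The smoothed series.
#' @export
smooth_series <- function(series, window = 13L, polyorder = 2L) {
  stopifnot(window %% 2 == 1, polyorder < window)
  km <- as_keypoint_matrixes(series)
  if (length(km$frames) < window) {
    stop(sprintf("smooth_series(): series length %d is shorter than window %d",
                 length(km$frames), window))
  }
  check_finite(km$x, "keypoint x coordinates")
  check_finite(km$y, "keypoint y coordinates")
  for (j in seq_len(ncol(km$x))) {
    km$x[, j] <- signal::sgolayfilt(km$x[, j], p = polyorder, n = window)
    km$y[, j] <- signal::sgolayfilt(km$y[, j], p = polyorder, n = window)
  }
  matrixes_to_series(km, series)
}

#' Pose matrix: pairwise Euclidean distances between joints
#'
#' @param pose a data frame with columns `joint`, `x`, `y` (one frame), or a
#'   two-column matrix of coordinates with joints as rows.
#' @return A symmetric 7x7 matrix of distances in pixels with zero diagonal.
#' @export
pose_matrix <- function(pose) {
  if (is.data.frame(pose)) {
    jn <- pose_joints()
    stopifnot(all(jn %in% pose$joint))
    pose <- as.matrix(pose[match(jn, pose$joint), c("x", "y")])
    rownames(pose) <- jn
  }
  check_finite(pose, "pose coordinates")
  as.matrix(stats::dist(pose))
}

# ---- the Laplacian comparison ----------------------------------------------

# Vectorised scoring over frames. xa/ya/xb/yb: n x 7 coordinate matrices.
# Returns per-frame scores; all arithmetic lives in score_pairs().
score_frames <- function(xa, ya, xb, yb, gain = similarity_gain()) {
  nj <- ncol(xa)
  pr <- utils::combn(nj, 2)
  i1 <- pr[1, ]; i2 <- pr[2, ]
  pair_d <- function(x, y) {
    sqrt((x[, i1, drop = FALSE] - x[, i2, drop = FALSE])^2 +
         (y[, i1, drop = FALSE] - y[, i2, drop = FALSE])^2)
  }
  score_pairs(pair_d(xa, ya), pair_d(xb, yb), nj, gain)
}

#' Graph-Laplacian similarity of two pose matrices
#'
#' Compares two poses through the degree-normalized graph Laplacians of
#' their distance structure: each pose matrix is scaled to unit Frobenius
#' norm, converted to an affinity `W = max(D) - D` (off-diagonal), and the
#' symmetric normalized Laplacian is formed; the score is
#' `1 / (1 + k * ||L_a - L_b||_F)` with packaged sensitivity constant `k`
#' ([similarity_gain()]). The score lies in (0, 1], equals 1 exactly when
#' the normalized pose matrices coincide, is symmetric in its arguments, and
#' is invariant to translation, rotation, reflection and isotropic scaling
#' of either pose.
#'
#' If exactly one pose is degenerate (all joints coincident) the score is
#' defined as 0 with a warning; if both are degenerate it is 1.
#'
#' @param a,b 7x7 pose matrices from [pose_matrix()] with identical joint
#'   ordering.
#' @param gain sensitivity constant; defaults to the packaged value.
#' @return A similarity score in `[0, 1]`.
#' @export
laplacian_similarity <- function(a, b, gain = similarity_gain()) {
  stopifnot(is.matrix(a), is.matrix(b), all(dim(a) == dim(b)))
  check_finite(a, "pose matrix a"); check_finite(b, "pose matrix b")
  # route both matrices through the same arithmetic as the vectorised path:
  # encode each D as its off-diagonal pair vector via coordinates-free input
  nj <- nrow(a)
  pr <- utils::combn(nj, 2)
  da <- a[t(pr)]
  db <- b[t(pr)]
  unname(score_pairs(rbind(da), rbind(db), nj, gain))
}

# Score from off-diagonal pair representations (n x choose(nj,2)); shared by
# laplacian_similarity and internal tests.
score_pairs <- function(Da, Db, nj, gain = similarity_gain()) {
  pr <- utils::combn(nj, 2)
  i1 <- pr[1, ]; i2 <- pr[2, ]
  lap <- function(D) {
    fro <- sqrt(2 * rowSums(D^2))
    deg_zero <- fro == 0
    fro[deg_zero] <- 1
    Dn <- D / fro
    W <- apply(Dn, 1, max) - Dn
    deg <- matrix(0, nrow(D), nj)
    for (p in seq_along(i1)) {
      deg[, i1[p]] <- deg[, i1[p]] + W[, p]
      deg[, i2[p]] <- deg[, i2[p]] + W[, p]
    }
    deg <- pmax(deg, .Machine$double.eps)
    list(L = -W / sqrt(deg[, i1, drop = FALSE] * deg[, i2, drop = FALSE]),
         degenerate = deg_zero)
  }
  la <- lap(Da); lb <- lap(Db)
  d <- sqrt(2 * rowSums((la$L - lb$L)^2))
  score <- 1 / (1 + gain * d)
  score[la$degenerate & lb$degenerate] <- 1
  one <- xor(la$degenerate, lb$degenerate)
  if (any(one)) {
    warning("degenerate pose in one input; score set to 0")
    score[one] <- 0
  }
  score
}

#' Frame-wise dyad similarity trace
#'
#' Runs the full manipulation-check pipeline on two keypoint series: align
#' frame counts (truncating to the shorter series with a warning), drop
#' frames in which either person has more than half of their joints missing,
#' impute remaining missing keypoints with per-joint medians, smooth each
#' trajectory with a Savitzky-Golay filter, and score every frame with
#' [laplacian_similarity()].
#'
#' @param series_a,series_b keypoint tibbles for the two people.
#' @param window,polyorder Savitzky-Golay settings (default 13 frames,
#'   order 2).
#' @param gain similarity sensitivity constant.
#' @return A `similarity_trace`: tibble with `frame` and `score`, carrying
#'   the dyad mean, SD and frame count as attributes (see
#'   [glance.similarity_trace()]).
#' @export
dyad_similarity <- function(series_a, series_b, window = 13L, polyorder = 2L,
                            gain = similarity_gain()) {
  ka <- as_keypoint_matrixes(series_a)
  kb <- as_keypoint_matrixes(series_b)
  n <- min(length(ka$frames), length(kb$frames))
  if (n == 0) stop("dyad_similarity(): no overlapping frames")
  if (length(ka$frames) != length(kb$frames)) {
    warning(sprintf("frame counts differ (%d vs %d); truncating to %d",
                    length(ka$frames), length(kb$frames), n))
  }
  trim <- function(km) {
    km$frames <- km$frames[seq_len(n)]
    for (f in c("x", "y", "conf")) km[[f]] <- km[[f]][seq_len(n), , drop = FALSE]
    km
  }
  ka <- trim(ka); kb <- trim(kb)
  # drop frames where either person is mostly missing (imputing a whole pose
  # would fabricate geometry)
  bad <- rowSums(missing_mask(ka)) > ncol(ka$x) / 2 |
    rowSums(missing_mask(kb)) > ncol(kb$x) / 2
  keep_frames <- ka$frames[!bad]
  if (length(keep_frames) == 0) stop("dyad_similarity(): all frames dropped")
  sa <- matrixes_to_series(trim_frames(ka, !bad), series_a)
  sb <- matrixes_to_series(trim_frames(kb, !bad), series_b)
  sa <- impute_missing(sa) |> smooth_series(window, polyorder)
  sb <- impute_missing(sb) |> smooth_series(window, polyorder)
  ma <- as_keypoint_matrixes(sa)
  mb <- as_keypoint_matrixes(sb)
  score <- score_frames(ma$x, ma$y, mb$x, mb$y, gain)
  out <- tibble::tibble(frame = keep_frames, score = score)
  attr(out, "mean") <- mean(score)
  attr(out, "sd") <- stats::sd(score)
  attr(out, "n_frames") <- length(score)
  class(out) <- c("similarity_trace", class(out))
  out
}

trim_frames <- function(km, keep) {
  km$frames <- km$frames[keep]
  for (f in c("x", "y", "conf")) km[[f]] <- km[[f]][keep, , drop = FALSE]
  km
}

#' @method glance similarity_trace
#' @export
glance.similarity_trace <- function(x, ...) {
  tibble::tibble(
    mean = attr(x, "mean"), sd = attr(x, "sd"), n_frames = attr(x, "n_frames")
  )
}

#' @method tidy similarity_trace
#' @export
tidy.similarity_trace <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("frame", "score")])
}

#' @method autoplot similarity_trace
#' @export
autoplot.similarity_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$score)) +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frame", y = "pose similarity",
                  title = sprintf("dyad mean similarity = %.3f",
                                  attr(object, "mean"))) +
    ggplot2::theme_minimal()
}
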