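# Reading and writing per-frame keypoint JSON (OpenPose dialect).

# BODY_25 indices (1-based) of the upper-body joints used here.
BODY25_IDX <- c(neck = 2L, l_shoulder = 6L, r_shoulder = 3L,
                l_elbow = 7L, r_elbow = 4L, l_wrist = 8L, r_wrist = 5L)

#' Write a dyad's keypoints as per-frame OpenPose-dialect JSON
#'
#' One file per frame named `frame_%06d_keypoints.json`, each containing
#' `people[].pose_keypoints_2d` as flat x, y, confidence triplets in
#' BODY_25 joint order (joints not tracked here are zero-filled).
#'
#' @param dyad a `dyad_motion` from [simulate_dyad_motion()], or a list with
#'   two keypoint tibbles.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_openpose_frames <- function(dyad, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  series <- if (inherits(dyad, "dyad_motion")) {
    list(dyad$participant, dyad$confederate)
  } else dyad
  kms <- lapply(series, as_keypoint_matrixes)
  n <- length(kms[[1]]$frames)
  paths <- character(n)
  for (f in seq_len(n)) {
    people <- lapply(kms, function(km) {
      flat <- numeric(25 * 3)
      for (j in seq_along(BODY25_IDX)) {
        b <- BODY25_IDX[j]
        flat[(b - 1) * 3 + 1:3] <- c(km$x[f, j], km$y[f, j], km$conf[f, j])
      }
      list(pose_keypoints_2d = flat)
    })
    paths[f] <- file.path(dir, sprintf("frame_%06d_keypoints.json", f))
    jsonlite::write_json(list(version = 1.3, people = people), paths[f],
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(paths)
}

#' Read per-frame OpenPose-dialect JSON into two keypoint series
#'
#' Parses a directory (or explicit file list) of per-frame JSON files and
#' assigns the detected people consistently across frames: in the first
#' frame people are ordered left-to-right by centroid x (image-midline
#' convention for a seated face-to-face dyad); in later frames detections
#' are matched to the previous frame's centroids by nearest-centroid
#' assignment, so swapped detection order does not swap identities.
#' Keypoints with confidence 0 are recorded as missing.
#'
#' @param path directory containing `*_keypoints.json` files, or a character
#'   vector of file paths (sorted as given).
#' @return List with elements `person_1` and `person_2` (keypoint tibbles).
#' @export
read_openpose_frames <- function(path) {
  files <- if (length(path) == 1 && dir.exists(path)) {
    sort(list.files(path, pattern = "_keypoints\\.json$", full.names = TRUE))
  } else path
  if (length(files) < 1) stop("read_openpose_frames(): no frame files found")
  jn <- pose_joints()
  n <- length(files)
  mk <- function() matrix(NA_real_, n, length(jn), dimnames = list(NULL, jn))
  res <- list(p1 = list(x = mk(), y = mk(), conf = mk()),
              p2 = list(x = mk(), y = mk(), conf = mk()))
  prev_cent <- NULL
  for (f in seq_len(n)) {
    doc <- tryCatch(
      jsonlite::read_json(files[f], simplifyVector = TRUE),
      error = function(e) {
        stop(sprintf("malformed keypoint JSON in '%s': %s",
                     basename(files[f]), conditionMessage(e)))
      }
    )
    ppl <- doc$people
    kp_list <- if (is.data.frame(ppl)) {
      ppl$pose_keypoints_2d
    } else if (is.list(ppl)) {
      lapply(ppl, function(p) unlist(p$pose_keypoints_2d))
    } else list()
    if (length(kp_list) > 2) {
      stop(sprintf("frame '%s' contains %d people; expected at most 2",
                   basename(files[f]), length(kp_list)))
    }
    persons <- lapply(kp_list, parse_flat_keypoints, jn = jn)
    cents <- vapply(persons, function(p) {
      ok <- p$conf > 0 & is.finite(p$x)
      if (!any(ok)) return(NA_real_)
      mean(p$x[ok])
    }, numeric(1))
    assign_idx <- assign_people(cents, prev_cent)
    for (k in seq_along(persons)) {
      slot <- assign_idx[k]
      if (is.na(slot)) next
      tgt <- if (slot == 1) "p1" else "p2"
      res[[tgt]]$x[f, ] <- persons[[k]]$x
      res[[tgt]]$y[f, ] <- persons[[k]]$y
      res[[tgt]]$conf[f, ] <- persons[[k]]$conf
    }
    new_cent <- prev_cent %||% c(NA_real_, NA_real_)
    for (k in seq_along(persons)) {
      if (!is.na(assign_idx[k]) && is.finite(cents[k])) {
        new_cent[assign_idx[k]] <- cents[k]
      }
    }
    prev_cent <- new_cent
  }
  build <- function(p, id) {
    p$conf[is.na(p$conf)] <- 0  # absent detection = missing
    km <- list(frames = seq_len(n), x = p$x, y = p$y, conf = p$conf)
    out <- matrixes_to_series(km, tibble::tibble())
    attr(out, "person_id") <- id
    out
  }
  list(person_1 = build(res$p1, "person_1"),
       person_2 = build(res$p2, "person_2"))
}

# Flat x,y,c triplets -> named coordinate vectors for the 7 tracked joints.
# Accepts BODY_25 (75 values) or the 7-joint packaged order (21 values).
parse_flat_keypoints <- function(flat, jn) {
  flat <- as.numeric(flat)
  if (length(flat) == 75) {
    idx <- BODY25_IDX
  } else if (length(flat) == 21) {
    idx <- setNames(seq_along(jn), jn)
  } else {
    stop(sprintf(
      "pose_keypoints_2d has %d values; expected 75 (BODY_25) or 21",
      length(flat)))
  }
  x <- flat[(idx - 1) * 3 + 1]
  y <- flat[(idx - 1) * 3 + 2]
  conf <- flat[(idx - 1) * 3 + 3]
  list(x = setNames(x, jn), y = setNames(y, jn), conf = setNames(conf, jn))
}

# Assign detections to person slots 1/2. First frame: left-to-right by
# centroid. Later frames: nearest previous centroid (best of the <=2
# pairings).
assign_people <- function(cents, prev_cent) {
  k <- length(cents)
  if (k == 0) return(integer(0))
  if (is.null(prev_cent)) {
    if (k == 1) return(1L)
    return(order(order(cents)))  # rank: leftmost -> slot 1
  }
  if (k == 1) {
    d <- abs(cents - prev_cent)
    return(which.min(replace(d, is.na(d), Inf)))
  }
  d11 <- abs(cents[1] - prev_cent[1]) + abs(cents[2] - prev_cent[2])
  d12 <- abs(cents[1] - prev_cent[2]) + abs(cents[2] - prev_cent[1])
  d11[is.na(d11)] <- Inf; d12[is.na(d12)] <- Inf
  if (d12 < d11) c(2L, 1L) else c(1L, 2L)
}
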