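# Shared fixtures and independent oracles, built in code at test time.

# Keypoint tibble from x/y coordinate matrices (frames x 7).
kp_series <- function(x, y, conf = NULL) {
  jn <- c("neck", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
          "l_wrist", "r_wrist")
  n <- nrow(x)
  if (is.null(conf)) conf <- matrix(0.9, n, 7)
  out <- tibble::tibble(
    frame = rep(seq_len(n), each = 7),
    joint = rep(jn, times = n),
    x = as.vector(t(x)), y = as.vector(t(y)),
    confidence = as.vector(t(conf))
  )
  out
}

# A plausible seated upper-body pose (7 x 2), optionally perturbed.
toy_pose <- function(jitter = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- rbind(
    neck = c(320, 140), l_shoulder = c(235, 170), r_shoulder = c(405, 170),
    l_elbow = c(210, 285), r_elbow = c(430, 285),
    l_wrist = c(190, 390), r_wrist = c(450, 390)
  )
  p + matrix(rnorm(14, 0, jitter), 7, 2)
}

# Independent brute-force implementation of the Laplacian similarity score,
# written directly from the documented formula with explicit matrix loops.
oracle_laplacian_score <- function(A, B, gain) {
  norm_lap <- function(D) {
    D <- D / sqrt(sum(D^2))
    n <- nrow(D)
    W <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) if (i != j) W[i, j] <- max(D) - D[i, j]
    deg <- rowSums(W)
    L <- diag(n)
    for (i in 1:n) for (j in 1:n) if (i != j) {
      L[i, j] <- -W[i, j] / sqrt(max(deg[i], .Machine$double.eps) *
                                   max(deg[j], .Machine$double.eps))
    }
    L
  }
  d <- norm(norm_lap(A) - norm_lap(B), type = "F")
  1 / (1 + gain * d)
}

# Small montage for fast fNIRS tests.
tiny_montage <- function(long_per_roi = c(LIFG = 2, RPFC = 2), n_short = 2) {
  default_montage(long_per_roi = long_per_roi, n_short = n_short)
}

# Bare fnirs_series wrapper around a value matrix (for filter tests).
bare_series <- function(values, rate, kind = "intensity",
                        montage = tiny_montage()) {
  info <- tidyr::expand_grid(channel = montage$channel,
                             wavelength = c(760L, 850L)) |>
    dplyr::left_join(montage, by = "channel")
  info <- info[seq_len(ncol(values)), ]
  dyadsync:::new_fnirs_series(
    values, info, (seq_len(nrow(values)) - 1) / rate, rate, montage,
    tibble::tibble(onset = numeric(0), condition = character(0),
                   duration = numeric(0)),
    kind
  )
}

# Synthetic ROI-estimate table drawn from known cell means (for second-level
# oracles that must not depend on the fNIRS forward model).
toy_roi_estimates <- function(n_per_group = 8, rois = c("LIFG", "RPFC"),
                              hbo_means = NULL, hbr_means = NULL,
                              sd_resid = 0.2, sd_id = 0.2, seed = 1) {
  set.seed(seed)
  grid <- tidyr::expand_grid(
    group = c("Control", "Synchronized"), roi = rois,
    block_type = c("AllGo", "Mixed")
  )
  if (is.null(hbo_means)) {
    grid$hbo_mean <- ifelse(grid$block_type == "Mixed", 1.2, 0.8)
  } else grid$hbo_mean <- hbo_means
  if (is.null(hbr_means)) grid$hbr_mean <- -grid$hbo_mean / 3
  else grid$hbr_mean <- hbr_means
  out <- list()
  pid <- 0
  for (g in c("Control", "Synchronized")) {
    for (p in seq_len(n_per_group)) {
      pid <- pid + 1
      u <- rnorm(2, 0, sd_id)  # participant intercepts per chromophore
      rows <- grid[grid$group == g, ]
      for (r in seq_len(nrow(rows))) {
        out[[length(out) + 1]] <- tibble::tibble(
          participant_id = sprintf("T%03d", pid), group = g,
          roi = rows$roi[r], block_type = rows$block_type[r],
          chromophore = c("hbo", "hbr"),
          beta = c(rows$hbo_mean[r] + u[1] + rnorm(1, 0, sd_resid),
                   rows$hbr_mean[r] + u[2] + rnorm(1, 0, sd_resid))
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

# MCMC settings that keep unit-test fits fast.
fast_mcmc <- list(n_chains = 2, n_adapt = 300, n_burn = 300, n_iter = 700)
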