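# Second-level Bayesian inference on ROI amplitude estimates: multivariate
# (HbO, HbR) model, marginal contrasts, the HbO-HbR difference statistic and
# the brain-behaviour model.

MV_MODEL <- "
model {
  for (i in 1:N) {
    y[i, 1:2] ~ dmnorm(mu[i, 1:2], OmegaE)
    mu[i, 1] <- beta[cell[i], 1] + u[id[i], 1] + u[id[i], 3] * B[i]
    mu[i, 2] <- beta[cell[i], 2] + u[id[i], 2] + u[id[i], 4] * B[i]
  }
  for (j in 1:J) { u[j, 1:4] ~ dmnorm(zero4, OmegaU) }
  for (c in 1:C) {
    beta[c, 1] ~ dnorm(0, prec_cell)
    beta[c, 2] ~ dnorm(0, prec_cell)
  }
  OmegaE ~ dwish(R2, 3)
  SigmaE <- inverse(OmegaE)
  OmegaU ~ dwish(R4, 5)
  SigmaU <- inverse(OmegaU)
}"

DIFF_MODEL <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(beta[cell[i]] + u[id[i], 1] + u[id[i], 2] * B[i], tau_e)
  }
  for (j in 1:J) { u[j, 1:2] ~ dmnorm(zero2, OmegaU) }
  for (c in 1:C) { beta[c] ~ dnorm(0, prec_cell) }
  OmegaU ~ dwish(R2, 3)
  SigmaU <- inverse(OmegaU)
  tau_e <- pow(sigma_e, -2)
  sigma_e ~ dunif(0, prior_sigma_max)
}"

BB_MODEL <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(beta[cell[i]] + bRT[cell[i]] * zrt[i] + bCE[cell[i]] * zce[i]
                 + u[id[i], 1] + u[id[i], 2] * B[i], tau_e)
  }
  for (j in 1:J) { u[j, 1:2] ~ dmnorm(zero2, OmegaU) }
  for (c in 1:C) {
    beta[c] ~ dnorm(0, prec_cell)
    bRT[c] ~ dnorm(0, 1)
    bCE[c] ~ dnorm(0, 1)
  }
  OmegaU ~ dwish(R2, 3)
  tau_e <- pow(sigma_e, -2)
  sigma_e ~ dunif(0, prior_sigma_max)
}"


# The additive split between cell means and mean-zero participant effects is
# identified only through the prior, which mixes poorly. The estimand the
# contrasts need is the likelihood-identified group-level cell mean: the cell
# coefficient plus the average random effect of that cell's group. This
# sweeps each chain's draws into those cell means.
sweep_cell_means <- function(samp, cells, members_by_group, beta_col,
                             u_int, u_slope, outcomes) {
  swept <- lapply(samp, function(ch) {
    m <- as.matrix(ch)
    cols <- list()
    for (r in seq_len(nrow(cells))) {
      g <- as.character(cells$group[r])
      B <- as.integer(cells$block_type[r] == "Mixed")
      members <- members_by_group[[g]]
      for (o in outcomes) {
        uint <- rowMeans(m[, sprintf("u[%d,%d]", members, u_int[[o]]),
                           drop = FALSE])
        uslp <- rowMeans(m[, sprintf("u[%d,%d]", members, u_slope[[o]]),
                           drop = FALSE])
        cols[[sprintf("cellmean[%d].%s", cells$cell_id[r], o)]] <-
          m[, beta_col(cells$cell_id[r], o)] + uint + B * uslp
      }
    }
    coda::mcmc(do.call(cbind, cols))
  })
  coda::as.mcmc.list(swept)
}

cellmean_col <- function(cell_id, outcome) {
  sprintf("cellmean[%d].%s", cell_id, outcome)
}

# Normalise a second-level input table; requires participant_id, group, roi,
# block_type, chromophore, beta (the `condition` name from the first level
# is accepted for block_type).
normalise_roi_estimates <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"block_type" %in% names(x) && "condition" %in% names(x)) {
    x <- dplyr::rename(x, block_type = "condition")
  }
  need <- c("participant_id", "group", "roi", "block_type", "chromophore",
            "beta")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("ROI estimate table lacks column(s): ", paste(miss, collapse = ", "))
  }
  dplyr::filter(x, !is.na(.data$beta))
}

# Cell lookup shared by the second-level models: block x roi x group.
make_cells <- function(df) {
  cells <- df |>
    dplyr::distinct(.data$block_type, .data$roi, .data$group) |>
    dplyr::arrange(.data$block_type, .data$roi, .data$group) |>
    dplyr::mutate(cell_id = dplyr::row_number())
  df <- dplyr::left_join(df, cells,
                         by = c("block_type", "roi", "group"))
  list(df = df, cells = cells)
}

#' Fit the multivariate (HbO, HbR) second-level model
#'
#' Bayesian multivariate Gaussian model of per-participant ROI amplitudes:
#' `(HbO, HbR) ~ BlockType x ROI x Group + (1 + BlockType | participant)`
#' with the participant intercepts and block-type slopes of both outcomes
#' drawn from one correlated 4-dimensional distribution (the shared
#' random-effects linkage) and a free 2x2 residual covariance capturing the
#' HbO-HbR correlation. The fixed-effect structure is parameterised
#' directly as cell means (one per block type x ROI x group per
#' chromophore), which is equivalent to the full treatment-coded
#' interaction model and feeds the marginal contrasts directly.
#' Participants with missing ROIs contribute their available rows; nothing
#' is imputed.
#'
#' @param roi_estimates tibble with `participant_id`, `group`, `roi`,
#'   `block_type` (or `condition`), `chromophore` (`hbo`/`hbr`), `beta`.
#' @param n_chains,n_adapt,n_burn,n_iter MCMC settings.
#' @param prior_sd_cell prior SD of cell means (uM).
#' @param rhat_threshold convergence flag threshold.
#' @param seed sampler seed.
#' @return A `dyad_fit` whose draws include every cell mean; summarise with
#'   [contrast_marginal()].
#' @export
fit_multivariate_model <- function(roi_estimates, n_chains = 2,
                                   n_adapt = 500, n_burn = 500,
                                   n_iter = 1500, prior_sd_cell = 10,
                                   rhat_threshold = 1.05, seed = 1L) {
  df <- normalise_roi_estimates(roi_estimates) |>
    tidyr::pivot_wider(
      id_cols = c("participant_id", "group", "roi", "block_type"),
      names_from = "chromophore", values_from = "beta"
    ) |>
    dplyr::filter(!is.na(.data$hbo), !is.na(.data$hbr))
  mc <- make_cells(df)
  df <- mc$df
  ids <- sort(unique(df$participant_id))
  if (length(ids) < 4) stop("fit_multivariate_model(): need >= 2 participants per group")
  data <- list(
    y = cbind(df$hbo, df$hbr), cell = df$cell_id,
    id = match(df$participant_id, ids),
    B = as.integer(df$block_type == "Mixed"),
    N = nrow(df), J = length(ids), C = nrow(mc$cells),
    zero4 = rep(0, 4), R2 = diag(2) * 0.01, R4 = diag(4) * 0.01,
    prec_cell = 1 / prior_sd_cell^2
  )
  samp <- run_jags(MV_MODEL, data, c("beta", "u", "SigmaE", "SigmaU"),
                   n_chains, n_adapt, n_burn, n_iter, seed = seed)
  members_by_group <- split(match(df$participant_id, ids), df$group) |>
    lapply(unique)
  swept <- sweep_cell_means(
    samp, mc$cells, members_by_group,
    beta_col = function(cell_id, outcome) {
      sprintf("beta[%d,%d]", cell_id, match(outcome, c("hbo", "hbr")))
    },
    u_int = list(hbo = 1, hbr = 2), u_slope = list(hbo = 3, hbr = 4),
    outcomes = c("hbo", "hbr")
  )
  mat_sw <- as.matrix(swept)
  mat <- as.matrix(samp)
  rho_e <- mat[, "SigmaE[2,1]"] /
    sqrt(mat[, "SigmaE[1,1]"] * mat[, "SigmaE[2,2]"])
  cell_effects <- purrr::pmap_dfr(mc$cells, function(block_type, roi, group,
                                                     cell_id) {
    dplyr::bind_rows(
      summarise_draws(mat_sw[, cellmean_col(cell_id, "hbo")],
                      sprintf("%s.%s.%s.hbo", roi, block_type, group),
                      scale = "uM"),
      summarise_draws(mat_sw[, cellmean_col(cell_id, "hbr")],
                      sprintf("%s.%s.%s.hbr", roi, block_type, group),
                      scale = "uM")
    )
  })
  effects <- dplyr::bind_rows(
    cell_effects,
    summarise_draws(rho_e, "residual_cor_hbo_hbr", scale = "correlation")
  )
  other <- mat[, grep("^Sigma", colnames(mat)), drop = FALSE]
  draws <- tibble::as_tibble(cbind(mat_sw, other))
  diag_samp <- coda::as.mcmc.list(lapply(seq_along(samp), function(i) {
    coda::mcmc(cbind(as.matrix(swept[[i]]),
                     as.matrix(samp[[i]])[, c("SigmaE[1,1]", "SigmaE[2,2]"),
                                          drop = FALSE]))
  }))
  new_dyad_fit(
    "dyad_fit_mv", effects, draws,
    mcmc_diagnostics(diag_samp, colnames(as.matrix(diag_samp))),
    list(description = "(HbO, HbR) ~ BlockType * ROI * Group + (1 + BlockType |p| ID)",
         cells = mc$cells, outcomes = c("hbo", "hbr"),
         beta_col = cellmean_col, n_obs = nrow(df)),
    seed, rhat_threshold = rhat_threshold
  )
}

# HPD-based evidence flag: substantial when the 95% HPD excludes zero,
# trend when zero sits in the 5% tail outside the 90% HPD.
evidence_flag <- function(draws) {
  h95 <- hpd_interval(draws, 0.95)
  if (h95[1] > 0 || h95[2] < 0) return("substantial")
  h90 <- hpd_interval(draws, 0.90)
  if (h90[1] > 0 || h90[2] < 0) return("trend")
  "none"
}

#' Marginal contrasts from a second-level fit
#'
#' Forms equal-weight marginal cell-mean contrasts from the posterior
#' draws: `"block"` compares AllGo minus Mixed per ROI with groups
#' combined (positive = AllGo amplitude more positive); `"group"` compares
#' Control minus Synchronized per ROI and block type (positive = Control
#' more positive). Each contrast carries the posterior mean, the 95% HPD
#' interval and an evidence flag (`substantial` when the 95% HPD excludes
#' zero, `trend` when zero lies outside the 90% but inside the 95% HPD).
#'
#' @param fit a `dyad_fit` from [fit_multivariate_model()],
#'   [fit_difference_model()] or [fit_brain_behaviour_model()].
#' @param contrast `"block"` or `"group"`.
#' @return Tibble with `roi`, (`block_type`,) `outcome`, `beta`, `hpd_lo`,
#'   `hpd_hi`, `flag`.
#' @export
contrast_marginal <- function(fit, contrast = c("block", "group")) {
  contrast <- match.arg(contrast)
  cells <- fit$model_info$cells
  outcomes <- fit$model_info$outcomes
  beta_col <- fit$model_info$beta_col
  mat <- as.matrix(fit$draws)
  empty <- fit$model_info$empty_cells %||% integer(0)
  cell_draws <- function(block, roi, group, outcome) {
    row <- cells[cells$block_type == block & cells$roi == roi &
                   cells$group == group, ]
    if (nrow(row) != 1) stop(sprintf("unknown cell: %s/%s/%s", block, roi, group))
    if (row$cell_id %in% empty) return(NULL)
    mat[, beta_col(row$cell_id, outcome)]
  }
  rois <- unique(cells$roi)
  out <- list()
  for (outcome in outcomes) {
    for (roi in rois) {
      if (contrast == "block") {
        parts <- lapply(unique(cells$group), function(g) {
          a <- cell_draws("AllGo", roi, g, outcome)
          m <- cell_draws("Mixed", roi, g, outcome)
          if (is.null(a) || is.null(m)) NULL else a - m
        })
        if (any(vapply(parts, is.null, logical(1)))) {
          out[[length(out) + 1]] <- tibble::tibble(
            roi = roi, outcome = outcome, beta = NA_real_,
            hpd_lo = NA_real_, hpd_hi = NA_real_, flag = "suppressed")
          next
        }
        d <- Reduce(`+`, parts) / length(parts)
        h <- hpd_interval(d)
        out[[length(out) + 1]] <- tibble::tibble(
          roi = roi, outcome = outcome, beta = mean(d),
          hpd_lo = unname(h[1]), hpd_hi = unname(h[2]), flag = evidence_flag(d))
      } else {
        for (block in unique(cells$block_type)) {
          cg <- cell_draws(block, roi, "Control", outcome)
          sg <- cell_draws(block, roi, "Synchronized", outcome)
          if (is.null(cg) || is.null(sg)) {
            out[[length(out) + 1]] <- tibble::tibble(
              roi = roi, block_type = block, outcome = outcome,
              beta = NA_real_, hpd_lo = NA_real_, hpd_hi = NA_real_,
              flag = "suppressed")
            next
          }
          d <- cg - sg
          h <- hpd_interval(d)
          out[[length(out) + 1]] <- tibble::tibble(
            roi = roi, block_type = block, outcome = outcome,
            beta = mean(d), hpd_lo = unname(h[1]), hpd_hi = unname(h[2]),
            flag = evidence_flag(d))
        }
      }
    }
  }
  dplyr::bind_rows(out)
}

#' HbO-HbR difference estimates
#'
#' Subtracts the HbR amplitude from the HbO amplitude per participant, ROI
#' and block type. Positive differences correspond to canonical
#' haemodynamic responses, negative to inverted (negative-BOLD-like)
#' responses. Each pair is classed `negative` (sign-discordant HbO and HbR,
#' the pattern expected of cortical activation) or `positive`
#' (sign-concordant, the pattern expected of systemic contamination).
#'
#' @param roi_estimates tibble as in [fit_multivariate_model()].
#' @return Tibble with `participant_id`, `group`, `roi`, `block_type`,
#'   `hbo`, `hbr`, `diff`, `corr_class`.
#' @export
hbo_hbr_difference <- function(roi_estimates) {
  wide <- normalise_roi_estimates(roi_estimates) |>
    tidyr::pivot_wider(
      id_cols = c("participant_id", "group", "roi", "block_type"),
      names_from = "chromophore", values_from = "beta"
    )
  if (!all(c("hbo", "hbr") %in% names(wide)) ||
      any(is.na(wide$hbo) != is.na(wide$hbr))) {
    stop("hbo_hbr_difference(): unpaired HbO/HbR estimates")
  }
  wide |>
    dplyr::filter(!is.na(.data$hbo)) |>
    dplyr::mutate(
      diff = .data$hbo - .data$hbr,
      corr_class = ifelse(sign(.data$hbo) * sign(.data$hbr) < 0,
                          "negative", "positive")
    )
}

#' Class proportions of HbO-HbR pairs
#'
#' Fraction of negatively correlated (sign-discordant) pairs per ROI,
#' block type and group.
#'
#' @param diffs output of [hbo_hbr_difference()].
#' @return Tibble with `roi`, `block_type`, `group`,
#'   `negative_fraction`, `n`.
#' @export
difference_class_proportions <- function(diffs) {
  diffs |>
    dplyr::group_by(.data$roi, .data$block_type, .data$group) |>
    dplyr::summarise(
      negative_fraction = mean(.data$corr_class == "negative"),
      n = dplyr::n(), .groups = "drop"
    )
}

#' Fit the HbO-HbR difference model
#'
#' Univariate hierarchical Gaussian model
#' `diff ~ BlockType x ROI x Group + (1 + BlockType | participant)` on the
#' difference values, optionally restricted to negatively correlated
#' (sign-discordant) pairs — the conservative analysis that excludes
#' responses more likely to be systemic.
#'
#' @param diffs tibble from [hbo_hbr_difference()].
#' @param filter `"all"` or `"negative_only"`.
#' @inheritParams fit_multivariate_model
#' @return A `dyad_fit`; summarise with [contrast_marginal()]. Cells
#'   emptied by the filter are flagged and their contrasts suppressed.
#' @export
fit_difference_model <- function(diffs, filter = c("all", "negative_only"),
                                 n_chains = 2, n_adapt = 500, n_burn = 500,
                                 n_iter = 1500, prior_sd_cell = 10,
                                 rhat_threshold = 1.05, seed = 1L) {
  filter <- match.arg(filter)
  df_all <- tibble::as_tibble(diffs)
  df <- if (filter == "negative_only") {
    dplyr::filter(df_all, .data$corr_class == "negative")
  } else df_all
  # the cell grid is defined on the unfiltered data so emptied cells are
  # detectable
  mc_all <- make_cells(df_all)
  df <- dplyr::left_join(df, mc_all$cells,
                         by = c("block_type", "roi", "group"))
  empty_cells <- setdiff(mc_all$cells$cell_id, unique(df$cell_id))
  if (length(empty_cells)) {
    warning("fit_difference_model(): filter emptied ",
            length(empty_cells), " cell(s); their contrasts are suppressed")
  }
  ids <- sort(unique(df$participant_id))
  data <- list(
    y = df$diff, cell = df$cell_id, id = match(df$participant_id, ids),
    B = as.integer(df$block_type == "Mixed"),
    N = nrow(df), J = length(ids), C = nrow(mc_all$cells),
    zero2 = c(0, 0), R2 = diag(2) * 0.01,
    prec_cell = 1 / prior_sd_cell^2,
    prior_sigma_max = max(10, 5 * stats::sd(df$diff))
  )
  samp <- run_jags(DIFF_MODEL, data, c("beta", "u", "sigma_e"),
                   n_chains, n_adapt, n_burn, n_iter, seed = seed)
  members_by_group <- split(match(df$participant_id, ids), df$group) |>
    lapply(unique)
  swept <- sweep_cell_means(
    samp, mc_all$cells, members_by_group,
    beta_col = function(cell_id, outcome) sprintf("beta[%d]", cell_id),
    u_int = list(diff = 1), u_slope = list(diff = 2), outcomes = "diff"
  )
  mat_sw <- as.matrix(swept)
  mat <- as.matrix(samp)
  cell_effects <- purrr::pmap_dfr(mc_all$cells, function(block_type, roi,
                                                         group, cell_id) {
    if (cell_id %in% empty_cells) return(NULL)
    summarise_draws(mat_sw[, cellmean_col(cell_id, "diff")],
                    sprintf("%s.%s.%s.diff", roi, block_type, group),
                    scale = "uM")
  })
  live <- setdiff(mc_all$cells$cell_id, empty_cells)
  new_dyad_fit(
    "dyad_fit_diff",
    dplyr::bind_rows(cell_effects,
                     summarise_draws(mat[, "sigma_e"], "sigma_resid")),
    tibble::as_tibble(cbind(mat_sw,
                            sigma_e = mat[, "sigma_e", drop = FALSE])),
    mcmc_diagnostics(swept, cellmean_col(live, "diff")),
    list(description = sprintf(
           "HbO-HbR diff ~ BlockType * ROI * Group + (1 + BlockType | ID) [%s]",
           filter),
         cells = mc_all$cells, outcomes = "diff",
         beta_col = cellmean_col,
         empty_cells = empty_cells,
         class_proportions = difference_class_proportions(df_all),
         filter = filter, n_obs = nrow(df)),
    seed, rhat_threshold = rhat_threshold
  )
}

#' Fit the brain-behaviour model
#'
#' Hierarchical Gaussian model of the HbO-HbR difference with
#' per-(ROI, block type, group) slopes on the participant's mean reaction
#' time and commission-error count:
#' `diff ~ BlockType x ROI x Group x RT x CE + (1 + BlockType | participant)`.
#' Covariates are standardized internally; slopes are reported both on the
#' standardized scale and per original unit (ms, errors).
#'
#' @param diffs tibble from [hbo_hbr_difference()].
#' @param behaviour per-participant behaviour: a trial tibble (summaries
#'   derived internally) or a tibble with `participant_id`, `mean_rt`,
#'   `commission_errors`.
#' @inheritParams fit_multivariate_model
#' @return A `dyad_fit`; `tidy()` lists cell means and slopes in the
#'   ROI x block type x group layout.
#' @export
fit_brain_behaviour_model <- function(diffs, behaviour, n_chains = 2,
                                      n_adapt = 500, n_burn = 500,
                                      n_iter = 1500, prior_sd_cell = 10,
                                      rhat_threshold = 1.05, seed = 1L) {
  ps <- if (all(c("mean_rt", "commission_errors") %in% names(behaviour))) {
    tibble::as_tibble(behaviour)
  } else participant_summary(behaviour)
  df <- dplyr::inner_join(tibble::as_tibble(diffs),
                          ps[, c("participant_id", "mean_rt",
                                 "commission_errors")],
                          by = "participant_id")
  lost <- setdiff(unique(diffs$participant_id), unique(df$participant_id))
  if (length(lost)) {
    warning("fit_brain_behaviour_model(): no behaviour for participant(s): ",
            paste(lost, collapse = ", "))
  }
  mc <- make_cells(df)
  df <- mc$df
  ids <- sort(unique(df$participant_id))
  sd_rt <- stats::sd(df$mean_rt)
  sd_ce <- stats::sd(df$commission_errors)
  data <- list(
    y = df$diff, cell = df$cell_id, id = match(df$participant_id, ids),
    B = as.integer(df$block_type == "Mixed"),
    zrt = as.numeric(scale(df$mean_rt)),
    zce = as.numeric(scale(df$commission_errors)),
    N = nrow(df), J = length(ids), C = nrow(mc$cells),
    zero2 = c(0, 0), R2 = diag(2) * 0.01,
    prec_cell = 1 / prior_sd_cell^2,
    prior_sigma_max = max(10, 5 * stats::sd(df$diff))
  )
  samp <- run_jags(BB_MODEL, data, c("beta", "u", "bRT", "bCE", "sigma_e"),
                   n_chains, n_adapt, n_burn, n_iter, seed = seed)
  members_by_group <- split(match(df$participant_id, ids), df$group) |>
    lapply(unique)
  swept <- sweep_cell_means(
    samp, mc$cells, members_by_group,
    beta_col = function(cell_id, outcome) sprintf("beta[%d]", cell_id),
    u_int = list(diff = 1), u_slope = list(diff = 2), outcomes = "diff"
  )
  mat_sw <- as.matrix(swept)
  mat <- as.matrix(samp)
  effects <- purrr::pmap_dfr(mc$cells, function(block_type, roi, group,
                                                cell_id) {
    lab <- sprintf("%s.%s.%s", roi, block_type, group)
    dplyr::bind_rows(
      summarise_draws(mat_sw[, cellmean_col(cell_id, "diff")],
                      paste0(lab, ".mean"), scale = "uM"),
      summarise_draws(mat[, sprintf("bRT[%d]", cell_id)],
                      paste0(lab, ".rt_slope"), scale = "uM per SD(RT)"),
      summarise_draws(mat[, sprintf("bRT[%d]", cell_id)] / sd_rt,
                      paste0(lab, ".rt_slope_per_ms"), scale = "uM per ms"),
      summarise_draws(mat[, sprintf("bCE[%d]", cell_id)],
                      paste0(lab, ".ce_slope"), scale = "uM per SD(CE)"),
      summarise_draws(mat[, sprintf("bCE[%d]", cell_id)] / sd_ce,
                      paste0(lab, ".ce_slope_per_error"), scale = "uM per error")
    )
  })
  keep <- !grepl("^u\\[", colnames(mat))
  new_dyad_fit(
    "dyad_fit_bb", effects,
    tibble::as_tibble(cbind(mat_sw, mat[, keep, drop = FALSE])),
    mcmc_diagnostics(samp, c(sprintf("bRT[%d]", mc$cells$cell_id), "sigma_e")),
    list(description = "HbO-HbR diff ~ BlockType * ROI * Group * RT * CE + (1 + BlockType | ID)",
         cells = mc$cells, outcomes = "diff",
         beta_col = cellmean_col,
         sd_rt = sd_rt, sd_ce = sd_ce, n_obs = nrow(df)),
    seed, rhat_threshold = rhat_threshold
  )
}
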