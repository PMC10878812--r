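# Poisson commission-error models.

CE_MODEL <- "
model {
  for (i in 1:J) {
    c[i] ~ dpois(exp(eta[i]) * expo[i] / 80)
    eta[i] ~ dnorm(a + bG * G[i], tau_u)
  }
  a ~ dnorm(0, 1e-4)
  bG ~ dnorm(0, prec_coef)
  tau_u <- pow(sigma_u, -2)
  sigma_u ~ dunif(0, 2)
}"

RTCE_MODEL <- "
model {
  for (i in 1:J) {
    c[i] ~ dpois(exp(eta[i]) * expo[i] / 80)
    eta[i] ~ dnorm(a + b * rtc[i], tau_u)
  }
  a ~ dnorm(0, 1e-4)
  b ~ dnorm(0, prec_slope)
  tau_u <- pow(sigma_u, -2)
  sigma_u ~ dunif(0, 2)
}"

#' Fit the Poisson commission-error model
#'
#' Fits `CE ~ 1 + Group + (1 | participant)` with a Poisson likelihood to
#' per-participant Mixed-block commission-error totals. The log rate is
#' parameterised per 80 NoGo trials (the full protocol) with the number of
#' NoGo trials actually seen entering as an exposure offset, so fits on
#' reduced schedules stay on the protocol's count scale.
#'
#' Count-scale effects are reported as differences of posterior marginal
#' mean counts per 80 NoGo trials: `group_effect_counts`
#' (Control - Synchronized; positive when the Synchronized group makes
#' fewer errors) and the same effect as an error-rate percentage
#' (`group_effect_rate_pct` = counts / 80 x 100).
#'
#' @inheritParams fit_rt_model
#' @param prior_sd_coef prior SD of the log-scale group coefficient.
#' @return A `dyad_fit`.
#' @export
fit_ce_model <- function(trials, n_chains = 2, n_adapt = 500, n_burn = 500,
                         n_iter = 2000, prior_sd_coef = 1,
                         rhat_threshold = 1.05, log_lik = FALSE, seed = 1L) {
  ps <- participant_summary(trials) |>
    dplyr::filter(!is.na(.data$commission_errors))
  if (nrow(ps) < 4) stop("fit_ce_model(): need at least 2 participants per group")
  G <- as.integer(ps$group == "Synchronized")
  data <- list(c = ps$commission_errors, G = G, expo = ps$n_nogo,
               J = nrow(ps), prec_coef = 1 / prior_sd_coef^2)
  monitors <- c("a", "bG", "sigma_u", if (log_lik) "eta")
  samp <- run_jags(CE_MODEL, data, monitors, n_chains, n_adapt, n_burn,
                   n_iter, seed = seed)
  mat <- as.matrix(samp)
  counts <- function(g) exp(mat[, "a"] + mat[, "bG"] * g + mat[, "sigma_u"]^2 / 2)
  gdiff <- counts(0) - counts(1)  # Control - Synchronized
  effects <- dplyr::bind_rows(
    summarise_draws(mat[, "a"], "intercept"),
    summarise_draws(mat[, "bG"], "group"),
    summarise_draws(mat[, "sigma_u"], "sd_intercept"),
    summarise_draws(gdiff, "group_effect_counts", scale = "counts"),
    summarise_draws(gdiff / 80 * 100, "group_effect_rate_pct", scale = "percent")
  )
  ll <- NULL
  if (log_lik) {
    eta_cols <- paste0("eta[", seq_len(nrow(ps)), "]")
    lam <- exp(mat[, eta_cols, drop = FALSE]) *
      matrix(ps$n_nogo / 80, nrow(mat), nrow(ps), byrow = TRUE)
    ll <- dpois(matrix(ps$commission_errors, nrow(mat), nrow(ps), byrow = TRUE),
                lam, log = TRUE)
  }
  keep <- !grepl("^eta\\[", colnames(mat))
  new_dyad_fit(
    "dyad_fit_ce", effects, tibble::as_tibble(mat[, keep, drop = FALSE]),
    mcmc_diagnostics(samp, c("a", "bG", "sigma_u")),
    list(description = "Poisson CE ~ Group + (1 | ID)",
         n_obs = nrow(ps), n_participants = nrow(ps)),
    seed, log_lik = ll, rhat_threshold = rhat_threshold
  )
}

#' Fit the exploratory reaction-time / commission-error model
#'
#' Poisson model of per-participant commission-error counts with the
#' participant's mean reaction time (ms, centred internally) as covariate
#' and a participant-level random intercept. The slope is reported on the
#' log-count-per-ms scale: at the study's baseline rates a slope of -0.005
#' corresponds to roughly one commission error fewer per 200 ms slowing.
#'
#' @param x either a trial tibble (participant summaries are derived with
#'   responded-Go mean RTs and Mixed-block commission totals) or a
#'   participant-level tibble with columns `mean_rt`, `commission_errors`
#'   and `n_nogo`.
#' @inheritParams fit_ce_model
#' @param prior_sd_slope prior SD of the RT slope (log count per ms).
#' @return A `dyad_fit`.
#' @export
fit_rt_ce_model <- function(x, n_chains = 2, n_adapt = 500, n_burn = 500,
                            n_iter = 2000, prior_sd_slope = 0.1,
                            rhat_threshold = 1.05, log_lik = FALSE,
                            seed = 1L) {
  ps <- if (all(c("mean_rt", "commission_errors") %in% names(x))) {
    tibble::as_tibble(x)
  } else {
    participant_summary(x)
  }
  ps <- dplyr::filter(ps, !is.na(.data$commission_errors), !is.na(.data$mean_rt))
  if (!"n_nogo" %in% names(ps)) ps$n_nogo <- 80L
  rtc <- ps$mean_rt - mean(ps$mean_rt)
  data <- list(c = ps$commission_errors, rtc = rtc, expo = ps$n_nogo,
               J = nrow(ps), prec_slope = 1 / prior_sd_slope^2)
  monitors <- c("a", "b", "sigma_u", if (log_lik) "eta")
  samp <- run_jags(RTCE_MODEL, data, monitors, n_chains, n_adapt, n_burn,
                   n_iter, seed = seed)
  mat <- as.matrix(samp)
  effects <- dplyr::bind_rows(
    summarise_draws(mat[, "a"], "intercept"),
    summarise_draws(mat[, "b"], "rt_slope", scale = "log-count per ms"),
    summarise_draws(mat[, "sigma_u"], "sd_intercept")
  )
  ll <- NULL
  if (log_lik) {
    eta_cols <- paste0("eta[", seq_len(nrow(ps)), "]")
    lam <- exp(mat[, eta_cols, drop = FALSE]) *
      matrix(ps$n_nogo / 80, nrow(mat), nrow(ps), byrow = TRUE)
    ll <- dpois(matrix(ps$commission_errors, nrow(mat), nrow(ps), byrow = TRUE),
                lam, log = TRUE)
  }
  keep <- !grepl("^eta\\[", colnames(mat))
  new_dyad_fit(
    "dyad_fit_rtce", effects, tibble::as_tibble(mat[, keep, drop = FALSE]),
    mcmc_diagnostics(samp, c("a", "b", "sigma_u")),
    list(description = "Poisson CE ~ mean RT + (1 | ID)", n_obs = nrow(ps),
         n_participants = nrow(ps)),
    seed, log_lik = ll, rhat_threshold = rhat_threshold
  )
}
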