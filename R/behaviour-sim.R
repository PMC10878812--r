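# Synthetic Go/NoGo behaviour with known ground truth.

#' Parameters for the Go/NoGo behaviour generator
#'
#' Packaged defaults reproduce the descriptive level of the study conditions:
#' Control AllGo reaction times centred on 230 ms and Control Mixed
#' commission errors centred on 19.7 per 80 NoGo trials, with the
#' Mixed-minus-AllGo marginal mean difference equal to 146.8 ms and the
#' Synchronized-minus-Control difference equal to 18.1 ms in expectation
#' under the fitted lognormal model.
#'
#' Reaction times are generated on the log scale with participant random
#' intercepts and block-type random slopes; the millisecond spreads are
#' converted to log-scale standard deviations by the coefficient-of-variation
#' approximation at the grand-mean RT. Cell means are mean-preserving: the
#' arithmetic mean RT of each (group, block type) cell equals the
#' `rt_means_ms` entry in expectation.
#'
#' @param n_per_group participants per group.
#' @param rt_means_ms named vector of target mean RTs (ms) for cells
#'   `Control.AllGo`, `Synchronized.AllGo`, `Control.Mixed`,
#'   `Synchronized.Mixed`.
#' @param rt_sd_between between-participant SD of mean RT, ms.
#' @param rt_sd_slope between-participant SD of the block-type effect, ms.
#' @param rt_sd_within within-participant trial-to-trial SD, ms.
#' @param ce_means named vector of mean commission-error counts per 80 NoGo
#'   trials for `Control` and `Synchronized` (Mixed blocks only).
#' @param ce_sd_log between-participant SD of the log commission rate.
#' @param omission_rate probability a Go trial receives no response.
#' @param ce_per_trial if `TRUE`, draw commission errors as independent
#'   per-trial Bernoulli events instead of per-block Poisson counts (stress
#'   testing option).
#' @param seed integer seed.
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(n_per_group = 20L,
                             rt_means_ms = c(
                               Control.AllGo = 230.0,
                               Synchronized.AllGo = 248.1,
                               Control.Mixed = 376.8,
                               Synchronized.Mixed = 394.9
                             ),
                             rt_sd_between = 8,
                             rt_sd_slope = 5,
                             rt_sd_within = 50,
                             ce_means = c(Control = 19.70, Synchronized = 16.70),
                             ce_sd_log = 0.38,
                             omission_rate = 0.01,
                             ce_per_trial = FALSE,
                             seed = 1L) {
  stopifnot(
    all(rt_means_ms > 0), all(ce_means > 0),
    rt_sd_between >= 0, rt_sd_slope >= 0, rt_sd_within >= 0, ce_sd_log >= 0,
    omission_rate >= 0, omission_rate < 1
  )
  needed <- c("Control.AllGo", "Synchronized.AllGo",
              "Control.Mixed", "Synchronized.Mixed")
  if (!all(needed %in% names(rt_means_ms))) {
    stop("rt_means_ms must name all four (group, block type) cells")
  }
  structure(
    list(
      n_per_group = as.integer(n_per_group), rt_means_ms = rt_means_ms,
      rt_sd_between = rt_sd_between, rt_sd_slope = rt_sd_slope,
      rt_sd_within = rt_sd_within, ce_means = ce_means, ce_sd_log = ce_sd_log,
      omission_rate = omission_rate, ce_per_trial = ce_per_trial,
      seed = as.integer(seed)
    ),
    class = "behaviour_params"
  )
}

# Log-scale sds via the CV approximation at the grand-mean RT.
rt_log_sds <- function(params) {
  m <- mean(params$rt_means_ms)
  list(
    u0 = params$rt_sd_between / m,
    u1 = params$rt_sd_slope / m,
    w  = sqrt(log(1 + (params$rt_sd_within / m)^2))
  )
}

#' Simulate Go/NoGo trial data
#'
#' Draws a full trial table for two groups running the supplied schedule.
#' Go-trial reaction times follow a lognormal distribution with participant
#' random intercepts and block-type random slopes; commission errors are
#' drawn per Mixed block as Poisson counts from a participant-specific rate
#' (truncated at the 4 NoGo trials available per block), matching the
#' likelihoods of the analysis models. Cell means match
#' `params$rt_means_ms` / `params$ce_means` in expectation.
#'
#' @param params a [behaviour_params()] object.
#' @param schedule a schedule from [simulate_task_schedule()].
#' @return A tibble of trials: `participant_id`, `group`, `block_index`,
#'   `block_type`, `trial_index`, `trial_type`, `responded`, `rt` (ms,
#'   `NA` when not responded). Ground truth is attached as attribute
#'   `truth`.
#' @examples
#' trials <- simulate_behaviour(behaviour_params(n_per_group = 4),
#'                              simulate_task_schedule(1, n_blocks = 8))
#' @export
simulate_behaviour <- function(params = behaviour_params(),
                               schedule = simulate_task_schedule()) {
  stopifnot(inherits(params, "behaviour_params"))
  sds <- rt_log_sds(params)
  n <- params$n_per_group
  groups <- rep(c("Control", "Synchronized"), each = n)
  ids <- sprintf("P%03d", seq_along(groups))
  n_nogo_full <- 80  # NoGo trials in the full 40-block protocol

  with_seed(params$seed, {
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      g <- groups[i]
      u0 <- rnorm(1, 0, sds$u0)
      u1 <- rnorm(1, 0, sds$u1)
      # commission rate per 80 NoGo trials, mean-preserving lognormal
      lam80 <- params$ce_means[[g]] *
        exp(rnorm(1, -params$ce_sd_log^2 / 2, params$ce_sd_log))
      tr <- schedule
      mixed <- tr$block_type == "Mixed"
      # mean-preserving log-mean per cell
      v_allgo <- sds$u0^2 + sds$w^2
      v_mixed <- sds$u0^2 + sds$u1^2 + sds$w^2
      mu_log <- ifelse(
        mixed,
        log(params$rt_means_ms[[paste0(g, ".Mixed")]]) - v_mixed / 2,
        log(params$rt_means_ms[[paste0(g, ".AllGo")]]) - v_allgo / 2
      ) + u0 + u1 * mixed
      rt <- rlnorm(nrow(tr), mu_log, sds$w)
      rt <- pmin(rt, 999)  # response window is 1000 ms
      responded <- rep(FALSE, nrow(tr))
      go <- tr$trial_type == "Go"
      responded[go] <- runif(sum(go)) > params$omission_rate
      # commission errors on NoGo trials
      nogo_idx <- which(!go)
      if (length(nogo_idx)) {
        if (params$ce_per_trial) {
          p_hit <- min(lam80 / n_nogo_full, 1)
          hits <- nogo_idx[runif(length(nogo_idx)) < p_hit]
        } else {
          hits <- integer(0)
          for (b in unique(tr$block_index[nogo_idx])) {
            slots <- nogo_idx[tr$block_index[nogo_idx] == b]
            k <- min(rpois(1, lam80 * length(slots) / n_nogo_full),
                     length(slots))
            if (k > 0) hits <- c(hits, sample(slots, k))
          }
        }
        responded[hits] <- TRUE
      }
      rt[!responded] <- NA_real_
      out[[i]] <- tr |>
        dplyr::mutate(
          participant_id = ids[i], group = g,
          responded = responded, rt = rt, .before = 1
        )
    }
    trials <- dplyr::bind_rows(out) |>
      dplyr::select("participant_id", "group", "block_index", "block_type",
                    "trial_index", "trial_type", "responded", "rt")
    sds <- rt_log_sds(params)
    attr(trials, "truth") <- list(
      params = params,
      block_effect_ms = mean(params$rt_means_ms[c("Control.Mixed", "Synchronized.Mixed")]) -
        mean(params$rt_means_ms[c("Control.AllGo", "Synchronized.AllGo")]),
      group_effect_ms = mean(params$rt_means_ms[c("Synchronized.AllGo", "Synchronized.Mixed")]) -
        mean(params$rt_means_ms[c("Control.AllGo", "Control.Mixed")]),
      ce_group_effect = params$ce_means[["Control"]] - params$ce_means[["Synchronized"]]
    )
    trials
  })
}

#' Simulate a cohort for the reaction-time / commission-error model
#'
#' Participant-level generator for the exploratory model linking mean
#' reaction time to commission errors: per-participant mean RTs are drawn
#' from a normal distribution and commission-error counts from a Poisson
#' whose log rate declines with RT at `slope` (log-count per ms, default
#' -0.005: roughly one error fewer per 200 ms slowing at baseline rates).
#'
#' @param n participants (both groups pooled; the model has no group term).
#' @param slope generating slope, log commission count per ms.
#' @param rt_mean,rt_sd mean and SD of participant mean RTs, ms.
#' @param baseline_count expected commission count (per 80 NoGo trials) for a
#'   participant at `rt_mean`.
#' @param id_sd_log between-participant SD of the log rate beyond RT.
#' @param n_nogo NoGo trials seen per participant (exposure).
#' @param seed integer seed.
#' @return Tibble with `participant_id`, `mean_rt`, `commission_errors`,
#'   `n_nogo`; generating values in attribute `truth`.
#' @export
simulate_rt_ce_cohort <- function(n = 59L, slope = -0.005,
                                  rt_mean = 375, rt_sd = 40,
                                  baseline_count = 18.2, id_sd_log = 0.1,
                                  n_nogo = 80L, seed = 1L) {
  stopifnot(rt_sd >= 0, id_sd_log >= 0, baseline_count > 0)
  with_seed(seed, {
    rt <- rnorm(n, rt_mean, rt_sd)
    lrate <- log(baseline_count) + slope * (rt - rt_mean) +
      rnorm(n, -id_sd_log^2 / 2, id_sd_log)
    ce <- rpois(n, exp(lrate) * n_nogo / 80)
    out <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      mean_rt = rt, commission_errors = ce, n_nogo = as.integer(n_nogo)
    )
    attr(out, "truth") <- list(slope = slope, baseline_count = baseline_count)
    out
  })
}
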