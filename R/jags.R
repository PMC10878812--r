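# Shared MCMC machinery (JAGS) and the posterior fit container.

# Run a JAGS model and return pooled draws plus per-parameter diagnostics.
run_jags <- function(model, data, monitors, n_chains = 2, n_adapt = 500,
                     n_burn = 500, n_iter = 1500, thin = 1, seed = 1L) {
  inits <- lapply(seq_len(n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, ch))
  })
  jm <- rjags::jags.model(textConnection(model), data = data, inits = inits,
                          n.chains = n_chains, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  samp <- rjags::coda.samples(jm, variable.names = monitors, n.iter = n_iter,
                              thin = thin, progress.bar = "none")
  samp
}

# Diagnostics tibble (Rhat across chains, pooled effective size) for the
# named scalar parameters.
mcmc_diagnostics <- function(samp, params) {
  mat <- as.matrix(samp)
  params <- intersect(params, colnames(mat))
  rhat <- rep(NA_real_, length(params))
  if (coda::nchain(samp) >= 2) {
    sub <- samp[, params, drop = FALSE]
    gd <- tryCatch(coda::gelman.diag(sub, autoburnin = FALSE,
                                     multivariate = FALSE),
                   error = function(e) NULL)
    if (!is.null(gd)) rhat <- gd$psrf[, 1]
  }
  ess <- tryCatch(coda::effectiveSize(samp[, params, drop = FALSE]),
                  error = function(e) rep(NA_real_, length(params)))
  tibble::tibble(parameter = params, rhat = unname(rhat), ess = unname(ess))
}

# Construct the fit container shared by all Bayesian models in the package.
new_dyad_fit <- function(subclass, effects, draws, diagnostics, model_info,
                         seed, log_lik = NULL, rhat_threshold = 1.05) {
  worst <- suppressWarnings(max(diagnostics$rhat, na.rm = TRUE))
  converged <- !is.finite(worst) || worst < rhat_threshold
  if (!converged) {
    warning(sprintf(
      "sampler convergence flagged: max Rhat = %.3f (threshold %.2f); treat estimates with caution",
      worst, rhat_threshold))
  }
  structure(
    list(effects = effects, draws = draws, diagnostics = diagnostics,
         model_info = model_info, seed = seed, log_lik = log_lik,
         converged = converged),
    class = c(subclass, "dyad_fit")
  )
}

#' @export
print.dyad_fit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1], x$model_info$description))
  cat(sprintf("  draws: %d   converged: %s\n",
              nrow(x$draws), x$converged))
  print(x$effects, n = Inf)
  invisible(x)
}

#' Tidy method for Bayesian fits
#'
#' @param x a `dyad_fit` object.
#' @param ... unused.
#' @return Tibble with `effect`, `scale`, `estimate` (posterior mean),
#'   `hpd_lo`, `hpd_hi` (95% highest-posterior-density bounds).
#' @method tidy dyad_fit
#' @export
tidy.dyad_fit <- function(x, ...) x$effects

#' Glance method for Bayesian fits
#'
#' @param x a `dyad_fit` object.
#' @param ... unused.
#' @return One-row tibble with draw count, worst Rhat, smallest effective
#'   sample size and the convergence flag.
#' @method glance dyad_fit
#' @export
glance.dyad_fit <- function(x, ...) {
  tibble::tibble(
    n_draws = nrow(x$draws),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    min_ess = suppressWarnings(min(x$diagnostics$ess, na.rm = TRUE)),
    converged = x$converged
  )
}

#' @method autoplot dyad_fit
#' @export
autoplot.dyad_fit <- function(object, scale = NULL, ...) {
  df <- object$effects
  if (!is.null(scale)) df <- df[df$scale %in% scale, ]
  df$effect <- factor(df$effect, levels = rev(unique(df$effect)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$effect)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hpd_lo,
                                          xmax = .data$hpd_hi)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scale), scales = "free") +
    ggplot2::labs(x = "posterior mean and 95% HPD", y = NULL) +
    ggplot2::theme_minimal()
}
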