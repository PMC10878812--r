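# Shared helpers: seed isolation, HPD intervals, input checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so generators with an explicit `seed`
#' argument do not disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483587L)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `mass` of the draws,
#' computed by sliding a window of `ceiling(mass * n)` order statistics over
#' the sorted sample (valid for unimodal posteriors). Ties are broken towards
#' the smallest lower bound.
#'
#' @param draws numeric vector of posterior draws (at least 2).
#' @param mass interval probability mass, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hpd_interval(rnorm(1e4))
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n == 0) stop("hpd_interval(): no finite draws supplied")
  if (mass <= 0 || mass > 1) stop("hpd_interval(): mass must be in (0, 1]")
  if (n == 1) return(c(lower = draws, upper = draws))
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  lo_idx <- seq_len(n - m + 1)
  widths <- x[lo_idx + m - 1] - x[lo_idx]
  i <- which.min(widths)  # which.min returns the first (smallest lo) on ties
  c(lower = x[i], upper = x[i + m - 1])
}

# Summarise a draws vector into mean + 95% HPD, as a one-row tibble.
summarise_draws <- function(draws, effect, scale = "model", mass = 0.95) {
  h <- hpd_interval(draws, mass)
  tibble::tibble(
    effect = effect, scale = scale,
    estimate = mean(draws), hpd_lo = h[["lower"]], hpd_hi = h[["upper"]]
  )
}

# Stop unless all values are finite.
check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
  invisible(x)
}
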