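#' Highest density interval
#'
#' The shortest contiguous interval containing `prob` of the posterior
#' draws: with `n` sorted draws and window size `m = ceiling(prob * n)`,
#' the minimal-width window `[x[i], x[i + m - 1]]`; ties broken by the
#' lowest start. For a unimodal symmetric posterior this approaches the
#' equal-tailed interval; for skewed posteriors it is shorter.
#'
#' @param draws Numeric vector of posterior draws (at least 100).
#' @param prob Probability mass (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(10000))
#' @export
hdi <- function(draws, prob = 0.95) {
  if (length(prob) != 1L || is.na(prob) || prob <= 0 || prob >= 1)
    cf_abort("prob must lie strictly between 0 and 1",
             "cogfrail_data_error")
  x <- sort(draws[!is.na(draws)])
  n <- length(x)
  if (n < 100L)
    cf_abort(sprintf("HDI needs at least 100 draws, got %d", n),
             "cogfrail_data_error")
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)  # which.min returns the first minimum
  c(lower = x[i], upper = x[i + m - 1L])
}

# HDI without the draw-count guard, for internal per-age band computation
# (gap curves may legitimately be built from point-mass draws)
hdi_unchecked <- function(x, prob = 0.95) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 1L) return(c(lower = x, upper = x))
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Convergence diagnostic comparing within- and between-chain variance
#' after splitting each chain in half (so non-stationarity within a chain
#' also inflates the statistic):
#' \eqn{\hat{R} = \sqrt{(\frac{n-1}{n} W + \frac{1}{n} B) / W}}.
#' Values near 1 indicate convergence; the conventional threshold used
#' throughout this package is 1.01.
#'
#' @param chains Matrix of draws, iterations x chains (at least 2 chains
#'   of at least 4 iterations), or an [coda::mcmc.list].
#' @return The R-hat statistic (>= 1 up to numerical tolerance; `NaN`
#'   when all draws are identical).
#' @examples
#' rhat(cbind(rnorm(500), rnorm(500)))
#' @export
rhat <- function(chains) {
  if (inherits(chains, "mcmc.list")) {
    if (coda::nvar(chains) != 1L)
      cf_abort("pass a single parameter's chains", "cogfrail_data_error")
    chains <- sapply(chains, as.numeric)
  }
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L)
    cf_abort("R-hat needs at least 2 chains", "cogfrail_data_error")
  if (nrow(chains) < 4L)
    cf_abort("R-hat needs chains of length >= 4", "cogfrail_data_error")
  half <- floor(nrow(chains) / 2)
  split <- cbind(chains[seq_len(half), , drop = FALSE],
                 chains[half + seq_len(half), , drop = FALSE])
  n <- nrow(split); m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) NaN else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}
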