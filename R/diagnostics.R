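#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance ratio for one scalar parameter,
#' `sqrt((W + B/n) / W)` with `W` the mean within-chain variance and `B/n`
#' the variance of the chain means.  Identical chains give exactly 1; values
#' well above 1 indicate that the chains have not mixed into a common
#' distribution.
#'
#' @param chains A list of equal-length numeric vectors (one per chain), or
#'   a matrix with one column per chain.
#' @return The potential scale reduction factor (scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains to compute the PSRF")
  n <- unique(lengths(chains))
  if (length(n) != 1L) stop("chains must have equal length")
  if (n < 2L) stop("chains must contain at least 2 draws")
  W <- mean(vapply(chains, stats::var, 0))
  B_over_n <- stats::var(vapply(chains, mean, 0))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt((W + B_over_n) / W)
}

#' Autocorrelation-based effective sample size
#'
#' Effective number of independent draws in an MCMC series, estimated from
#' the empirical autocorrelation function with Geyer's initial positive
#' sequence truncation: consecutive autocorrelation pairs are summed and
#' accumulation stops at the first non-positive pair.  A constant series is
#' flagged degenerate and reported as its own length.
#'
#' @param draws Numeric vector of retained draws from one chain.
#' @return ESS (scalar), with attributes `lag1` (lag-1 autocorrelation, `NA`
#'   for a degenerate series) and `degenerate` (logical).
#' @export
effective_sample_size <- function(draws) {
  draws <- as.numeric(draws)
  n <- length(draws)
  if (n < 2L) stop("need at least 2 draws")
  if (stats::var(draws) == 0)
    return(structure(n, lag1 = NA_real_, degenerate = TRUE))
  lag_max <- min(n - 1L, max(100L, floor(10 * sqrt(n))))
  rho <- as.numeric(stats::acf(draws, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  # Geyer initial positive sequence on pair sums rho[2k] + rho[2k+1]
  tau <- -1
  k <- 1L
  while (k + 1L <= length(rho)) {
    gamma_k <- rho[k] + rho[k + 1L]
    if (gamma_k <= 0) break
    tau <- tau + 2 * gamma_k
    k <- k + 2L
  }
  tau <- max(tau, 1 / n)
  structure(min(n / tau, n * 1.5), lag1 = rho[2L], degenerate = FALSE)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `prob` of the draws:
#' among all windows of `ceiling(prob * n)` consecutive sorted draws, the one
#' of smallest width.
#'
#' @param draws Numeric vector of posterior draws.
#' @param prob Coverage probability in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, prob = 0.95) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1)
    stop("'prob' must be a single probability in (0, 1)")
  draws <- as.numeric(draws[!is.na(draws)])
  n <- length(draws)
  k <- ceiling(prob * n)
  if (n < 2L || k < 1L || k > n)
    stop("too few draws (", n, ") for a ", prob, " HPD interval")
  xs <- sort(draws)
  starts <- seq_len(n - k + 1L)
  widths <- xs[starts + k - 1L] - xs[starts]
  i <- which.min(widths)
  c(lower = xs[i], upper = xs[i + k - 1L])
}

#' Posterior median
#'
#' Median over retained draws pooled across chains.
#'
#' @param draws Numeric vector of posterior draws.
#' @return Scalar median.
#' @export
posterior_median <- function(draws) {
  draws <- as.numeric(draws[!is.na(draws)])
  if (length(draws) == 0L) stop("no draws supplied")
  stats::median(draws)
}
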