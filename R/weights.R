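#' Exponential distance weight for a neighbouring nest box
#'
#' Weight given to a nest box at distance `d` from a focal box when
#' accumulating neighbourhood social cues.  The weight decays exponentially
#' with distance, `exp(-d / alpha)`, so that `alpha` (in meters) sets the
#' spatial scale of the neighbourhood: small `alpha` restricts the
#' neighbourhood to the focal box and its immediate surroundings, large
#' `alpha` lets most boxes in a forest patch contribute.
#'
#' @param d Distance in meters (non-negative, vectorised).
#' @param alpha Spatial-scale parameter in meters (positive scalar).
#' @return Numeric vector of weights in `(0, 1]`; `exp(0) = 1` at `d = 0`.
#' @examples
#' exp_weight(0, 7)          # 1: the focal box itself
#' exp_weight(248, 83)       # just above the 0.05 descriptive threshold
#' @seealso [nonnegligible_radius()]
#' @export
exp_weight <- function(d, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number (meters)")
  if (!is.numeric(d) || any(!is.finite(d)) || any(d < 0))
    stop("'d' must be finite non-negative distances in meters")
  exp(-d / alpha)
}

#' Radius of the non-negligible neighbourhood
#'
#' Largest integer distance (meters) at which the exponential weight
#' [exp_weight()] still exceeds `threshold`.  This is a descriptive summary
#' of how far a neighbourhood with scale `alpha` effectively reaches; it is
#' not used as a cutoff in any cue computation.
#'
#' @param alpha Spatial-scale parameter in meters (positive scalar).
#' @param threshold Weight threshold in `(0, 1)`; default 0.05.
#' @return Integer radius in meters (>= 0).
#' @examples
#' nonnegligible_radius(83)   # 248 m
#' nonnegligible_radius(1)    # 2 m
#' @export
nonnegligible_radius <- function(alpha, threshold = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number (meters)")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold) ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single weight strictly between 0 and 1")
  # exp(-d/alpha) > t  <=>  d < -alpha * log(t); take the largest integer
  # strictly below, stepping down if rounding lands on the boundary
  r <- floor(-alpha * log(threshold))
  while (r > 0 && exp(-r / alpha) <= threshold) r <- r - 1L
  as.integer(r)
}
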