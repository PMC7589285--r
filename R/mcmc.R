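#' MCMC chain settings
#'
#' Chain protocol for the Gibbs sampler.  The `"paper"` profile is the full
#' field protocol (3 chains of 2,550,000 iterations, burn-in 50,000,
#' thinning 500, i.e. 5000 stored draws per chain); the `"desk"` profile is
#' a scaled-down protocol for interactive work and testing (3 chains of
#' 55,000 iterations, burn-in 5,000, thinning 50).  Individual fields can be
#' overridden.  Per-chain seeds are derived deterministically from `seed`.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param n_chains,n_iter,burn_in,thin Overrides of the profile values.
#' @param seed Master seed (integer).
#' @return List of class `mcmc_settings`.
#' @export
mcmc_settings <- function(profile = c("desk", "paper"), n_chains = NULL,
                          n_iter = NULL, burn_in = NULL, thin = NULL,
                          seed = 1L) {
  profile <- match.arg(profile)
  def <- switch(profile,
                desk = list(n_chains = 3L, n_iter = 55000L, burn_in = 5000L,
                            thin = 50L),
                paper = list(n_chains = 3L, n_iter = 2550000L,
                             burn_in = 50000L, thin = 500L))
  s <- list(profile = profile,
            n_chains = as.integer(n_chains %||% def$n_chains),
            n_iter = as.integer(n_iter %||% def$n_iter),
            burn_in = as.integer(burn_in %||% def$burn_in),
            thin = as.integer(thin %||% def$thin),
            seed = as.integer(seed))
  if (s$n_chains < 1L) stop("need at least one chain")
  if (s$burn_in >= s$n_iter) stop("burn-in must be smaller than n_iter")
  if ((s$n_iter - s$burn_in) / s$thin < 100)
    stop("settings retain fewer than 100 draws per chain")
  set.seed(s$seed)
  s$chain_seeds <- sample.int(.Machine$integer.max %/% 2L, s$n_chains)
  class(s) <- "mcmc_settings"
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prior specification for the variance components
#'
#' Defaults follow the analysis protocol: an inverse-Wishart prior
#' (`V = 1`, `nu = 1`) on the residual variance, and parameter-expanded
#' priors (`V = 1`, `nu = 1`, working-parameter mean 0 and variance 1000)
#' on every other variance component.  For the 2x2 female/male additive
#' genetic block the inverse-Wishart prior is on the working covariance
#' matrix (`V = diag(2)`, `nu = 2`) with independent working parameters per
#' sex.
#'
#' @param residual List with `V` and `nu` for the residual variance.
#' @param variance List with `V`, `nu`, `alpha_mu`, `alpha_V` for scalar
#'   parameter-expanded components.
#' @param genetic2 List with `V` (2x2), `nu`, `alpha_V` for the cross-sex
#'   additive genetic block.
#' @return List of class `prior_spec`.
#' @export
default_priors <- function(residual = list(V = 1, nu = 1),
                           variance = list(V = 1, nu = 1, alpha_mu = 0,
                                           alpha_V = 1000),
                           genetic2 = list(V = diag(2), nu = 2,
                                           alpha_V = 1000)) {
  stopifnot(residual$V > 0, residual$nu > 0, variance$V > 0, variance$nu > 0,
            variance$alpha_V > 0, genetic2$nu > 0, genetic2$alpha_V > 0)
  structure(list(residual = residual, variance = variance,
                 genetic2 = genetic2),
            class = "prior_spec")
}
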