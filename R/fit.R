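#' Fit the repeatability mixed model for one cue response
#'
#' Partitions phenotypic variance in a normalized cue response into female
#' and male permanent individual, forest patch, nest box and residual
#' components, conditional on the status-by-status-by-date fixed effects:
#' `y = X beta + PI_f + PI_m + Patch + Box + e`.  Female and male
#' repeatabilities and the total repeatability are derived per posterior
#' draw with [repeatability_metrics()].
#'
#' @param data Data frame (typically a [build_response_table()] result) with
#'   the response column, `female_id`, `male_id`, `patch_id`,
#'   `chosen_box_id`, and the fixed-effect covariates.
#' @param response Name of the response column; rows with missing response
#'   are dropped with a message.
#' @param fixed `"full"` or `"intercept"` (see [build_design()]).
#' @param priors A [default_priors()] object.
#' @param mcmc An [mcmc_settings()] object.
#' @return Object of class `cueqg_fit`.
#' @export
fit_repeatability <- function(data, response, fixed = "full",
                              priors = default_priors(),
                              mcmc = mcmc_settings()) {
  prep <- .prepare_model_data(data, response)
  des <- build_design(prep$data, fixed = fixed)
  terms <- list(term_iid("PI_f", prep$data$female_id, block = "f"),
                term_iid("PI_m", prep$data$male_id, block = "m"),
                term_iid("patch", prep$data$patch_id),
                term_iid("box", prep$data$chosen_box_id))
  samples <- gibbs_fit(prep$y, des$X, terms, priors, mcmc)
  .new_fit(samples, model = "repeatability", response = response,
           data = prep$data, call = match.call())
}

#' Fit the joint-phenotype animal model for one cue response
#'
#' Extends the repeatability model with female and male additive genetic
#' effects (covariance structured by the additive relationship matrix from
#' the pruned pedigree) and, optionally, female and male dominance effects
#' (structured by the dominance relationship matrix):
#' `y = X beta + a_f + a_m + Dom_f + Dom_m + PI_f + PI_m + Patch + Box + e`.
#' With `cross_sex_covariance = TRUE` the female and male additive effects
#' are sampled jointly with an estimated 2x2 genetic covariance matrix;
#' otherwise the cross-sex covariance is fixed at zero.  Genetic effect
#' vectors are defined over the phenotyped individuals, with the remaining
#' pedigree members marginalized out through the relationship submatrices
#' (an exact operation for multivariate normal effects).
#'
#' @inheritParams fit_repeatability
#' @param pedigree Pedigree data frame (`id`, `dam`, `sire`); pruned
#'   internally to phenotyped individuals and their ancestors.
#' @param cross_sex_covariance Estimate the female-male additive genetic
#'   covariance (default `FALSE`, as in the headline analyses).
#' @param dominance Include dominance genetic effects (default `TRUE`).
#' @return Object of class `cueqg_fit`, with the mean mate relatedness
#'   `two_k_mean` attached for [heritability_metrics()].
#' @export
fit_animal_model <- function(data, response, pedigree,
                             cross_sex_covariance = FALSE, dominance = TRUE,
                             fixed = "full", priors = default_priors(),
                             mcmc = mcmc_settings()) {
  prep <- .prepare_model_data(data, response)
  d <- prep$data
  ped <- prune_pedigree(pedigree, c(d$female_id, d$male_id))
  A <- additive_matrix(ped)
  two_k <- mean_pair_relatedness(A, d)$two_k_mean
  terms <- if (cross_sex_covariance) {
    list(term_genetic2(d$female_id, d$male_id, A, name = "A"))
  } else {
    list(term_struct("A_f", d$female_id, A, marginalize = FALSE, block = "f"),
         term_struct("A_m", d$male_id, A, marginalize = FALSE, block = "m"))
  }
  if (dominance) {
    D <- dominance_matrix(ped, A)
    terms <- c(terms, list(term_struct("DOM_f", d$female_id, D, block = "f"),
                           term_struct("DOM_m", d$male_id, D, block = "m")))
  }
  terms <- c(terms, list(term_iid("PI_f", d$female_id, block = "f"),
                         term_iid("PI_m", d$male_id, block = "m"),
                         term_iid("patch", d$patch_id),
                         term_iid("box", d$chosen_box_id)))
  des <- build_design(d, fixed = fixed)
  samples <- gibbs_fit(prep$y, des$X, terms, priors, mcmc)
  fit <- .new_fit(samples, model = "animal", response = response, data = d,
                  call = match.call())
  fit$two_k_mean <- two_k
  fit$cross_sex_covariance <- cross_sex_covariance
  fit$dominance <- dominance
  fit
}

.prepare_model_data <- function(data, response) {
  if (!response %in% names(data))
    stop("response column '", response, "' not found")
  need <- c("female_id", "male_id", "patch_id", "chosen_box_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks columns: ", paste(miss, collapse = ", "))
  y <- data[[response]]
  keep <- !is.na(y)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing '", response, "' dropped")
  data <- data[keep, , drop = FALSE]
  for (col in need) data[[col]] <- as.character(data[[col]])
  list(data = data, y = as.numeric(y[keep]))
}

.new_fit <- function(samples, model, response, data, call) {
  structure(list(samples = samples, model = model, response = response,
                 n_obs = samples$n_obs,
                 n_females = length(unique(data$female_id)),
                 n_males = length(unique(data$male_id)),
                 call = call),
            class = "cueqg_fit")
}

#' @export
print.cueqg_fit <- function(x, ...) {
  cat("Bayesian", if (x$model == "animal") "joint-phenotype animal model"
      else "repeatability mixed model", "\n")
  cat("Response:", x$response, "  observations:", x$n_obs,
      " (", x$n_females, "females,", x$n_males, "males )\n")
  s <- x$samples$settings
  cat(sprintf("Chains: %d x %d iterations (burn-in %d, thin %d); %d retained draws\n",
              s$n_chains, s$n_iter, s$burn_in, s$thin, nrow(x$samples$draws)))
  cat("\nVariance components (posterior median [95% HPD]):\n")
  vs <- variance_summary(x)
  for (i in seq_len(nrow(vs)))
    cat(sprintf("  %-8s %9.4g  [%.3g, %.3g]\n", vs$component[i],
                vs$median[i], vs$hpd_lower[i], vs$hpd_upper[i]))
  invisible(x)
}

#' Posterior summaries of the variance components of a fit
#'
#' @param fit A `cueqg_fit` object.
#' @param prob HPD coverage probability.
#' @return Data frame with columns `component`, `median`, `hpd_lower`,
#'   `hpd_upper`.
#' @export
variance_summary <- function(fit, prob = 0.95) {
  draws <- fit$samples$draws
  comps <- c(fit$samples$term_labels, "V_R")
  out <- do.call(rbind, lapply(comps, function(cp) {
    h <- hpd_interval(draws[, cp], prob)
    data.frame(component = cp, median = posterior_median(draws[, cp]),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
summary.cueqg_fit <- function(object, prob = 0.95, ...) {
  metrics <- if (object$model == "animal")
    heritability_metrics(object, two_k_mean = object$two_k_mean, prob = prob)
  else repeatability_metrics(object, prob = prob)
  out <- list(fit = object, variances = variance_summary(object, prob),
              metrics = metrics$summary,
              diagnostics = object$samples$diagnostics)
  class(out) <- "summary.cueqg_fit"
  out
}

#' @export
print.summary.cueqg_fit <- function(x, ...) {
  print(x$fit)
  cat("\nDerived metrics (posterior median [95% HPD]):\n")
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-12s %9.4g  [%.3g, %.3g]\n", m$quantity[i], m$median[i],
                m$hpd_lower[i], m$hpd_upper[i]))
  d <- x$diagnostics
  cat(sprintf("\nDiagnostics: max PSRF %.3f, min ESS %.0f, max |lag-1 acf| %.3f\n",
              max(d$psrf, na.rm = TRUE), min(d$ess), max(abs(d$lag1), na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.cueqg_fit <- function(object, ...) {
  draws <- object$samples$draws
  fe <- setdiff(colnames(draws), c(object$samples$term_labels, "V_R"))
  vapply(fe, function(cp) posterior_median(draws[, cp]), 0)
}

#' @export
as.matrix.cueqg_fit <- function(x, ...) x$samples$draws

#' Forest plot of posterior variance components
#'
#' Medians and 95% HPD intervals of the variance components of a fit, drawn
#' with base graphics.
#'
#' @param x A `cueqg_fit` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cueqg_fit <- function(x, ...) {
  vs <- variance_summary(x)
  k <- nrow(vs)
  graphics::plot(vs$median, seq_len(k), xlim = range(0, vs$hpd_upper),
                 ylim = c(0.5, k + 0.5), yaxt = "n", pch = 16,
                 xlab = "variance (posterior median, 95% HPD)", ylab = "", ...)
  graphics::segments(vs$hpd_lower, seq_len(k), vs$hpd_upper, seq_len(k))
  graphics::axis(2, at = seq_len(k), labels = vs$component, las = 1)
  invisible(x)
}
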