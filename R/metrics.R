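#' Per-draw repeatability metrics
#'
#' From posterior draws of the repeatability-model variance components,
#' computes per draw the total phenotypic variance
#' `V_P = V_PI_f + V_PI_m + V_patch + V_box + V_R`, the female and male
#' repeatabilities `R_f = V_PI_f / V_P` and `R_m = V_PI_m / V_P`, the total
#' permanent individual variance `V_PI_total = V_PI_f + V_PI_m` and the
#' total repeatability `R_total = V_PI_total / V_P`.  All ratios are formed
#' per draw and only then summarized (median and HPD interval), never as
#' ratios of summaries.
#'
#' @param draws A `cueqg_fit`, `cueqg_samples`, or a matrix / data frame of
#'   draws with columns `V_PI_f`, `V_PI_m`, `V_patch`, `V_box`, `V_R`.
#' @param prob HPD coverage probability (default 0.95).
#' @return Object of class `derived_metrics`: list with `draws` (per-draw
#'   data frame) and `summary` (quantity, median, hpd_lower, hpd_upper).
#' @export
repeatability_metrics <- function(draws, prob = 0.95) {
  d <- .metric_draws(draws, c("V_PI_f", "V_PI_m", "V_patch", "V_box", "V_R"))
  V_P <- d$V_PI_f + d$V_PI_m + d$V_patch + d$V_box + d$V_R
  per_draw <- data.frame(
    V_P = V_P,
    V_PI_total = d$V_PI_f + d$V_PI_m,
    R_f = d$V_PI_f / V_P,
    R_m = d$V_PI_m / V_P,
    R_total = (d$V_PI_f + d$V_PI_m) / V_P)
  .derived_metrics(per_draw, prob)
}

#' Per-draw heritability metrics of the joint phenotype
#'
#' From posterior draws of the animal-model variance components, computes
#' per draw the total phenotypic variance
#' `V_P = V_A_f + V_A_m + two_k_mean * 2 * Cov_A + V_DOM_f + V_DOM_m +
#' V_PI_f + V_PI_m + V_patch + V_box + V_R` (the cross-sex covariance enters
#' the phenotypic variance scaled by the mean mate relatedness), the female
#' and male heritabilities `h2_f = V_A_f / V_P` and `h2_m = V_A_m / V_P`,
#' the total additive genetic variance
#' `V_A_total = V_A_f + V_A_m + 2 * Cov_A`, and the total heritability
#' `T2 = V_A_total / V_P`.  A missing `Cov_A` column (model fitted without
#' the cross-sex covariance) is treated as zero.
#'
#' @inheritParams repeatability_metrics
#' @param two_k_mean Mean female-male relatedness across breeding pairs
#'   (twice the mean kinship coefficient), in `[0, 2]`; see
#'   [mean_pair_relatedness()].
#' @return Object of class `derived_metrics`.
#' @export
heritability_metrics <- function(draws, two_k_mean, prob = 0.95) {
  if (!is.numeric(two_k_mean) || length(two_k_mean) != 1L ||
      is.na(two_k_mean) || two_k_mean < 0 || two_k_mean > 2)
    stop("'two_k_mean' must be a single number in [0, 2]")
  need <- c("V_A_f", "V_A_m", "V_DOM_f", "V_DOM_m", "V_PI_f", "V_PI_m",
            "V_patch", "V_box", "V_R")
  d <- .metric_draws(draws, need, optional = "Cov_A")
  if (is.null(d$Cov_A)) d$Cov_A <- 0
  V_P <- d$V_A_f + d$V_A_m + two_k_mean * 2 * d$Cov_A + d$V_DOM_f +
    d$V_DOM_m + d$V_PI_f + d$V_PI_m + d$V_patch + d$V_box + d$V_R
  V_A_total <- d$V_A_f + d$V_A_m + 2 * d$Cov_A
  per_draw <- data.frame(
    V_P = V_P, V_A_total = V_A_total,
    h2_f = d$V_A_f / V_P, h2_m = d$V_A_m / V_P, T2 = V_A_total / V_P)
  .derived_metrics(per_draw, prob)
}

.metric_draws <- function(draws, need, optional = character(0)) {
  if (inherits(draws, "cueqg_fit")) draws <- draws$samples$draws
  if (inherits(draws, "cueqg_samples")) draws <- draws$draws
  draws <- as.data.frame(draws)
  miss <- setdiff(need, names(draws))
  if (length(miss))
    stop("draws lack variance component column(s): ",
         paste(miss, collapse = ", "))
  draws[, c(need, intersect(optional, names(draws))), drop = FALSE]
}

.derived_metrics <- function(per_draw, prob) {
  summ <- do.call(rbind, lapply(names(per_draw), function(q) {
    h <- if (nrow(per_draw) < 2L) {
      c(lower = per_draw[[q]], upper = per_draw[[q]])
    } else hpd_interval(per_draw[[q]], prob)
    data.frame(quantity = q, median = posterior_median(per_draw[[q]]),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  structure(list(draws = per_draw, summary = summ, prob = prob),
            class = "derived_metrics")
}

#' @export
print.derived_metrics <- function(x, ...) {
  cat("Derived posterior metrics (median [", 100 * x$prob, "% HPD]):\n",
      sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %9.4g  [%.3g, %.3g]\n", x$summary$quantity[i],
                x$summary$median[i], x$summary$hpd_lower[i],
                x$summary$hpd_upper[i]))
  invisible(x)
}

#' Screening rule for repeatable cues
#'
#' Operationalizes "the posterior of the total repeatability is distributed
#' away from zero": a cue passes when the lower bound of the `prob` HPD
#' interval of `R_total` is at least `delta` and at most `max_mass_below`
#' of the posterior mass lies below `mass_at`.
#'
#' @param delta Minimum lower HPD bound (default 0.01).
#' @param mass_at Threshold under which posterior mass is counted
#'   (default 0.01).
#' @param max_mass_below Maximum tolerated posterior mass below `mass_at`
#'   (default 0.20).
#' @param prob HPD coverage probability (default 0.95).
#' @return List of class `screen_rule`.
#' @export
screen_rule <- function(delta = 0.01, mass_at = 0.01, max_mass_below = 0.20,
                        prob = 0.95) {
  stopifnot(delta >= 0, mass_at >= 0, max_mass_below >= 0,
            max_mass_below <= 1, prob > 0, prob < 1)
  structure(list(delta = delta, mass_at = mass_at,
                 max_mass_below = max_mass_below, prob = prob),
            class = "screen_rule")
}

#' Screen cues for repeatability
#'
#' Applies a [screen_rule()] to the `R_total` posterior of each cue's
#' repeatability metrics and returns the names of the cues that pass, i.e.
#' those carried forward to the quantitative genetic stage.
#'
#' @param metrics Named list of [repeatability_metrics()] results (one per
#'   cue), or a single `derived_metrics` object.
#' @param rule A [screen_rule()].
#' @return Character vector of passing cue names, with attribute `stats` (a
#'   data frame of the statistics used per cue).
#' @export
screen_repeatable <- function(metrics, rule = screen_rule()) {
  if (inherits(metrics, "derived_metrics")) metrics <- list(cue = metrics)
  stats_df <- do.call(rbind, lapply(names(metrics), function(nm) {
    r <- metrics[[nm]]$draws$R_total
    h <- hpd_interval(r, rule$prob)
    data.frame(cue = nm, median = posterior_median(r),
               hpd_lower = h[["lower"]],
               mass_below = mean(r < rule$mass_at),
               stringsAsFactors = FALSE)
  }))
  stats_df$pass <- stats_df$hpd_lower >= rule$delta &
    stats_df$mass_below <= rule$max_mass_below
  message("repeatability screen: ",
          paste(sprintf("%s [lower HPD %.3g, mass<%.3g: %.2f] %s",
                        stats_df$cue, stats_df$hpd_lower, rule$mass_at,
                        stats_df$mass_below,
                        ifelse(stats_df$pass, "pass", "fail")),
                collapse = "; "))
  structure(stats_df$cue[stats_df$pass], stats = stats_df)
}
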