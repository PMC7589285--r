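#' Run the full social-cue quantitative-genetic pipeline
#'
#' Orchestrates the complete analysis sequence: build the five normalized
#' cue responses from nest-box records, fit a repeatability mixed model per
#' cue, screen the cues whose total repeatability is distributed away from
#' zero, and fit the joint-phenotype animal model for each retained cue --
#' first with the cross-sex additive genetic covariance, refitting without
#' it when its HPD interval spans zero (the headline heritabilities then
#' come from the no-covariance model).  Writes repeatability and genetic
#' variance-component tables, the per-event responses, and a JSON manifest
#' with seeds, settings and convergence diagnostics.
#'
#' @param config List with elements:
#'   * `data`: list of CSV paths (`boxes`, `states`, `events`, `pedigree`)
#'     -- or `simulation`: a config list for [simulate_dataset()], whose
#'     `truth` may also be a named per-cue list; in simulation mode each
#'     cue's analysis column is a model-simulated response with known
#'     variance components (see Details in the source);
#'   * `alphas`: optional vector of five spatial scales for
#'     [default_cue_specs()];
#'   * `mcmc`: arguments for [mcmc_settings()];
#'   * `screen`: arguments for [screen_rule()];
#'   * `seed`: master seed.
#'   A path to a YAML file with this structure is also accepted.
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, a list with the response table, per-cue repeatability
#'   fits and metrics, retained cue names, genetic fits and metrics, and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(what, cue, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "'",
           if (!is.null(cue)) paste0(" [", cue, "]"), " failed: ",
           conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$simulation)) {
    sim <- stage("simulate", NULL,
                 simulate_dataset(config$simulation, seed = seed))
    boxes <- sim$boxes; states <- sim$states; events <- sim$events
    pedigree <- sim$pedigree
  } else if (!is.null(config$data)) {
    boxes <- stage("read", NULL, read_boxes(config$data$boxes))
    states <- stage("read", NULL, read_states(config$data$states))
    events <- stage("read", NULL, read_events(config$data$events))
    pedigree <- stage("read", NULL, read_pedigree(config$data$pedigree))
  } else stop("config needs either a 'data' or a 'simulation' block")

  specs <- if (is.null(config$alphas)) default_cue_specs()
           else default_cue_specs(config$alphas)
  responses <- stage("responses", NULL,
                     build_response_table(events, boxes, states, specs))

  # In simulation mode the choice-derived responses carry no ground truth,
  # so each cue's analysis column is replaced by a response simulated from
  # the joint-phenotype model on the same records (missingness pattern kept),
  # using either one shared truth or a per-cue truth list.  The
  # choice-derived normalized responses stay available as y_obs_<cue>.
  if (!is.null(config$simulation)) {
    truth_cfg <- config$simulation$truth %||% list()
    per_cue <- !inherits(truth_cfg, "sim_truth") && length(truth_cfg) &&
      all(names(truth_cfg) %in% names(specs))
    for (i in seq_along(specs)) {
      cue <- names(specs)[i]
      tr <- if (per_cue) truth_cfg[[cue]] %||% list() else truth_cfg
      if (!inherits(tr, "sim_truth")) tr <- do.call(sim_truth, tr)
      col <- paste0("y_", cue)
      rows <- which(!is.na(responses[[col]]))
      responses[[paste0("y_obs_", cue)]] <- responses[[col]]
      sim_y <- stage("simulate-response", cue,
                     simulate_phenotypes(pedigree,
                                         responses[rows, , drop = FALSE],
                                         tr, seed = seed + 1000L + i,
                                         fixed = config$fixed %||% "full"))
      responses[[col]][rows] <- sim_y$data$y
    }
  }
  .write_csv_exact(responses, file.path(out_dir, "responses.csv"))

  mk_settings <- function(offset)
    do.call(mcmc_settings, c(config$mcmc, list(seed = seed + offset)))
  rule <- do.call(screen_rule, config$screen %||% list())
  fixed <- config$fixed %||% "full"

  cues <- names(specs)
  rep_fits <- list(); rep_metrics <- list()
  for (i in seq_along(cues)) {
    cue <- cues[i]
    rep_fits[[cue]] <- stage("repeatability", cue,
      fit_repeatability(responses, paste0("y_", cue), fixed = fixed,
                        mcmc = mk_settings(i)))
    rep_metrics[[cue]] <- repeatability_metrics(rep_fits[[cue]])
  }
  retained <- stage("screen", NULL, screen_repeatable(rep_metrics, rule))

  gen_fits <- list(); gen_metrics <- list(); cov_decision <- list()
  for (j in seq_along(retained)) {
    cue <- retained[j]
    fit_cov <- stage("genetic", cue,
      fit_animal_model(responses, paste0("y_", cue), pedigree,
                       cross_sex_covariance = TRUE, fixed = fixed,
                       mcmc = mk_settings(100L + j)))
    cov_hpd <- hpd_interval(fit_cov$samples$draws[, "Cov_A"], rule$prob)
    keep_cov <- cov_hpd[["lower"]] > 0 || cov_hpd[["upper"]] < 0
    cov_decision[[cue]] <- list(hpd = unname(cov_hpd), retained = keep_cov)
    fit <- if (keep_cov) fit_cov else stage("genetic", cue,
      fit_animal_model(responses, paste0("y_", cue), pedigree,
                       cross_sex_covariance = FALSE, fixed = fixed,
                       mcmc = mk_settings(200L + j)))
    gen_fits[[cue]] <- fit
    gen_metrics[[cue]] <- heritability_metrics(fit, fit$two_k_mean)
  }

  .write_csv_exact(.summary_table(rep_fits, rep_metrics),
                   file.path(out_dir, "table2.csv"))
  if (length(gen_fits))
    .write_csv_exact(.summary_table(gen_fits, gen_metrics),
                     file.path(out_dir, "table3.csv"))

  manifest <- list(
    seed = seed,
    settings = unclass(mk_settings(1L))[c("profile", "n_chains", "n_iter",
                                          "burn_in", "thin")],
    screen_rule = unclass(rule),
    cue_n = as.list(attr(responses, "cue_n")),
    n_dropped_status = attr(responses, "n_dropped"),
    retained_cues = as.vector(retained),
    cross_sex_covariance = cov_decision,
    two_k_mean = if (length(gen_fits)) gen_fits[[1L]]$two_k_mean else NULL,
    diagnostics = c(
      lapply(rep_fits, function(f) f$samples$diagnostics),
      lapply(gen_fits, function(f) f$samples$diagnostics)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  invisible(list(responses = responses, repeatability = rep_fits,
                 repeatability_metrics = rep_metrics, retained = retained,
                 genetic = gen_fits, genetic_metrics = gen_metrics,
                 manifest = manifest, out_dir = out_dir))
}

# wide per-cue summary table: one row per variance component / derived
# metric, three columns (median, hpd_lower, hpd_upper) per cue
.summary_table <- function(fits, metrics) {
  cues <- names(fits)
  blocks <- lapply(cues, function(cue) {
    vs <- variance_summary(fits[[cue]])
    ms <- metrics[[cue]]$summary
    names(ms)[names(ms) == "quantity"] <- "component"
    rbind(vs, ms)
  })
  out <- data.frame(component = blocks[[1L]]$component,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cues)) {
    b <- blocks[[i]]
    if (!identical(b$component, out$component))
      b <- b[match(out$component, b$component), , drop = FALSE]
    out[[paste0(cues[i], ".median")]] <- b$median
    out[[paste0(cues[i], ".hpd_lower")]] <- b$hpd_lower
    out[[paste0(cues[i], ".hpd_upper")]] <- b$hpd_upper
  }
  out
}
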