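#' Simulate a multi-patch nest-box landscape
#'
#' Generates nest boxes placed uniformly at random inside disjoint square
#' forest patches laid out on a grid, with per-box historical occupancy
#' probabilities drawn from a beta distribution.  The defaults emulate the
#' study system: 15 discrete patches with boxes provided in excess and about
#' two thirds of boxes occupied in a typical year.
#'
#' @param n_patches Number of forest patches (>= 1).
#' @param boxes_per_patch Boxes per patch (>= 2).
#' @param patch_side Side length of each square patch, meters.
#' @param patch_gap Gap between neighbouring patch squares, meters.
#' @param occ_shape1,occ_shape2 Beta parameters of the historical occupancy
#'   probability (defaults give mean 2/3).
#' @param seed Integer seed; identical inputs give identical tables.
#' @return Data frame of nest boxes (`box_id`, `patch_id`, `x`, `y`,
#'   `occupancy_prob`).
#' @export
simulate_landscape <- function(n_patches = 15L, boxes_per_patch = 56L,
                               patch_side = 300, patch_gap = 400,
                               occ_shape1 = 4, occ_shape2 = 2, seed = 1L) {
  if (n_patches < 1L || boxes_per_patch < 2L || patch_side <= 0)
    stop("landscape dimensions must be positive (>= 1 patch, >= 2 boxes)")
  set.seed(seed)
  ncol_grid <- ceiling(sqrt(n_patches))
  out <- do.call(rbind, lapply(seq_len(n_patches), function(k) {
    ox <- ((k - 1L) %% ncol_grid) * (patch_side + patch_gap)
    oy <- ((k - 1L) %/% ncol_grid) * (patch_side + patch_gap)
    data.frame(
      box_id = sprintf("P%02dB%03d", k, seq_len(boxes_per_patch)),
      patch_id = sprintf("P%02d", k),
      x = ox + stats::runif(boxes_per_patch, 0, patch_side),
      y = oy + stats::runif(boxes_per_patch, 0, patch_side),
      occupancy_prob = stats::rbeta(boxes_per_patch, occ_shape1, occ_shape2),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a multi-generation pedigree
#'
#' Founders (unknown parents) form random pairs; each pair produces a
#' Poisson number of offspring of which a fraction is recruited into the
#' next breeding generation; unknown-parent immigrants are added each
#' generation.  This reproduces the structural features a wild passerine
#' pedigree presents to an animal model: sib families, multi-generation
#' links, and a large share of unknown-parent individuals.
#'
#' @param n_founders Even number of founders (>= 2).
#' @param n_generations Number of generations after the founders (>= 0).
#' @param mean_offspring Mean offspring per pair (Poisson).
#' @param recruitment_prob Probability an offspring is recruited.
#' @param immigrant_fraction Immigrants added per generation, as a fraction
#'   of that generation's recruits.
#' @param seed Integer seed.
#' @return List with `pedigree` (data frame `id`, `dam`, `sire`) and
#'   `individuals` (data frame `id`, `sex` (`"F"`/`"M"`), `generation`).
#' @export
simulate_pedigree <- function(n_founders = 100L, n_generations = 4L,
                              mean_offspring = 4, recruitment_prob = 0.35,
                              immigrant_fraction = 0.2, seed = 1L) {
  if (n_founders < 2L || n_founders %% 2L != 0L)
    stop("'n_founders' must be an even number >= 2")
  if (recruitment_prob < 0 || recruitment_prob > 1 ||
      immigrant_fraction < 0 || immigrant_fraction > 1)
    stop("recruitment and immigrant fractions must lie in [0, 1]")
  set.seed(seed)
  founders <- sprintf("F%04d", seq_len(n_founders))
  ped <- data.frame(id = founders, dam = NA_character_, sire = NA_character_,
                    stringsAsFactors = FALSE)
  ind <- data.frame(id = founders,
                    sex = rep(c("F", "M"), length.out = n_founders),
                    generation = 0L, stringsAsFactors = FALSE)
  adults <- ind
  for (g in seq_len(n_generations)) {
    fem <- sample(adults$id[adults$sex == "F"])
    mal <- sample(adults$id[adults$sex == "M"])
    n_pairs <- min(length(fem), length(mal))
    if (n_pairs == 0L) {
      warning("pedigree simulation stopped at generation ", g,
              ": no breeding pairs left")
      break
    }
    n_off <- stats::rpois(n_pairs, mean_offspring)
    dam <- rep(fem[seq_len(n_pairs)], n_off)
    sire <- rep(mal[seq_len(n_pairs)], n_off)
    recruited <- stats::runif(length(dam)) < recruitment_prob
    dam <- dam[recruited]; sire <- sire[recruited]
    if (length(dam) == 0L) {
      warning("pedigree simulation stopped at generation ", g,
              ": no recruits")
      break
    }
    # a fraction of the new breeders are immigrants of unknown parentage,
    # displacing local recruits
    n_new <- length(dam)
    n_imm <- round(immigrant_fraction * n_new)
    if (n_imm > 0L) {
      drop <- sample.int(n_new, n_imm)
      dam <- dam[-drop]; sire <- sire[-drop]
    }
    ids <- if (length(dam)) sprintf("G%d_%04d", g, seq_along(dam)) else character(0)
    imm <- if (n_imm > 0L) sprintf("I%d_%04d", g, seq_len(n_imm)) else character(0)
    ped <- rbind(ped,
                 data.frame(id = ids, dam = dam, sire = sire,
                            stringsAsFactors = FALSE),
                 data.frame(id = imm, dam = NA_character_,
                            sire = NA_character_, stringsAsFactors = FALSE))
    new_ind <- data.frame(id = c(ids, imm),
                          sex = sample(c("F", "M"), length(ids) + n_imm,
                                       replace = TRUE),
                          generation = g, stringsAsFactors = FALSE)
    ind <- rbind(ind, new_ind)
    adults <- new_ind
  }
  list(pedigree = ped, individuals = ind)
}

#' Ground-truth variance components for simulation
#'
#' Named list of generative parameters: the fixed-effect vector `beta`
#' (recycled against the design; a scalar is the intercept), the nine
#' variance components and the cross-sex additive genetic covariance.  The
#' defaults are shaped like the variance partition estimated for a
#' repeatable cue in the study system: a dominant residual component, a
#' moderate nest-box component, and small genetic and permanent individual
#' components (all on the scale of a normalized response with phenotypic
#' variance near 1).
#'
#' @param ... Overrides of the default components.
#' @return Named list of class `sim_truth`.
#' @export
sim_truth <- function(...) {
  truth <- list(beta = 0, V_A_f = 0.0076, V_A_m = 0.037, Cov_A = 0,
                V_DOM_f = 0.0064, V_DOM_m = 0.093, V_PI_f = 0.0061,
                V_PI_m = 0.067, V_patch = 0.015, V_box = 0.012, V_R = 0.66)
  over <- list(...)
  bad <- setdiff(names(over), names(truth))
  if (length(bad)) stop("unknown truth component(s): ", paste(bad, collapse = ", "))
  truth[names(over)] <- over
  vs <- unlist(truth[setdiff(names(truth), c("beta", "Cov_A"))])
  if (any(vs < 0)) stop("variance components must be >= 0")
  if (abs(truth$Cov_A) > sqrt(truth$V_A_f * truth$V_A_m) + 1e-12)
    stop("|Cov_A| must not exceed sqrt(V_A_f * V_A_m)")
  structure(truth, class = "sim_truth")
}

# recursive pedigree kinship with memoisation; indices are row numbers of an
# ordered pedigree, 0 = unknown parent
.kinship_fun <- function(si, di) {
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  kin <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }   # recurse on the later-born
    key <- paste0(i, "|", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) {
      0.5 * (1 + kin(.zero_na(si[i]), .zero_na(di[i])))
    } else {
      0.5 * (kin(.zero_na(si[i]), j) + kin(.zero_na(di[i]), j))
    }
    memo[[key]] <- v
    v
  }
  kin
}

.zero_na <- function(x) if (is.na(x)) 0L else x

# symmetric PSD square root, tolerant of zero and near-singular matrices
.psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate pair phenotypes from the joint-phenotype animal model
#'
#' Generates one Gaussian response per breeding-pair record as the sum of
#' fixed effects, female and male additive genetic values, dominance
#' deviations, permanent individual effects, patch and box effects, and a
#' residual, with the variance components of `truth`.  Additive genetic
#' values are sampled by gene dropping: founders draw from
#' `MVN(0, C_A)` and descendants from the parental mean plus a Mendelian
#' segregation deviation with variance `C_A * (0.5 - 0.25 (F_sire + F_dam))`
#' (adjusted when a parent is unknown), which is exact for the pedigree
#' multivariate normal model without factorizing `C_A %x% A`.
#'
#' @param pedigree Pedigree data frame (`id`, `dam`, `sire`).
#' @param pairs Data frame of breeding-pair records with `female_id`,
#'   `male_id`, `patch_id`, `chosen_box_id`, and (for the full fixed design)
#'   `female_status`, `male_status`, `choice_date`.
#' @param truth A [sim_truth()] list.
#' @param seed Integer seed.
#' @param fixed `"full"` or `"intercept"` design for the fixed effects.
#' @return List with `data` (the `pairs` table plus response column `y`),
#'   `components` (per-row additive decomposition of `y`; its row sums equal
#'   `y` exactly), `latents` (per-individual genetic, dominance and
#'   permanent effects, per-patch and per-box effects) and `truth`.
#' @export
simulate_phenotypes <- function(pedigree, pairs, truth = sim_truth(),
                                seed = 1L, fixed = c("full", "intercept")) {
  fixed <- match.arg(fixed)
  if (!inherits(truth, "sim_truth")) truth <- do.call(sim_truth, truth)
  set.seed(seed)
  ped <- prune_pedigree(pedigree, c(pairs$female_id, pairs$male_id))
  n_ped <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  kin <- .kinship_fun(si, di)

  # inbreeding coefficient of each individual (kinship of its parents)
  Fi <- vapply(seq_len(n_ped), function(i)
    kin(.zero_na(si[i]), .zero_na(di[i])), 0)

  CA <- matrix(c(truth$V_A_f, truth$Cov_A, truth$Cov_A, truth$V_A_m), 2, 2)
  sqrtCA <- .psd_sqrt(CA)
  a <- matrix(0, n_ped, 2, dimnames = list(ped$id, c("a_f", "a_m")))
  for (i in seq_len(n_ped)) {
    s <- si[i]; d <- di[i]
    if (!is.na(s) && !is.na(d)) {
      mu <- 0.5 * (a[s, ] + a[d, ])
      w <- 0.5 - 0.25 * (Fi[s] + Fi[d])
    } else if (!is.na(s) || !is.na(d)) {
      p <- if (is.na(s)) d else s
      mu <- 0.5 * a[p, ]
      w <- 0.75 - 0.25 * Fi[p]
    } else {
      mu <- c(0, 0)
      w <- 1
    }
    a[i, ] <- mu + sqrt(w) * as.numeric(sqrtCA %*% stats::rnorm(2))
  }

  ids_used <- unique(c(as.character(pairs$female_id),
                       as.character(pairs$male_id)))
  dom <- matrix(0, length(ids_used), 2,
                dimnames = list(ids_used, c("dom_f", "dom_m")))
  if (truth$V_DOM_f > 0 || truth$V_DOM_m > 0) {
    D <- dominance_matrix(ped)[ids_used, ids_used, drop = FALSE]
    sqrtD <- .psd_sqrt(D)
    if (truth$V_DOM_f > 0)
      dom[, 1L] <- sqrt(truth$V_DOM_f) * as.numeric(sqrtD %*% stats::rnorm(length(ids_used)))
    if (truth$V_DOM_m > 0)
      dom[, 2L] <- sqrt(truth$V_DOM_m) * as.numeric(sqrtD %*% stats::rnorm(length(ids_used)))
  }

  pi_f <- stats::rnorm(length(ids_used), 0, sqrt(truth$V_PI_f))
  pi_m <- stats::rnorm(length(ids_used), 0, sqrt(truth$V_PI_m))
  names(pi_f) <- names(pi_m) <- ids_used
  patches <- unique(as.character(pairs$patch_id))
  boxes <- unique(as.character(pairs$chosen_box_id))
  patch_eff <- stats::rnorm(length(patches), 0, sqrt(truth$V_patch))
  box_eff <- stats::rnorm(length(boxes), 0, sqrt(truth$V_box))
  names(patch_eff) <- patches
  names(box_eff) <- boxes

  X <- build_design(pairs, fixed = fixed)$X
  if (length(truth$beta) > ncol(X))
    stop("truth$beta has more coefficients than the fixed design has columns")
  beta <- rep(0, ncol(X))
  beta[seq_along(truth$beta)] <- truth$beta
  f <- as.character(pairs$female_id)
  m <- as.character(pairs$male_id)
  components <- data.frame(
    fixed = as.numeric(X %*% beta),
    a_f = a[f, 1L], a_m = a[m, 2L],
    dom_f = dom[f, 1L], dom_m = dom[m, 2L],
    pi_f = unname(pi_f[f]), pi_m = unname(pi_m[m]),
    patch = unname(patch_eff[as.character(pairs$patch_id)]),
    box = unname(box_eff[as.character(pairs$chosen_box_id)]),
    resid = stats::rnorm(nrow(pairs), 0, sqrt(truth$V_R)))
  rownames(components) <- NULL
  data <- pairs
  data$y <- rowSums(components)
  list(data = data, components = components,
       latents = list(a = a, dom = dom, pi_f = pi_f, pi_m = pi_m,
                      patch = patch_eff, box = box_eff,
                      inbreeding = stats::setNames(Fi, ped$id)),
       truth = truth)
}

#' Simulate yearly occupancy states and breeding-site choices
#'
#' Simulates, year by year, great tit occupancy, flycatcher pair formation
#' and sequential breeding-site choices among the currently empty boxes.
#' When any attraction coefficient is non-zero, a pair chooses a box with
#' probability proportional to `exp(sum_c attraction_c * N_bc)` where
#' `N_bc` is the box's neighbourhood value for cue `c` (computed with
#' [neighborhood_value()] from the states simulated so far); with all
#' coefficients zero the choice is uniform over available boxes.
#' Individuals surviving to a later year re-pair at random; statuses are
#' derived from individual histories (yearling in the first breeding year,
#' then philopatric or immigrant by comparison with the previous year's
#' patch).
#'
#' @param boxes Landscape data frame from [simulate_landscape()].
#' @param individuals Data frame with `id` and `sex` (`"F"`/`"M"`), e.g.
#'   from [simulate_pedigree()]; the recruitment pool.
#' @param attraction Named numeric vector of attraction coefficients, one
#'   per cue in `specs` (default all zero).
#' @param specs Cue specifications (default [default_cue_specs()]).
#' @param n_years,start_year Number of breeding seasons and first year.
#' @param pairs_per_year Breeding pairs formed each year.
#' @param survival Probability a breeder returns the next year.
#' @param philopatry Probability a returning female settles in her previous
#'   patch when it has empty boxes.
#' @param gt_prob Probability a box is taken by great tits before the
#'   flycatchers arrive.
#' @param fledge_lambda,fledge_max Poisson mean and cap of fledgling counts
#'   for occupied boxes.
#' @param seed Integer seed.
#' @return List with `states` (box-year table) and `events` (choice table
#'   including the per-event available-box set and both statuses).
#' @export
simulate_choice_histories <- function(boxes, individuals,
                                      attraction = NULL,
                                      specs = default_cue_specs(),
                                      n_years = 6L, start_year = 2005L,
                                      pairs_per_year = 100L, survival = 0.5,
                                      philopatry = 0.6, gt_prob = 0.15,
                                      fledge_lambda = 4, fledge_max = 8L,
                                      seed = 1L) {
  if (is.null(attraction)) {
    attraction <- stats::setNames(rep(0, length(specs)), names(specs))
  }
  if (any(!is.finite(attraction))) stop("attraction coefficients must be finite")
  if (pairs_per_year > nrow(boxes))
    stop("more pairs per year than nest boxes")
  set.seed(seed)
  use_cues <- any(attraction != 0)
  pool_f <- sample(individuals$id[individuals$sex == "F"])
  pool_m <- sample(individuals$id[individuals$sex == "M"])
  last_patch <- character(0)        # named by individual id
  first_year <- integer(0)
  active_f <- character(0); active_m <- character(0)
  states_by_year <- vector("list", n_years)
  events_by_year <- vector("list", n_years)
  prev_states <- NULL
  for (yr in start_year + seq_len(n_years) - 1L) {
    active_f <- active_f[stats::runif(length(active_f)) < survival]
    active_m <- active_m[stats::runif(length(active_m)) < survival]
    need_f <- pairs_per_year - length(active_f)
    need_m <- pairs_per_year - length(active_m)
    if (need_f > length(pool_f) || need_m > length(pool_m))
      stop("recruitment pool exhausted in year ", yr,
           "; supply more individuals or fewer pairs")
    rec_f <- pool_f[seq_len(max(need_f, 0L))]; pool_f <- setdiff(pool_f, rec_f)
    rec_m <- pool_m[seq_len(max(need_m, 0L))]; pool_m <- setdiff(pool_m, rec_m)
    # returning birds of both sexes tend to settle in their previous patch,
    # so pair them assortatively by previous patch (new recruits at random)
    fem <- sample(c(active_f, rec_f))[seq_len(pairs_per_year)]
    mal <- sample(c(active_m, rec_m))[seq_len(pairs_per_year)]
    fem <- fem[order(!fem %in% names(last_patch),
                     unname(last_patch[fem]), method = "radix")]
    mal <- mal[order(!mal %in% names(last_patch),
                     unname(last_patch[mal]), method = "radix")]
    first_year[setdiff(c(rec_f, rec_m), names(first_year))] <- yr

    occ <- ifelse(stats::runif(nrow(boxes)) < gt_prob, "great_tit", "empty")
    cur <- data.frame(box_id = boxes$box_id, year = yr, occupant = occ,
                      fledglings = 0L, stringsAsFactors = FALSE)
    dates <- sort(sample.int(40L, pairs_per_year, replace = TRUE))
    yr_events <- vector("list", pairs_per_year)
    for (k in seq_len(pairs_per_year)) {
      empty <- cur$box_id[cur$occupant == "empty"]
      if (length(empty) == 0L)
        stop("no empty box left in year ", yr, "; fewer pairs needed")
      prev <- stats::na.omit(unname(c(last_patch[fem[k]], last_patch[mal[k]])))
      patch_of <- boxes$patch_id[match(empty, boxes$box_id)]
      prev <- prev[prev %in% patch_of]
      pick_patch <- if (length(prev) && stats::runif(1) < philopatry) {
        prev[sample.int(length(prev), 1L)]
      } else {
        tab <- table(patch_of)
        sample(names(tab), 1L, prob = as.numeric(tab))
      }
      avail <- empty[patch_of == pick_patch]
      chosen <- if (!use_cues || length(avail) == 1L) {
        avail[sample.int(length(avail), 1L)]
      } else {
        st_view <- rbind(prev_states, cur)
        score <- numeric(length(avail))
        for (cn in names(specs)) {
          if (attraction[[cn]] == 0) next
          if (specs[[cn]]$year_offset < 0L && yr == start_year) next
          score <- score + attraction[[cn]] *
            vapply(avail, neighborhood_value, 0, spec = specs[[cn]],
                   boxes = boxes, states = st_view, year = yr)
        }
        avail[sample.int(length(avail), 1L,
                         prob = exp(score - max(score)))]
      }
      cur$occupant[cur$box_id == chosen] <- "flycatcher"
      f_stat <- .breeder_status(fem[k], yr, first_year, last_patch, pick_patch)
      m_stat <- .breeder_status(mal[k], yr, first_year, last_patch,
                                boxes$patch_id[boxes$box_id == chosen])
      yr_events[[k]] <- data.frame(
        pair_id = paste(fem[k], mal[k], yr, sep = "_"),
        female_id = fem[k], male_id = mal[k], year = yr,
        chosen_box_id = chosen, patch_id = pick_patch,
        choice_date = dates[k],
        female_status = f_stat, male_status = m_stat,
        available_box_ids = paste(avail, collapse = ";"),
        stringsAsFactors = FALSE)
    }
    occupied <- cur$occupant != "empty"
    cur$fledglings[occupied] <- pmin(stats::rpois(sum(occupied), fledge_lambda),
                                     fledge_max)
    states_by_year[[yr - start_year + 1L]] <- cur
    events_by_year[[yr - start_year + 1L]] <- do.call(rbind, yr_events)
    prev_states <- cur
    chosen_patch <- vapply(yr_events, function(e) e$patch_id, "")
    last_patch[fem] <- chosen_patch
    last_patch[mal] <- chosen_patch
    active_f <- fem; active_m <- mal
  }
  states <- do.call(rbind, states_by_year)
  events <- do.call(rbind, events_by_year)
  rownames(states) <- rownames(events) <- NULL
  list(states = states, events = events)
}

.breeder_status <- function(id, yr, first_year, last_patch, patch_now) {
  fy <- first_year[id]
  if (!is.na(fy) && fy == yr) return("yearling")
  prev <- last_patch[id]
  if (!is.null(prev) && !is.na(prev) && identical(unname(prev), patch_now))
    "older_philopatric"
  else "older_immigrant"
}

#' Simulate a complete synthetic study dataset
#'
#' Chains the landscape, pedigree, choice-history and phenotype simulators
#' under one master seed, producing every table the analysis pipeline
#' consumes (boxes, states, events, pedigree) together with the generative
#' truth and latent effects.  The same configuration and seed always yield
#' identical tables.
#'
#' @param config Nested list of arguments for the component simulators:
#'   `landscape`, `pedigree`, `choices` (passed to the respective
#'   `simulate_*` functions) and `truth` (a [sim_truth()] or list of
#'   overrides); missing parts use the component defaults.
#' @param seed Master seed; component seeds are derived deterministically.
#' @return List with `boxes`, `states`, `events`, `pedigree`,
#'   `individuals`, `phenotypes` (the [simulate_phenotypes()] result on the
#'   simulated events) and `truth`.
#' @export
simulate_dataset <- function(config = list(), seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 4L)
  boxes <- do.call(simulate_landscape,
                   c(config$landscape, list(seed = seeds[1L])))
  ped <- do.call(simulate_pedigree,
                 c(config$pedigree, list(seed = seeds[2L])))
  hist <- do.call(simulate_choice_histories,
                  c(list(boxes = boxes, individuals = ped$individuals),
                    config$choices, list(seed = seeds[3L])))
  truth_cfg <- config$truth %||% list()
  truth <- if (inherits(truth_cfg, "sim_truth")) truth_cfg
           else if (length(truth_cfg) &&
                    !all(names(truth_cfg) %in% names(unclass(sim_truth()))))
             sim_truth()   # per-cue truth lists are handled by run_pipeline()
           else do.call(sim_truth, truth_cfg)
  phen <- simulate_phenotypes(ped$pedigree, hist$events, truth,
                              seed = seeds[4L], fixed = "intercept")
  list(boxes = boxes, states = hist$states, events = hist$events,
       pedigree = ped$pedigree, individuals = ped$individuals,
       phenotypes = phen, truth = truth)
}
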