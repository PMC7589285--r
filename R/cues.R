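#' Specification of one social cue
#'
#' A social cue is the distance-weighted abundance or fledging success of a
#' focal species (conspecific flycatchers or great tits) in the neighbourhood
#' of a nest box, in either the current breeding year or the previous one.
#' The spatial scale of the neighbourhood is set by `alpha` (meters), the
#' decay constant of the exponential distance weight.
#'
#' @param cue_name Short identifier for the cue (used as a column name).
#' @param species `"conspecific"` (flycatcher) or `"great_tit"`.
#' @param field `"abundance"` (weighted count of occupied boxes) or
#'   `"success"` (weighted sum of fledgling counts).
#' @param year_offset `0` for the current year, `-1` for the previous year.
#' @param alpha Spatial-scale parameter in meters (> 0).
#' @return An object of class `cue_spec`.
#' @seealso [default_cue_specs()] for the five standard cues.
#' @export
cue_spec <- function(cue_name, species = c("conspecific", "great_tit"),
                     field = c("abundance", "success"),
                     year_offset = 0L, alpha = 7) {
  species <- match.arg(species)
  field <- match.arg(field)
  if (!year_offset %in% c(0L, -1L)) stop("'year_offset' must be 0 or -1")
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive number (meters)")
  structure(list(cue_name = as.character(cue_name), species = species,
                 field = field, year_offset = as.integer(year_offset),
                 alpha = alpha),
            class = "cue_spec")
}

#' The five standard social cues
#'
#' Cue definitions and spatial scales for the five response variables:
#' (a) conspecific abundance in the current year (alpha = 7 m),
#' (b) conspecific abundance in the previous year (alpha = 1 m),
#' (c) conspecific fledging success in the previous year (alpha = 83 m),
#' (d) great tit abundance in the current year (alpha = 11 m), and
#' (e) great tit abundance in the previous year (alpha = 75 m).
#'
#' @param alphas Named or positional numeric vector of length 5 overriding
#'   the default spatial scales, in the (a)--(e) order above.
#' @return Named list of five [cue_spec()] objects.
#' @export
default_cue_specs <- function(alphas = c(7, 1, 83, 11, 75)) {
  stopifnot(length(alphas) == 5L, all(alphas > 0))
  specs <- list(
    cue_spec("consp_abund_current", "conspecific", "abundance", 0L, alphas[[1L]]),
    cue_spec("consp_abund_prev", "conspecific", "abundance", -1L, alphas[[2L]]),
    cue_spec("consp_success_prev", "conspecific", "success", -1L, alphas[[3L]]),
    cue_spec("gt_abund_current", "great_tit", "abundance", 0L, alphas[[4L]]),
    cue_spec("gt_abund_prev", "great_tit", "abundance", -1L, alphas[[5L]])
  )
  names(specs) <- vapply(specs, `[[`, "", "cue_name")
  specs
}

# occupant code that counts for a cue species
.species_code <- function(species) {
  switch(species, conspecific = "flycatcher", great_tit = "great_tit",
         stop("unknown species '", species, "'"))
}

.check_boxes <- function(boxes) {
  need <- c("box_id", "patch_id", "x", "y")
  miss <- setdiff(need, names(boxes))
  if (length(miss)) stop("'boxes' lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(boxes$box_id)) stop("duplicated box_id in 'boxes'")
  if (any(!is.finite(boxes$x)) || any(!is.finite(boxes$y)))
    stop("box coordinates must be finite")
  if (!is.null(boxes$occupancy_prob) &&
      any(boxes$occupancy_prob < 0 | boxes$occupancy_prob > 1, na.rm = TRUE))
    stop("'occupancy_prob' must lie in [0, 1]")
  invisible(boxes)
}

#' Distance-weighted neighbourhood value of a cue at one nest box
#'
#' Sum over all nest boxes `j` in the focal box's forest patch (the focal box
#' included, with weight 1) of `exp(-d_ij / alpha) * c_j`, where `c_j` is the
#' occupancy indicator of the cue's species (abundance cues) or its fledgling
#' count (success cues) in the cue's reference year.  Boxes in other patches
#' never contribute, whatever their distance.
#'
#' @param focal_box Box id of the focal nest box.
#' @param spec A [cue_spec()].
#' @param boxes Data frame of nest boxes (`box_id`, `patch_id`, `x`, `y`,
#'   optionally `occupancy_prob`); planar coordinates in meters.
#' @param states Data frame of per-box per-year states (`box_id`, `year`,
#'   `occupant`, `fledglings`).
#' @param year Focal (choice) year; the cue is evaluated in
#'   `year + spec$year_offset`.
#' @return Weighted count (abundance) or weighted fledgling sum (success).
#' @export
neighborhood_value <- function(focal_box, spec, boxes, states, year) {
  .check_boxes(boxes)
  i <- match(focal_box, boxes$box_id)
  if (is.na(i)) stop("focal box '", focal_box, "' not found in 'boxes'")
  patch <- boxes[boxes$patch_id == boxes$patch_id[i], , drop = FALSE]
  ref_year <- year + spec$year_offset
  st <- states[states$year == ref_year &
                 states$box_id %in% patch$box_id, , drop = FALSE]
  covered <- patch$box_id %in% st$box_id
  if (!all(covered)) {
    missing_boxes <- patch$box_id[!covered]
    cond <- structure(
      class = c("cueqg_missing_state", "error", "condition"),
      list(message = paste0(
        "no state record for year ", ref_year, " for box(es): ",
        paste(utils::head(missing_boxes, 10L), collapse = ", "),
        if (length(missing_boxes) > 10L) ", ..."),
        call = sys.call(),
        boxes = missing_boxes,
        whole_patch = !any(covered)))
    stop(cond)
  }
  st <- st[match(patch$box_id, st$box_id), , drop = FALSE]
  code <- .species_code(spec$species)
  c_j <- if (spec$field == "abundance") {
    as.numeric(st$occupant == code)
  } else {
    ifelse(st$occupant == code, as.numeric(st$fledglings), 0)
  }
  d <- sqrt((patch$x - patch$x[patch$box_id == focal_box])^2 +
              (patch$y - patch$y[patch$box_id == focal_box])^2)
  sum(exp_weight(d, spec$alpha) * c_j)
}

.available_ids <- function(event) {
  av <- event$available_box_ids
  if (is.list(av)) av <- av[[1L]]
  if (is.character(av) && length(av) == 1L && grepl(";", av))
    av <- strsplit(av, ";", fixed = TRUE)[[1L]]
  av <- trimws(as.character(av))
  av[nzchar(av)]
}

#' Expected neighbourhood cue value under random breeding-site choice
#'
#' Average of [neighborhood_value()] over all nest boxes available to the
#' pair on its choice date (empty boxes in the patch, the chosen one
#' included), weighted by each box's historical probability of occupancy so
#' that intrinsically preferred sites count more.  When every occupancy
#' probability is zero the plain mean is used, with a warning.
#'
#' @param event One choice event: a list or one-row data frame with at least
#'   `chosen_box_id`, `year` and `available_box_ids` (character vector, list
#'   column, or `";"`-separated string).
#' @inheritParams neighborhood_value
#' @return Expected cue value for a random choice among available boxes.
#' @export
expected_random_choice_value <- function(event, spec, boxes, states) {
  av <- .available_ids(event)
  if (length(av) == 0L) stop("event has an empty available-box set")
  chosen <- as.character(event$chosen_box_id)
  if (!chosen %in% av)
    stop("chosen box '", chosen, "' is not in the available-box set")
  bad <- setdiff(av, boxes$box_id)
  if (length(bad)) stop("available box(es) not in 'boxes': ",
                        paste(bad, collapse = ", "))
  patches <- boxes$patch_id[match(av, boxes$box_id)]
  if (length(unique(patches)) != 1L)
    stop("available boxes span more than one patch")
  vals <- vapply(av, neighborhood_value, 0, spec = spec, boxes = boxes,
                 states = states, year = event$year)
  p <- boxes$occupancy_prob[match(av, boxes$box_id)]
  if (is.null(p) || all(is.na(p))) p <- rep(1, length(av))
  p[is.na(p)] <- 0
  if (sum(p) == 0) {
    warning("all occupancy probabilities are zero over the available set; ",
            "falling back to the unweighted mean")
    p <- rep(1, length(av))
  }
  sum(p * vals) / sum(p)
}

#' Raw social-cue response of one breeding-site choice
#'
#' Difference between the neighbourhood cue value at the chosen nest box and
#' its expectation under random choice among the available boxes
#' ([expected_random_choice_value()]).  Positive values indicate attraction
#' to above-average neighbourhoods for this cue, zero a random choice, and
#' negative values avoidance.  Returns `NA` when the cue's reference year is
#' entirely unmonitored for the patch (for example a previous-year cue in a
#' patch with no earlier records); partially missing state records are an
#' error naming the offending boxes.
#'
#' @inheritParams expected_random_choice_value
#' @return Raw response `Y` in cue units, or `NA` if undefined.
#' @export
cue_response <- function(event, spec, boxes, states) {
  tryCatch({
    chosen_val <- neighborhood_value(as.character(event$chosen_box_id), spec,
                                     boxes, states, event$year)
    chosen_val - expected_random_choice_value(event, spec, boxes, states)
  }, cueqg_missing_state = function(cond) {
    if (isTRUE(cond$whole_patch)) NA_real_ else stop(cond)
  })
}

#' Normalize raw responses by their root mean square
#'
#' Divides each raw response by the square root of the mean of its squares,
#' computed once over all non-missing observations of the response variable,
#' so that the normalized values satisfy `mean(y^2) = 1`.  Missing entries
#' stay missing.
#'
#' @param Y Numeric vector of raw responses (may contain `NA`).
#' @return Numeric vector of normalized responses, same length as `Y`.
#' @export
normalize_responses <- function(Y) {
  ok <- !is.na(Y)
  if (!any(ok)) stop("cannot normalize: all responses are missing")
  if (any(!is.finite(Y[ok]))) stop("responses must be finite or NA")
  rms <- sqrt(mean(Y[ok]^2))
  if (rms == 0) stop("cannot normalize: all non-missing responses are zero")
  Y / rms
}

#' Build the table of normalized cue responses and covariates
#'
#' Computes, for every breeding-pair choice event, the raw and normalized
#' response for each requested cue, and attaches the fixed-effect covariates
#' (female and male status, choice date).  Events for which the status of
#' either pair member is undefined are dropped (with a message giving the
#' count).  Each cue's normalization constant is computed over that cue's
#' non-missing responses, so sample sizes may differ across cues.
#'
#' @param events Data frame of choice events (`pair_id`, `female_id`,
#'   `male_id`, `year`, `chosen_box_id`, `choice_date`, `female_status`,
#'   `male_status`, `available_box_ids`).
#' @param boxes,states As in [neighborhood_value()].
#' @param specs List of [cue_spec()]s; defaults to the five standard cues.
#' @return A data frame of class `cue_response_table` with one row per
#'   retained event, columns `Y_<cue>` (raw) and `y_<cue>` (normalized) per
#'   cue, the covariates, and attributes `cue_n` (non-missing count per cue)
#'   and `n_dropped` (events removed for undefined status).
#' @export
build_response_table <- function(events, boxes, states,
                                 specs = default_cue_specs()) {
  .check_boxes(boxes)
  status_levels <- c("yearling", "older_philopatric", "older_immigrant")
  defined <- !is.na(events$female_status) & !is.na(events$male_status) &
    events$female_status %in% status_levels &
    events$male_status %in% status_levels
  n_dropped <- sum(!defined)
  if (n_dropped > 0L)
    message(n_dropped, " event(s) dropped: status undefined for one pair member")
  events <- events[defined, , drop = FALSE]

  out <- data.frame(
    pair_id = as.character(events$pair_id),
    female_id = as.character(events$female_id),
    male_id = as.character(events$male_id),
    year = events$year,
    chosen_box_id = as.character(events$chosen_box_id),
    patch_id = boxes$patch_id[match(as.character(events$chosen_box_id),
                                    boxes$box_id)],
    choice_date = events$choice_date,
    female_status = factor(events$female_status, levels = status_levels),
    male_status = factor(events$male_status, levels = status_levels),
    stringsAsFactors = FALSE
  )
  cue_n <- integer(length(specs))
  names(cue_n) <- vapply(specs, `[[`, "", "cue_name")
  for (spec in specs) {
    Y <- numeric(nrow(events))
    for (r in seq_len(nrow(events)))
      Y[r] <- cue_response(events[r, , drop = FALSE], spec, boxes, states)
    nm <- spec$cue_name
    out[[paste0("Y_", nm)]] <- Y
    out[[paste0("y_", nm)]] <- if (all(is.na(Y) | Y == 0)) {
      if (any(!is.na(Y))) warning("cue '", nm, "' has an all-zero response; ",
                                  "left unnormalized")
      Y
    } else normalize_responses(Y)
    cue_n[[nm]] <- sum(!is.na(Y))
  }
  attr(out, "cue_n") <- cue_n
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("cue_response_table", class(out))
  out
}
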