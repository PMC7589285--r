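spec_ab <- cue_spec("ab", "conspecific", "abundance", 0L, alpha = 10)

test_that("neighbourhood value sums weighted occupancy over the patch", {
  boxes <- make_line_boxes(3)
  st <- make_states(boxes, 2000)
  # no occupied boxes -> empty sum
  expect_identical(neighborhood_value("P1_b1", spec_ab, boxes, st, 2000), 0)
  # the focal box itself counts with weight 1
  st$occupant[1] <- "flycatcher"
  expect_equal(neighborhood_value("P1_b1", spec_ab, boxes, st, 2000), 1)
  # two occupied neighbours at 10 and 20 m, alpha = 10
  st$occupant <- c("empty", "flycatcher", "flycatcher")
  expect_equal(neighborhood_value("P1_b1", spec_ab, boxes, st, 2000),
               exp(-1) + exp(-2))
})

test_that("success cues sum fledgling counts of the cue species only", {
  boxes <- make_line_boxes(3)
  st <- make_states(boxes, 1999,
                    occupant = c("flycatcher", "great_tit", "flycatcher"),
                    fledglings = c(4L, 6L, 2L))
  sp <- cue_spec("sc", "conspecific", "success", -1L, alpha = 10)
  expect_equal(neighborhood_value("P1_b1", sp, boxes, st, 2000),
               4 + exp(-2) * 2)
  sp_gt <- cue_spec("gt", "great_tit", "abundance", -1L, alpha = 10)
  expect_equal(neighborhood_value("P1_b1", sp_gt, boxes, st, 2000), exp(-1))
})

test_that("boxes outside the focal patch never contribute", {
  boxes <- rbind(make_line_boxes(3),
                 data.frame(box_id = "P2_b1", patch_id = "P2",
                            x = 0.01, y = 0.01, occupancy_prob = 0.5))
  st <- make_states(boxes, 2000, occupant = c("empty", "empty", "empty",
                                              "flycatcher"))
  expect_identical(neighborhood_value("P1_b1", spec_ab, boxes, st, 2000), 0)
})

test_that("missing state rows raise an error naming the boxes", {
  boxes <- make_line_boxes(3)
  st <- make_states(boxes, 2000)[-2, ]
  err <- tryCatch(neighborhood_value("P1_b1", spec_ab, boxes, st, 2000),
                  error = function(e) e)
  expect_s3_class(err, "cueqg_missing_state")
  expect_match(conditionMessage(err), "P1_b2")
})

test_that("expected value under random choice is the occupancy-weighted mean", {
  # two available boxes in distant clusters of one patch: the first sits on
  # top of 1 occupied box (value 1), the second on top of 3 (value 3)
  boxes <- data.frame(
    box_id = paste0("b", 1:6), patch_id = "P1",
    x = c(0, 5000, 0, 5000, 5000, 5000), y = 0,
    occupancy_prob = c(0.8, 0.2, 0, 0, 0, 0), stringsAsFactors = FALSE)
  st <- make_states(boxes, 2000,
                    occupant = c("empty", "empty", "flycatcher",
                                 "flycatcher", "flycatcher", "flycatcher"))
  ev <- make_event("b1", c("b1", "b2"))
  expect_equal(expected_random_choice_value(ev, spec_ab, boxes, st),
               (0.8 * 1 + 0.2 * 3) / 1.0, tolerance = 1e-12)
  expect_equal(cue_response(ev, spec_ab, boxes, st), 1 - 1.4,
               tolerance = 1e-12)
  # equal occupancy weights over values {1, 3} -> the plain mean, 2
  boxes$occupancy_prob <- c(0.5, 0.5, 0, 0, 0, 0)
  expect_equal(expected_random_choice_value(ev, spec_ab, boxes, st), 2,
               tolerance = 1e-12)
  # single available box -> its own neighbourhood value
  ev1 <- make_event("b1", "b1")
  expect_equal(expected_random_choice_value(ev1, spec_ab, boxes, st),
               neighborhood_value("b1", spec_ab, boxes, st, 2000))
  expect_error(expected_random_choice_value(make_event("b1", character(0)),
                                            spec_ab, boxes, st), "empty")
  expect_error(expected_random_choice_value(make_event("b1", "b2"),
                                            spec_ab, boxes, st), "not in the")
})

test_that("all-zero occupancy weights fall back to the plain mean with warning", {
  boxes <- make_line_boxes(2)
  boxes$occupancy_prob <- 0
  st <- make_states(boxes, 2000, occupant = c("flycatcher", "empty"))
  ev <- make_event("P1_b1", boxes$box_id)
  expect_warning(v <- expected_random_choice_value(ev, spec_ab, boxes, st),
                 "unweighted")
  nv <- sapply(boxes$box_id, neighborhood_value, spec = spec_ab,
               boxes = boxes, states = st, year = 2000)
  expect_equal(v, mean(nv))
})

test_that("cue response is zero under symmetric environments and missing when unmonitored", {
  boxes <- make_line_boxes(4)
  st <- make_states(boxes, 2000)
  ev <- make_event("P1_b2", boxes$box_id)
  expect_equal(cue_response(ev, spec_ab, boxes, st), 0)
  # previous-year cue with no previous-year records at all -> missing
  sp_prev <- cue_spec("abp", "conspecific", "abundance", -1L, alpha = 10)
  expect_true(is.na(cue_response(ev, sp_prev, boxes, st)))
  # partial previous-year coverage -> hard error
  st_part <- rbind(st, make_states(boxes, 1999)[-1, ])
  expect_error(cue_response(ev, sp_prev, boxes, st_part), "P1_b1")
})

test_that("cue response matches a brute-force double-loop oracle", {
  set.seed(401)
  for (rep in 1:8) {
    k <- sample(3:10, 1)
    boxes <- data.frame(box_id = sprintf("b%d", 1:k), patch_id = "P1",
                        x = runif(k, 0, 80), y = runif(k, 0, 80),
                        occupancy_prob = runif(k, 0.1, 0.9),
                        stringsAsFactors = FALSE)
    occ <- sample(c("empty", "flycatcher", "great_tit"), k, replace = TRUE)
    st <- rbind(make_states(boxes, 2000, occupant = occ,
                            fledglings = sample(0:6, k, replace = TRUE)),
                make_states(boxes, 1999,
                            occupant = sample(c("empty", "flycatcher"), k,
                                              replace = TRUE),
                            fledglings = sample(0:6, k, replace = TRUE)))
    avail <- boxes$box_id[occ == "empty"]
    if (length(avail) == 0) next
    ev <- make_event(sample(avail, 1), avail)
    for (sp in list(spec_ab,
                    cue_spec("s", "conspecific", "success", -1L, 25),
                    cue_spec("g", "great_tit", "abundance", 0L, 40))) {
      expect_equal(cue_response(ev, sp, boxes, st),
                   oracle_cue_response(ev, sp, boxes, st), tolerance = 1e-12)
    }
  }
})

test_that("relabelling unavailable boxes never changes the response", {
  set.seed(402)
  boxes <- make_line_boxes(6)
  occ <- c("flycatcher", "empty", "flycatcher", "empty", "empty", "flycatcher")
  st <- make_states(boxes, 2000, occupant = occ)
  avail <- boxes$box_id[occ == "empty"]
  ev <- make_event(avail[1], avail)
  y0 <- cue_response(ev, spec_ab, boxes, st)
  # permute ids of the unavailable (occupied) boxes
  unav <- which(occ != "empty")
  perm <- sample(unav)
  boxes2 <- boxes
  boxes2$box_id[unav] <- boxes$box_id[perm]
  st2 <- make_states(boxes2, 2000, occupant = occ)
  expect_equal(cue_response(ev, spec_ab, boxes2, st2), y0)
})

test_that("normalization gives unit mean square and keeps missing values", {
  expect_equal(normalize_responses(c(3, 4)), c(3, 4) / sqrt(12.5))
  expect_equal(normalize_responses(c(7, 7, 7)), c(1, 1, 1))
  expect_equal(normalize_responses(c(-2, -2)), c(-1, -1))
  expect_equal(normalize_responses(c(1, -1)), c(1, -1))
  y <- normalize_responses(c(1.5, NA, -0.3, 2))
  expect_true(is.na(y[2]))
  expect_equal(mean(y[!is.na(y)]^2), 1, tolerance = 1e-12)
  expect_error(normalize_responses(c(0, 0)), "zero")
  expect_error(normalize_responses(c(NA_real_, NA_real_)), "missing")
})

test_that("response table drops undefined statuses and counts per-cue n", {
  boxes <- make_line_boxes(5)
  st <- rbind(make_states(boxes, 1999,
                          occupant = c("flycatcher", "empty", "great_tit",
                                       "empty", "flycatcher"),
                          fledglings = c(3L, 0L, 5L, 0L, 2L)),
              make_states(boxes, 2000,
                          occupant = c("empty", "flycatcher", "empty",
                                       "empty", "empty")))
  ev <- rbind(make_event("P1_b1", c("P1_b1", "P1_b3"), year = 2000,
                         female = "f1", male = "m1"),
              make_event("P1_b4", c("P1_b4", "P1_b5"), year = 2000,
                         female = "f2", male = "m2",
                         m_status = NA_character_))
  suppressWarnings(
    expect_message(tab <- build_response_table(ev, boxes, st), "1 event"))
  expect_identical(nrow(tab), 1L)
  expect_identical(unname(attr(tab, "cue_n")),
                   rep(1L, 5L))
  expect_identical(attr(tab, "n_dropped"), 1L)
  expect_true(all(paste0("y_", names(default_cue_specs())) %in% names(tab)))
  # zero events still yields the full column set
  expect_message(
    tab0 <- build_response_table(ev[ev$female_id == "none", ], boxes, st),
    NA)
  expect_identical(nrow(tab0), 0L)
  expect_true(all(paste0("Y_", names(default_cue_specs())) %in% names(tab0)))
})

test_that("each cue column of a built table has unit mean square", {
  s <- small_study()
  tab <- build_response_table(s$hist$events, s$boxes, s$hist$states)
  for (cue in names(default_cue_specs())) {
    y <- tab[[paste0("y_", cue)]]
    y <- y[!is.na(y)]
    expect_equal(mean(y^2), 1, tolerance = 1e-12)
  }
  # previous-year cues lose the first season, current-year cues do not
  n <- attr(tab, "cue_n")
  expect_true(all(n[c("consp_abund_prev", "consp_success_prev",
                      "gt_abund_prev")] < nrow(tab)))
  expect_identical(unname(n["consp_abund_current"]), nrow(tab))
})
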