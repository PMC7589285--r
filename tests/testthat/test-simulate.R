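test_that("landscape simulation is deterministic with exact patch counts", {
  b1 <- simulate_landscape(n_patches = 15, boxes_per_patch = 40, seed = 101)
  b2 <- simulate_landscape(n_patches = 15, boxes_per_patch = 40, seed = 101)
  expect_identical(b1, b2)
  expect_identical(nrow(b1), 600L)
  expect_true(all(table(b1$patch_id) == 40L))
  expect_true(all(b1$occupancy_prob >= 0 & b1$occupancy_prob <= 1))
  expect_false(anyDuplicated(b1$box_id) > 0)
  b3 <- simulate_landscape(n_patches = 1, boxes_per_patch = 2, seed = 1)
  expect_identical(nrow(b3), 2L)
  expect_identical(unique(b3$patch_id), "P01")
  expect_error(simulate_landscape(n_patches = 0), "positive")
})

test_that("pedigree simulation produces the requested structure", {
  p0 <- simulate_pedigree(n_founders = 20, n_generations = 0, seed = 102)
  expect_identical(nrow(p0$pedigree), 20L)
  expect_true(all(is.na(p0$pedigree$dam)))
  # all-immigrant recruitment severs every genetic link
  pim <- simulate_pedigree(n_founders = 30, n_generations = 3,
                           immigrant_fraction = 1, seed = 103)
  expect_true(all(is.na(pim$pedigree$dam)) && all(is.na(pim$pedigree$sire)))
  A <- additive_matrix(pim$pedigree)
  expect_equal(unname(A), diag(nrow(A)))
  # full-sib counts match an independent recount from the parent columns
  ped <- simulate_pedigree(n_founders = 100, n_generations = 4,
                           seed = 104)$pedigree
  known <- ped[!is.na(ped$dam) & !is.na(ped$sire), ]
  fam <- paste(known$dam, known$sire)
  n_fullsib_pairs <- sum(choose(table(fam), 2))
  Af <- additive_matrix(ped)
  sib_from_A <- 0
  for (i in seq_len(nrow(known))) for (j in seq_len(nrow(known))) {
    if (i < j && known$dam[i] == known$dam[j] && known$sire[i] == known$sire[j])
      sib_from_A <- sib_from_A + 1
  }
  expect_identical(sib_from_A, n_fullsib_pairs)
  expect_identical(simulate_pedigree(n_founders = 100, n_generations = 4,
                                     seed = 104)$pedigree, ped)
  expect_error(simulate_pedigree(n_founders = 3), "even")
})

test_that("phenotype simulation is exact in its degenerate and latent identities", {
  s <- small_study()
  zero <- sim_truth(V_A_f = 0, V_A_m = 0, Cov_A = 0, V_DOM_f = 0,
                    V_DOM_m = 0, V_PI_f = 0, V_PI_m = 0, V_patch = 0,
                    V_box = 0, V_R = 0, beta = 0.7)
  ph <- simulate_phenotypes(s$ped$pedigree, s$hist$events, zero, seed = 105,
                            fixed = "intercept")
  expect_equal(ph$data$y, rep(0.7, nrow(ph$data)), tolerance = 1e-12)
  full <- simulate_phenotypes(s$ped$pedigree, s$hist$events, sim_truth(),
                              seed = 106, fixed = "intercept")
  expect_identical(full$data$y, rowSums(full$components))
  expect_error(sim_truth(V_A_f = 1, V_A_m = 1, Cov_A = 1.5), "Cov_A")
  expect_error(sim_truth(V_R = -1), ">= 0")
})

test_that("gene dropping reproduces the target genetic moments", {
  n <- 5000
  founders <- data.frame(id = sprintf("i%04d", 1:n), dam = NA, sire = NA)
  pairs <- data.frame(female_id = founders$id[seq(1, n, 2)],
                      male_id = founders$id[seq(2, n, 2)],
                      patch_id = "P1", chosen_box_id = "b1")
  tr <- sim_truth(V_A_f = 1, V_A_m = 0, Cov_A = 0, V_DOM_f = 0, V_DOM_m = 0,
                  V_PI_f = 0, V_PI_m = 0, V_patch = 0, V_box = 0, V_R = 0)
  ph <- simulate_phenotypes(founders, pairs, tr, seed = 107,
                            fixed = "intercept")
  expect_gt(var(ph$latents$a[, "a_f"]), 0.95)
  expect_lt(var(ph$latents$a[, "a_f"]), 1.05)
  tr2 <- sim_truth(V_A_f = 1, V_A_m = 1, Cov_A = 0.5, V_DOM_f = 0,
                   V_DOM_m = 0, V_PI_f = 0, V_PI_m = 0, V_patch = 0,
                   V_box = 0, V_R = 0)
  ph2 <- simulate_phenotypes(founders, pairs, tr2, seed = 108,
                             fixed = "intercept")
  r <- cor(ph2$latents$a[, "a_f"], ph2$latents$a[, "a_m"])
  expect_gt(r, 0.45); expect_lt(r, 0.55)
  # parent-offspring additive covariance is half the variance
  trio <- data.frame(id = c(sprintf("p%04d", 1:4000),
                            sprintf("k%04d", 1:2000)),
                     dam = c(rep(NA, 4000), sprintf("p%04d", 1:2000)),
                     sire = c(rep(NA, 4000), sprintf("p%04d", 2001:4000)))
  pairs3 <- data.frame(female_id = trio$id[1:2000],
                       male_id = trio$id[4001:6000],
                       patch_id = "P1", chosen_box_id = "b1")
  ph3 <- simulate_phenotypes(trio, pairs3, tr, seed = 109,
                             fixed = "intercept")
  a <- ph3$latents$a
  expect_equal(cov(a[sprintf("p%04d", 1:2000), "a_f"],
                   a[sprintf("k%04d", 1:2000), "a_f"]), 0.5,
               tolerance = 0.07)
})

test_that("choice histories are deterministic, respect availability, and derive statuses", {
  s <- small_study()
  h2 <- simulate_choice_histories(s$boxes, s$ped$individuals, n_years = 4L,
                                  pairs_per_year = 40L, survival = 0.6,
                                  seed = 13L)
  expect_identical(h2$states, s$hist$states)
  expect_identical(h2$events, s$hist$events)
  ev <- s$hist$events
  for (i in seq_len(nrow(ev))) {
    avail <- strsplit(ev$available_box_ids[i], ";")[[1]]
    expect_true(ev$chosen_box_id[i] %in% avail)
    expect_identical(unique(s$boxes$patch_id[match(avail, s$boxes$box_id)]),
                     ev$patch_id[i])
  }
  # first-year breeders are yearlings
  first_season <- ev[ev$year == min(ev$year), ]
  expect_true(all(first_season$female_status == "yearling"))
  expect_true(all(c("older_philopatric", "older_immigrant") %in%
                    ev$female_status))
  expect_true(all(s$hist$states$fledglings >= 0))
  expect_true(all(s$hist$states$occupant[s$hist$states$fledglings > 0] !=
                    "empty"))
  expect_error(
    simulate_choice_histories(s$boxes[1:10, ], s$ped$individuals,
                              pairs_per_year = 50L, seed = 1),
    "more pairs")
})

test_that("with zero attraction the choice among available boxes is uniform", {
  boxes <- make_line_boxes(12)
  pool <- data.frame(id = sprintf("x%05d", 1:20000),
                     sex = rep(c("F", "M"), 10000),
                     stringsAsFactors = FALSE)
  h <- simulate_choice_histories(boxes, pool, n_years = 8000L,
                                 pairs_per_year = 1L, survival = 0,
                                 gt_prob = 0, seed = 110L)
  counts <- table(factor(h$events$chosen_box_id, levels = boxes$box_id))
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("positive conspecific attraction yields attraction-signed responses", {
  boxes <- simulate_landscape(n_patches = 2, boxes_per_patch = 25, seed = 111)
  pool <- data.frame(id = sprintf("y%04d", 1:2000),
                     sex = rep(c("F", "M"), 1000), stringsAsFactors = FALSE)
  attr_vec <- c(consp_abund_current = 2, consp_abund_prev = 0,
                consp_success_prev = 0, gt_abund_current = 0,
                gt_abund_prev = 0)
  h <- simulate_choice_histories(boxes, pool, attraction = attr_vec,
                                 n_years = 3L, pairs_per_year = 15L,
                                 survival = 0.5, seed = 112L)
  tab <- build_response_table(h$events, boxes, h$states)
  y <- tab$y_consp_abund_current
  expect_gt(mean(y, na.rm = TRUE), 0)
})

test_that("a full simulated dataset is reproducible byte for byte on disk", {
  cfg <- list(landscape = list(n_patches = 3, boxes_per_patch = 12),
              pedigree = list(n_founders = 60, n_generations = 2),
              choices = list(n_years = 3, pairs_per_year = 12),
              truth = list(V_DOM_f = 0, V_DOM_m = 0))
  d1 <- simulate_dataset(cfg, seed = 113)
  d2 <- simulate_dataset(cfg, seed = 113)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$phenotypes$data$y, d2$phenotypes$data$y)
  t1 <- file.path(tempdir(), "simA"); t2 <- file.path(tempdir(), "simB")
  write_dataset_csv(d1, t1)
  write_dataset_csv(d2, t2)
  for (f in list.files(t1)) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))))
  }
  # every event member has a pedigree record
  expect_true(all(c(d1$events$female_id, d1$events$male_id) %in%
                    d1$pedigree$id))
})
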