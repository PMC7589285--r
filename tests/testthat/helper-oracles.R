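# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written in the most naive way possible
# (explicit loops, recursive definitions) so the package implementation is
# checked against a genuinely different computation path.

# recursive kinship coefficient f(i, j) on an ordered pedigree data frame;
# unknown parents contribute 0
oracle_kinship <- function(ped) {
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i == j) 0.5 * (1 + f(si[i], di[i]))
         else 0.5 * (f(si[i], j) + f(di[i], j))
    memo[[key]] <- v
    v
  }
  n <- nrow(ped)
  out <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) out[i, j] <- out[j, i] <- f(i, j)
  out
}

# random valid pedigree: parents always drawn from earlier individuals
random_pedigree <- function(n, p_known = 0.7, seed = 1) {
  set.seed(seed)
  id <- sprintf("i%03d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (i in 3:n) {
    if (runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      dam[i] <- id[pick[1L]]
      sire[i] <- id[pick[2L]]
    }
  }
  data.frame(id = id, dam = dam, sire = sire, stringsAsFactors = FALSE)
}

# brute-force ancestor closure by repeated single-parent lookups
oracle_ancestor_closure <- function(ped, keep) {
  res <- character(0)
  todo <- keep
  while (length(todo)) {
    x <- todo[[1L]]
    todo <- todo[-1L]
    if (x %in% res) next
    res <- c(res, x)
    row <- ped[ped$id == x, ]
    if (nrow(row) == 1L) {
      for (p in c(row$dam, row$sire))
        if (!is.na(p)) todo <- c(todo, p)
    }
  }
  sort(res)
}

# brute-force cue response: explicit double loop, no vectorization
oracle_cue_response <- function(event, spec, boxes, states) {
  code <- if (spec$species == "conspecific") "flycatcher" else "great_tit"
  nv <- function(fb) {
    i <- which(boxes$box_id == fb)
    ref_year <- event$year + spec$year_offset
    tot <- 0
    for (j in seq_len(nrow(boxes))) {
      if (boxes$patch_id[j] != boxes$patch_id[i]) next
      st <- states[states$box_id == boxes$box_id[j] &
                     states$year == ref_year, ]
      if (nrow(st) != 1L) stop("oracle: missing state")
      cj <- if (spec$field == "abundance") {
        if (st$occupant == code) 1 else 0
      } else {
        if (st$occupant == code) st$fledglings else 0
      }
      dd <- sqrt((boxes$x[j] - boxes$x[i])^2 + (boxes$y[j] - boxes$y[i])^2)
      tot <- tot + exp(-dd / spec$alpha) * cj
    }
    tot
  }
  av <- strsplit(event$available_box_ids, ";")[[1L]]
  num <- 0; den <- 0
  for (b in av) {
    p <- boxes$occupancy_prob[boxes$box_id == b]
    num <- num + p * nv(b)
    den <- den + p
  }
  nv(event$chosen_box_id) - num / den
}

# tiny single-patch fixture: k boxes on a line, 10 m apart
make_line_boxes <- function(k, patch = "P1", spacing = 10, occ = 0.5) {
  data.frame(box_id = sprintf("%s_b%d", patch, seq_len(k)),
             patch_id = patch,
             x = spacing * (seq_len(k) - 1L), y = 0,
             occupancy_prob = rep_len(occ, k),
             stringsAsFactors = FALSE)
}

make_states <- function(boxes, year, occupant = "empty", fledglings = 0L) {
  data.frame(box_id = boxes$box_id, year = year,
             occupant = rep_len(occupant, nrow(boxes)),
             fledglings = rep_len(fledglings, nrow(boxes)),
             stringsAsFactors = FALSE)
}

make_event <- function(chosen, available, year = 2000,
                       female = "f1", male = "m1",
                       f_status = "yearling", m_status = "yearling",
                       date = 10) {
  data.frame(pair_id = paste(female, male, year, sep = "_"),
             female_id = female, male_id = male, year = year,
             chosen_box_id = chosen, choice_date = date,
             female_status = f_status, male_status = m_status,
             available_box_ids = paste(available, collapse = ";"),
             stringsAsFactors = FALSE)
}

# moderate synthetic study used by several fitting tests (built once)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ped <- simulate_pedigree(n_founders = 120L, n_generations = 2L,
                               mean_offspring = 5, recruitment_prob = 0.5,
                               immigrant_fraction = 0.2, seed = 11L)
      boxes <- simulate_landscape(n_patches = 5L, boxes_per_patch = 16L,
                                  seed = 12L)
      hist <- simulate_choice_histories(boxes, ped$individuals,
                                        n_years = 4L, pairs_per_year = 40L,
                                        survival = 0.6, seed = 13L)
      cache <<- list(ped = ped, boxes = boxes, hist = hist)
    }
    cache
  }
})
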