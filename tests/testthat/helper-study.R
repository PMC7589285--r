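# Replicate-study generator for the sampler validation suites: a synthetic
# population (pedigree + landscape + yearly choices) and pair phenotypes
# drawn from the joint-phenotype model with the given true components.
simulate_qg_replicate <- function(seed, truth,
                                  n_founders = 300L, n_generations = 3L,
                                  n_patches = 10L, boxes_per_patch = 30L,
                                  n_years = 5L, pairs_per_year = 160L,
                                  survival = 0.65) {
  set.seed(seed)
  seeds <- sample.int(2^30, 3L)
  ped <- simulate_pedigree(n_founders = n_founders,
                           n_generations = n_generations,
                           mean_offspring = 5, recruitment_prob = 0.45,
                           immigrant_fraction = 0.2, seed = seeds[1L])
  boxes <- simulate_landscape(n_patches = n_patches,
                              boxes_per_patch = boxes_per_patch,
                              seed = seeds[2L])
  hist <- simulate_choice_histories(boxes, ped$individuals,
                                    n_years = n_years,
                                    pairs_per_year = pairs_per_year,
                                    survival = survival, seed = seeds[3L])
  ph <- simulate_phenotypes(ped$pedigree, hist$events, truth,
                            seed = seeds[3L] + 1L, fixed = "intercept")
  list(data = ph$data, pedigree = ped$pedigree, truth = ph$truth)
}
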