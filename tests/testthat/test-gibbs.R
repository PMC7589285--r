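intercept_X <- function(n) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))

test_that("residual posterior matches the conjugate closed form", {
  set.seed(31)
  y <- rnorm(80, 2, 1.5)
  st <- mcmc_settings(n_chains = 1L, n_iter = 4500L, burn_in = 500L,
                      thin = 1L, seed = 3L)
  s <- gibbs_fit(y, intercept_X(80), settings = st)
  vr <- s$draws[, "V_R"]
  n <- length(y)
  a <- (1 + n - 1) / 2                    # prior nu = 1, flat location
  b <- (1 + sum((y - mean(y))^2)) / 2
  mcse <- sd(vr) / sqrt(as.numeric(effective_sample_size(vr)))
  expect_lt(abs(mean(vr) - b / (a - 1)), 3 * mcse)
  expect_equal(mean(s$draws[, "(Intercept)"]), mean(y), tolerance = 0.1)
})

test_that("fixed-effect posterior matches conjugate linear regression", {
  set.seed(32)
  n <- 120
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = runif(n))
  beta_true <- c(1, -2, 0.5)
  y <- as.numeric(X %*% beta_true) + rnorm(n, 0, 0.7)
  st <- mcmc_settings(n_chains = 1L, n_iter = 4000L, burn_in = 500L,
                      thin = 1L, seed = 4L)
  s <- gibbs_fit(y, X, settings = st)
  bhat <- solve(crossprod(X), crossprod(X, y))
  for (j in 1:3) {
    d <- s$draws[, colnames(X)[j]]
    expect_lt(abs(mean(d) - bhat[j]), 4 * sd(d) / sqrt(1000))
  }
})

test_that("draws are invariant to the ordering of observations", {
  set.seed(33)
  n <- 60
  g <- sample(paste0("id", 1:12), n, replace = TRUE)
  y <- rnorm(n) + rnorm(12)[as.integer(factor(g))]
  st <- mcmc_settings(n_chains = 1L, n_iter = 400L, burn_in = 100L,
                      thin = 3L, seed = 5L)
  f1 <- gibbs_fit(y, intercept_X(n), list(term_iid("g", g)), settings = st)
  perm <- sample(n)
  f2 <- gibbs_fit(y[perm], intercept_X(n), list(term_iid("g", g[perm])),
                  settings = st)
  expect_equal(f1$draws, f2$draws, tolerance = 1e-9)
})

test_that("swapping the labels of identical individuals leaves summaries unchanged", {
  set.seed(34)
  n <- 40
  g <- rep(paste0("id", 1:8), each = 5)
  y <- rep(rnorm(8, 0, 1), each = 5) + rnorm(n, 0, 0.5)
  # make id1 and id2 carry literally identical records
  y[g == "id2"] <- y[g == "id1"]
  st <- mcmc_settings(n_chains = 1L, n_iter = 3000L, burn_in = 500L,
                      thin = 2L, seed = 6L)
  f1 <- gibbs_fit(y, intercept_X(n), list(term_iid("g", g)), settings = st)
  g2 <- g
  g2[g == "id1"] <- "id2"
  g2[g == "id2"] <- "id1"
  f2 <- gibbs_fit(y, intercept_X(n), list(term_iid("g", g2)), settings = st)
  expect_identical(f1$draws, f2$draws)   # same matrices after level sorting
})

test_that("a duplicated iid term splits the variance its single-term fit finds", {
  set.seed(35)
  n_g <- 40
  g <- rep(sprintf("id%02d", 1:n_g), each = 5)
  y <- rep(rnorm(n_g, 0, 1), each = 5) + rnorm(length(g), 0, 0.7)
  st <- mcmc_settings(n_chains = 1L, n_iter = 6000L, burn_in = 1000L,
                      thin = 2L, seed = 7L)
  f1 <- gibbs_fit(y, intercept_X(length(g)), list(term_iid("g", g)),
                  settings = st)
  f2 <- gibbs_fit(y, intercept_X(length(g)),
                  list(term_iid("g1", g), term_iid("g2", g)), settings = st)
  v_single <- posterior_median(f1$draws[, "V_g"])
  v_total <- posterior_median(f2$draws[, "V_g1"] + f2$draws[, "V_g2"])
  expect_lt(abs(v_total - v_single) / v_single, 0.25)
})

test_that("posterior medians agree with an REML cross-check on strong signal", {
  skip_if_not_installed("lme4")
  set.seed(36)
  n_g <- 50
  g <- rep(sprintf("id%02d", 1:n_g), each = 6)
  y <- rep(rnorm(n_g, 0, 1.2), each = 6) + rnorm(length(g), 0, 0.6)
  st <- mcmc_settings(n_chains = 1L, n_iter = 4000L, burn_in = 1000L,
                      thin = 2L, seed = 8L)
  s <- gibbs_fit(y, intercept_X(length(g)), list(term_iid("g", g)),
                 settings = st)
  lf <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE,
                   data = data.frame(y = y, g = g))
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_lt(abs(posterior_median(s$draws[, "V_g"]) - vc$vcov[1]) / vc$vcov[1],
            0.3)
  expect_lt(abs(posterior_median(s$draws[, "V_R"]) - vc$vcov[2]) / vc$vcov[2],
            0.3)
})

test_that("variance draws are positive and the sampled 2x2 genetic block is PD", {
  s <- small_study()
  tab <- build_response_table(s$hist$events, s$boxes, s$hist$states)
  st <- mcmc_settings(n_chains = 1L, n_iter = 700L, burn_in = 200L,
                      thin = 5L, seed = 9L)
  fit <- fit_animal_model(tab, "y_consp_abund_current", s$ped$pedigree,
                          cross_sex_covariance = TRUE, fixed = "intercept",
                          mcmc = st)
  dr <- fit$samples$draws
  vs <- dr[, c(fit$samples$term_labels[fit$samples$term_labels != "Cov_A"],
               "V_R")]
  expect_true(all(vs > 0))
  expect_true(all(dr[, "V_A_f"] * dr[, "V_A_m"] - dr[, "Cov_A"]^2 > 0))
})

test_that("missing responses are rejected by the engine but dropped by fitters", {
  expect_error(gibbs_fit(c(1, NA, 3), intercept_X(3)), "missing")
  s <- small_study()
  tab <- build_response_table(s$hist$events, s$boxes, s$hist$states)
  st <- mcmc_settings(n_chains = 1L, n_iter = 300L, burn_in = 100L,
                      thin = 2L, seed = 10L)
  expect_message(
    fit <- fit_repeatability(tab, "y_gt_abund_prev", fixed = "intercept",
                             mcmc = st),
    "dropped")
  expect_identical(fit$n_obs, sum(!is.na(tab$y_gt_abund_prev)))
})

test_that("fit objects print, summarize, plot and expose draws", {
  s <- small_study()
  tab <- build_response_table(s$hist$events, s$boxes, s$hist$states)
  st <- mcmc_settings(n_chains = 2L, n_iter = 400L, burn_in = 100L,
                      thin = 3L, seed = 12L)
  fit <- fit_repeatability(tab, "y_consp_abund_current", fixed = "intercept",
                           mcmc = st)
  out <- capture.output(print(fit))
  expect_true(any(grepl("Variance components", out)))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.cueqg_fit")
  expect_true(any(grepl("Derived metrics", capture.output(print(sm)))))
  expect_named(coef(fit), "(Intercept)")
  expect_identical(nrow(as.matrix(fit)), 200L)
  expect_true(all(c("psrf", "ess", "lag1") %in%
                    names(fit$samples$diagnostics)))
  expect_true(all(is.finite(fit$samples$diagnostics$psrf)))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
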