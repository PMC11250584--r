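test_that("pointwise log-likelihood entries follow the normal closed form", {
  eff <- data.frame(study_id = c("s1", "s2"), effect_id = c("e1", "e2"),
                    g = c(0.5, -0.2), se_g = c(1, 2))
  spec <- meta_model_spec()
  design <- build_design_matrix(eff, spec)
  fit <- structure(list(
    beta = array(0.5, c(2, 2, 1), dimnames = list(NULL, NULL, "(Intercept)")),
    u = array(0, c(2, 2, 2)), tau = matrix(0.3, 2, 2), sigma_res = NULL,
    design = design), class = "posterior_draws")
  ll <- pointwise_loglik(fit)
  # observation at its predicted mean with se = 1: -0.5 log(2 pi)
  expect_equal(ll[1, 1], -0.5 * log(2 * pi), tolerance = 1e-12)
  expect_equal(ll[1, 2], dnorm(-0.2, 0.5, 2, log = TRUE), tolerance = 1e-12)

  # consistency with the likelihood part of log_posterior
  lp_all <- log_posterior(0.5, c(0, 0), 0.3, design, eff$g, eff$se_g)
  prior <- dnorm(0.5, 0, 1, log = TRUE) +
    sum(dnorm(c(0, 0), 0, 0.3, log = TRUE)) +
    log(2 / (pi * 0.5)) - log1p((0.3 / 0.5)^2)
  expect_equal(sum(ll[1, ]), lp_all - prior, tolerance = 1e-10)
})

test_that("the generalized Pareto tail estimator recovers known shapes", {
  set.seed(20)
  x <- rgpd(10000, k = 0.5, sigma = 1)
  f <- fit_generalized_pareto(x)
  expect_lt(abs(f$k_hat - 0.5), 0.05)
  expect_lt(abs(f$sigma_hat - 1), 0.1)

  # exponential data sit at the GPD limit k -> 0
  e <- fit_generalized_pareto(rexp(10000))
  expect_lt(abs(e$k_hat), 0.05)

  # scale equivariance: scaling the sample scales sigma, not k
  f10 <- fit_generalized_pareto(10 * x)
  expect_equal(f10$k_hat, f$k_hat, tolerance = 1e-10)
  expect_equal(f10$sigma_hat, 10 * f$sigma_hat, tolerance = 1e-6)

  expect_error(fit_generalized_pareto(c(1, 2)), ">= 5")
  expect_warning(fit_generalized_pareto(rep(1, 10)), "degenerate")
})

test_that("PSIS-LOO agrees with brute-force leave-one-out refits", {
  # 8 effects, intercept-only, tau fixed: exact LOO via closed-form
  # posterior-predictive density on each held-out point
  set.seed(22)
  n <- 8
  tau <- 0.3
  se <- runif(n, 0.2, 0.4)
  g <- rnorm(n, 0.3, sqrt(se^2 + tau^2))
  eff <- data.frame(study_id = sprintf("s%d", 1:n),
                    effect_id = sprintf("e%d", 1:n), g = g, se_g = se)
  fit <- sample_posterior(eff, meta_model_spec(), chains = 4, iter = 3000,
                          warmup = 1000, seed = 24, fix_tau = tau)
  # marginal likelihood of effect i: N(b0, se_i^2 + tau^2); draws carry u
  beta <- as_draws_matrix(fit, "beta")[, 1]
  u <- as_draws_matrix(fit, "u")
  ll <- vapply(seq_len(n), function(i)
    dnorm(g[i], beta + u[, i], se[i], log = TRUE),
    numeric(length(beta)))
  res <- psis_loo(ll)
  # exact LOO oracle: with one effect per study and tau fixed, dropping
  # effect i gives conjugate posterior b0 | g[-i]; integrating b0 and u_i
  # out, the held-out density is N(g_i | m_-i, v_-i + se_i^2 + tau^2)
  exact <- vapply(seq_len(n), function(i) {
    post <- conjugate_intercept_posterior(g[-i], se[-i], tau)
    dnorm(g[i], post$mean, sqrt(post$sd^2 + tau^2 + se[i]^2), log = TRUE)
  }, 0)
  ok <- res$pareto_k < 0.7
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(res$pointwise_elpd[ok] - exact[ok])), 2 * res$elpd_se)
  # LOO penalizes relative to the in-sample log pointwise density
  expect_lt(res$elpd_total, sum(res$lpd))
  expect_equal(res$elpd_total, sum(res$pointwise_elpd))
  expect_equal(res$elpd_se, sqrt(n * var(res$pointwise_elpd)))
})

test_that("smoothed weights never exceed the raw maximum", {
  set.seed(25)
  ll <- matrix(rnorm(400 * 6, sd = 2), 400, 6)
  res <- psis_loo(ll)
  expect_true(all(is.finite(res$pointwise_elpd)))
  expect_error(psis_loo(cbind(ll, NA)), "non-finite")
})

test_that("model comparisons behave like paired Z statistics", {
  set.seed(26)
  ll_a <- matrix(rnorm(200 * 10), 200, 10)
  ll_b <- ll_a + matrix(rnorm(200 * 10, 0, 0.1), 200, 10)
  la <- psis_loo(ll_a)
  lb <- psis_loo(ll_b)
  self <- compare_models(la, la)
  expect_equal(self$elpd_diff, 0)
  expect_equal(self$se_diff, 0)
  expect_true(is.na(self$ratio))
  ab <- compare_models(la, lb)
  ba <- compare_models(lb, la)
  expect_equal(ab$elpd_diff, -ba$elpd_diff)
  expect_equal(ab$se_diff, ba$se_diff)
  expect_error(compare_models(la, psis_loo(ll_a[, 1:5])), "different")
})

test_that("candidate enumeration matches the binomial coefficients", {
  base8 <- meta_model_spec(default_moderator_schemas())
  expect_length(enumerate_candidates(base8, 2), 28)
  expect_length(enumerate_candidates(base8, 3), 56)
  base3 <- meta_model_spec(default_moderator_schemas()[1:3])
  expect_length(enumerate_candidates(base3, 2), 3)
  expect_error(enumerate_candidates(base8, 4), "order")
  # each order-3 candidate carries its three marginal two-way interactions
  c3 <- enumerate_candidates(base8, 3)[[1]]
  expect_equal(lengths(c3$interactions), c(2, 2, 2, 3))
})

test_that("a strong interaction in the truth is detected by the sweep", {
  # moderators are study-level, so part of any interaction signal is
  # absorbed by the random intercepts; detection needs a sizable corpus
  tr <- simulation_truth(
    n_studies = 80, effects_per_study = c(4, 6), tau = 0.1,
    subjects_per_arm = c(25, 40),
    beta = c("polarity: anodal - cathodal x intensity" = 1.0),
    spec = meta_model_spec(
      list(moderator_schema("polarity", "categorical",
                            levels = c("anodal", "cathodal")),
           moderator_schema("intensity", "continuous"),
           moderator_schema("duration", "continuous")),
      interactions = list(c("polarity", "intensity"))))
  sim <- simulate_meta_dataset(tr, seed = 30)
  base <- meta_model_spec(tr$spec$moderators)
  sw <- run_sweep(sim$effects, base, order = 2, chains = 2, iter = 1500,
                  warmup = 500, seed = 33)
  expect_equal(sw$n_models, 4)           # base + choose(3, 2)
  expect_equal(sw$best_model, "polarity x intensity")
  base_row <- sw$table[sw$table$model_id == "Base Model (Only Additive Terms)", ]
  expect_lt(base_row$ratio, -2)
  # repeated run with the same seed is identical
  sw2 <- run_sweep(sim$effects, base, order = 2, chains = 2, iter = 1500,
                   warmup = 500, seed = 33)
  expect_identical(sw$table, sw2$table)
})
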