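test_that("log posterior matches term-by-term density evaluation", {
  spec <- meta_model_spec()
  eff <- data.frame(study_id = "s1", effect_id = "e1", g = 0, se_g = 1)
  d <- build_design_matrix(eff, spec)
  # lik log N(0|0,1) + prior log N(0|0,1) + log N(0|0,0.5) + log HC(0.5|0.5)
  expected <- dnorm(0, 0, 1, log = TRUE) * 2 +
    dnorm(0, 0, 0.5, log = TRUE) + log(2 / pi)
  expect_equal(log_posterior(0, 0, 0.5, d, eff$g, eff$se_g), expected,
               tolerance = 1e-10)
  expect_equal(expected, -2.51525, tolerance = 1e-5)
})

test_that("location shifts move only the intercept prior term", {
  spec <- meta_model_spec()
  eff <- tiny_effects(4, 2, seed = 2)
  d <- build_design_matrix(eff, spec)
  u <- rnorm(4, 0, 0.1)
  base <- log_posterior(0.2, u, 0.4, d, eff$g, eff$se_g)
  shift <- log_posterior(0.2 + 1, u, 0.4, d, eff$g + 1, eff$se_g)
  prior_delta <- dnorm(1.2, 0, 1, log = TRUE) - dnorm(0.2, 0, 1, log = TRUE)
  expect_equal(shift - base, prior_delta, tolerance = 1e-10)
})

test_that("degenerate random-effect scales are rejected states, not errors", {
  spec <- meta_model_spec()
  eff <- tiny_effects(3, 2)
  d <- build_design_matrix(eff, spec)
  expect_identical(log_posterior(0, rep(0.5, 3), -1, d, eff$g, eff$se_g), -Inf)
  expect_identical(log_posterior(0, rep(0.5, 3), 0, d, eff$g, eff$se_g), -Inf)
})

test_that("sampling is deterministic given a seed and rejects degenerate input", {
  eff <- tiny_effects(5, 2, polarity = function(n)
    sample(c("anodal", "cathodal"), n, TRUE),
    intensity = function(n) runif(n, 0.25, 5))
  spec <- small_spec()
  f1 <- sample_posterior(eff, spec, chains = 2, iter = 300, warmup = 100,
                         seed = 99)
  f2 <- sample_posterior(eff, spec, chains = 2, iter = 300, warmup = 100,
                         seed = 99)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$tau, f2$tau)

  expect_error(sample_posterior(eff[0, ], spec), "no effects")
  one_study <- eff[eff$study_id == "s01", ]
  expect_error(sample_posterior(one_study, spec), "single study")
})

test_that("posterior of the intercept matches the conjugate closed form", {
  # one effect per study, tau fixed: marginally g_i ~ N(b0, se_i^2 + tau^2)
  set.seed(42)
  n <- 20
  tau <- 0.35
  se <- runif(n, 0.15, 0.5)
  g <- rnorm(n, 0.4, sqrt(se^2 + tau^2))
  eff <- data.frame(study_id = sprintf("s%02d", 1:n),
                    effect_id = sprintf("e%02d", 1:n), g = g, se_g = se)
  oracle <- conjugate_intercept_posterior(g, se, tau)
  fit <- sample_posterior(eff, meta_model_spec(), chains = 4, iter = 4000,
                          warmup = 1000, seed = 7, fix_tau = tau)
  b0 <- as_draws_matrix(fit, "beta")[, 1]
  mcse_mean <- sd(b0) / sqrt(suppressWarnings(
    convergence_diagnostics(fit))$ess[1])
  expect_lt(abs(mean(b0) - oracle$mean), 3 * mcse_mean)
  expect_equal(sd(b0), oracle$sd, tolerance = 0.05)
})

test_that("prior-only sampling reproduces the stated priors", {
  eff <- tiny_effects(10, 2, polarity = function(n)
    sample(c("anodal", "cathodal"), n, TRUE),
    intensity = function(n) runif(n, 0.25, 5))
  fit <- sample_posterior(eff, small_spec(), chains = 2, iter = 6000,
                          warmup = 1000, seed = 31, prior_only = TRUE)
  beta <- as_draws_matrix(fit, "beta")
  tau <- as_draws_matrix(fit, "tau")[, 1]
  S <- nrow(beta)
  # intercept ~ N(0,1), slopes ~ N(0,2.5); MC tolerance ~3 SE of the mean/SD
  expect_lt(abs(mean(beta[, 1])), 4 / sqrt(S))
  expect_equal(sd(beta[, 1]), 1, tolerance = 0.06)
  expect_equal(sd(beta[, 2]), 2.5, tolerance = 0.15)
  # half-Cauchy(0, 0.5): median = scale, quartiles at scale*tan(pi/8, 3pi/8)
  expect_equal(median(tau), 0.5, tolerance = 0.06)
  expect_equal(unname(quantile(tau, 0.25)), 0.5 * tan(pi / 8),
               tolerance = 0.05)
})

test_that("vanishing sampling error drives the posterior onto the true surface", {
  # data generated exactly on the model surface with se -> 0: the
  # posterior mean surface must reproduce it, overriding the priors
  set.seed(8)
  eff <- tiny_effects(12, 3, se = 1e-4,
    polarity = function(n) sample(c("anodal", "cathodal"), n, TRUE),
    intensity = function(n) runif(n, 0.25, 5))
  spec <- small_spec()
  d <- build_design_matrix(eff, spec)
  beta_true <- c(0.3, 0.4, 0.1)
  u_true <- rnorm(12, 0, 0.3)
  eff$g <- drop(d$X %*% beta_true) + u_true[as.integer(d$study)]
  fit <- sample_posterior(eff, spec, chains = 2, iter = 800, warmup = 300,
                          seed = 5)
  beta_hat <- colMeans(as_draws_matrix(fit, "beta"))
  u_hat <- colMeans(as_draws_matrix(fit, "u"))
  pred <- drop(d$X %*% beta_hat) + u_hat[as.integer(d$study)]
  expect_equal(unname(pred), unname(eff$g), tolerance = 1e-3)
  # the non-intercept slopes are identified and recovered
  expect_equal(unname(beta_hat[2:3]), beta_true[2:3], tolerance = 0.05)
})

test_that("row order does not change posterior summaries", {
  eff <- tiny_effects(8, 3, seed = 13, polarity = function(n)
    sample(c("anodal", "cathodal"), n, TRUE),
    intensity = function(n) runif(n, 0.25, 5))
  spec <- small_spec()
  perm <- sample(nrow(eff))
  f1 <- sample_posterior(eff, spec, chains = 2, iter = 2000, warmup = 500,
                         seed = 3)
  f2 <- sample_posterior(eff[perm, ], spec, chains = 2, iter = 2000,
                         warmup = 500, seed = 3)
  s1 <- summarize_fit(f1)
  s2 <- summarize_fit(f2)
  # summation order changes floating point at ~1e-15, which the sampler's
  # accept/reject decisions can amplify; agreement is to Monte Carlo error
  expect_lt(max(abs(s1$fixed$median - s2$fixed$median)), 0.08)
  expect_lt(abs(s1$random$median - s2$random$median), 0.08)
  expect_identical(s1$fixed$term, s2$fixed$term)
})

test_that("an optional residual SD can be estimated for sensitivity checks", {
  set.seed(17)
  n_st <- 15
  eff <- tiny_effects(n_st, 3, se = 0.1, seed = 17)
  # inflate observation noise well beyond the declared SEs
  eff$g <- eff$g + rnorm(nrow(eff), 0, 0.5)
  spec <- meta_model_spec(estimate_residual_sd = TRUE)
  fit <- sample_posterior(eff, spec, chains = 2, iter = 800, warmup = 300,
                          seed = 23)
  sig <- as_draws_matrix(fit, "sigma_res")[, 1]
  expect_true(all(sig > 0))
  expect_gt(median(sig), 0.2)
})

test_that("posterior point estimates agree with a frequentist REML fit", {
  skip_if_not_installed("metafor")
  set.seed(29)
  tr <- small_truth(beta = c("(Intercept)" = 0.3), tau = 0.3, n_studies = 40)
  sim <- simulate_meta_dataset(tr, seed = 44)
  eff <- sim$effects
  fit <- sample_posterior(eff, meta_model_spec(), chains = 2, iter = 2500,
                          warmup = 500, seed = 45)
  s <- summarize_fit(fit)
  rma_fit <- metafor::rma.mv(yi = eff$g, V = eff$se_g^2,
                             random = ~ 1 | study_id, data = eff,
                             method = "REML")
  expect_equal(s$fixed$median[1], unname(rma_fit$beta[1, 1]), tolerance = 0.05)
  expect_equal(s$random$median, sqrt(rma_fit$sigma2), tolerance = 0.08)
})
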