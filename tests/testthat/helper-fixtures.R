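# Shared fixtures and independent oracles used across test files.

# A minimal effect table: `per_study` effects from each of `n_studies`
# studies, optional moderator columns supplied via `...` as generator
# functions of the row count.
tiny_effects <- function(n_studies = 5, per_study = 2, g = NULL, se = 0.3,
                         seed = 1, ...) {
  set.seed(seed)
  n <- n_studies * per_study
  out <- data.frame(
    study_id = rep(sprintf("s%02d", seq_len(n_studies)), each = per_study),
    effect_id = sprintf("e%03d", seq_len(n)),
    g = if (is.null(g)) rnorm(n, 0, 0.5) else rep_len(g, n),
    se_g = rep_len(se, n))
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]](n)
  out
}

# Brute-force HPD oracle: exhaustive search over all contiguous windows of
# the sorted sample holding ceiling(mass * S) draws.
hpd_bruteforce <- function(draws, mass) {
  x <- sort(draws)
  S <- length(x)
  m <- ceiling(mass * S)
  best <- c(x[1], x[S])
  best_w <- Inf
  for (i in seq_len(S - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < best_w) {
      best_w <- w
      best <- c(x[i], x[i + m - 1])
    }
  }
  best
}

# Closed-form posterior for the intercept of an intercept-only model with
# one effect per study and fixed tau: marginally g_i ~ N(b0, se_i^2 + tau^2)
# with prior b0 ~ N(0, prior_sd^2). Independent of the Gibbs route.
conjugate_intercept_posterior <- function(g, se, tau, prior_sd = 1) {
  w <- 1 / (se^2 + tau^2)
  post_var <- 1 / (sum(w) + 1 / prior_sd^2)
  list(mean = post_var * sum(w * g), sd = sqrt(post_var))
}

# GPD random numbers for tail-estimator checks (inverse cdf).
rgpd <- function(n, k, sigma) {
  u <- runif(n)
  if (abs(k) < 1e-12) -sigma * log1p(-u) else sigma * ((1 - u)^(-k) - 1) / k
}

# Two-moderator specification used by several sampling tests.
small_spec <- function() {
  meta_model_spec(moderators = list(
    moderator_schema("polarity", "categorical", levels = c("anodal", "cathodal")),
    moderator_schema("intensity", "continuous")))
}

small_truth <- function(beta = NULL, tau = 0.3, n_studies = 25) {
  simulation_truth(n_studies = n_studies, effects_per_study = c(2, 4),
                   tau = tau, subjects_per_arm = c(15, 30),
                   beta = beta, spec = small_spec())
}
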