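# Posterior summaries: HPD intervals, probability of direction,
# standardized effects, Bayesian R-squared, and per-term summary tables.

#' Highest posterior density interval
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(mass * length(draws))` draws. When several windows tie on
#' width, the one starting at the lowest sorted index is returned.
#'
#' @param draws Nonempty numeric vector of posterior draws.
#' @param mass Interval mass in (0, 1); 0.95 by default (0.90 is the other
#'   conventional choice for interval plots).
#' @return Numeric vector `c(low, high)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (!length(draws)) stop("draws must be nonempty")
  if (!is.finite(mass) || mass <= 0 || mass >= 1) {
    stop("mass must lie strictly inside (0, 1)")
  }
  x <- sort(draws)
  S <- length(x)
  m <- ceiling(mass * S)
  if (m >= S) return(c(x[1], x[S]))
  starts <- seq_len(S - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- which.min(widths)  # lowest starting index on ties
  c(x[i], x[i + m - 1])
}

#' Probability of direction
#'
#' The larger of the posterior fractions above and below zero; draws
#' exactly at zero are split equally between the two sides. Ranges from
#' 0.50 (posterior centered on zero) to 1 (no density crosses zero).
#'
#' @param draws Nonempty numeric vector.
#' @return A proportion in \[0.5, 1\].
#' @export
prob_direction <- function(draws) {
  if (!length(draws)) stop("draws must be nonempty")
  S <- length(draws)
  pos <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / S
  max(pos, 1 - pos)
}

#' Standardized effect size (Bayesian analogue of Cohen's d)
#'
#' Divides each posterior draw of a coefficient by the square root of the
#' summed residual and random-effect variances,
#' \eqn{d^{(s)} = b^{(s)} / \sqrt{\sigma_{res}^2 + \tau^{(s)2}}}.
#' With known per-effect sampling SEs the model has no free residual SD, so
#' `residual_variance` defaults to 0 and the denominator is the
#' between-study SD alone; passing the mean known sampling variance instead
#' is a useful sensitivity check.
#'
#' @param term_draws Draws of the coefficient.
#' @param tau_draws Matching draws of the between-study SD (recycled if
#'   scalar).
#' @param residual_variance Non-negative residual variance (default 0).
#' @return Per-draw standardized effects.
#' @export
standardized_effect <- function(term_draws, tau_draws, residual_variance = 0) {
  if (length(tau_draws) == 1) tau_draws <- rep(tau_draws, length(term_draws))
  if (length(tau_draws) != length(term_draws)) {
    stop("term and tau draws must be aligned")
  }
  if (residual_variance < 0) stop("residual variance must be >= 0")
  denom2 <- residual_variance + tau_draws^2
  if (any(denom2 == 0)) {
    stop("undefined scale: tau = 0 with zero residual variance")
  }
  term_draws / sqrt(denom2)
}

#' Marginal and conditional Bayesian R-squared
#'
#' Per posterior draw, partitions variance into a fixed-effect part (the
#' variance across observations of the linear predictor), the random-effect
#' part tau^2, and the residual part (the mean of the known squared
#' sampling SEs, plus any estimated residual variance):
#' marginal R2 = V_fix / (V_fix + V_ran + V_res), conditional
#' R2 = (V_fix + V_ran) / (V_fix + V_ran + V_res). By construction the
#' per-draw marginal value never exceeds the conditional one.
#'
#' @param fit A `posterior_draws` object.
#' @param mass Interval mass for the reported credible intervals.
#' @return A `fit_indices` list: `r2_marginal` and `r2_conditional`, each
#'   with `median`, `low`, `high`, and the per-draw vectors.
#' @export
bayes_r2 <- function(fit, mass = 0.95) {
  beta <- as_draws_matrix(fit, "beta")
  tau <- as_draws_matrix(fit, "tau")[, 1]
  X <- fit$design$X
  n <- nrow(X)
  if (n < 2) stop("R-squared needs >= 2 observations")
  # V_fix per draw = b' S_x b with S_x the sample covariance of design rows
  Sx <- cov(X)
  v_fix <- rowSums((beta %*% Sx) * beta)
  v_ran <- tau^2
  v_res <- mean(fit$design$effects$se_g^2)
  if (!is.null(fit$sigma_res)) {
    v_res <- v_res + as_draws_matrix(fit, "sigma_res")[, 1]^2
  }
  tot <- v_fix + v_ran + v_res
  if (any(tot == 0)) stop("zero total variance")
  r2m <- v_fix / tot
  r2c <- (v_fix + v_ran) / tot
  summ <- function(x) {
    h <- hpd_interval(x, mass)
    list(median = median(x), low = h[1], high = h[2], draws = x)
  }
  structure(list(r2_marginal = summ(r2m), r2_conditional = summ(r2c)),
            class = "fit_indices")
}

#' Summarize a fitted meta-regression
#'
#' Builds the standard reporting table: one row per fixed-effect term with
#' posterior median, SD, HPD interval, probability of direction, and the
#' standardized effect (median and HPD), followed by a random-effects row
#' for the between-study SD and the marginal/conditional R-squared block.
#'
#' @param fit A `posterior_draws` object.
#' @param mass HPD interval mass (default 0.95).
#' @param residual_variance Residual variance used in the standardized
#'   effect denominator; 0 by default (see [standardized_effect()]).
#' @return A `meta_fit_summary` list with elements `fixed` (data.frame),
#'   `random` (data.frame), `r2` (`fit_indices`), `n_studies`, `n_effects`.
#' @export
summarize_fit <- function(fit, mass = 0.95, residual_variance = 0) {
  beta <- as_draws_matrix(fit, "beta")
  tau <- as_draws_matrix(fit, "tau")[, 1]
  labels <- colnames(beta)
  rows <- lapply(seq_along(labels), function(j) {
    b <- beta[, j]
    h <- hpd_interval(b, mass)
    d <- standardized_effect(b, tau, residual_variance)
    dh <- hpd_interval(d, mass)
    data.frame(term = labels[j], median = median(b), sd = sd(b),
               hpd_low = h[1], hpd_high = h[2], pd = prob_direction(b),
               d_median = median(d), d_low = dh[1], d_high = dh[2])
  })
  fixed <- do.call(rbind, rows)
  rownames(fixed) <- NULL
  th <- hpd_interval(tau, mass)
  random <- data.frame(term = "sigma_StudyID (Intercept)",
                       median = median(tau), sd = sd(tau),
                       hpd_low = th[1], hpd_high = th[2])
  structure(list(fixed = fixed, random = random, r2 = bayes_r2(fit, mass),
                 n_studies = nlevels(fit$design$study),
                 n_effects = nrow(fit$design$X), mass = mass),
            class = "meta_fit_summary")
}

#' @export
print.meta_fit_summary <- function(x, digits = 2, ...) {
  cat("Fixed predictors (posterior median, SD, HPD, pd):\n")
  f <- x$fixed
  body <- data.frame(term = f$term,
                     est = round(f$median, digits),
                     sd = round(f$sd, digits),
                     ci = sprintf("%.2f - %.2f (%.3f)",
                                  f$hpd_low, f$hpd_high, f$pd))
  print(body, row.names = FALSE, right = FALSE)
  cat(sprintf("\nRandom effects (N studies = %d)\n", x$n_studies))
  cat(sprintf("  %s  %.2f  %.2f  %.2f - %.2f\n", x$random$term,
              x$random$median, x$random$sd, x$random$hpd_low, x$random$hpd_high))
  cat(sprintf("N total effects = %d\n", x$n_effects))
  cat(sprintf("Marginal R2 = %.2f [%.2f, %.2f]\n",
              x$r2$r2_marginal$median, x$r2$r2_marginal$low, x$r2$r2_marginal$high))
  cat(sprintf("Conditional R2 = %.2f [%.2f, %.2f]\n",
              x$r2$r2_conditional$median, x$r2$r2_conditional$low,
              x$r2$r2_conditional$high))
  invisible(x)
}
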