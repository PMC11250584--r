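# Hedges' g effect sizes for active-vs-sham comparisons.

#' Small-sample correction factor for standardized mean differences
#'
#' Computes Hedges' correction \eqn{J = 1 - 3/(4 df - 1)}, which shrinks
#' Cohen's d toward zero to remove its small-sample positive bias.
#'
#' @param df Degrees of freedom (\eqn{n_1 + n_2 - 2} for two independent
#'   groups, \eqn{n - 1} for paired designs). Must be >= 1.
#' @return The correction factor, in (0, 1) for all `df >= 1`.
#' @export
hedges_j <- function(df) {
  if (any(!is.finite(df)) || any(df < 1)) {
    stop("degrees of freedom must be finite and >= 1")
  }
  1 - 3 / (4 * df - 1)
}

validate_groups <- function(m1, s1, m2, s2, n1, n2, paired = FALSE) {
  n <- length(m1)
  lens <- lengths(list(s1, m2, s2, n1, n2))
  if (any(lens != n)) stop("all group-summary vectors must share a length")
  if (any(!is.finite(c(m1, m2)))) stop("group means must be finite")
  if (any(!is.finite(c(s1, s2))) || any(s1 < 0) || any(s2 < 0)) {
    stop("group SDs must be finite and non-negative")
  }
  if (any(s1 == 0 & s2 == 0)) {
    stop("degenerate variance: both group SDs are zero")
  }
  if (any(n1 < 2) || any(n2 < 2) || any(n1 != round(n1)) || any(n2 != round(n2))) {
    stop("sample sizes must be integers >= 2")
  }
  if (paired && any(n1 != n2)) {
    stop("within-subject designs have a single subject count (n_active = n_control)")
  }
  invisible(TRUE)
}

#' Hedges' g for a between-subject comparison
#'
#' Standardizes the active-minus-control mean difference by the pooled SD,
#' applies the small-sample correction, and propagates the usual
#' large-sample variance of d:
#' \deqn{d = (m_1 - m_2)/s_p, \quad
#'   s_p^2 = \frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2},}
#' \deqn{\mathrm{Var}(d) = \frac{n_1+n_2}{n_1 n_2} + \frac{d^2}{2(n_1+n_2-2)},
#'   \quad g = J d, \quad \mathrm{SE}(g) = J \sqrt{\mathrm{Var}(d)}.}
#'
#' The sign is not yet harmonized for outcome direction; see
#' [harmonize_sign()].
#'
#' @param mean_active,sd_active,mean_control,sd_control Group means and SDs
#'   (vectorized).
#' @param n_active,n_control Group sizes, integers >= 2.
#' @return A data.frame with columns `g`, `se_g`, `d`, `j`.
#' @export
hedges_g_between <- function(mean_active, sd_active, mean_control, sd_control,
                             n_active, n_control) {
  validate_groups(mean_active, sd_active, mean_control, sd_control,
                  n_active, n_control)
  df <- n_active + n_control - 2
  s_pooled <- sqrt(((n_active - 1) * sd_active^2 +
                    (n_control - 1) * sd_control^2) / df)
  d <- (mean_active - mean_control) / s_pooled
  j <- hedges_j(df)
  var_d <- (n_active + n_control) / (n_active * n_control) + d^2 / (2 * df)
  data.frame(g = j * d, se_g = j * sqrt(var_d), d = d, j = j)
}

#' Hedges' g for a within-subject (repeated-measures) comparison
#'
#' Primary studies essentially never report the correlation between repeated
#' measures, so a moderate correlation (r = 0.50) is assumed by default. Two
#' standardizers are offered:
#'
#' * `"average"` (default): the mean difference is divided by
#'   \eqn{s_{av} = \sqrt{(s_1^2 + s_2^2)/2}}, keeping g on the same metric
#'   as a between-subject comparison; the sampling variance is
#'   \eqn{\mathrm{Var}(d) = 2(1-r)\,(1/n + d^2/(2n))}.
#' * `"difference"`: the difference-score standardizer
#'   \eqn{s_D = \sqrt{s_1^2 + s_2^2 - 2 r s_1 s_2}} gives
#'   \eqn{d_z} with \eqn{\mathrm{Var}(d_z) = 1/n + d_z^2/(2n)}. Note
#'   \eqn{d_z} is inflated relative to the between-subject metric when
#'   r > 0.5.
#'
#' When \eqn{s_1 = s_2} the averaged-variance standardizer at r = 0.50
#' coincides with taking an average of the variances exactly; with unequal
#' SDs the two readings differ slightly, which is why the standardizer is
#' exposed as an option. Degrees of freedom for the correction are n - 1.
#'
#' @inheritParams hedges_g_between
#' @param n Number of subjects measured twice, integer >= 2.
#' @param r Assumed correlation between repeated measures, in (-1, 1).
#' @param standardizer `"average"` or `"difference"`.
#' @return A data.frame with columns `g`, `se_g`, `d`, `j`.
#' @export
hedges_g_within <- function(mean_active, sd_active, mean_control, sd_control,
                            n, r = 0.5, standardizer = c("average", "difference")) {
  standardizer <- match.arg(standardizer)
  validate_groups(mean_active, sd_active, mean_control, sd_control,
                  n, n, paired = TRUE)
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("within-subject correlation must lie strictly inside (-1, 1)")
  }
  diff <- mean_active - mean_control
  if (standardizer == "average") {
    s_std <- sqrt((sd_active^2 + sd_control^2) / 2)
    if (any(s_std == 0)) stop("zero standardizer: both SDs are zero")
    d <- diff / s_std
    var_d <- 2 * (1 - r) * (1 / n + d^2 / (2 * n))
  } else {
    s_std <- sqrt(sd_active^2 + sd_control^2 - 2 * r * sd_active * sd_control)
    if (any(s_std == 0)) stop("zero standardizer: difference-score SD is zero")
    d <- diff / s_std
    var_d <- 1 / n + d^2 / (2 * n)
  }
  j <- hedges_j(n - 1)
  data.frame(g = j * d, se_g = j * sqrt(var_d), d = d, j = j)
}

#' Harmonize the sign of an effect size with behavioral improvement
#'
#' Positive g always encodes that active stimulation improved behavior
#' relative to sham. For outcomes where lower raw values are better (reaction
#' times, error rates), the raw standardized difference is negated.
#'
#' @param g Effect size(s), finite.
#' @param higher_is_better Logical; `TRUE` when larger raw outcome values
#'   mean better performance.
#' @return g with improvement-positive sign.
#' @export
harmonize_sign <- function(g, higher_is_better) {
  if (any(!is.finite(g))) stop("g must be finite")
  ifelse(higher_is_better, g, -g)
}

#' Convert a raw group-summary table into signed effect sizes
#'
#' Applies [hedges_g_between()] or [hedges_g_within()] row-by-row according
#' to the `design` column, then harmonizes signs via the `higher_is_better`
#' column. Rows reporting standard errors instead of SDs (columns
#' `se_active`/`se_control`, used where `sd_active`/`sd_control` are missing)
#' are converted first via SD = SE * sqrt(n).
#'
#' @param raw A data.frame with columns `study_id`, `effect_id`, `design`
#'   (`"between"` or `"within"`), `mean_active`, `sd_active`, `mean_control`,
#'   `sd_control`, `n_active`, `n_control`, `higher_is_better`, optionally
#'   `within_correlation` (default 0.5), plus any moderator columns, which
#'   are carried through untouched.
#' @param standardizer Within-subject standardizer, see [hedges_g_within()].
#' @return A data.frame of effect records: `study_id`, `effect_id`, `g`,
#'   `se_g`, and the carried-through moderator columns.
#' @export
compute_effect_sizes <- function(raw, standardizer = "average") {
  required <- c("study_id", "effect_id", "design", "mean_active",
                "mean_control", "n_active", "n_control", "higher_is_better")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("raw table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(raw$design %in% c("between", "within"))) {
    stop("design must be 'between' or 'within'")
  }
  sd1 <- if ("sd_active" %in% names(raw)) raw$sd_active else rep(NA_real_, nrow(raw))
  sd2 <- if ("sd_control" %in% names(raw)) raw$sd_control else rep(NA_real_, nrow(raw))
  if ("se_active" %in% names(raw)) {
    fill <- is.na(sd1) & !is.na(raw$se_active)
    sd1[fill] <- raw$se_active[fill] * sqrt(raw$n_active[fill])
  }
  if ("se_control" %in% names(raw)) {
    fill <- is.na(sd2) & !is.na(raw$se_control)
    sd2[fill] <- raw$se_control[fill] * sqrt(raw$n_control[fill])
  }
  if (any(is.na(sd1)) || any(is.na(sd2))) {
    stop("every row needs an SD (or SE) for both groups")
  }
  r <- if ("within_correlation" %in% names(raw)) {
    ifelse(is.na(raw$within_correlation), 0.5, raw$within_correlation)
  } else rep(0.5, nrow(raw))

  g <- se_g <- numeric(nrow(raw))
  bt <- raw$design == "between"
  if (any(bt)) {
    res <- hedges_g_between(raw$mean_active[bt], sd1[bt],
                            raw$mean_control[bt], sd2[bt],
                            raw$n_active[bt], raw$n_control[bt])
    g[bt] <- res$g
    se_g[bt] <- res$se_g
  }
  if (any(!bt)) {
    res <- hedges_g_within(raw$mean_active[!bt], sd1[!bt],
                           raw$mean_control[!bt], sd2[!bt],
                           raw$n_active[!bt], r[!bt],
                           standardizer = standardizer)
    g[!bt] <- res$g
    se_g[!bt] <- res$se_g
  }
  g <- harmonize_sign(g, as.logical(raw$higher_is_better))
  keep <- setdiff(names(raw),
                  c("mean_active", "sd_active", "mean_control", "sd_control",
                    "se_active", "se_control", "n_active", "n_control",
                    "higher_is_better", "within_correlation"))
  out <- cbind(data.frame(study_id = raw$study_id, effect_id = raw$effect_id,
                          g = g, se_g = se_g),
               raw[setdiff(keep, c("study_id", "effect_id"))])
  rownames(out) <- NULL
  out
}
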