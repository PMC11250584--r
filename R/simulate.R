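# Synthetic meta-analytic datasets with known ground truth, emulating the
# structure of an extracted tDCS effect-size table: studies with random
# intercepts, design-parameter moderators over their observed ranges, and
# per-effect sampling SEs derived from simulated group sizes.

#' Default moderator schemas for the domain-general model
#'
#' The eight stimulation/experiment parameters of the combined model:
#' polarity (anodal/cathodal), target laterality (left/right/bilateral),
#' stimulation timing (offline/online/mixed), design type (within/between),
#' plus continuous intensity (mA), duration per session (min), session
#' count, and electrode count. Reference levels are the last declared
#' level, matching the reporting convention (e.g., "Within - Between").
#'
#' @return Named list of [moderator_schema()] objects.
#' @export
default_moderator_schemas <- function() {
  list(
    polarity = moderator_schema("polarity", "categorical",
                                levels = c("anodal", "cathodal")),
    laterality = moderator_schema("laterality", "categorical",
                                  levels = c("left", "right", "bilateral")),
    timing = moderator_schema("timing", "categorical",
                              levels = c("offline", "online", "mixed")),
    design = moderator_schema("design", "categorical",
                              levels = c("within", "between")),
    intensity = moderator_schema("intensity", "continuous"),
    duration = moderator_schema("duration", "continuous"),
    sessions = moderator_schema("sessions", "continuous"),
    electrodes = moderator_schema("electrodes", "continuous")
  )
}

#' Define the ground truth of a simulated meta-analytic dataset
#'
#' Defaults mirror the scale of the domain-general analysis this package
#' targets: about 100 studies contributing about 7 effects each (721 / 106
#' effects per study in the motivating corpus), between-study SD 0.4, and
#' per-arm group sizes of 10-40 subjects. Moderators are drawn over their
#' observed ranges: intensity 0.25-5 mA, duration 5-30 min, sessions 1-20
#' (skewed toward single-session designs), electrodes 2-10 (skewed toward
#' conventional two-electrode montages).
#'
#' @param n_studies Number of studies.
#' @param effects_per_study Integer range `c(min, max)` of effects per
#'   study.
#' @param tau Between-study SD of the random intercepts.
#' @param subjects_per_arm Integer range of per-arm group sizes.
#' @param beta Named numeric vector of true coefficients on the coded
#'   scale; names must match design-matrix column labels. Unnamed terms
#'   default to 0, so `beta = NULL` is an all-null truth.
#' @param spec A [meta_model_spec()]; defaults to the additive
#'   domain-general model.
#' @param within_correlation Assumed repeated-measures correlation used for
#'   within-subject sampling variances.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(n_studies = 100, effects_per_study = c(5, 9),
                             tau = 0.4, subjects_per_arm = c(10, 40),
                             beta = NULL, spec = NULL,
                             within_correlation = 0.5) {
  if (is.null(spec)) {
    spec <- meta_model_spec(moderators = default_moderator_schemas())
  }
  if (length(effects_per_study) == 1) effects_per_study <- rep(effects_per_study, 2)
  if (length(subjects_per_arm) == 1) subjects_per_arm <- rep(subjects_per_arm, 2)
  if (n_studies < 2) stop("need at least 2 studies")
  if (tau < 0) stop("tau must be non-negative")
  if (subjects_per_arm[1] < 2) stop("per-arm group sizes must be >= 2")
  structure(list(n_studies = n_studies,
                 effects_per_study = effects_per_study,
                 tau = tau, subjects_per_arm = subjects_per_arm,
                 beta = beta, spec = spec,
                 within_correlation = within_correlation),
            class = "simulation_truth")
}

# Uniform integer draw over a closed range (safe for degenerate ranges,
# where sample() would reinterpret a scalar as 1:x).
sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

# Draw study-level moderator values (design parameters are properties of a
# study, so they are constant across that study's effects).
draw_moderators <- function(spec, n_studies) {
  out <- list()
  for (sch in spec$moderators) {
    nm <- sch$name
    if (sch$kind == "categorical") {
      out[[nm]] <- sample(sch$levels, n_studies, replace = TRUE)
    } else {
      out[[nm]] <- switch(nm,
        intensity = round(runif(n_studies, 0.25, 5), 2),
        duration = round(runif(n_studies, 5, 30)),
        sessions = pmin(1 + rgeom(n_studies, 0.45), 20),
        electrodes = sample(c(2, 4, 8, 10), n_studies, replace = TRUE,
                            prob = c(0.7, 0.15, 0.1, 0.05)),
        runif(n_studies))
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Simulate an effect-size table with known truth
#'
#' Draws study intercepts u_s ~ N(0, tau^2), samples study-level moderator
#' configurations, builds the coded design, sets each true effect
#' theta_i = x_i' beta + u_s(i), derives a sampling SE from simulated
#' per-arm group sizes via the Hedges' g variance formula appropriate to
#' the study design, and observes g_i ~ N(theta_i, se_i^2).
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @return List with `effects` (the observable table: `study_id`,
#'   `effect_id`, `g`, `se_g`, moderators) and `truth` (the generating
#'   `beta` aligned to design columns, `tau`, `u`, `theta`).
#' @export
simulate_meta_dataset <- function(truth, seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(as.integer(seed))
  spec <- truth$spec
  S <- truth$n_studies
  u <- rnorm(S, 0, truth$tau)
  mods <- draw_moderators(spec, S)
  n_eff <- sample_range(truth$effects_per_study, S)
  study_of_row <- rep(seq_len(S), n_eff)
  tab <- mods[study_of_row, , drop = FALSE]
  tab$study_id <- sprintf("study%03d", study_of_row)
  tab$effect_id <- sprintf("%s_e%d", tab$study_id,
                           unlist(lapply(n_eff, seq_len)))
  rownames(tab) <- NULL

  design <- build_design_matrix(tab, spec)
  beta_full <- numeric(ncol(design$X))
  names(beta_full) <- colnames(design$X)
  if (!is.null(truth$beta)) {
    unknown <- setdiff(names(truth$beta), names(beta_full))
    if (length(unknown)) {
      stop("truth beta names not in design: ", paste(unknown, collapse = ", "))
    }
    beta_full[names(truth$beta)] <- truth$beta
  }
  theta <- drop(design$X %*% beta_full) + u[study_of_row]

  n_arm <- sample_range(truth$subjects_per_arm, nrow(tab))
  within <- if ("design" %in% names(tab)) tab$design == "within" else
    rep(TRUE, nrow(tab))
  r <- truth$within_correlation
  se <- numeric(nrow(tab))
  df_b <- 2 * n_arm - 2
  se[!within] <- hedges_j(df_b[!within]) *
    sqrt(2 / n_arm[!within] + theta[!within]^2 / (2 * df_b[!within]))
  se[within] <- hedges_j(n_arm[within] - 1) *
    sqrt(2 * (1 - r) * (1 / n_arm[within] + theta[within]^2 / (2 * n_arm[within])))
  g <- rnorm(nrow(tab), theta, se)

  effects <- cbind(data.frame(study_id = tab$study_id,
                              effect_id = tab$effect_id,
                              g = g, se_g = se),
                   tab[setdiff(names(tab), c("study_id", "effect_id"))])
  list(effects = effects,
       truth = list(beta = beta_full, tau = truth$tau, u = u,
                    theta = theta, n_arm = n_arm, seed = seed))
}

#' Simulate a raw group-summary table
#'
#' Emits per-effect group means, SDs, and sample sizes (plus
#' `higher_is_better` flags, a fraction of them FALSE to exercise sign
#' harmonization) constructed so that running [compute_effect_sizes()] on
#' the output reproduces the intended signed g: group SDs are 1, the
#' control mean 0, and the active mean is set to the uncorrected d implied
#' by the target g. Lower-is-better rows carry a negated raw mean
#' difference, so harmonization restores the intended sign.
#'
#' @param truth A [simulation_truth()].
#' @param seed Integer seed.
#' @param prop_lower_better Fraction of rows flagged lower-is-better.
#' @return List with `raw` (group-summary table), `effects` (the intended
#'   signed effect table, as from [simulate_meta_dataset()]), and `truth`.
#' @export
simulate_raw_groups <- function(truth, seed = 1, prop_lower_better = 0.3) {
  sim <- simulate_meta_dataset(truth, seed)
  eff <- sim$effects
  n <- nrow(eff)
  n_arm <- sim$truth$n_arm
  within <- if ("design" %in% names(eff)) eff$design == "within" else rep(TRUE, n)
  df <- ifelse(within, n_arm - 1, 2 * n_arm - 2)
  d_target <- eff$g / hedges_j(df)      # invert the small-sample correction
  hib <- runif(n) > prop_lower_better
  raw_diff <- ifelse(hib, d_target, -d_target)
  raw <- data.frame(study_id = eff$study_id, effect_id = eff$effect_id,
                    design = if ("design" %in% names(eff)) eff$design else "within",
                    mean_active = raw_diff, sd_active = 1,
                    mean_control = 0, sd_control = 1,
                    n_active = n_arm, n_control = n_arm,
                    higher_is_better = hib,
                    within_correlation = truth$within_correlation)
  keep <- setdiff(names(eff), c("g", "se_g", "design"))
  raw <- cbind(raw, eff[setdiff(keep, names(raw))])
  list(raw = raw, effects = eff, truth = sim$truth)
}
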