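# Moderator coding: deviation contrasts, centering, design-matrix assembly.

#' Declare how one moderator enters the model
#'
#' @param name Column name in the effect table.
#' @param kind `"categorical"` or `"continuous"`.
#' @param levels For categorical moderators, the ordered level labels. The
#'   reference defaults to the *last* declared level, mirroring the
#'   convention used for reporting (e.g., "Within -- Between" with Between
#'   as reference).
#' @param reference Reference level label (categorical only).
#' @param collapse_map Optional named character vector mapping sparse level
#'   labels to their replacement group label (see
#'   [collapse_sparse_levels()]).
#' @return A `moderator_schema` object.
#' @export
moderator_schema <- function(name, kind = c("categorical", "continuous"),
                             levels = NULL, reference = NULL,
                             collapse_map = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) < 2) {
      stop("categorical moderator '", name, "' needs >= 2 levels")
    }
    if (anyDuplicated(levels)) stop("levels must be distinct")
    if (is.null(reference)) reference <- levels[length(levels)]
    if (!reference %in% levels) {
      stop("reference level '", reference, "' not among declared levels")
    }
  } else {
    levels <- NULL
    reference <- NULL
  }
  structure(list(name = name, kind = kind, levels = levels,
                 reference = reference, collapse_map = collapse_map),
            class = "moderator_schema")
}

#' Specify a meta-regression model
#'
#' Bundles the moderator schemas, any interaction terms, and the prior
#' scales of the hierarchical model. Defaults reproduce the weakly
#' informative priors used throughout: intercept ~ Normal(0, 1),
#' slopes ~ Normal(0, 2.5), between-study SD ~ half-Cauchy(0, 0.5), with
#' prior scales read as standard deviations. Observation noise is fixed at
#' the known per-effect sampling SE, so no residual SD is estimated unless
#' `estimate_residual_sd = TRUE`.
#'
#' @param moderators List of [moderator_schema()] objects (possibly empty
#'   for an intercept-only model).
#' @param interactions List of character vectors of length 2 or 3 naming
#'   moderators whose product terms enter the design. A three-way term
#'   always implies its three marginal two-way products (added automatically
#'   if absent).
#' @param prior_intercept_sd,prior_slope_sd Normal prior SDs.
#' @param prior_tau_scale Half-Cauchy scale of the between-study SD.
#' @param estimate_residual_sd Estimate an additional residual SD on top of
#'   the known sampling SEs (off by default; sensitivity analyses only).
#' @return A `meta_model_spec` object.
#' @export
meta_model_spec <- function(moderators = list(), interactions = list(),
                            prior_intercept_sd = 1, prior_slope_sd = 2.5,
                            prior_tau_scale = 0.5,
                            estimate_residual_sd = FALSE) {
  if (inherits(moderators, "moderator_schema")) moderators <- list(moderators)
  stopifnot(all(vapply(moderators, inherits, TRUE, "moderator_schema")))
  if (prior_intercept_sd <= 0 || prior_slope_sd <= 0 || prior_tau_scale <= 0) {
    stop("prior scales must be strictly positive")
  }
  names(moderators) <- vapply(moderators, `[[`, "", "name")
  interactions <- lapply(interactions, as.character)
  for (term in interactions) {
    if (!length(term) %in% 2:3) stop("interaction terms must involve 2 or 3 moderators")
    if (!all(term %in% names(moderators))) {
      stop("interaction references unknown moderator(s): ",
           paste(setdiff(term, names(moderators)), collapse = ", "))
    }
  }
  # a three-way product is only interpretable with its marginal two-ways
  three <- Filter(function(t) length(t) == 3, interactions)
  for (t3 in three) {
    for (pair in list(t3[1:2], t3[c(1, 3)], t3[2:3])) {
      have <- any(vapply(interactions,
                         function(t) length(t) == 2 && setequal(t, pair),
                         logical(1)))
      if (!have) interactions <- c(interactions, list(pair))
    }
  }
  ord <- order(lengths(interactions))
  structure(list(moderators = moderators, interactions = interactions[ord],
                 prior_intercept_sd = prior_intercept_sd,
                 prior_slope_sd = prior_slope_sd,
                 prior_tau_scale = prior_tau_scale,
                 estimate_residual_sd = estimate_residual_sd),
            class = "meta_model_spec")
}

#' Sum-to-zero deviation contrast matrix
#'
#' Each non-reference level gets an indicator column (1 on its own row, 0
#' elsewhere); the reference row is -1 in every column, so every column
#' sums to zero across levels. Coefficients are deviations of each level
#' from the grand mean, enabling ANOVA-like comparisons.
#'
#' @param k Number of levels, >= 2.
#' @param reference_index Row index of the reference level (default last).
#' @return A k x (k-1) matrix.
#' @export
deviation_contrasts <- function(k, reference_index = k) {
  if (k < 2) stop("deviation contrasts need k >= 2 levels")
  if (reference_index < 1 || reference_index > k) stop("invalid reference index")
  C <- diag(k)[, -reference_index, drop = FALSE]
  C[reference_index, ] <- -1
  C
}

#' Center a continuous moderator about its mean
#'
#' @param values Numeric vector with at least one finite value.
#' @return `values - mean(values)`.
#' @export
center_continuous <- function(values) {
  if (length(values) == 0) stop("cannot center an empty vector")
  if (any(!is.finite(values))) stop("values must be finite")
  values - mean(values)
}

#' Collapse sparsely represented factor levels
#'
#' Levels of a categorical moderator observed in fewer than `min_effects`
#' rows are relabeled per `collapse_map` (typically into an "Other" group
#' with anatomically proximal targets). Row counts are conserved; only
#' labels change.
#'
#' @param table Effect table (data.frame).
#' @param moderator Column name of the categorical moderator.
#' @param min_effects Minimum effect count for a level to stand alone
#'   (default 5).
#' @param collapse_map Named character vector: `c(sparse_level = "Group")`.
#'   Every below-threshold level must appear.
#' @return The table with relabeled levels.
#' @export
collapse_sparse_levels <- function(table, moderator, min_effects = 5,
                                   collapse_map = NULL) {
  if (!moderator %in% names(table)) stop("no column '", moderator, "' in table")
  x <- as.character(table[[moderator]])
  counts <- table(x)
  sparse <- names(counts)[counts < min_effects]
  if (!length(sparse)) return(table)
  unmapped <- setdiff(sparse, names(collapse_map))
  if (length(unmapped)) {
    stop("level(s) below threshold but absent from collapse_map: ",
         paste(unmapped, collapse = ", "))
  }
  hit <- x %in% sparse
  x[hit] <- unname(collapse_map[x[hit]])
  table[[moderator]] <- x
  table
}

# Coded column block for one moderator. `override_level` forces every row
# to a given level (used for counterfactual predictions); `center` reuses a
# stored centering constant so counterfactual designs stay on the same scale.
code_moderator <- function(values, schema, override_level = NULL,
                           center = NULL) {
  if (schema$kind == "continuous") {
    v <- as.numeric(values)
    if (any(!is.finite(v))) stop("non-finite values in moderator '", schema$name, "'")
    if (is.null(center)) center <- mean(v)
    M <- matrix(v - center, ncol = 1,
                dimnames = list(NULL, schema$name))
    return(list(M = M, center = center))
  }
  lv <- schema$levels
  x <- if (is.null(override_level)) as.character(values) else
    rep(override_level, length(values))
  unseen <- setdiff(unique(x), lv)
  if (length(unseen)) {
    stop("moderator '", schema$name, "' has level(s) not in schema: ",
         paste(unseen, collapse = ", "))
  }
  ref_idx <- match(schema$reference, lv)
  C <- deviation_contrasts(length(lv), ref_idx)
  M <- C[match(x, lv), , drop = FALSE]
  colnames(M) <- paste0(schema$name, ": ", lv[-ref_idx], " - ", schema$reference)
  list(M = M, center = NULL)
}

#' Build the coded design matrix for a model specification
#'
#' Produces an intercept column, one centered column per continuous
#' moderator, k-1 deviation-contrast columns per k-level categorical
#' moderator, and elementwise products of coded columns for each interaction
#' term. Contrast columns are labeled "Moderator: Level - Reference".
#'
#' @param effects Effect table containing every moderator named in `spec`
#'   plus a `study_id` column.
#' @param spec A [meta_model_spec()].
#' @return A `meta_design` object: list with the model matrix `X`, per-row
#'   `study` factor, column `labels`, and per-term coding metadata.
#' @export
build_design_matrix <- function(effects, spec) {
  stopifnot(inherits(spec, "meta_model_spec"))
  missing_mods <- setdiff(names(spec$moderators), names(effects))
  if (length(missing_mods)) {
    stop("effect table lacks moderator column(s): ",
         paste(missing_mods, collapse = ", "))
  }
  n <- nrow(effects)
  blocks <- list()
  centers <- list()
  for (sch in spec$moderators) {
    cb <- code_moderator(effects[[sch$name]], sch)
    blocks[[sch$name]] <- cb$M
    centers[[sch$name]] <- cb$center
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  for (nm in names(blocks)) X <- cbind(X, blocks[[nm]])
  for (term in spec$interactions) {
    X <- cbind(X, interaction_block(blocks[term]))
  }
  if (qr(X)$rank < ncol(X)) {
    warning("design matrix is rank deficient (collinear columns)")
  }
  structure(list(X = X, labels = colnames(X),
                 study = factor(effects$study_id),
                 centers = centers, spec = spec, effects = effects),
            class = "meta_design")
}

# All elementwise products across the coded column blocks of 2-3 moderators.
interaction_block <- function(blocks) {
  combo <- blocks[[1]]
  for (b in blocks[-1]) {
    out <- matrix(0, nrow(combo), 0)
    for (i in seq_len(ncol(combo))) {
      prod <- combo[, i] * b
      colnames(prod) <- paste(colnames(combo)[i], colnames(b), sep = " x ")
      out <- cbind(out, prod)
    }
    combo <- out
  }
  combo
}

# Rebuild the full design with one categorical moderator forced to a level,
# keeping stored centering constants (counterfactual design for AMEs).
design_at_level <- function(design, factor_name, level) {
  spec <- design$spec
  sch <- spec$moderators[[factor_name]]
  if (is.null(sch)) stop("no moderator named '", factor_name, "' in the model")
  if (sch$kind != "categorical") {
    stop("'", factor_name, "' is continuous; report its slope instead of an AME")
  }
  if (!level %in% sch$levels) {
    stop("level '", level, "' not in schema for '", factor_name, "'")
  }
  effects <- design$effects
  blocks <- list()
  for (s in spec$moderators) {
    ov <- if (s$name == factor_name) level else NULL
    blocks[[s$name]] <- code_moderator(effects[[s$name]], s,
                                       override_level = ov,
                                       center = design$centers[[s$name]])$M
  }
  X <- cbind(`(Intercept)` = rep(1, nrow(effects)))
  for (nm in names(blocks)) X <- cbind(X, blocks[[nm]])
  for (term in spec$interactions) X <- cbind(X, interaction_block(blocks[term]))
  X
}
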