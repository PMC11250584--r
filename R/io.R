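# File I/O, validation, and the end-to-end pipeline.

#' Read and validate an effect-size table
#'
#' Loads a CSV of extracted effects, checks the required columns
#' (`study_id`, `effect_id`, `g`, `se_g`), verifies that g and se_g are
#' numeric and usable (finite g, strictly positive se), and rejects rows
#' with missing moderator values, reporting offending row numbers. Summary
#' counts (studies, effects, and per-domain counts when a `domain` column
#' is present) are emitted as messages.
#'
#' @param path CSV file path.
#' @param moderators Optional character vector of moderator columns that
#'   must be present and complete.
#' @return The validated data.frame.
#' @export
read_effect_table <- function(path, moderators = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("study_id", "effect_id", "g", "se_g")
  missing_cols <- setdiff(c(required, moderators), names(tab))
  if (length(missing_cols)) {
    stop("effect table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("g", "se_g")) {
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop("non-numeric ", col, " at row ", bad)
    }
  }
  if (any(!is.finite(tab$g))) {
    stop("non-finite g at row ", which(!is.finite(tab$g))[1])
  }
  if (any(!is.finite(tab$se_g) | tab$se_g <= 0)) {
    stop("se_g must be finite and positive; first bad row ",
         which(!is.finite(tab$se_g) | tab$se_g <= 0)[1])
  }
  if (!is.null(moderators)) {
    for (m in moderators) {
      bad <- which(is.na(tab[[m]]) | tab[[m]] == "")
      if (length(bad)) {
        stop("moderator '", m, "' missing at row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
      }
    }
  }
  message(sprintf("read %d effects from %d studies",
                  nrow(tab), length(unique(tab$study_id))))
  if ("domain" %in% names(tab)) {
    counts <- table(tab$domain)
    message("per-domain effects: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  tab
}

#' Write summary tables to disk
#'
#' Emits the fixed-effect table, random-effect row, and R-squared block as
#' CSV and JSON with a fixed column order (term, median, SD, HPD bounds,
#' pd, standardized-effect summaries). Numbers in the CSV are rendered at
#' a configurable precision (default 2 decimals, the convention of
#' published meta-regression tables); the JSON keeps full precision.
#'
#' @param summary A `meta_fit_summary` from [summarize_fit()].
#' @param dir Output directory (created if needed).
#' @param ames Optional list of `ame_result` objects.
#' @param comparison Optional `sweep_result`.
#' @param precision Decimal places for CSV rendering.
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(summary, dir, ames = NULL, comparison = NULL,
                         precision = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  fixed <- summary$fixed[, c("term", "median", "sd", "hpd_low", "hpd_high",
                             "pd", "d_median", "d_low", "d_high")]
  num <- vapply(fixed, is.numeric, TRUE)
  fixed_csv <- fixed
  fixed_csv[num] <- lapply(fixed_csv[num], round, precision)
  f <- file.path(dir, "fixed_effects.csv")
  utils::write.csv(fixed_csv, f, row.names = FALSE)
  written <- c(written, f)

  rnd <- summary$random
  rnd[-1] <- lapply(rnd[-1], round, precision)
  f <- file.path(dir, "random_effects.csv")
  utils::write.csv(rnd, f, row.names = FALSE)
  written <- c(written, f)

  r2 <- data.frame(
    index = c("marginal_r2", "conditional_r2"),
    median = c(summary$r2$r2_marginal$median, summary$r2$r2_conditional$median),
    low = c(summary$r2$r2_marginal$low, summary$r2$r2_conditional$low),
    high = c(summary$r2$r2_marginal$high, summary$r2$r2_conditional$high))
  r2[-1] <- lapply(r2[-1], round, precision)
  f <- file.path(dir, "fit_indices.csv")
  utils::write.csv(r2, f, row.names = FALSE)
  written <- c(written, f)

  f <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(fixed = summary$fixed, random = summary$random,
         r2 = r2, n_studies = summary$n_studies,
         n_effects = summary$n_effects),
    f, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  written <- c(written, f)

  if (!is.null(ames) && length(ames)) {
    amedf <- do.call(rbind, lapply(ames, function(a) {
      data.frame(factor = a$factor, level_a = a$level_a, level_b = a$level_b,
                 median = a$median, hpd_low = a$hpd_low, hpd_high = a$hpd_high)
    }))
    f <- file.path(dir, "ames.json")
    jsonlite::write_json(amedf, f, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    written <- c(written, f)
  } else {
    message("no AMEs requested; skipping AME file")
  }
  if (!is.null(comparison)) {
    f <- file.path(dir, "model_comparison.csv")
    utils::write.csv(comparison$table, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Run the full meta-regression pipeline
#'
#' Orchestrates every stage from input table to report: effect-size
#' computation (when the input is a raw group-summary table), moderator
#' coding, posterior sampling, convergence diagnostics, summary tables,
#' optional average marginal effects, and an optional interaction-model
#' sweep. A machine-readable manifest (settings, seed, package version,
#' diagnostics notes, files written) is saved alongside the outputs, so a
#' run can be reproduced exactly.
#'
#' @param config Named list (or path to a YAML/JSON file) with elements:
#'   `effects` (data.frame or CSV path) or `raw` (group-summary table or
#'   path); `moderators` (list of [moderator_schema()], or NULL for the
#'   defaults); `interactions`; `sampler` (list: chains, iter, warmup,
#'   seed); `ames` (list of `c(factor, level_a, level_b)`); `sweep_order`
#'   (NULL, 2, or 3); `out` (output directory); prior scales
#'   (`prior_intercept_sd`, `prior_slope_sd`, `prior_tau_scale`).
#' @return Invisibly, a list with the fit, summary, diagnostics, AMEs,
#'   sweep, and manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  out_dir <- config$out %||% stop("config needs an 'out' directory")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  effects <- stage("input", {
    if (!is.null(config$raw)) {
      raw <- if (is.character(config$raw)) {
        utils::read.csv(config$raw, stringsAsFactors = FALSE)
      } else config$raw
      compute_effect_sizes(raw)
    } else if (!is.null(config$effects)) {
      if (is.character(config$effects)) {
        read_effect_table(config$effects)
      } else config$effects
    } else stop("config needs 'effects' or 'raw'")
  })

  spec <- stage("coding", {
    mods <- config$moderators %||% default_moderator_schemas()
    mods <- Filter(function(m) m$name %in% names(effects), mods)
    meta_model_spec(
      moderators = mods,
      interactions = config$interactions %||% list(),
      prior_intercept_sd = config$prior_intercept_sd %||% 1,
      prior_slope_sd = config$prior_slope_sd %||% 2.5,
      prior_tau_scale = config$prior_tau_scale %||% 0.5)
  })

  smp <- config$sampler %||% list()
  chains <- smp$chains %||% 4
  iter <- smp$iter %||% 15000
  warmup <- smp$warmup %||% 5000
  seed <- smp$seed %||% 1

  fit <- stage("fit", sample_posterior(effects, spec, chains = chains,
                                       iter = iter, warmup = warmup,
                                       seed = seed))
  diag <- stage("diagnostics", suppressWarnings(convergence_diagnostics(fit)))
  summ <- stage("summarize", summarize_fit(fit))

  ames <- NULL
  if (!is.null(config$ames)) {
    ames <- stage("ame", lapply(config$ames, function(a) {
      posterior_predictive_ame(fit, a[[1]], a[[2]], a[[3]])
    }))
  }
  sweep <- NULL
  if (!is.null(config$sweep_order)) {
    sweep <- stage("sweep", run_sweep(effects, spec,
                                      order = config$sweep_order,
                                      chains = smp$sweep_chains %||% 2,
                                      iter = smp$sweep_iter %||% 2000,
                                      warmup = smp$sweep_warmup %||% 500,
                                      seed = seed))
  }

  files <- stage("report", write_report(summ, out_dir, ames = ames,
                                        comparison = sweep))
  f <- file.path(out_dir, "diagnostics.csv")
  utils::write.csv(as.data.frame(diag), f, row.names = FALSE)
  files <- c(files, f)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stimmeta")),
    seed = seed, chains = chains, iter = iter, warmup = warmup,
    priors = list(intercept_sd = spec$prior_intercept_sd,
                  slope_sd = spec$prior_slope_sd,
                  tau_scale = spec$prior_tau_scale),
    n_effects = nrow(effects),
    n_studies = length(unique(effects$study_id)),
    slice_stepout_failures = fit$slice_fails,
    diagnostic_notes = attr(diag, "notes"),
    files = basename(files),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(fit = fit, summary = summ, diagnostics = diag,
                 ames = ames, sweep = sweep, manifest = manifest))
}
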