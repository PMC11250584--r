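# Split-chain R-hat, autocorrelation-based effective sample size, and
# Monte Carlo standard errors, following the standard variogram/initial
# positive-sequence constructions used for MCMC monitoring.

# draws: iterations x chains matrix for one scalar parameter
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1):n, , drop = FALSE])
}

rhat_scalar <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  if (n < 2) return(NA_real_)
  chain_means <- colMeans(sp)
  chain_vars <- apply(sp, 2, var)
  W <- mean(chain_vars)
  B <- n * var(chain_means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# autocovariance of one chain via FFT (biased, as used for ESS)
autocov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  nf <- 2^ceiling(log2(2 * n))
  f <- fft(c(x, rep(0, nf - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / nf
  ac / n * (n / (n - 1))
}

ess_scalar <- function(draws) {
  sp <- split_chains(draws)
  n <- nrow(sp)
  m <- ncol(sp)
  if (n < 4) return(NA_real_)
  chain_vars <- apply(sp, 2, var)
  W <- mean(chain_vars)
  if (!is.finite(W) || W == 0) return(NA_real_)
  chain_means <- colMeans(sp)
  var_plus <- (n - 1) / n * W + n * var(chain_means) / n
  acov <- sapply(seq_len(m), function(j) autocov_fft(sp[, j]))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence over paired sums
  max_pairs <- floor((n - 1) / 2)
  tau_hat <- -1 + 2 * rho[1]
  prev_pair <- Inf
  for (k in seq_len(max_pairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair <= 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau_hat <- tau_hat + 2 * pair
  }
  ess <- n * m / tau_hat
  min(ess, n * m * log10(n * m))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes split-chain R-hat (the between/within variance ratio on
#' half-chains), autocorrelation-based effective sample sizes, and Monte
#' Carlo standard errors (posterior SD / sqrt(ESS)) for every regression
#' coefficient and the between-study SD. Warnings are collected in `$notes`
#' for R-hat > 1.01 or ESS < 400; constant chains yield `NA` diagnostics
#' and a note rather than an error.
#'
#' @param fit A `posterior_draws` object, or a kept x chains x parameters
#'   array (chains >= 2, >= 4 kept draws).
#' @return A `convergence_diagnostics` data.frame-backed object with
#'   columns `parameter`, `rhat`, `ess`, `mcse`, `sd`, and attribute
#'   `notes`.
#' @export
convergence_diagnostics <- function(fit) {
  if (inherits(fit, "posterior_draws")) {
    p <- dim(fit$beta)[3]
    mats <- lapply(seq_len(p), function(j) fit$beta[, , j, drop = TRUE])
    names(mats) <- dimnames(fit$beta)[[3]]
    if (is.null(fit$fix_tau)) mats$tau <- fit$tau
    if (!is.null(fit$sigma_res)) mats$sigma_res <- fit$sigma_res
  } else if (is.array(fit) && length(dim(fit)) == 3) {
    mats <- lapply(seq_len(dim(fit)[3]), function(j) fit[, , j, drop = TRUE])
    names(mats) <- dimnames(fit)[[3]] %||%
      paste0("param", seq_len(dim(fit)[3]))
  } else if (is.matrix(fit)) {
    mats <- list(param = fit)
  } else {
    stop("unsupported draws container")
  }
  first <- mats[[1]]
  if (ncol(first) < 2) stop("diagnostics need >= 2 chains")
  if (nrow(first) < 4) stop("diagnostics need >= 4 kept draws per chain")

  notes <- character()
  rows <- lapply(names(mats), function(nm) {
    d <- mats[[nm]]
    sdev <- sd(as.numeric(d))
    if (!is.finite(sdev) || sdev == 0) {
      notes <<- c(notes, sprintf("'%s': constant chains, diagnostics undefined", nm))
      return(data.frame(parameter = nm, rhat = NA_real_, ess = NA_real_,
                        mcse = NA_real_, sd = sdev))
    }
    r <- rhat_scalar(d)
    e <- ess_scalar(d)
    if (is.finite(r) && r > 1.01) {
      notes <<- c(notes, sprintf("'%s': R-hat %.3f exceeds 1.01", nm, r))
    }
    if (is.finite(e) && e < 400) {
      notes <<- c(notes, sprintf("'%s': effective sample size %.0f below 400", nm, e))
    }
    data.frame(parameter = nm, rhat = r, ess = e,
               mcse = sdev / sqrt(e), sd = sdev)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (w in notes) warning(w, call. = FALSE)
  structure(out, notes = notes, class = c("convergence_diagnostics", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
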