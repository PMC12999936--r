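#' Gelman-Rubin potential scale reduction
#'
#' Classic (non-split) potential scale reduction factor per scalar parameter:
#' with `m` chains of length `n`, within-chain variance `W` (mean of the
#' per-chain variances) and between-chain variance `B` (`n` times the variance
#' of the chain means), the PSR is `sqrt(((n-1)/n * W + B/n) / W)`. Values
#' above the threshold (1.1 by default) flag non-convergence.
#'
#' Chains that are all constant and equal give PSR 1 by convention; constant
#' chains at different values give `Inf`.
#'
#' @param x a `"bmlmm"` fit or a list of equal-length labeled trace matrices
#'   (one per chain, post burn-in).
#' @param threshold convergence threshold on the maximum PSR.
#' @return an object of class `"mlmm_convergence"`: per-parameter `psr`,
#'   `max_psr`, logical `converged` (max PSR <= threshold), `iterations`
#'   (per-chain retained length) and `threshold`.
#' @export
psr <- function(x, threshold = 1.1) {
  chains <- if (inherits(x, "bmlmm")) x$draws else x
  if (!is.list(chains) || length(chains) < 2L)
    stop("need at least 2 chains for the potential scale reduction",
         call. = FALSE)
  chains <- lapply(chains, as.matrix)
  n <- unique(vapply(chains, nrow, 0L))
  if (length(n) != 1L) stop("chains have unequal lengths", call. = FALSE)
  if (n < 10L) stop("chains too short (need >= 10 retained draws)", call. = FALSE)
  m <- length(chains)
  means <- sapply(chains, colMeans)                    # P x m
  vars <- sapply(chains, function(d) apply(d, 2, stats::var))
  means <- matrix(means, ncol = m); vars <- matrix(vars, ncol = m)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  R <- sqrt(((n - 1) / n * W + B / n) / W)
  zero <- W <= 0
  if (any(zero)) R[zero] <- ifelse(B[zero] <= 1e-300, 1.0, Inf)
  names(R) <- colnames(chains[[1]])
  structure(list(psr = R, max_psr = max(R),
                 converged = max(R) <= threshold,
                 iterations = n, threshold = threshold),
            class = "mlmm_convergence")
}

#' @export
print.mlmm_convergence <- function(x, ...) {
  cat("Gelman-Rubin diagnostic over", length(x$psr), "parameters:",
      "max PSR", round(x$max_psr, 4), "on", x$iterations,
      "retained draws/chain —",
      if (x$converged) "converged" else "NOT converged",
      "(threshold", paste0(x$threshold, ")\n"))
  worst <- sort(x$psr, decreasing = TRUE)
  print(round(utils::head(worst, 5), 4))
  invisible(x)
}

#' Convergence report as JSON
#'
#' @param report an `"mlmm_convergence"` object.
#' @param path output path; if `NULL` the JSON string is returned.
#' @export
convergence_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "mlmm_convergence"))
  obj <- list(max_psr = report$max_psr, converged = report$converged,
              iterations = report$iterations, threshold = report$threshold,
              psr = as.list(report$psr))
  if (is.null(path)) return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fit with automatic chain extension until convergence
#'
#' Fits the model and checks the maximum PSR over all stored parameters. As
#' long as it exceeds the threshold, each chain is continued from its final
#' state so that the retained length doubles, and — following the classic
#' Gelman-Rubin practice of discarding the early portion of a run — the
#' pre-extension half is promoted to burn-in. The cycle repeats until the
#' per-chain iteration ceiling `mcmc$max_total` is reached; the PSR is always
#' computed on the currently retained draws.
#'
#' @inheritParams bmlmm
#' @param threshold PSR convergence threshold.
#' @return list with `fit` (a `"bmlmm"`) and `report`
#'   (`"mlmm_convergence"`); `report$converged` is `FALSE` only if the
#'   maximum PSR still exceeds the threshold at the ceiling.
#' @export
fit_until_converged <- function(data, spec = brcp_spec(),
                                mcmc = mcmc_control(), threshold = 1.1,
                                cluster = "cluster") {
  fit <- bmlmm(data, spec, mcmc, cluster = cluster)
  repeat {
    report <- psr(fit, threshold = threshold)
    if (report$converged) break
    R <- fit$n_retained
    extra <- min(2L * R, mcmc$max_total - fit$iter_total)
    if (extra <= 0L) break
    fit <- extend_fit(fit, extra)
    # promote the pre-extension draws to burn-in: keep the newest 2R (or
    # whatever a capped extension allows)
    drop <- min(R, extra)
    for (ch in seq_along(fit$draws))
      fit$draws[[ch]] <- fit$draws[[ch]][-seq_len(drop), , drop = FALSE]
    fit$n_retained <- fit$n_retained - drop
  }
  list(fit = fit, report = report)
}
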