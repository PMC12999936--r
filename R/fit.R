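#' MCMC settings
#'
#' @param chains number of chains (>= 2 so convergence can be assessed).
#' @param iter total iterations per chain (burn-in included).
#' @param burn burn-in iterations discarded from the front of each chain.
#' @param seed integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @param max_total ceiling on total iterations per chain when chains are
#'   extended after a failed convergence check (see
#'   [fit_until_converged()]).
#' @return an object of class `"mcmc_control"`.
#' @export
mcmc_control <- function(chains = 2L, iter = 3000L, burn = 1000L,
                         seed = 1L, max_total = 100000L) {
  chains <- as.integer(chains); iter <- as.integer(iter)
  burn <- as.integer(burn)
  if (chains < 2L) stop("need >= 2 chains for convergence diagnostics",
                        call. = FALSE)
  if (burn >= iter) stop("burn-in must be smaller than total iterations",
                         call. = FALSE)
  structure(list(chains = chains, iter = iter, burn = burn,
                 seed = as.integer(seed), max_total = as.integer(max_total)),
            class = "mcmc_control")
}

scalar_par_names <- function() {
  c("psi_Xw", "res_Mw", "res_Yw", "psi_Xb", "res_Mb", "res_Yb",
    "c_w", "beta_MZw", "beta_YZw", "gamma_a0", "gamma_b0", "mod_a", "mod_b",
    "T11", "T12", "T22",
    "a_b", "b_b", "c_b", "beta_MZb", "beta_YZb",
    "mu_Z", "psi_Zw", "psi_Zb", "a_w", "b_w")
}

default_control <- function(prior_only = FALSE) {
  list(update_measurement = TRUE, update_scores = TRUE,
       update_scores_within = TRUE, update_scores_between = TRUE,
       update_z = TRUE, update_slopes = TRUE,
       update_struct_within = TRUE, update_slope_reg = TRUE,
       update_struct_between = TRUE, update_mu_Z = TRUE,
       update_variances = TRUE, update_T = TRUE,
       prior_only = prior_only)
}

# Arrange data for the sampler: reorder indicator columns anchor-first and
# rows by cluster.
prepare_data <- function(data, spec, cluster = "cluster") {
  df <- if (inherits(data, "mlmm_data")) data$data else as.data.frame(data)
  cols <- unlist(lapply(spec$blocks, function(b) {
    ord <- c(b$anchor, setdiff(seq_along(b$indicators), b$anchor))
    b$indicators[ord]
  }), use.names = FALSE)
  need <- c(cluster, cols, spec$moderator)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(df[need]))
    stop("missing values in model columns are not supported", call. = FALSE)
  g <- factor(df[[cluster]])
  if (nlevels(g) < 2L) stop("need at least 2 clusters", call. = FALSE)
  ord <- order(as.integer(g))
  df <- df[ord, , drop = FALSE]
  g <- g[ord]
  csize <- as.integer(table(g))
  cstart <- c(0L, cumsum(csize)[-length(csize)])
  list(Y = as.matrix(df[cols]), Z = as.numeric(df[[spec$moderator]]),
       cstart = cstart, csize = csize, cols = cols,
       cluster_levels = levels(g), p = length(spec$blocks$X$indicators))
}

initial_state <- function(prep, jitter_sd = 0) {
  Y <- prep$Y; p <- prep$p; K <- ncol(Y); J <- length(prep$csize)
  N <- nrow(Y)
  g <- rep(seq_len(J), prep$csize)
  # least-squares composites: block means, split into cluster means and
  # within-cluster deviations
  comp <- sapply(1:3, function(f) rowMeans(Y[, ((f - 1) * p + 1):(f * p),
                                             drop = FALSE]))
  cm <- apply(comp, 2, function(v) tapply(v, g, mean))
  cm <- matrix(cm, nrow = J)
  eta_b <- sweep(cm, 2, colMeans(comp))
  eta_w <- comp - cm[g, , drop = FALSE]
  Zcm <- as.numeric(tapply(prep$Z, g, mean))
  jit <- function(n = 1) if (jitter_sd > 0) stats::rnorm(n, 0, jitter_sd) else rep(0, n)
  list(nu = colMeans(Y) + jit(K),
       lam_w = rep(1, K), lam_b = rep(1, K),
       th_w = rep(1, K), th_b = rep(1, K),
       psi_Xw = 1, res_Mw = 1, res_Yw = 1,
       psi_Xb = 1, res_Mb = 1, res_Yb = 1,
       c_w = jit(), beta_MZw = jit(), beta_YZw = jit(),
       gamma_a0 = jit(), gamma_b0 = jit(), mod_a = jit(), mod_b = jit(),
       Tmat = diag(2),
       a_b = jit(), b_b = jit(),
       c_b = jit(), beta_MZb = jit(), beta_YZb = jit(),
       mu_Z = mean(prep$Z) + jit(), psi_Zw = 1, psi_Zb = 1,
       eta_w = eta_w, eta_b = eta_b,
       delta = matrix(0, J, K), Zb = Zcm,
       u = matrix(0, J, 2))
}

par_labels <- function(cols) {
  c(paste0("nu_", cols), paste0("lam_w_", cols), paste0("lam_b_", cols),
    paste0("th_w_", cols), paste0("th_b_", cols), scalar_par_names())
}

#' Fit the Bayesian two-level latent moderated mediation model
#'
#' Gibbs sampling of the full joint posterior: loadings, between-level
#' intercepts, residual variances at both levels, within and between
#' structural paths, cluster-specific random a/b slopes with 2x2 covariance,
#' the latent between/within decomposition of the observed moderator, and all
#' factor scores. The parameterization (`brcp_spec()` or `bint_spec()`)
#' decides whether the cross-level moderation weight is drawn in the
#' cluster-level slope regression or as a product-term coefficient in the
#' row-level structural regression; the two are posterior-equivalent and the
#' shared canonical labels `mod_a`/`mod_b` hold the weight either way.
#'
#' The stored trace also carries the derived slope means `a_w`, `b_w`
#' (cluster slope expectation at the moderator's latent between-level mean)
#' and the slope covariance entries `T11`, `T12`, `T22`, from which indirect
#' effects are computed (see [indirect_within()]).
#'
#' @param data an `"mlmm_data"` object from [simulate_mlmm()] or a long-format
#'   data.frame with a cluster id column, the indicator columns of `spec`, and
#'   the moderator column.
#' @param spec an `"mlmm_spec"` from [brcp_spec()] or [bint_spec()].
#' @param mcmc an [mcmc_control()] object.
#' @param cluster name of the cluster id column.
#' @param control advanced: list of update flags (internal blocks can be
#'   frozen for validation runs); see [default_control()] source. Latent
#'   quantities frozen by a flag stay at their `init` values.
#' @param init advanced: named list overriding entries of the default initial
#'   state.
#' @return an object of class `"bmlmm"` with elements `draws` (list of
#'   retained trace matrices, one per chain, labeled columns), `spec`, `mcmc`,
#'   `states` (final sampler states, used for chain extension), `labels`,
#'   `n_retained`, `iter_total`, and data dimensions.
#' @export
bmlmm <- function(data, spec = brcp_spec(), mcmc = mcmc_control(),
                  cluster = "cluster", control = NULL, init = NULL) {
  stopifnot(inherits(spec, "mlmm_spec"), inherits(mcmc, "mcmc_control"))
  prep <- prepare_data(data, spec, cluster)
  ctrl <- default_control()
  if (!is.null(control)) ctrl[names(control)] <- control
  labels <- par_labels(prep$cols)
  pr <- spec$priors
  priors <- list(coef_mean = pr$coef_mean, coef_var = pr$coef_var,
                 var_shape = pr$var_shape, var_scale = pr$var_scale,
                 slope_cov_scale = pr$slope_cov_scale,
                 slope_cov_df = pr$slope_cov_df)
  draws <- vector("list", mcmc$chains)
  states <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + 1000L * (ch - 1L))
    ini <- initial_state(prep, jitter_sd = if (ch == 1L) 0 else 0.1)
    if (!is.null(init)) ini[names(init)] <- init
    res <- .gibbs_mlmm(prep$Y, prep$Z, prep$cstart, prep$csize, prep$p,
                       spec$parameterization == "bint",
                       priors, ini, ctrl, mcmc$iter, mcmc$burn)
    colnames(res$draws) <- labels
    draws[[ch]] <- res$draws
    states[[ch]] <- res$state
  }
  structure(list(draws = draws, spec = spec, mcmc = mcmc,
                 states = states, labels = labels,
                 n_retained = mcmc$iter - mcmc$burn,
                 iter_total = mcmc$iter,
                 N = nrow(prep$Y), J = length(prep$csize),
                 control = ctrl, priors = priors, prep = prep),
            class = "bmlmm")
}

#' Continue sampling from a fitted model
#'
#' Restarts every chain from its stored final state and appends `extra`
#' retained iterations (no additional burn-in); used by
#' [fit_until_converged()] to extend non-converged runs.
#'
#' @param fit a `"bmlmm"` object.
#' @param extra additional iterations per chain.
#' @return the extended `"bmlmm"` object.
#' @export
extend_fit <- function(fit, extra) {
  stopifnot(inherits(fit, "bmlmm"))
  extra <- as.integer(extra)
  prep <- fit$prep
  if (is.null(prep))
    stop("fit was not created with bmlmm(); cannot extend", call. = FALSE)
  for (ch in seq_along(fit$draws)) {
    set.seed(fit$mcmc$seed + 1000L * (ch - 1L) + fit$iter_total)
    res <- .gibbs_mlmm(prep$Y, prep$Z, prep$cstart, prep$csize, prep$p,
                       fit$spec$parameterization == "bint",
                       fit$priors, fit$states[[ch]], fit$control, extra, 0L)
    colnames(res$draws) <- fit$labels
    fit$draws[[ch]] <- rbind(fit$draws[[ch]], res$draws)
    fit$states[[ch]] <- res$state
  }
  fit$n_retained <- fit$n_retained + extra
  fit$iter_total <- fit$iter_total + extra
  fit
}

#' Pooled posterior trace of selected parameters
#'
#' @param fit a `"bmlmm"` object.
#' @param pars character vector of parameter labels (default all).
#' @return matrix of pooled post-burn-in draws (chains stacked).
#' @export
pooled_draws <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "bmlmm"))
  m <- do.call(rbind, fit$draws)
  if (is.null(pars)) return(m)
  miss <- setdiff(pars, colnames(m))
  if (length(miss))
    stop("unknown parameter label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m[, pars, drop = FALSE]
}

#' Posterior medians of all parameters
#'
#' Point estimates are the medians of the pooled post-burn-in chains.
#'
#' @param fit a `"bmlmm"` object (or a list of labeled trace matrices).
#' @return named numeric vector of posterior medians.
#' @export
point_estimates <- function(fit) {
  m <- if (inherits(fit, "bmlmm")) pooled_draws(fit) else do.call(rbind, fit)
  if (is.null(m) || nrow(m) == 0L) stop("empty trace", call. = FALSE)
  apply(m, 2, stats::median)
}

#' @export
coef.bmlmm <- function(object, ...) point_estimates(object)

#' @export
confint.bmlmm <- function(object, parm = NULL, level = 0.95, ...) {
  m <- pooled_draws(object, parm)
  al <- (1 - level) / 2
  t(apply(m, 2, stats::quantile, probs = c(al, 1 - al), type = 7))
}

#' @export
print.bmlmm <- function(x, ...) {
  cat("Bayesian two-level latent moderated mediation fit (",
      toupper(x$spec$parameterization), ")\n", sep = "")
  cat("  ", x$N, " rows in ", x$J, " clusters; ", length(x$draws),
      " chains x ", x$n_retained, " retained draws (",
      x$iter_total, " total iterations/chain)\n", sep = "")
  est <- point_estimates(x)
  show <- c("a_w", "b_w", "c_w", "mod_a", "mod_b", "T11", "T12", "T22",
            "a_b", "b_b", "c_b")
  print(round(est[show], 3))
  invisible(x)
}

#' @export
summary.bmlmm <- function(object, level = 0.95, ...) {
  m <- pooled_draws(object)
  al <- (1 - level) / 2
  med <- apply(m, 2, stats::median)
  lo <- apply(m, 2, stats::quantile, probs = al, type = 7)
  hi <- apply(m, 2, stats::quantile, probs = 1 - al, type = 7)
  tab <- data.frame(median = med, lower = lo, upper = hi,
                    significant = (lo > 0 | hi < 0))
  structure(list(table = tab, parameterization = object$spec$parameterization,
                 level = level, chains = length(object$draws),
                 n_retained = object$n_retained),
            class = "summary.bmlmm")
}

#' @export
print.summary.bmlmm <- function(x, ...) {
  cat("Posterior summary (", toupper(x$parameterization), "), ",
      x$chains, " chains x ", x$n_retained, " draws, ",
      100 * x$level, "% credible intervals\n\n", sep = "")
  focal <- c("a_w", "b_w", "c_w", "beta_MZw", "beta_YZw",
             "a_b", "b_b", "c_b", "beta_MZb", "beta_YZb",
             "mod_a", "mod_b", "T11", "T12", "T22")
  tab <- x$table[focal, ]
  tab[, 1:3] <- round(tab[, 1:3], 3)
  print(tab)
  cat("\n(use pooled_draws() for full traces incl. measurement parameters)\n")
  invisible(x)
}

#' @export
plot.bmlmm <- function(x, pars = c("a_w", "b_w", "mod_a", "mod_b"), ...) {
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    traces <- lapply(x$draws, function(d) d[, p])
    rng <- range(unlist(traces))
    graphics::plot(traces[[1]], type = "l", ylim = rng, ylab = p,
                   xlab = "", col = 1, ...)
    if (length(traces) > 1)
      for (ch in 2:length(traces))
        graphics::lines(traces[[ch]], col = ch)
  }
  invisible(x)
}
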