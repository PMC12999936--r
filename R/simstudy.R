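# Monte Carlo harness over the simulation grid: per-condition detection
# (type-I error when the generating moderation is 0, power when it is not),
# relative bias of the moderation and moderated-mediation estimates, and the
# non-convergence rate, for either parameterization.

#' Define a simulation condition
#'
#' One cell of the 2 (clusters) x 2 (slope variance) x 2 (moderation) grid
#' crossed with parameterization. Cluster size stays at 30; all other
#' generating values come from [mlmm_design()] defaults.
#'
#' @param J number of clusters (20 or 100 in the study grid).
#' @param slope_var random-slope variance (0 or 0.50).
#' @param moderation cross-level moderation effect (0 or 0.30).
#' @param model `"brcp"` or `"bint"`.
#' @param reps number of converged replications to collect.
#' @param base_seed integer; replication r uses `base_seed + r`, replacement
#'   seeds come from the disjoint stream `base_seed + 100000 + k`.
#' @param n cluster size.
#' @return an object of class `"sim_condition"`.
#' @export
sim_condition <- function(J, slope_var, moderation,
                          model = c("brcp", "bint"),
                          reps = 100L, base_seed = 1L, n = 30L) {
  model <- match.arg(model)
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be >= 1", call. = FALSE)
  structure(list(J = as.integer(J), n = as.integer(n),
                 slope_var = slope_var, moderation = moderation,
                 model = model, reps = reps,
                 base_seed = as.integer(base_seed)),
            class = "sim_condition")
}

default_fitter <- function(data, spec, mcmc)
  fit_until_converged(data, spec, mcmc)

#' Run one Monte Carlo condition
#'
#' For each replication: generate a dataset under the condition, fit until
#' converged (extending chains up to the ceiling), and record the posterior
#' medians and 95% credible intervals of the two moderation weights and of
#' the conditional indirect effects at +/-1 SD of the between moderator.
#' Replications that still exceed the PSR threshold at the iteration ceiling
#' are counted as non-converged and replaced with fresh seeds from a disjoint
#' stream until `reps` converged replications exist.
#'
#' @param cond a [sim_condition()].
#' @param mcmc an [mcmc_control()]; its seed field is ignored (seeds follow
#'   the condition's seed policy).
#' @param fitter function `(data, spec, mcmc) -> list(fit, report)`;
#'   replaceable so the harness logic can be exercised with a stub sampler.
#' @param max_attempts safety cap on total replications attempted.
#' @return an object of class `"sim_result"`: `per_rep` data.frame (one row
#'   per converged replication: seed, estimates, CI bounds, detection flags),
#'   `metrics` (detection rate per moderation weight and averaged; mean
#'   absolute relative bias of moderation and of moderated mediation when the
#'   generating effect is nonzero; non-convergence rate), `truth`, and the
#'   condition.
#' @export
run_condition <- function(cond, mcmc = mcmc_control(),
                          fitter = default_fitter,
                          max_attempts = 10L * cond$reps) {
  stopifnot(inherits(cond, "sim_condition"))
  design <- mlmm_design(J = cond$J, n = cond$n, slope_var = cond$slope_var,
                        moderation = cond$moderation)
  spec <- if (cond$model == "brcp") brcp_spec() else bint_spec()
  rows <- list()
  seeds_used <- integer(0)
  n_nonconv <- 0L
  attempts <- 0L
  r <- 0L
  repl <- 0L
  while (length(rows) < cond$reps && attempts < max_attempts) {
    attempts <- attempts + 1L
    if (r < cond$reps) {            # primary stream
      r <- r + 1L
      seed <- cond$base_seed + r
    } else {                        # disjoint replacement stream
      repl <- repl + 1L
      seed <- cond$base_seed + 100000L + repl
    }
    dat <- simulate_mlmm(design, seed = seed)
    m <- mcmc_control(chains = mcmc$chains, iter = mcmc$iter,
                      burn = mcmc$burn, seed = seed,
                      max_total = mcmc$max_total)
    res <- fitter(dat, spec, m)
    if (!res$report$converged) {
      n_nonconv <- n_nonconv + 1L
      next
    }
    fit <- res$fit
    ci <- function(v) stats::quantile(v, c(0.025, 0.975), type = 7,
                                      names = FALSE)
    ma <- get_pooled(fit, "mod_a")[, 1]; mb <- get_pooled(fit, "mod_b")[, 1]
    cia <- ci(ma); cib <- ci(mb)
    sdz <- dat$truth$sd_zb
    cp <- conditional_indirect(fit, sdz); cm <- conditional_indirect(fit, -sdz)
    cip <- ci(cp); cim <- ci(cm)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = seed,
      mod_a_est = stats::median(ma), mod_a_lo = cia[1], mod_a_hi = cia[2],
      mod_b_est = stats::median(mb), mod_b_lo = cib[1], mod_b_hi = cib[2],
      detect_a = (cia[1] > 0 | cia[2] < 0),
      detect_b = (cib[1] > 0 | cib[2] < 0),
      ci_plus_est = stats::median(cp), ci_plus_lo = cip[1], ci_plus_hi = cip[2],
      ci_minus_est = stats::median(cm), ci_minus_lo = cim[1],
      ci_minus_hi = cim[2],
      iterations = fit$iter_total)
    seeds_used <- c(seeds_used, seed)
  }
  per_rep <- if (length(rows)) do.call(rbind, rows) else data.frame()
  n_conv <- nrow(per_rep)
  if (n_conv < cond$reps)
    warning("collected only ", n_conv, " converged replications in ",
            attempts, " attempts")
  truth <- simulate_mlmm(design, seed = 1L)$truth
  det_a <- if (n_conv) mean(per_rep$detect_a) else NA_real_
  det_b <- if (n_conv) mean(per_rep$detect_b) else NA_real_
  metrics <- list(
    detection_a = det_a, detection_b = det_b,
    detection = mean(c(det_a, det_b)),
    nonconvergence = n_nonconv / attempts,
    attempts = attempts, converged_reps = n_conv)
  if (cond$moderation != 0 && n_conv > 0) {
    rb_a <- relative_bias(per_rep$mod_a_est, cond$moderation)
    rb_b <- relative_bias(per_rep$mod_b_est, cond$moderation)
    metrics$rb_moderation <- mean(abs(c(rb_a, rb_b)))
    rb_p <- relative_bias(per_rep$ci_plus_est, truth$cond_indirect_plus1sd)
    rb_m <- relative_bias(per_rep$ci_minus_est, truth$cond_indirect_minus1sd)
    metrics$rb_modmed <- mean(abs(c(rb_p, rb_m)))
  }
  structure(list(condition = cond, per_rep = per_rep, metrics = metrics,
                 truth = truth[c("moderation", "within_indirect",
                                 "cond_indirect_plus1sd",
                                 "cond_indirect_minus1sd", "sd_zb")],
                 seeds = seeds_used),
            class = "sim_result")
}

#' Relative bias of a set of estimates
#'
#' `(mean(estimates) - truth) / truth`. A generating value of zero admits no
#' relative bias; the raw bias `mean(estimates)` is returned instead, with a
#' warning and attribute `type = "raw"`.
#'
#' @param estimates per-replication point estimates.
#' @param truth generating value.
#' @return relative bias (or raw bias when `truth == 0`).
#' @export
relative_bias <- function(estimates, truth) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0L) stop("no estimates", call. = FALSE)
  if (truth == 0) {
    warning("truth is 0: returning raw bias, not relative bias")
    return(structure(mean(estimates), type = "raw"))
  }
  (mean(estimates) - truth) / truth
}

#' @export
print.sim_result <- function(x, ...) {
  cond <- x$condition
  cat("Monte Carlo condition: J=", cond$J, ", n=", cond$n,
      ", tau2=", cond$slope_var, ", moderation=", cond$moderation,
      ", model=", toupper(cond$model), "\n", sep = "")
  m <- x$metrics
  cat("  detection rate ", round(m$detection, 3),
      " (mod_a ", round(m$detection_a, 3), ", mod_b ",
      round(m$detection_b, 3), ")",
      if (cond$moderation == 0) "  [type-I error]" else "  [power]", "\n",
      sep = "")
  if (!is.null(m$rb_moderation))
    cat("  mean |relative bias|: moderation ", round(m$rb_moderation, 3),
        ", moderated mediation ", round(m$rb_modmed, 3), "\n", sep = "")
  cat("  non-convergence rate ", round(m$nonconvergence, 3), " (",
      m$converged_reps, "/", m$attempts, " attempts converged)\n", sep = "")
  invisible(x)
}

#' Plot a metric across simulation conditions
#'
#' Dot chart of one metric from a [summarize_grid()] table, one panel row per
#' condition (clusters x slope variance x moderation x model), in the style
#' of condition-by-condition operating-characteristic figures. A reference
#' line marks the conventional bound for the metric (0.05 for type-I-style
#' detection under no moderation, 0.80 for power, 0.10 for relative bias).
#'
#' @param table data.frame from [summarize_grid()].
#' @param metric one of the metric names in the table (e.g. `"detection"`,
#'   `"rb_moderation"`, `"rb_modmed"`, `"nonconvergence"`).
#' @param ref optional reference value drawn as a dashed line.
#' @param ... passed to [graphics::dotchart()].
#' @return the plotted subset, invisibly.
#' @export
plot_grid_metric <- function(table, metric = "detection", ref = NULL, ...) {
  sub <- table[table$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0L) stop("metric not present in table: ", metric,
                            call. = FALSE)
  labels <- paste0("J=", sub$J, ", tau2=", sub$slope_var,
                   ", mod=", sub$moderation, ", ", toupper(sub$model))
  graphics::dotchart(sub$value, labels = labels, xlab = metric,
                     xlim = range(0, sub$value, ref), ...)
  if (!is.null(ref)) graphics::abline(v = ref, lty = 2)
  invisible(sub)
}

#' Long-format summary table over conditions
#'
#' @param results list of `"sim_result"` objects.
#' @return data.frame: one row per condition x metric, suitable for
#'   condition-by-condition plots of detection, bias and non-convergence.
#' @export
summarize_grid <- function(results) {
  if (inherits(results, "sim_result")) results <- list(results)
  if (length(results) == 0L) stop("no results", call. = FALSE)
  do.call(rbind, lapply(results, function(r) {
    cond <- r$condition
    met <- r$metrics
    keep <- intersect(c("detection_a", "detection_b", "detection",
                        "rb_moderation", "rb_modmed", "nonconvergence"),
                      names(met))
    data.frame(J = cond$J, n = cond$n, slope_var = cond$slope_var,
               moderation = cond$moderation, model = cond$model,
               metric = keep,
               value = unlist(met[keep], use.names = FALSE),
               row.names = NULL)
  }))
}
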