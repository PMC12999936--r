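# Posterior indirect and conditional indirect effects. All functions operate
# draw-by-draw on the pooled post-burn-in traces, so credible intervals come
# straight from posterior percentiles of the effect itself.

get_pooled <- function(x, pars) {
  m <- if (inherits(x, "bmlmm")) pooled_draws(x)
  else if (is.list(x) && !is.data.frame(x)) do.call(rbind, x)
  else as.matrix(x)
  miss <- setdiff(pars, colnames(m))
  if (length(miss))
    stop("trace is missing parameter label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  m[, pars, drop = FALSE]
}

#' Within-level indirect effect trace
#'
#' With cluster-varying a and b slopes the expected indirect effect is not
#' the product of the slope means alone: `E(a_g b_g) = E(a) E(b) + sigma_ab`,
#' where `sigma_ab` is the covariance of the two random slopes. Computed per
#' posterior draw as `a_w * b_w + T12`.
#'
#' @param x a `"bmlmm"` fit, list of trace matrices, or labeled trace matrix
#'   containing `a_w`, `b_w`, `T12`.
#' @return numeric vector: one indirect-effect value per posterior draw.
#' @export
indirect_within <- function(x) {
  m <- get_pooled(x, c("a_w", "b_w", "T12"))
  m[, "a_w"] * m[, "b_w"] + m[, "T12"]
}

#' Between-level indirect effect trace
#'
#' Elementwise product `a_b * b_b` per posterior draw (the between paths are
#' fixed, so no covariance correction applies).
#'
#' @inheritParams indirect_within
#' @return numeric vector of per-draw indirect effects.
#' @export
indirect_between <- function(x) {
  m <- get_pooled(x, c("a_b", "b_b"))
  m[, "a_b"] * m[, "b_b"]
}

#' Conditional (moderated) indirect effect trace
#'
#' At moderator deviation `z` from the latent between-level moderator mean,
#' the cluster-expected slopes are `a_w + mod_a * z` and `b_w + mod_b * z`
#' (where `mod_*` is the slope-on-moderator weight under BRCP and the
#' product-term coefficient under BINT — same canonical label), giving the
#' per-draw conditional indirect effect
#' `(a_w + mod_a z)(b_w + mod_b z) + sigma_ab`.
#'
#' @inheritParams indirect_within
#' @param z moderator value, as a deviation from the between-level moderator
#'   mean. With `scale = "sd"`, `z` is expressed in posterior standard
#'   deviations of the latent between moderator component and is multiplied
#'   per draw by `sqrt(psi_Zb)` (so `z = 1` means +1 SD).
#' @param scale `"moderator"` (raw units) or `"sd"`.
#' @return numeric vector of per-draw conditional indirect effects.
#' @export
conditional_indirect <- function(x, z, scale = c("moderator", "sd")) {
  scale <- match.arg(scale)
  pars <- c("a_w", "b_w", "mod_a", "mod_b", "T12")
  if (scale == "sd") pars <- c(pars, "psi_Zb")
  m <- get_pooled(x, pars)
  zz <- if (scale == "sd") z * sqrt(m[, "psi_Zb"]) else z
  (m[, "a_w"] + m[, "mod_a"] * zz) * (m[, "b_w"] + m[, "mod_b"] * zz) +
    m[, "T12"]
}

#' Summarize an effect trace
#'
#' Posterior median with a 95% percentile credible interval (2.5th and 97.5th
#' percentiles, linear interpolation between order statistics); the effect is
#' flagged significant when the interval excludes zero.
#'
#' @param trace numeric vector of per-draw effect values (length >= 40).
#' @param level credible level.
#' @return an object of class `"effect_summary"`: `estimate` (median),
#'   `lower`, `upper`, `significant`.
#' @export
summarize_effect <- function(trace, level = 0.95) {
  trace <- as.numeric(trace)
  if (length(trace) == 0L) stop("empty effect trace", call. = FALSE)
  if (length(trace) < 40L)
    stop("effect trace too short for percentile intervals (need >= 40)",
         call. = FALSE)
  al <- (1 - level) / 2
  qs <- stats::quantile(trace, probs = c(al, 1 - al), type = 7, names = FALSE)
  est <- stats::median(trace)
  structure(list(estimate = est, lower = qs[1], upper = qs[2],
                 significant = (qs[1] > 0 | qs[2] < 0), level = level),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%.4f (%.4f, %.4f)%s\n", x$estimate, x$lower, x$upper,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Mediation and moderated-mediation effect table
#'
#' Convenience wrapper producing the standard reporting table: within and
#' between indirect effects and the conditional indirect effect at +/-1 SD of
#' the between-level moderator (per-draw SD by default).
#'
#' @inheritParams indirect_within
#' @param sd_scale if `TRUE` (default) evaluate +/-1 SD per draw via
#'   `sqrt(psi_Zb)`; otherwise `z_sd` gives the raw SD value to use.
#' @param z_sd raw moderator SD used when `sd_scale = FALSE`.
#' @return data.frame with one row per effect: estimate, lower, upper,
#'   significant.
#' @export
effect_table <- function(x, sd_scale = TRUE, z_sd = NULL) {
  traces <- list(
    indirect_within = indirect_within(x),
    indirect_between = indirect_between(x),
    cond_indirect_plus1sd = if (sd_scale) conditional_indirect(x, 1, "sd")
      else conditional_indirect(x, z_sd),
    cond_indirect_minus1sd = if (sd_scale) conditional_indirect(x, -1, "sd")
      else conditional_indirect(x, -z_sd))
  rows <- lapply(traces, summarize_effect)
  data.frame(effect = names(rows),
             estimate = vapply(rows, `[[`, 0, "estimate"),
             lower = vapply(rows, `[[`, 0, "lower"),
             upper = vapply(rows, `[[`, 0, "upper"),
             significant = vapply(rows, `[[`, TRUE, "significant"),
             row.names = NULL)
}
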