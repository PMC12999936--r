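# Agreement between the posteriors of the two parameterizations: overlap
# coefficient (integral of the pointwise minimum of two densities) and a
# probability-based standardized difference.

#' Posterior overlap coefficient
#'
#' Estimates the overlapping coefficient `OVL = int min(f_a, f_b)` between
#' the densities of two posterior samples from kernel density estimates
#' evaluated on a common grid (`bins` points spanning the pooled range, with
#' a shared bandwidth averaged across the two samples), integrating the
#' pointwise minimum by the trapezoidal rule. 1 means identical
#' distributions, 0 disjoint support. Degenerate (zero-variance) samples are
#' treated as point masses: the overlap is 1 when both sit at the same value
#' and 0 otherwise.
#'
#' @param a,b numeric posterior samples (length >= 100 each).
#' @param bins number of grid points.
#' @return overlap coefficient in `[0, 1]`.
#' @export
overlap_coefficient <- function(a, b, bins = 512L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 100L || length(b) < 100L)
    stop("need >= 100 draws in each sample", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(as.numeric(a[1] == b[1]))
    return(0)
  }
  bw <- mean(c(stats::bw.nrd0(a), stats::bw.nrd0(b)))
  rng <- range(a, b) + c(-3, 3) * bw
  fa <- stats::density(a, bw = bw, from = rng[1], to = rng[2], n = bins)
  fb <- stats::density(b, bw = bw, from = rng[1], to = rng[2], n = bins)
  fmin <- pmin(fa$y, fb$y)
  dx <- diff(fa$x)
  min(1, sum((fmin[-1] + fmin[-length(fmin)]) / 2 * dx))
}

#' Probability-based effect size between two posteriors
#'
#' Standardized difference of posterior means:
#' `|mean(a) - mean(b)| / sqrt((var(a) + var(b)) / 2)`. Near zero when the two
#' posteriors coincide.
#'
#' @inheritParams overlap_coefficient
#' @return nonnegative standardized difference.
#' @export
probability_effect_size <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 100L || length(b) < 100L)
    stop("need >= 100 draws in each sample", call. = FALSE)
  pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (pooled == 0) stop("zero pooled posterior SD", call. = FALSE)
  abs(mean(a) - mean(b)) / pooled
}

#' Focal parameters shared by the two parameterizations
#'
#' The canonical labels under which BRCP and BINT store the same quantities:
#' slope means, fixed paths at both levels, moderation weights (slope
#' regression weight vs product-term coefficient), and the random-slope
#' covariance entries.
#'
#' @return character vector of labels.
#' @export
focal_parameters <- function() {
  c("a_w", "b_w", "c_w", "beta_MZw", "beta_YZw",
    "a_b", "b_b", "c_b", "beta_MZb", "beta_YZb",
    "mod_a", "mod_b", "T11", "T12", "T22")
}

#' Compare BRCP and BINT posteriors parameter by parameter
#'
#' For every shared (mapped) parameter label, computes the probability-based
#' effect size and the posterior overlap coefficient between the two fits and
#' flags the difference negligible when the effect size is below `es_cut`
#' (0.2) and the overlap exceeds `ovl_cut` (0.9).
#'
#' @param fit_a,fit_b `"bmlmm"` fits (or labeled trace matrices); typically
#'   one BRCP and one BINT fit of the same dataset.
#' @param labels parameter labels to compare; defaults to the intersection of
#'   [focal_parameters()] with the labels present in both fits.
#' @param es_cut,ovl_cut negligibility thresholds.
#' @return data.frame with one row per parameter: `parameter`,
#'   `effect_size`, `overlap`, `negligible`.
#' @export
compare_models <- function(fit_a, fit_b, labels = NULL,
                           es_cut = 0.2, ovl_cut = 0.9) {
  ga <- function(x) if (inherits(x, "bmlmm")) pooled_draws(x)
    else if (is.list(x) && !is.data.frame(x)) do.call(rbind, x) else as.matrix(x)
  ma <- ga(fit_a); mb <- ga(fit_b)
  if (is.null(labels))
    labels <- intersect(focal_parameters(),
                        intersect(colnames(ma), colnames(mb)))
  else labels <- intersect(labels, intersect(colnames(ma), colnames(mb)))
  if (length(labels) == 0L)
    stop("no shared parameter labels to compare", call. = FALSE)
  es <- vapply(labels, function(l)
    probability_effect_size(ma[, l], mb[, l]), 0)
  ovl <- vapply(labels, function(l)
    overlap_coefficient(ma[, l], mb[, l]), 0)
  data.frame(parameter = labels, effect_size = es, overlap = ovl,
             negligible = (es < es_cut & ovl > ovl_cut),
             row.names = NULL)
}
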