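#' Simulation design for the two-level moderated mediation model
#'
#' Collects the generating values of the study design: a 1-1-1 latent
#' mediation chain (X -> M -> Y) measured by `p` continuous indicators per
#' factor at reliability `reliability`, with latent intraclass correlation
#' `icc`, structural paths `a`, `b`, `cprime` applied at both levels, random
#' a/b slopes with variance `slope_var`, cross-level moderation `moderation`
#' of both slopes by an observed cluster-level moderator, and an observed
#' moderator Z with variance `z_var` at each level.
#'
#' Total latent variance is 1, split `psi_b = icc` between clusters and
#' `psi_w = 1 - icc` within. Structural residual variances are derived so the
#' baseline model (zero slope variance, zero moderation) reproduces those
#' factor variances exactly; all loadings are 1 and indicator residual
#' variances are split across levels in proportion to the level's factor
#' variance so that total indicator reliability equals `reliability`.
#'
#' @param J number of clusters (>= 2).
#' @param n cluster size (>= 2).
#' @param slope_var variance of each random slope (tau^2), >= 0.
#' @param slope_cov covariance of the two random slopes.
#' @param moderation cross-level effect of the between moderator on each slope.
#' @param a,b,cprime structural paths X->M, M->Y, X->Y, used at both levels.
#' @param z_effects named vector: within effects `MZw` (Z_w -> M_w), `YZw`
#'   (Z_w -> Y_w) and between effects `MZb`, `YZb`.
#' @param z_var moderator variance per level (same at both levels).
#' @param icc latent intraclass correlation in (0,1).
#' @param reliability total indicator reliability in (0,1).
#' @param p indicators per factor.
#' @return an object of class `"mlmm_design"` with all generating values,
#'   including the derived residual variances.
#' @export
mlmm_design <- function(J = 100L, n = 30L, slope_var = 0, slope_cov = 0,
                        moderation = 0,
                        a = 0.4, b = 0.50, cprime = -0.20,
                        z_effects = c(MZw = -0.10, YZw = 0.10,
                                      MZb = -0.20, YZb = 0.20),
                        z_var = 0.50, icc = 0.20, reliability = 0.60,
                        p = 6L) {
  J <- as.integer(J); n <- as.integer(n); p <- as.integer(p)
  if (J < 2L || n < 2L) stop("need J >= 2 clusters and n >= 2 per cluster",
                             call. = FALSE)
  if (slope_var < 0) stop("slope_var must be >= 0", call. = FALSE)
  if (icc <= 0 || icc >= 1) stop("icc must lie in (0,1)", call. = FALSE)
  if (reliability <= 0 || reliability >= 1)
    stop("reliability must lie in (0,1)", call. = FALSE)
  if (z_var <= 0) stop("z_var must be positive", call. = FALSE)
  need <- c("MZw", "YZw", "MZb", "YZb")
  if (!all(need %in% names(z_effects)))
    stop("z_effects needs elements ", paste(need, collapse = ", "), call. = FALSE)
  Tmat <- matrix(c(slope_var, slope_cov, slope_cov, slope_var), 2, 2)
  if (slope_var > 0 && abs(slope_cov) >= slope_var)
    stop("|slope_cov| must be < slope_var for a positive definite T", call. = FALSE)
  if (slope_var == 0 && slope_cov != 0)
    stop("slope_cov must be 0 when slope_var is 0", call. = FALSE)

  psi_b <- icc
  psi_w <- 1 - icc
  zw <- z_var; zb <- z_var
  # residual variances from the baseline (tau^2 = 0, moderation = 0) model so
  # factor variances hit psi_w / psi_b there
  res_Mw <- psi_w - a^2 * psi_w - z_effects[["MZw"]]^2 * zw
  res_Yw <- psi_w - (b^2 * psi_w + cprime^2 * psi_w + z_effects[["YZw"]]^2 * zw +
                     2 * b * cprime * a * psi_w +
                     2 * b * z_effects[["YZw"]] * z_effects[["MZw"]] * zw)
  res_Mb <- psi_b - a^2 * psi_b - z_effects[["MZb"]]^2 * zb
  res_Yb <- psi_b - (b^2 * psi_b + cprime^2 * psi_b + z_effects[["YZb"]]^2 * zb +
                     2 * b * cprime * a * psi_b +
                     2 * b * z_effects[["YZb"]] * z_effects[["MZb"]] * zb)
  if (min(res_Mw, res_Yw, res_Mb, res_Yb) <= 0)
    stop("structural paths imply non-positive residual variance; reduce path sizes",
         call. = FALSE)
  # indicator residuals: total error (1 - rel)/rel split in proportion to the
  # level's share of latent variance
  theta_total <- (1 - reliability) / reliability
  theta_w <- psi_w * theta_total
  theta_b <- psi_b * theta_total

  structure(list(J = J, n = n, p = p,
                 slope_var = slope_var, slope_cov = slope_cov,
                 moderation = moderation,
                 a = a, b = b, cprime = cprime,
                 z_effects = z_effects, z_var = z_var,
                 icc = icc, reliability = reliability,
                 psi_w = psi_w, psi_b = psi_b,
                 res_Mw = res_Mw, res_Yw = res_Yw,
                 res_Mb = res_Mb, res_Yb = res_Yb,
                 theta_w = theta_w, theta_b = theta_b,
                 Tmat = Tmat),
            class = "mlmm_design")
}

#' Implied latent intraclass correlation
#'
#' @param design an [mlmm_design()] object.
#' @return `psi_b / (psi_b + psi_w)`.
#' @export
implied_icc <- function(design) {
  stopifnot(inherits(design, "mlmm_design"))
  design$psi_b / (design$psi_b + design$psi_w)
}

#' Implied per-indicator reliability
#'
#' With unit loadings: `var(eta_total) / (var(eta_total) + theta_total)`.
#'
#' @param design an [mlmm_design()] object.
#' @return total-score reliability of a single indicator.
#' @export
implied_reliability <- function(design) {
  stopifnot(inherits(design, "mlmm_design"))
  v <- design$psi_w + design$psi_b
  th <- design$theta_w + design$theta_b
  v / (v + th)
}

#' Generate a two-level moderated mediation dataset
#'
#' Draws one dataset from the generating model of an [mlmm_design()]:
#' cluster-level moderator component, exogenous between factor, correlated
#' random slopes, between structural equations; then row-level within
#' components using the cluster-specific slopes; finally indicators as
#' `anchor-metric factor + between residual + within residual` with unit
#' loadings. Deterministic given `seed`.
#'
#' @param design an [mlmm_design()] object.
#' @param seed integer seed.
#' @return an object of class `"mlmm_data"`: a list with `data` (data.frame:
#'   `cluster`, `X1..Xp`, `M1..Mp`, `Y1..Yp`, `Z`), `truth` (all generating
#'   values, per-cluster slopes, latent scores, and the implied within
#'   indirect `a*b + sigma_ab` plus conditional indirects at +/-1 SD of the
#'   between moderator), and `design`.
#' @export
simulate_mlmm <- function(design = mlmm_design(), seed = 1L) {
  stopifnot(inherits(design, "mlmm_design"))
  set.seed(as.integer(seed))
  J <- design$J; n <- design$n; p <- design$p
  N <- J * n
  ze <- design$z_effects
  g <- rep(seq_len(J), each = n)

  # cluster level
  Zb <- rnorm(J, 0, sqrt(design$z_var))
  Xb <- rnorm(J, 0, sqrt(design$psi_b))
  u <- MASS::mvrnorm(J, mu = c(0, 0), Sigma = design$Tmat)
  if (design$slope_var == 0) u <- matrix(0, J, 2)
  a_g <- design$a + design$moderation * Zb + u[, 1]
  b_g <- design$b + design$moderation * Zb + u[, 2]
  Mb <- design$a * Xb + ze[["MZb"]] * Zb + rnorm(J, 0, sqrt(design$res_Mb))
  Yb <- design$b * Mb + design$cprime * Xb + ze[["YZb"]] * Zb +
    rnorm(J, 0, sqrt(design$res_Yb))

  # row level, cluster-specific slopes
  Zw <- rnorm(N, 0, sqrt(design$z_var))
  Xw <- rnorm(N, 0, sqrt(design$psi_w))
  Mw <- a_g[g] * Xw + ze[["MZw"]] * Zw + rnorm(N, 0, sqrt(design$res_Mw))
  Yw <- b_g[g] * Mw + design$cprime * Xw + ze[["YZw"]] * Zw +
    rnorm(N, 0, sqrt(design$res_Yw))

  eta_w <- cbind(X = Xw, M = Mw, Y = Yw)
  eta_b <- cbind(X = Xb, M = Mb, Y = Yb)

  ind <- matrix(0, N, 3L * p)
  cols <- character(3L * p)
  for (f in 1:3) {
    lab <- c("X", "M", "Y")[f]
    for (k in seq_len(p)) {
      j <- (f - 1L) * p + k
      delta <- rnorm(J, 0, sqrt(design$theta_b))
      eps <- rnorm(N, 0, sqrt(design$theta_w))
      ind[, j] <- eta_b[g, f] + delta[g] + eta_w[, f] + eps
      cols[j] <- paste0(lab, k)
    }
  }
  colnames(ind) <- cols
  df <- data.frame(cluster = g, ind, Z = Zb[g] + Zw, check.names = FALSE)

  sdzb <- sqrt(design$z_var)
  cond_ind <- function(z)
    (design$a + design$moderation * z) * (design$b + design$moderation * z) +
      design$slope_cov
  truth <- list(
    a = design$a, b = design$b, cprime = design$cprime,
    moderation = design$moderation,
    slope_var = design$slope_var, slope_cov = design$slope_cov,
    z_effects = as.list(design$z_effects),
    psi_w = design$psi_w, psi_b = design$psi_b,
    res = list(Mw = design$res_Mw, Yw = design$res_Yw,
               Mb = design$res_Mb, Yb = design$res_Yb),
    theta_w = design$theta_w, theta_b = design$theta_b,
    within_indirect = design$a * design$b + design$slope_cov,
    between_indirect = design$a * design$b,
    cond_indirect_plus1sd = cond_ind(sdzb),
    cond_indirect_minus1sd = cond_ind(-sdzb),
    sd_zb = sdzb,
    a_g = a_g, b_g = b_g,
    Zb = Zb, Zw = Zw,
    eta_w = eta_w, eta_b = eta_b,
    seed = as.integer(seed))
  structure(list(data = df, truth = truth, design = design),
            class = "mlmm_data")
}

#' @export
print.mlmm_data <- function(x, ...) {
  cat("Two-level moderated mediation dataset: ",
      nrow(x$data), " rows, ", x$design$J, " clusters of ", x$design$n,
      ", ", 3L * x$design$p, " indicators + moderator Z\n", sep = "")
  cat("  generating values: a=", x$truth$a, ", b=", x$truth$b,
      ", c'=", x$truth$cprime, ", tau2=", x$truth$slope_var,
      ", moderation=", x$truth$moderation,
      ", within indirect=", x$truth$within_indirect, "\n", sep = "")
  invisible(x)
}

#' Write / read a generated dataset as CSV
#'
#' `write_mlmm_csv()` writes the long-format table (header row, `cluster`
#' first column) and, when `truth_path` is given, the scalar generating values
#' and per-cluster slopes as a JSON sidecar.
#'
#' @param x an `"mlmm_data"` object or plain data.frame.
#' @param path CSV output path.
#' @param truth_path optional JSON sidecar path for the generating values.
#' @return `path`, invisibly.
#' @export
write_mlmm_csv <- function(x, path, truth_path = NULL) {
  df <- if (inherits(x, "mlmm_data")) x$data else x
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path) && inherits(x, "mlmm_data")) {
    tr <- x$truth
    keep <- setdiff(names(tr), c("eta_w", "eta_b", "Zw"))
    jsonlite::write_json(tr[keep], truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
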