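only_flags <- function(...) {
  on <- c(...)
  flags <- list(update_measurement = FALSE, update_scores = FALSE,
                update_slopes = FALSE, update_struct_within = FALSE,
                update_slope_reg = FALSE, update_struct_between = FALSE,
                update_mu_Z = FALSE, update_variances = FALSE,
                update_T = FALSE, prior_only = FALSE)
  flags[on] <- TRUE
  flags
}

test_that("sampling is deterministic given the seed", {
  sim <- simulate_mlmm(mlmm_design(J = 8, n = 5), seed = 2)
  m <- mcmc_control(chains = 2, iter = 60, burn = 20, seed = 5)
  f1 <- bmlmm(sim, brcp_spec(), m)
  f2 <- bmlmm(sim, brcp_spec(), m)
  expect_identical(f1$draws, f2$draws)
  f3 <- bmlmm(sim, brcp_spec(), mcmc_control(chains = 2, iter = 60,
                                             burn = 20, seed = 6))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("data validation reports missing columns, NAs and tiny cluster counts", {
  sim <- simulate_mlmm(mlmm_design(J = 6, n = 4), seed = 2)
  df <- sim$data
  expect_error(bmlmm(df[, setdiff(names(df), "M3")], brcp_spec(),
                     mcmc_control(iter = 20, burn = 10)), "M3")
  df_na <- df; df_na$X1[3] <- NA
  expect_error(bmlmm(df_na, brcp_spec(), mcmc_control(iter = 20, burn = 10)),
               "missing values")
  df1 <- df[df$cluster == 1, ]
  expect_error(bmlmm(df1, brcp_spec(), mcmc_control(iter = 20, burn = 10)),
               "2 clusters")
})

test_that("with the likelihood disabled, coefficient draws reproduce the prior", {
  sim <- simulate_mlmm(mlmm_design(J = 6, n = 4), seed = 9)
  pri <- mlmm_priors(coef_mean = 0, coef_var = 4)
  ctrl <- only_flags("update_struct_within", "update_slope_reg",
                     "update_struct_between", "update_measurement")
  ctrl$prior_only <- TRUE
  fit <- bmlmm(sim, brcp_spec(priors = pri),
               mcmc_control(chains = 2, iter = 1000, burn = 0, seed = 4),
               control = ctrl)
  for (par in c("c_w", "beta_MZw", "a_b", "b_b", "mod_a", "gamma_a0",
                "nu_M2", "lam_w_Y3")) {
    x <- pooled_draws(fit, par)[, 1]
    n <- length(x)
    expect_lt(abs(mean(x)), 3 * 2 / sqrt(n))            # prior mean 0, sd 2
    expect_lt(abs(stats::var(x) - 4), 3 * 4 * sqrt(2 / (n - 1)))
  }
})

test_that("collapsed conditionals match the closed-form conjugate posterior", {
  sim <- simulate_mlmm(mlmm_design(J = 80, n = 10, slope_var = 0,
                                   moderation = 0.3), seed = 21)
  d <- sim$design; tr <- sim$truth
  ti <- truth_init(sim)
  m <- mcmc_control(chains = 2, iter = 2500, burn = 0, seed = 8)

  # between-level regressions with scores, moderator split and variances known
  fitb <- bmlmm(sim, brcp_spec(), m, control = only_flags("update_struct_between"),
                init = ti)
  Xm <- cbind(tr$eta_b[, "X"], tr$Zb)
  post <- conjugate_posterior(Xm, tr$eta_b[, "M"], d$res_Mb)
  for (j in 1:2) {
    x <- pooled_draws(fitb, c("a_b", "beta_MZb")[j])[, 1]
    se <- sqrt(post$cov[j, j] / length(x))
    expect_lt(abs(mean(x) - post$mean[j]), 2 * se)
    expect_lt(abs(stats::sd(x) / sqrt(post$cov[j, j]) - 1), 0.05)
  }
  Xy <- cbind(tr$eta_b[, "M"], tr$eta_b[, "X"], tr$Zb)
  post <- conjugate_posterior(Xy, tr$eta_b[, "Y"], d$res_Yb)
  for (j in 1:3) {
    x <- pooled_draws(fitb, c("b_b", "c_b", "beta_YZb")[j])[, 1]
    se <- sqrt(post$cov[j, j] / length(x))
    expect_lt(abs(mean(x) - post$mean[j]), 2 * se)
  }

  # within-level fixed coefficients under the product-term (BINT) blocking
  fitw <- bmlmm(sim, bint_spec(), m, control = only_flags("update_struct_within"),
                init = ti)
  g <- sim$data$cluster
  zw <- sim$data$Z - tr$Zb[g]
  Xm <- cbind(zw, tr$eta_w[, "X"] * tr$Zb[g])
  post <- conjugate_posterior(Xm, tr$eta_w[, "M"] - d$a * tr$eta_w[, "X"],
                              d$res_Mw)
  for (j in 1:2) {
    x <- pooled_draws(fitw, c("beta_MZw", "mod_a")[j])[, 1]
    se <- sqrt(post$cov[j, j] / length(x))
    expect_lt(abs(mean(x) - post$mean[j]), 2 * se)
  }
  Xy <- cbind(tr$eta_w[, "X"], zw, tr$eta_w[, "M"] * tr$Zb[g])
  post <- conjugate_posterior(Xy, tr$eta_w[, "Y"] - d$b * tr$eta_w[, "M"],
                              d$res_Yw)
  for (j in 1:3) {
    x <- pooled_draws(fitw, c("c_w", "beta_YZw", "mod_b")[j])[, 1]
    se <- sqrt(post$cov[j, j] / length(x))
    expect_lt(abs(mean(x) - post$mean[j]), 2 * se)
  }
})

test_that("stored draws respect the identification and positivity invariants", {
  fit <- small_fit()
  m <- pooled_draws(fit)
  # anchor loadings exactly 1 at both levels, in every draw
  for (anchor in c("lam_w_X1", "lam_w_M1", "lam_w_Y1",
                   "lam_b_X1", "lam_b_M1", "lam_b_Y1"))
    expect_true(all(m[, anchor] == 1))
  # residual variances strictly positive
  th <- m[, grep("^th_[wb]_", colnames(m))]
  expect_true(all(th > 0))
  expect_true(all(m[, c("psi_Xw", "res_Mw", "res_Yw",
                        "psi_Xb", "res_Mb", "res_Yb",
                        "psi_Zw", "psi_Zb")] > 0))
  # slope covariance positive definite in every draw
  expect_true(all(m[, "T11"] > 0 & m[, "T22"] > 0))
  expect_true(all(m[, "T11"] * m[, "T22"] - m[, "T12"]^2 > 0))
})

test_that("posterior medians pool chains and handle simple traces", {
  d1 <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(point_estimates(list(d1))[["x"]], 2)
  dc <- matrix(rep(7, 5), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(point_estimates(list(dc))[["x"]], 7)
  dsym <- matrix(c(-4, -1, -2), ncol = 1, dimnames = list(NULL, "x"))
  dsym2 <- matrix(c(4, 1, 2), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(point_estimates(list(dsym, dsym2))[["x"]], 0)
  expect_error(point_estimates(list(d1[0, , drop = FALSE])), "empty")
})

test_that("mapped parameters agree across parameterizations on one dataset", {
  fa <- small_fit(); fb <- small_fit_bint()
  for (par in focal_parameters()) {
    xa <- pooled_draws(fa, par)[, 1]; xb <- pooled_draws(fb, par)[, 1]
    se <- sqrt(batch_mcse(xa)^2 + batch_mcse(xb)^2)
    expect_lt(abs(stats::median(xa) - stats::median(xb)), 3 * se + 1e-8)
  }
})

test_that("the fit covers the generating values of the focal paths", {
  fit <- small_fit()
  truth <- c(a_w = 0.4, b_w = 0.5, c_w = -0.2, mod_a = 0.3, mod_b = 0.3,
             beta_MZw = -0.1, beta_YZw = 0.1)
  ci <- confint(fit, names(truth))
  covered <- truth >= ci[, 1] & truth <= ci[, 2]
  expect_gte(sum(covered), length(truth) - 1)
})

test_that("Monte Carlo error shrinks like one over root chain length", {
  sim <- small_sim()
  fit <- bmlmm(sim, brcp_spec(),
               mcmc_control(chains = 2, iter = 4200, burn = 200, seed = 13))
  pars <- c("c_w", "beta_MZw", "beta_YZw", "a_b", "b_b")
  ratios <- vapply(pars, function(p) {
    x <- fit$draws[[1]][, p]
    batch_mcse(x[1:2000]) / batch_mcse(x)
  }, 0)
  expect_lt(abs(mean(ratios) - sqrt(2)), 0.25 * sqrt(2))
})

test_that("extending a fit continues the chains and grows the trace", {
  sim <- simulate_mlmm(mlmm_design(J = 8, n = 5), seed = 2)
  fit <- bmlmm(sim, brcp_spec(), mcmc_control(chains = 2, iter = 80,
                                              burn = 30, seed = 5))
  fit2 <- extend_fit(fit, 50)
  expect_equal(fit2$n_retained, 100)
  expect_equal(nrow(fit2$draws[[1]]), 100)
  expect_identical(fit2$draws[[1]][1:50, ], fit$draws[[1]])
})
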