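# independent closed-form oracle: model-implied covariance of the observed
# columns (18 indicators + Z) at one level, from path substitution
implied_level_cov <- function(psi, zv, a, b, cc, bMZ, bYZ, resM, resY,
                              theta, p = 6) {
  L <- rbind(X = c(1, 0, 0, 0),
             Z = c(0, 1, 0, 0),
             M = c(a, bMZ, 1, 0),
             Y = c(b * a + cc, b * bMZ + bYZ, b, 1))
  S_eta <- L %*% diag(c(psi, zv, resM, resY)) %*% t(L)
  fac <- rep(c("X", "M", "Y"), each = p)
  K <- 3 * p
  S <- matrix(0, K + 1, K + 1)
  for (i in 1:K) for (j in 1:K)
    S[i, j] <- S_eta[fac[i], fac[j]] + (i == j) * theta
  S[K + 1, 1:K] <- S[1:K, K + 1] <- S_eta["Z", fac]
  S[K + 1, K + 1] <- zv
  S
}

test_that("generation is deterministic given config and seed", {
  d <- mlmm_design(J = 10, n = 5, slope_var = 0.5, moderation = 0.3)
  s1 <- simulate_mlmm(d, seed = 99)
  s2 <- simulate_mlmm(d, seed = 99)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$eta_w, s2$truth$eta_w)
  expect_false(identical(s1$data, simulate_mlmm(d, seed = 100)$data))
})

test_that("degenerate slope variance gives constant cluster slopes", {
  s <- simulate_mlmm(mlmm_design(J = 15, n = 4, slope_var = 0, moderation = 0),
                     seed = 1)
  expect_identical(unname(s$truth$a_g), rep(0.4, 15))
  expect_identical(unname(s$truth$b_g), rep(0.5, 15))
})

test_that("implied quantities match the design targets", {
  d <- mlmm_design()
  expect_equal(implied_icc(d), 0.20)
  expect_equal(implied_icc(mlmm_design(icc = 0.5)), 0.5)   # psi_b = psi_w
  expect_equal(implied_reliability(d), 0.60)
  d0 <- d; d0$theta_w <- 0; d0$theta_b <- 0                # no measurement error
  expect_equal(implied_reliability(d0), 1.0)
  expect_equal(simulate_mlmm(d, seed = 2)$truth$within_indirect, 0.2)
  # nonzero slope covariance enters the implied indirect
  d2 <- mlmm_design(slope_var = 0.5, slope_cov = 0.05)
  expect_equal(simulate_mlmm(d2, seed = 2)$truth$within_indirect, 0.25)
})

test_that("config validation rejects impossible settings", {
  expect_error(mlmm_design(J = 1), "J >= 2")
  expect_error(mlmm_design(icc = 1.2), "icc")
  expect_error(mlmm_design(slope_var = -0.1), "slope_var")
  expect_error(mlmm_design(slope_var = 0, slope_cov = 0.1), "slope_cov")
  expect_error(mlmm_design(a = 0.99, b = 0.99), "residual")
})

test_that("sample moments at J=2000 match the model-implied covariance", {
  d <- mlmm_design(J = 2000, n = 30)                # baseline design
  sim <- simulate_mlmm(d, seed = 5)
  obs <- as.matrix(sim$data[, -1])                  # indicators + Z
  g <- sim$data$cluster
  N <- nrow(obs); J <- d$J
  ze <- d$z_effects
  Sw <- implied_level_cov(d$psi_w, d$z_var, d$a, d$b, d$cprime,
                          ze[["MZw"]], ze[["YZw"]], d$res_Mw, d$res_Yw,
                          d$theta_w)
  Sb <- implied_level_cov(d$psi_b, d$z_var, d$a, d$b, d$cprime,
                          ze[["MZb"]], ze[["YZb"]], d$res_Mb, d$res_Yb,
                          d$theta_b)
  # pooled within-cluster covariance estimates Sigma_w
  cm <- apply(obs, 2, function(v) tapply(v, g, mean))
  dev <- obs - cm[g, ]
  Sw_hat <- crossprod(dev) / (N - J)
  se_w <- sqrt((outer(diag(Sw), diag(Sw)) + Sw^2) / (N - J))
  ratio_w <- abs(Sw_hat - Sw) / se_w
  expect_gt(mean(ratio_w <= 3), 0.98)
  expect_lt(max(ratio_w), 5)
  # cluster means estimate Sigma_b + Sigma_w / n
  Sb_hat <- stats::cov(cm)
  Sb_imp <- Sb + Sw / d$n
  se_b <- sqrt((outer(diag(Sb_imp), diag(Sb_imp)) + Sb_imp^2) / (J - 1))
  ratio_b <- abs(Sb_hat - Sb_imp) / se_b
  expect_gt(mean(ratio_b <= 3), 0.98)
  expect_lt(max(ratio_b), 5)
  # total moderator variance is 1 in expectation
  expect_lt(abs(stats::var(sim$data$Z) - 1), 0.03)
  # indicator variance = latent total + residual total
  expect_lt(abs(stats::var(sim$data$X1) - (1 + d$theta_w + d$theta_b)), 0.05)
})

test_that("latent scores reproduce the target intraclass correlation", {
  sim <- simulate_mlmm(mlmm_design(J = 2000, n = 30), seed = 6)
  vb <- stats::var(sim$truth$eta_b[, "X"])
  vw <- stats::var(sim$truth$eta_w[, "X"])
  expect_lt(abs(vb / (vb + vw) - 0.20), 0.02)
})

test_that("realized cluster slopes regress on the moderator at rate gamma", {
  d <- mlmm_design(J = 2000, n = 2, slope_var = 0.5, moderation = 0.3)
  sim <- simulate_mlmm(d, seed = 7)
  fit <- stats::lm(sim$truth$a_g ~ sim$truth$Zb)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.3), 3 * est["Std. Error"])
})

test_that("datasets round-trip through CSV with a truth sidecar", {
  sim <- simulate_mlmm(mlmm_design(J = 5, n = 4), seed = 3)
  f <- tempfile(fileext = ".csv"); tj <- tempfile(fileext = ".json")
  write_mlmm_csv(sim, f, truth_path = tj)
  back <- read_mlmm_data(f)
  expect_equal(nrow(back), 20)
  expect_equal(as.character(unique(back$cluster)), as.character(1:5))
  expect_equal(back$X1, sim$data$X1)
  truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
  expect_equal(truth$within_indirect, 0.2)
  expect_equal(truth$seed, 3)
  unlink(c(f, tj))
})
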