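# Shared fixtures: small datasets and cached fits reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (!exists(key, envir = .cache)) assign(key, make(), envir = .cache)
  get(key, envir = .cache)
}

# small dataset with active moderation and slope variance
small_sim <- function() cached("small_sim", function()
  simulate_mlmm(mlmm_design(J = 30, n = 10, slope_var = 0.5, moderation = 0.3),
                seed = 11))

# short full fit on the small dataset (both parameterizations)
small_fit <- function() cached("small_fit", function()
  bmlmm(small_sim(), brcp_spec(),
        mcmc_control(chains = 2, iter = 700, burn = 300, seed = 3)))

small_fit_bint <- function() cached("small_fit_bint", function()
  bmlmm(small_sim(), bint_spec(),
        mcmc_control(chains = 2, iter = 700, burn = 300, seed = 3)))

# labeled fake trace matrix for effect-arithmetic tests
fake_draws <- function(n = 100, a_w = 0.4, b_w = 0.5, mod_a = 0, mod_b = 0,
                       T12 = 0, a_b = 0.4, b_b = 0.5) {
  m <- cbind(a_w = rep(a_w, n), b_w = rep(b_w, n),
             mod_a = rep(mod_a, n), mod_b = rep(mod_b, n),
             T12 = rep(T12, n), a_b = rep(a_b, n), b_b = rep(b_b, n),
             psi_Zb = rep(0.5, n))
  m
}

# batch-means Monte Carlo standard error of a single trace
batch_mcse <- function(x, n_batch = 20) {
  n <- length(x)
  bs <- floor(n / n_batch)
  bm <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 0)
  stats::sd(bm) / sqrt(n_batch)
}

# truth-aligned initial state for collapsed-conditional runs: all latent
# quantities at their generating values
truth_init <- function(sim) {
  tr <- sim$truth
  d <- sim$design
  Zc <- tr$Zb          # generator draws Zb around 0, mu_Z = 0
  list(eta_w = unname(tr$eta_w), eta_b = unname(tr$eta_b),
       Zb = tr$Zb, u = cbind(tr$a_g - d$a - d$moderation * Zc,
                             tr$b_g - d$b - d$moderation * Zc),
       delta = matrix(0, d$J, 3 * d$p),
       nu = rep(0, 3 * d$p), lam_w = rep(1, 3 * d$p), lam_b = rep(1, 3 * d$p),
       th_w = rep(d$theta_w, 3 * d$p), th_b = rep(d$theta_b, 3 * d$p),
       psi_Xw = d$psi_w, res_Mw = d$res_Mw, res_Yw = d$res_Yw,
       psi_Xb = d$psi_b, res_Mb = d$res_Mb, res_Yb = d$res_Yb,
       c_w = d$cprime, beta_MZw = d$z_effects[["MZw"]],
       beta_YZw = d$z_effects[["YZw"]],
       gamma_a0 = d$a, gamma_b0 = d$b,
       mod_a = d$moderation, mod_b = d$moderation,
       Tmat = if (d$slope_var > 0) d$Tmat else diag(2) * 1e-4,
       a_b = d$a, b_b = d$b, c_b = d$cprime,
       beta_MZb = d$z_effects[["MZb"]], beta_YZb = d$z_effects[["YZb"]],
       mu_Z = 0, psi_Zw = d$z_var, psi_Zb = d$z_var)
}

# closed-form conjugate posterior for y = X beta + e, e ~ N(0, v),
# beta ~ N(0, v0 I): returns mean vector and covariance
conjugate_posterior <- function(X, y, v, v0 = 1e6) {
  X <- as.matrix(X)
  Vn <- solve(crossprod(X) / v + diag(ncol(X)) / v0)
  list(mean = drop(Vn %*% (crossprod(X, y) / v)), cov = Vn)
}
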