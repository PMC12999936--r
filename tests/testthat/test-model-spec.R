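test_that("factor blocks validate their indicators and anchor", {
  b <- factor_block("X", c("x1", "x2", "x3"))
  expect_s3_class(b, "factor_block")
  expect_equal(b$anchor, 1L)
  # two indicators is the minimum viable block
  expect_s3_class(factor_block("M", c("m1", "m2")), "factor_block")
  expect_error(factor_block("X", "x1"), "at least 2")
  expect_error(factor_block("X", c("x1", "x1")), "duplicate")
  expect_error(factor_block("X", c("x1", "x2"), anchor = 3), "anchor")
})

test_that("spec construction enforces uniqueness and completeness", {
  expect_s3_class(brcp_spec(), "mlmm_spec")
  # two blocks sharing an indicator name
  bl <- default_blocks()
  bl$M$indicators[1] <- "X1"
  expect_error(brcp_spec(bl), "duplicated across blocks")
  # moderator equal to an indicator name
  expect_error(bint_spec(moderator = "M3"), "collides")
  # missing block
  expect_error(brcp_spec(default_blocks()[c("X", "M")]), "three factor blocks")
  # minimum-size blocks are valid
  tiny <- list(X = factor_block("X", c("x1", "x2")),
               M = factor_block("M", c("m1", "m2")),
               Y = factor_block("Y", c("y1", "y2")))
  expect_s3_class(brcp_spec(tiny), "mlmm_spec")
})

test_that("the two parameterizations carry moderation differently but once", {
  s1 <- brcp_spec(); s2 <- bint_spec()
  expect_equal(s1$structural$moderation$target, c("slope_a", "slope_b"))
  expect_equal(s2$structural$moderation$target, c("M", "Y"))
  # exactly two random slopes in each
  expect_equal(sum(s1$structural$within$random), 2L)
  expect_equal(sum(s2$structural$within$random), 2L)
  # identification: anchors fixed at 1, latent means at zero
  for (s in list(s1, s2)) {
    expect_identical(s$identification$anchor_loading, 1)
    expect_identical(s$identification$latent_means, 0)
  }
})

test_that("default diffuse priors are applied when omitted", {
  s <- bint_spec()
  expect_s3_class(s$priors, "mlmm_priors")
  expect_equal(s$priors$coef_var, 1e6)
  expect_equal(s$priors$var_shape, 0.001)
  expect_equal(s$priors$slope_cov_df, 3)
  expect_error(mlmm_priors(coef_var = -1), "positive")
  expect_error(mlmm_priors(slope_cov_df = 1), "df")
})

test_that("mixed forms of BRCP and BINT reduce to the same canonical terms", {
  f1 <- mixed_form(brcp_spec())
  f2 <- mixed_form(bint_spec())
  expect_identical(f1$M, f2$M)
  expect_identical(f1$Y, f2$Y)
  # the moderation weight sits on the cross-level product terms
  expect_equal(f1$M$coefficient[f1$M$term == "Xw:Zb"], "mod_a")
  expect_equal(f1$Y$coefficient[f1$Y$term == "Mw:Zb"], "mod_b")
})

test_that("conditional means agree across parameterizations on random configs", {
  set.seed(42)
  s1 <- brcp_spec(); s2 <- bint_spec()
  for (i in 1:100) {
    pars <- as.list(stats::rnorm(9, 0, 0.7))
    names(pars) <- c("a0", "b0", "mod_a", "mod_b", "c_w",
                     "beta_MZw", "beta_YZw", "u_a", "u_b")
    data <- list(Xw = stats::rnorm(5), Zw = stats::rnorm(5),
                 Zb = stats::rnorm(1))
    m1 <- conditional_mean(s1, pars, data)
    m2 <- conditional_mean(s2, pars, data)
    expect_equal(m1$M, m2$M, tolerance = 1e-12)
    expect_equal(m1$Y, m2$Y, tolerance = 1e-12)
  }
  # zero moderation: no cross-level dependence left
  pars <- list(a0 = 0.4, b0 = 0.5, mod_a = 0, mod_b = 0, c_w = -0.2,
               beta_MZw = -0.1, beta_YZw = 0.1, u_a = 0, u_b = 0)
  d1 <- list(Xw = 1, Zw = 0, Zb = -2)
  d2 <- list(Xw = 1, Zw = 0, Zb = 2)
  expect_equal(conditional_mean(s1, pars, d1), conditional_mean(s1, pars, d2))
})

test_that("specs round-trip through YAML", {
  s <- bint_spec(moderator = "rel",
                 priors = mlmm_priors(coef_var = 100, slope_cov_df = 4))
  txt <- spec_to_yaml(s)
  s2 <- spec_from_yaml(text = txt)
  expect_identical(s2$parameterization, "bint")
  expect_identical(s2$moderator, "rel")
  expect_equal(s2$priors$coef_var, 100)
  expect_equal(s2$priors$slope_cov_df, 4)
  expect_identical(lapply(s2$blocks, `[[`, "indicators"),
                   lapply(s$blocks, `[[`, "indicators"))
  f <- tempfile(fileext = ".yaml")
  spec_to_yaml(s, f)
  expect_identical(spec_from_yaml(f)$moderator, "rel")
  unlink(f)
})
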