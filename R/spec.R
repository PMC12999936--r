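#' Define a latent factor block
#'
#' A factor block names one latent variable of the 1-1-1 mediation chain
#' (`X` predictor, `M` mediator, `Y` outcome) together with the observed
#' indicator columns that measure it at both levels. One indicator per block
#' is the anchor: its loading is fixed to 1 at the within and the between
#' level, which sets the factor's metric while its variance is estimated
#' freely.
#'
#' @param name factor label, one of `"X"`, `"M"`, `"Y"`.
#' @param indicators character vector of indicator column names (at least 2).
#' @param anchor index of the anchor indicator whose loading is fixed to 1.
#' @return an object of class `"factor_block"`.
#' @export
factor_block <- function(name, indicators, anchor = 1L) {
  name <- match.arg(name, c("X", "M", "Y"))
  indicators <- as.character(indicators)
  if (length(indicators) < 2L)
    stop("factor block '", name, "' needs at least 2 indicators", call. = FALSE)
  if (anyDuplicated(indicators))
    stop("duplicate indicator names within block '", name, "'", call. = FALSE)
  anchor <- as.integer(anchor)
  if (anchor < 1L || anchor > length(indicators))
    stop("anchor index out of range for block '", name, "'", call. = FALSE)
  structure(list(name = name, indicators = indicators, anchor = anchor),
            class = "factor_block")
}

#' Default factor blocks
#'
#' Six indicators per factor, named `X1..X6`, `M1..M6`, `Y1..Y6`, anchored at
#' the first indicator — the layout emitted by [simulate_mlmm()].
#'
#' @param p indicators per factor.
#' @return named list of three [factor_block()] objects.
#' @export
default_blocks <- function(p = 6L) {
  list(X = factor_block("X", paste0("X", seq_len(p))),
       M = factor_block("M", paste0("M", seq_len(p))),
       Y = factor_block("Y", paste0("Y", seq_len(p))))
}

#' Conjugate prior settings
#'
#' Diffuse conjugate priors: normal for regression coefficients, loadings and
#' intercepts; inverse-gamma for residual variances; inverse-Wishart for the
#' 2x2 random-slope covariance matrix.
#'
#' @param coef_mean,coef_var normal prior mean and variance for coefficients
#'   and loadings.
#' @param var_shape,var_scale inverse-gamma shape and scale for variances.
#' @param slope_cov_scale,slope_cov_df inverse-Wishart scale matrix and
#'   degrees of freedom for the slope covariance.
#' @return an object of class `"mlmm_priors"`.
#' @export
mlmm_priors <- function(coef_mean = 0, coef_var = 1e6,
                        var_shape = 0.001, var_scale = 0.001,
                        slope_cov_scale = diag(2), slope_cov_df = 3) {
  if (coef_var <= 0 || var_shape <= 0 || var_scale <= 0)
    stop("prior variances and inverse-gamma hyperparameters must be positive",
         call. = FALSE)
  slope_cov_scale <- as.matrix(slope_cov_scale)
  if (!isTRUE(all.equal(slope_cov_scale, t(slope_cov_scale))) ||
      any(eigen(slope_cov_scale, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("slope_cov_scale must be symmetric positive definite", call. = FALSE)
  if (slope_cov_df < nrow(slope_cov_scale))
    stop("inverse-Wishart df must be >= dimension", call. = FALSE)
  structure(list(coef_mean = coef_mean, coef_var = coef_var,
                 var_shape = var_shape, var_scale = var_scale,
                 slope_cov_scale = slope_cov_scale, slope_cov_df = slope_cov_df),
            class = "mlmm_priors")
}

path_table <- function(source, target, label, random = FALSE, level) {
  data.frame(source = source, target = target, label = label,
             random = random, level = level, stringsAsFactors = FALSE)
}

build_spec <- function(parameterization, blocks, moderator, priors) {
  stopifnot(parameterization %in% c("brcp", "bint"))
  if (!is.list(blocks) || length(blocks) != 3L)
    stop("blocks must be a list of three factor blocks (X, M, Y)", call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    if (!inherits(b, "factor_block")) stop("blocks must be factor_block objects", call. = FALSE)
    b
  })
  names(blocks) <- vapply(blocks, `[[`, "", "name")
  missing <- setdiff(c("X", "M", "Y"), names(blocks))
  if (length(missing))
    stop("missing factor block(s): ", paste(missing, collapse = ", "), call. = FALSE)
  blocks <- blocks[c("X", "M", "Y")]
  all_ind <- unlist(lapply(blocks, `[[`, "indicators"), use.names = FALSE)
  if (anyDuplicated(all_ind))
    stop("indicator names duplicated across blocks: ",
         paste(unique(all_ind[duplicated(all_ind)]), collapse = ", "), call. = FALSE)
  moderator <- as.character(moderator)[1]
  if (moderator %in% all_ind)
    stop("moderator column '", moderator, "' collides with an indicator name",
         call. = FALSE)
  if (is.null(priors)) priors <- mlmm_priors()
  if (!inherits(priors, "mlmm_priors")) stop("priors must come from mlmm_priors()", call. = FALSE)

  within <- rbind(
    path_table("X", "M", "a_w",  random = TRUE,  level = "within"),
    path_table("M", "Y", "b_w",  random = TRUE,  level = "within"),
    path_table("X", "Y", "c_w",  random = FALSE, level = "within"),
    path_table("Z_w", "M", "beta_MZw", random = FALSE, level = "within"),
    path_table("Z_w", "Y", "beta_YZw", random = FALSE, level = "within"))
  between <- rbind(
    path_table("X_b", "M_b", "a_b", level = "between"),
    path_table("M_b", "Y_b", "b_b", level = "between"),
    path_table("X_b", "Y_b", "c_b", level = "between"),
    path_table("Z_b", "M_b", "beta_MZb", level = "between"),
    path_table("Z_b", "Y_b", "beta_YZb", level = "between"))
  moderation <- if (parameterization == "brcp") {
    # the moderator predicts each random slope at level 2
    rbind(path_table("Z_b", "slope_a", "gamma_aZ", level = "slope"),
          path_table("Z_b", "slope_b", "gamma_bZ", level = "slope"))
  } else {
    # fixed cross-level product terms in the within structural model
    rbind(path_table("X:Z_b", "M", "beta_cross_a", level = "within"),
          path_table("M:Z_b", "Y", "beta_cross_b", level = "within"))
  }
  structure(list(
    parameterization = parameterization,
    blocks = blocks,
    moderator = moderator,
    priors = priors,
    structural = list(within = within, between = between, moderation = moderation),
    identification = list(anchor_loading = 1, latent_means = 0,
                          between_intercepts = "free")),
    class = "mlmm_spec")
}

#' Random coefficient prediction (BRCP) model specification
#'
#' The within-level a path (X to M) and b path (M to Y) are cluster-specific
#' latent slopes. At the between level each slope is regressed on the observed
#' cluster-level moderator; slope residuals have an unstructured 2x2
#' covariance matrix, whose off-diagonal enters the expected indirect effect
#' as \eqn{E(a_g b_g) = E(a)E(b) + \sigma_{ab}}.
#'
#' @param blocks named list of three [factor_block()]s (`X`, `M`, `Y`).
#' @param moderator name of the observed moderator column.
#' @param priors an [mlmm_priors()] object; defaults are diffuse conjugate.
#' @return an object of class `"mlmm_spec"`.
#' @seealso [bint_spec()], [mixed_form()]
#' @export
brcp_spec <- function(blocks = default_blocks(), moderator = "Z",
                      priors = mlmm_priors()) {
  build_spec("brcp", blocks, moderator, priors)
}

#' Latent interaction (BINT) model specification
#'
#' Cross-level moderation is carried by fixed coefficients on the product
#' terms `X_w * Z_b` (in the mediator equation) and `M_w * Z_b` (in the
#' outcome equation); the random slopes are retained intercept-only, with
#' residual covariance matrix as in [brcp_spec()]. Substituting the slope
#' equations into the level-1 model shows the product-term coefficient plays
#' exactly the role of the slope-on-moderator regression weight, so the two
#' parameterizations express the same moderation effect.
#'
#' @inheritParams brcp_spec
#' @return an object of class `"mlmm_spec"`.
#' @export
bint_spec <- function(blocks = default_blocks(), moderator = "Z",
                      priors = mlmm_priors()) {
  build_spec("bint", blocks, moderator, priors)
}

#' @export
print.mlmm_spec <- function(x, ...) {
  cat("Two-level latent moderated mediation spec (",
      toupper(x$parameterization), ")\n", sep = "")
  for (b in x$blocks)
    cat("  ", b$name, ": ", paste(b$indicators, collapse = ", "),
        " (anchor ", b$indicators[b$anchor], ")\n", sep = "")
  cat("  moderator:", x$moderator, "\n")
  mod <- x$structural$moderation
  cat("  moderation terms:", paste(mod$label, collapse = ", "), "\n")
  invisible(x)
}

# Canonical parameter set shared by both parameterizations. `mod_a`/`mod_b`
# are the moderation weights: gamma_aZ/gamma_bZ under BRCP, beta_cross_a/
# beta_cross_b under BINT.
canonical_par_names <- function() {
  c("a0", "b0", "mod_a", "mod_b", "c_w", "beta_MZw", "beta_YZw")
}

#' Canonical mixed-model form of a specification
#'
#' Substitutes the cluster-level slope equations into the level-1 structural
#' equations and returns the expanded ("mixed") equations for the mediator and
#' the outcome as term lists with canonical coefficient names. BRCP and BINT
#' specifications map onto the same canonical form: the slope-on-moderator
#' weight of the one and the product-term coefficient of the other both appear
#' as the coefficient of the `Xw:Zb` (resp. `Mw:Zb`) term.
#'
#' @param spec an `"mlmm_spec"` object.
#' @return an object of class `"mlmm_mixed_form"`: per-equation data frames of
#'   `(term, coefficient)` rows in canonical order.
#' @export
mixed_form <- function(spec) {
  stopifnot(inherits(spec, "mlmm_spec"))
  m_terms <- data.frame(
    term        = c("Xw", "Xw:Zb", "Xw:u_a", "Zw"),
    coefficient = c("a0", "mod_a", "1", "beta_MZw"),
    stringsAsFactors = FALSE)
  y_terms <- data.frame(
    term        = c("Mw", "Mw:Zb", "Mw:u_b", "Xw", "Zw"),
    coefficient = c("b0", "mod_b", "1", "c_w", "beta_YZw"),
    stringsAsFactors = FALSE)
  m_terms <- m_terms[order(m_terms$term), , drop = FALSE]
  y_terms <- y_terms[order(y_terms$term), , drop = FALSE]
  rownames(m_terms) <- rownames(y_terms) <- NULL
  structure(list(M = m_terms, Y = y_terms,
                 parameterization = spec$parameterization),
            class = "mlmm_mixed_form")
}

#' Model-implied conditional means under a specification
#'
#' Evaluates the conditional expectations of the within components of the
#' mediator and the outcome given within predictor score, within and between
#' moderator components and cluster random effects, following the
#' specification's own route: BRCP composes the cluster slope from its
#' level-2 regression and multiplies once; BINT keeps an intercept-only random
#' slope and adds the product-term contribution. With the moderation weights
#' mapped onto each other the two routes give identical values.
#'
#' @param spec an `"mlmm_spec"` object.
#' @param pars named list/vector with elements `a0`, `b0`, `mod_a`, `mod_b`,
#'   `c_w`, `beta_MZw`, `beta_YZw`, `u_a`, `u_b` (canonical names, see
#'   [mixed_form()]).
#' @param data list/data.frame with `Xw`, `Zw`, `Zb` (vectors recycled).
#' @return data frame with columns `M` and `Y` of conditional means.
#' @export
conditional_mean <- function(spec, pars, data) {
  stopifnot(inherits(spec, "mlmm_spec"))
  p <- as.list(pars)
  need <- c(canonical_par_names(), "u_a", "u_b")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  Xw <- data$Xw; Zw <- data$Zw; Zb <- data$Zb
  if (spec$parameterization == "brcp") {
    a_g <- p$a0 + p$mod_a * Zb + p$u_a
    b_g <- p$b0 + p$mod_b * Zb + p$u_b
    M <- a_g * Xw + p$beta_MZw * Zw
    Y <- b_g * M + p$c_w * Xw + p$beta_YZw * Zw
  } else {
    a_g <- p$a0 + p$u_a                     # intercept-only random slope
    M <- a_g * Xw + p$mod_a * Xw * Zb + p$beta_MZw * Zw
    b_g <- p$b0 + p$u_b
    Y <- b_g * M + p$mod_b * M * Zb + p$c_w * Xw + p$beta_YZw * Zw
  }
  data.frame(M = M, Y = Y)
}

#' Serialize / restore a model specification
#'
#' Writes the specification (parameterization, blocks, moderator, priors,
#' identification constraints) as YAML; `spec_from_yaml()` reads it back.
#' JSON files are accepted on read.
#'
#' @param spec an `"mlmm_spec"` object.
#' @param path file path; if `NULL`, the YAML text is returned.
#' @return `spec_to_yaml()`: the path (or YAML string) invisibly;
#'   `spec_from_yaml()`: an `"mlmm_spec"`.
#' @export
spec_to_yaml <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "mlmm_spec"))
  obj <- list(
    parameterization = spec$parameterization,
    blocks = lapply(spec$blocks, function(b)
      list(name = b$name, indicators = b$indicators, anchor = b$anchor)),
    moderator = spec$moderator,
    priors = list(coef_mean = spec$priors$coef_mean,
                  coef_var = spec$priors$coef_var,
                  var_shape = spec$priors$var_shape,
                  var_scale = spec$priors$var_scale,
                  slope_cov_scale = as.vector(spec$priors$slope_cov_scale),
                  slope_cov_df = spec$priors$slope_cov_df),
    identification = spec$identification)
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname spec_to_yaml
#' @param text YAML text (alternative to `path`).
#' @export
spec_from_yaml <- function(path = NULL, text = NULL) {
  obj <- if (!is.null(text)) yaml::yaml.load(text) else {
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  blocks <- lapply(obj$blocks, function(b)
    factor_block(b$name, unlist(b$indicators), b$anchor))
  pr <- obj$priors
  priors <- if (is.null(pr)) mlmm_priors() else
    mlmm_priors(pr$coef_mean, pr$coef_var, pr$var_shape, pr$var_scale,
                matrix(unlist(pr$slope_cov_scale), 2, 2), pr$slope_cov_df)
  build_spec(obj$parameterization, blocks, obj$moderator, priors)
}
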