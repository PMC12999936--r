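// Gibbs sampler for the two-level latent moderated mediation model.
//
// Model (per cluster g, row i), with Zc_g = Zb_g - mu_Z the centered latent
// between component of the observed moderator:
//   indicators:  y_ki = nu_k + lam_b_k * etab_{f(k),g} + delta_kg
//                      + lam_w_k * etaw_{f(k),i} + eps_ki
//   within:      Mw = s_a,g Xw + bMZw Zw + e,  Yw = s_b,g Mw + c_w Xw + bYZw Zw + e
//   slopes:      s_a,g = gamma_a0 + mod_a * Zc_g + u_a,g,  (u_a,u_b) ~ N(0, T)
//   between:     Mb = a_b Xb + bMZb Zc + e,  Yb = b_b Mb + c_b Xb + bYZb Zc + e
//   moderator:   Z_i = Zb_g + Zw_i,  Zb_g ~ N(mu_Z, psi_Zb), Zw ~ N(0, psi_Zw)
//
// Identification: anchor loadings fixed to 1 at both levels, latent means 0
// (no structural intercepts; the centered moderator keeps them 0), between
// indicator intercepts nu free.
//
// BRCP and BINT share this generative structure; they differ in the Gibbs
// blocking of the moderation weight mod_*: BRCP draws it in the cluster-level
// slope regression (J observations), BINT in the row-level structural
// regression through the product term (N observations), with the random slope
// then intercept-only. All conditionals are conjugate (normal/inverse-gamma/
// inverse-Wishart).
//
// Cluster-level measurement conditionals (nu, lam_b, the between scores) use
// sufficient cluster sums, with the indicator's between residual delta
// integrated out (variance th_b + th_w/n_g); delta is redrawn from its full
// conditional immediately after each collapsed draw so no later update
// conditions on a stale value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double rnorm1() { return R::norm_rand(); }

static double rinvgamma(double shape, double scale) {
  // density ~ x^{-shape-1} exp(-scale/x)
  double g = R::rgamma(shape, 1.0 / scale);
  if (g <= 0) g = 1e-300;
  return 1.0 / g;
}

static vec draw_mvn_prec(const mat& prec, const vec& lin) {
  mat U;
  if (!chol(U, prec))
    Rcpp::stop("non-positive-definite conditional covariance in Gibbs update");
  vec mu = solve(trimatu(U), solve(trimatl(U.t()), lin));
  vec z(lin.n_elem);
  for (uword i = 0; i < z.n_elem; ++i) z(i) = rnorm1();
  return mu + solve(trimatu(U), z);
}

static double draw_norm_prec(double prec, double lin) {
  return lin / prec + rnorm1() / std::sqrt(prec);
}

// Bayesian linear regression draw: y = X beta + e, e ~ N(0, v), prior
// beta ~ N(prior_mean, prior_var I)
static vec draw_reg(const mat& X, const vec& y, double v,
                    double prior_mean, double prior_var, bool lik_on) {
  uword q = X.n_cols;
  mat prec = eye(q, q) / prior_var;
  vec lin = ones(q) * (prior_mean / prior_var);
  if (lik_on) {
    prec += X.t() * X / v;
    lin += X.t() * y / v;
  }
  return draw_mvn_prec(prec, lin);
}

static mat riwish(const mat& S, double df) {
  // T ~ IW(S, df)  <=>  T^{-1} ~ Wishart(S^{-1}, df)
  mat Sinv = inv_sympd(S);
  mat L = chol(Sinv, "lower");
  uword d = S.n_rows;
  mat A(d, d, fill::zeros);
  for (uword i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (uword j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  mat W = L * A * A.t() * L.t();
  return inv_sympd(W);
}

// [[Rcpp::export(name = ".gibbs_mlmm")]]
Rcpp::List gibbs_mlmm(const arma::mat& Y, const arma::vec& Zobs,
                      const arma::ivec& cstart, const arma::ivec& csize,
                      int p, bool bint,
                      Rcpp::List priors, Rcpp::List init, Rcpp::List control,
                      int n_iter, int n_burn) {
  const uword N = Y.n_rows, K = Y.n_cols, J = cstart.n_elem;
  if (K != (uword)(3 * p)) Rcpp::stop("indicator matrix has wrong width");

  // priors
  const double m0 = priors["coef_mean"], v0 = priors["coef_var"];
  const double ig_a = priors["var_shape"], ig_b = priors["var_scale"];
  const mat S0 = Rcpp::as<mat>(priors["slope_cov_scale"]);
  const double iw_df = priors["slope_cov_df"];

  // control
  const bool up_meas   = control["update_measurement"];
  const bool up_score  = control["update_scores"];
  const bool up_sc_w   = up_score && Rcpp::as<bool>(control["update_scores_within"]);
  const bool up_sc_b   = up_score && Rcpp::as<bool>(control["update_scores_between"]);
  const bool up_z      = up_score && Rcpp::as<bool>(control["update_z"]);
  const bool up_slope  = control["update_slopes"];
  const bool up_str_w  = control["update_struct_within"];
  const bool up_sreg   = control["update_slope_reg"];
  const bool up_str_b  = control["update_struct_between"];
  const bool up_mu     = control["update_mu_Z"];
  const bool up_var    = control["update_variances"];
  const bool up_T      = control["update_T"];
  const bool lik_on    = !Rcpp::as<bool>(control["prior_only"]);

  // state
  vec nu = Rcpp::as<vec>(init["nu"]);
  vec lam_w = Rcpp::as<vec>(init["lam_w"]), lam_b = Rcpp::as<vec>(init["lam_b"]);
  vec th_w = Rcpp::as<vec>(init["th_w"]), th_b = Rcpp::as<vec>(init["th_b"]);
  double psi_Xw = init["psi_Xw"], res_Mw = init["res_Mw"], res_Yw = init["res_Yw"];
  double psi_Xb = init["psi_Xb"], res_Mb = init["res_Mb"], res_Yb = init["res_Yb"];
  double c_w = init["c_w"], bMZw = init["beta_MZw"], bYZw = init["beta_YZw"];
  double g_a0 = init["gamma_a0"], g_b0 = init["gamma_b0"];
  double mod_a = init["mod_a"], mod_b = init["mod_b"];
  mat T = Rcpp::as<mat>(init["Tmat"]);
  double a_b = init["a_b"], b_b = init["b_b"], c_b = init["c_b"];
  double bMZb = init["beta_MZb"], bYZb = init["beta_YZb"];
  double mu_Z = init["mu_Z"], psi_Zw = init["psi_Zw"], psi_Zb = init["psi_Zb"];
  mat eta_w = Rcpp::as<mat>(init["eta_w"]);   // N x 3
  mat eta_b = Rcpp::as<mat>(init["eta_b"]);   // J x 3
  mat delta = Rcpp::as<mat>(init["delta"]);   // J x K
  vec Zb = Rcpp::as<vec>(init["Zb"]);         // J
  mat u = Rcpp::as<mat>(init["u"]);           // J x 2

  // anchor indices (loading fixed at 1): first indicator of each factor
  uvec anchors(3);
  for (int f = 0; f < 3; ++f) anchors(f) = (uword)(f * p);
  auto fac = [p](uword k) { return (int)(k / (uword)p); };

  uvec gidx(N);            // cluster id per row
  for (uword g = 0; g < J; ++g)
    for (int i = 0; i < csize(g); ++i) gidx(cstart(g) + i) = g;
  vec ngv(J);
  for (uword g = 0; g < J; ++g) ngv(g) = (double)csize(g);

  // data summaries that never change
  mat SUMY(J, K, fill::zeros);       // cluster sums of indicators
  vec SUMY2(K, fill::zeros);         // total sums of squares
  vec SZ(J, fill::zeros);            // cluster sums of the moderator
  for (uword i = 0; i < N; ++i) {
    uword g = gidx(i);
    for (uword k = 0; k < K; ++k) {
      SUMY(g, k) += Y(i, k);
      SUMY2(k) += Y(i, k) * Y(i, k);
    }
    SZ(g) += Zobs(i);
  }

  // cluster sums of the current within factor scores
  mat SXW(J, 3);
  auto refresh_SXW = [&]() {
    SXW.zeros();
    for (uword i = 0; i < N; ++i) {
      uword g = gidx(i);
      SXW(g, 0) += eta_w(i, 0);
      SXW(g, 1) += eta_w(i, 1);
      SXW(g, 2) += eta_w(i, 2);
    }
  };

  const int n_keep = n_iter - n_burn;
  const uword P = 5 * K + 26;
  mat out(n_keep, P);

  Rcpp::RNGScope scope;

  for (int it = 0; it < n_iter; ++it) {
    // centered moderator component and effective slopes per cluster
    vec Zc = Zb - mu_Z;
    vec s_a = g_a0 + mod_a * Zc + u.col(0);
    vec s_b = g_b0 + mod_b * Zc + u.col(1);

    // ---------------- measurement parameters ----------------
    if (up_meas) {
      refresh_SXW();
      mat XY = eta_w.t() * Y;                          // 3 x K
      vec SXX(3), SXW_tot(3);
      for (int f = 0; f < 3; ++f) {
        SXX(f) = dot(eta_w.col(f), eta_w.col(f));
        SXW_tot(f) = accu(SXW.col(f));
      }
      for (uword k = 0; k < K; ++k) {
        int f = fac(k);
        // cluster sums of Y - lam_w * eta_w for this indicator
        vec SYg = SUMY.col(k) - lam_w(k) * SXW.col(f);
        vec vk = th_b(k) + th_w(k) / ngv;              // delta integrated out
        // nu_k | lam, eta (delta collapsed)
        {
          double prec = 1.0 / v0, lin = m0 / v0;
          if (lik_on)
            for (uword g = 0; g < J; ++g) {
              double m = SYg(g) / ngv(g) - lam_b(k) * eta_b(g, f);
              prec += 1.0 / vk(g);
              lin += m / vk(g);
            }
          nu(k) = draw_norm_prec(prec, lin);
        }
        // delta_kg | nu, lam, eta
        auto draw_delta_k = [&]() {
          for (uword g = 0; g < J; ++g) {
            double S = SYg(g) - ngv(g) * (nu(k) + lam_b(k) * eta_b(g, f));
            double prec = ngv(g) / th_w(k) + 1.0 / th_b(k);
            delta(g, k) = draw_norm_prec(prec, S / th_w(k));
          }
        };
        draw_delta_k();
        if (k != anchors(f)) {
          // lam_w_k | rest (row-level regression on eta_w)
          {
            double cross = 0;   // sum_g (lam_b eta_b + delta) * sum eta_w
            for (uword g = 0; g < J; ++g)
              cross += (lam_b(k) * eta_b(g, f) + delta(g, k)) * SXW(g, f);
            double sxy = XY(f, k) - nu(k) * SXW_tot(f) - cross;
            double prec = 1.0 / v0, lin = m0 / v0;
            if (lik_on) { prec += SXX(f) / th_w(k); lin += sxy / th_w(k); }
            lam_w(k) = draw_norm_prec(prec, lin);
            SYg = SUMY.col(k) - lam_w(k) * SXW.col(f);
          }
          // lam_b_k | eta_b (delta collapsed): cluster-mean regression
          {
            double sxx = 0, sxy = 0;
            for (uword g = 0; g < J; ++g) {
              double x = eta_b(g, f);
              double m = SYg(g) / ngv(g) - nu(k);
              sxx += x * x / vk(g); sxy += x * m / vk(g);
            }
            double prec = 1.0 / v0, lin = m0 / v0;
            if (lik_on) { prec += sxx; lin += sxy; }
            lam_b(k) = draw_norm_prec(prec, lin);
          }
          draw_delta_k();
        }
      }
    }

    // ---------------- within factor scores ----------------
    if (up_sc_w) {
      mat Wmat(K, 3, fill::zeros);
      vec q_w(3, fill::zeros);
      for (uword k = 0; k < K; ++k) {
        int f = fac(k);
        Wmat(k, f) = lam_w(k) / th_w(k);
        q_w(f) += lam_w(k) * lam_w(k) / th_w(k);
      }
      // H(i,f) = sum_k Wmat(k,f) (y_ki - nu_k - lam_b_k etab - delta_kg):
      // row-level part by GEMM, cluster-level part subtracted per cluster
      mat Ht = (Y * Wmat).t();                         // 3 x N
      mat Hc(J, 3, fill::zeros);                       // cluster-level offset
      for (uword k = 0; k < K; ++k) {
        int f = fac(k);
        for (uword g = 0; g < J; ++g)
          Hc(g, f) += Wmat(k, f) *
            (nu(k) + lam_b(k) * eta_b(g, f) + delta(g, k));
      }
      vec Dinv = { 1.0 / psi_Xw, 1.0 / res_Mw, 1.0 / res_Yw };
      for (uword g = 0; g < J; ++g) {
        mat B = eye(3, 3);
        B(1, 0) = -s_a(g); B(2, 0) = -c_w; B(2, 1) = -s_b(g);
        mat BD = B.t() * diagmat(Dinv);
        mat Pmat = BD * B + diagmat(q_w);
        mat U;
        if (!chol(U, Pmat))
          Rcpp::stop("non-positive-definite conditional covariance (within scores)");
        vec cvec = { 0.0, bMZw, bYZw };
        vec vg = BD * cvec;
        int ng = csize(g);
        uword r0 = cstart(g), r1 = r0 + ng - 1;
        rowvec zw = Zobs.subvec(r0, r1).t() - Zb(g);
        mat Lin = Ht.cols(r0, r1);
        Lin.each_col() -= Hc.row(g).t();
        Lin += vg * zw;
        mat Mu = solve(trimatu(U), solve(trimatl(U.t()), Lin));
        mat Zr(3, ng);
        for (uword a = 0; a < 3; ++a)
          for (int i = 0; i < ng; ++i) Zr(a, i) = rnorm1();
        eta_w.rows(r0, r1) = (Mu + solve(trimatu(U), Zr)).t();
      }
    }

    // ---------------- between factor scores (delta collapsed) ----------
    if (up_sc_b) {
      refresh_SXW();
      vec Dbinv = { 1.0 / psi_Xb, 1.0 / res_Mb, 1.0 / res_Yb };
      mat Bb = eye(3, 3);
      Bb(1, 0) = -a_b; Bb(2, 0) = -c_b; Bb(2, 1) = -b_b;
      mat BbD = Bb.t() * diagmat(Dbinv);
      for (uword g = 0; g < J; ++g) {
        vec q_b(3, fill::zeros), h(3, fill::zeros);
        for (uword k = 0; k < K; ++k) {
          int f = fac(k);
          double m = (SUMY(g, k) - lam_w(k) * SXW(g, f)) / ngv(g) - nu(k);
          double vk = th_b(k) + th_w(k) / ngv(g);
          q_b(f) += lam_b(k) * lam_b(k) / vk;
          h(f) += lam_b(k) * m / vk;
        }
        vec cb = { 0.0, bMZb * Zc(g), bYZb * Zc(g) };
        mat Pmat = BbD * Bb + diagmat(q_b);
        vec lin = BbD * cb + h;
        eta_b.row(g) = draw_mvn_prec(Pmat, lin).t();
      }
      // delta | eta_b (completes the collapsed block update)
      for (uword k = 0; k < K; ++k) {
        int f = fac(k);
        for (uword g = 0; g < J; ++g) {
          double S = SUMY(g, k) - lam_w(k) * SXW(g, f)
                     - ngv(g) * (nu(k) + lam_b(k) * eta_b(g, f));
          double prec = ngv(g) / th_w(k) + 1.0 / th_b(k);
          delta(g, k) = draw_norm_prec(prec, S / th_w(k));
        }
      }
    }

    // ---------------- latent decomposition of Z ----------------
    // draw the centered component xc = Zb_g - mu_Z conditional on the
    // primitive random effects u (effective slopes recomputed after)
    if (up_z) {
      for (uword g = 0; g < J; ++g) {
        int ng = csize(g);
        double prec = 1.0 / psi_Zb + ng / psi_Zw;
        double lin = (SZ(g) - ng * mu_Z) / psi_Zw;
        double sa0 = g_a0 + u(g, 0), sb0 = g_b0 + u(g, 1);
        for (int i = 0; i < ng; ++i) {
          uword r = cstart(g) + i;
          double zi = Zobs(r) - mu_Z;
          // within M equation: resid = rM + xc * wM
          double wM = bMZw - mod_a * eta_w(r, 0);
          double rM = eta_w(r, 1) - sa0 * eta_w(r, 0) - bMZw * zi;
          prec += wM * wM / res_Mw;
          lin -= wM * rM / res_Mw;
          // within Y equation
          double wY = bYZw - mod_b * eta_w(r, 1);
          double rY = eta_w(r, 2) - sb0 * eta_w(r, 1) - c_w * eta_w(r, 0)
                      - bYZw * zi;
          prec += wY * wY / res_Yw;
          lin -= wY * rY / res_Yw;
        }
        // between structural equations
        double rMb = eta_b(g, 1) - a_b * eta_b(g, 0);
        prec += bMZb * bMZb / res_Mb;
        lin += bMZb * rMb / res_Mb;
        double rYb = eta_b(g, 2) - b_b * eta_b(g, 1) - c_b * eta_b(g, 0);
        prec += bYZb * bYZb / res_Yb;
        lin += bYZb * rYb / res_Yb;
        double xc = draw_norm_prec(prec, lin);
        Zb(g) = mu_Z + xc;
      }
      Zc = Zb - mu_Z;
      s_a = g_a0 + mod_a * Zc + u.col(0);
      s_b = g_b0 + mod_b * Zc + u.col(1);
    }

    // ---------------- random slope effects ----------------
    if (up_slope) {
      mat Tinv = inv_sympd(T);
      for (uword g = 0; g < J; ++g) {
        int ng = csize(g);
        double sxx = 0, sxr = 0, smm = 0, smq = 0;
        double ma = g_a0 + mod_a * Zc(g), mb = g_b0 + mod_b * Zc(g);
        for (int i = 0; i < ng; ++i) {
          uword r = cstart(g) + i;
          double zw = Zobs(r) - Zb(g);
          double x = eta_w(r, 0), m = eta_w(r, 1);
          double rM = m - ma * x - bMZw * zw;
          double rY = eta_w(r, 2) - mb * m - c_w * x - bYZw * zw;
          sxx += x * x; sxr += x * rM;
          smm += m * m; smq += m * rY;
        }
        mat prec = Tinv;
        vec lin(2, fill::zeros);
        if (lik_on) {
          prec(0, 0) += sxx / res_Mw;
          prec(1, 1) += smm / res_Yw;
          lin(0) += sxr / res_Mw;
          lin(1) += smq / res_Yw;
        }
        u.row(g) = draw_mvn_prec(prec, lin).t();
      }
      s_a = g_a0 + mod_a * Zc + u.col(0);
      s_b = g_b0 + mod_b * Zc + u.col(1);
    }

    // ---------------- structural coefficients ----------------
    {
      vec zw(N);
      for (uword i = 0; i < N; ++i) zw(i) = Zobs(i) - Zb(gidx(i));
      if (!bint) {
        // BRCP blocking: within fixed effects exclude the moderation weight
        if (up_str_w) {
          vec r(N);
          for (uword i = 0; i < N; ++i)
            r(i) = eta_w(i, 1) - s_a(gidx(i)) * eta_w(i, 0);
          vec beta = draw_reg(mat(zw), r, res_Mw, m0, v0, lik_on);
          bMZw = beta(0);
        }
        if (up_str_w) {
          mat X(N, 2);
          vec r(N);
          for (uword i = 0; i < N; ++i) {
            X(i, 0) = eta_w(i, 0); X(i, 1) = zw(i);
            r(i) = eta_w(i, 2) - s_b(gidx(i)) * eta_w(i, 1);
          }
          vec beta = draw_reg(X, r, res_Yw, m0, v0, lik_on);
          c_w = beta(0); bYZw = beta(1);
        }
        // slope-on-moderator regression, bivariate responses, error cov T:
        // (a_g, b_g) = A_g theta + u_g, A_g = [1 Zc 0 0; 0 0 1 Zc]
        if (up_sreg) {
          mat Tinv = inv_sympd(T);
          mat prec = eye(4, 4) / v0;
          vec lin = ones(4) * (m0 / v0);
          if (lik_on) {
            for (uword g = 0; g < J; ++g) {
              mat A(2, 4, fill::zeros);
              A(0, 0) = 1; A(0, 1) = Zc(g); A(1, 2) = 1; A(1, 3) = Zc(g);
              vec sg = { s_a(g), s_b(g) };
              prec += A.t() * Tinv * A;
              lin += A.t() * Tinv * sg;
            }
          }
          vec th = draw_mvn_prec(prec, lin);
          g_a0 = th(0); mod_a = th(1); g_b0 = th(2); mod_b = th(3);
          u.col(0) = s_a - g_a0 - mod_a * Zc;
          u.col(1) = s_b - g_b0 - mod_b * Zc;
        }
      } else {
        // BINT blocking: product terms sit in the row-level regressions
        if (up_str_w) {
          mat X(N, 2);
          vec r(N);
          for (uword i = 0; i < N; ++i) {
            uword g = gidx(i);
            X(i, 0) = zw(i); X(i, 1) = eta_w(i, 0) * Zc(g);
            r(i) = eta_w(i, 1) - (g_a0 + u(g, 0)) * eta_w(i, 0);
          }
          vec beta = draw_reg(X, r, res_Mw, m0, v0, lik_on);
          bMZw = beta(0); mod_a = beta(1);
        }
        if (up_str_w) {
          mat X(N, 3);
          vec r(N);
          for (uword i = 0; i < N; ++i) {
            uword g = gidx(i);
            X(i, 0) = eta_w(i, 0); X(i, 1) = zw(i);
            X(i, 2) = eta_w(i, 1) * Zc(g);
            r(i) = eta_w(i, 2) - (g_b0 + u(g, 1)) * eta_w(i, 1);
          }
          vec beta = draw_reg(X, r, res_Yw, m0, v0, lik_on);
          c_w = beta(0); bYZw = beta(1); mod_b = beta(2);
        }
        // intercept-only slope regression with error cov T
        if (up_sreg) {
          s_a = g_a0 + mod_a * Zc + u.col(0);
          s_b = g_b0 + mod_b * Zc + u.col(1);
          vec sma = s_a - mod_a * Zc, smb = s_b - mod_b * Zc;
          mat Tinv = inv_sympd(T);
          mat prec = eye(2, 2) / v0;
          vec lin = ones(2) * (m0 / v0);
          if (lik_on) {
            prec += (double)J * Tinv;
            vec sbar = { accu(sma), accu(smb) };
            lin += Tinv * sbar;
          }
          vec th = draw_mvn_prec(prec, lin);
          g_a0 = th(0); g_b0 = th(1);
          u.col(0) = sma - g_a0;
          u.col(1) = smb - g_b0;
        }
      }
      s_a = g_a0 + mod_a * Zc + u.col(0);
      s_b = g_b0 + mod_b * Zc + u.col(1);

      // between-level regressions (no intercept: latent means fixed at 0)
      if (up_str_b) {
        mat X(J, 2);
        vec r(J);
        for (uword g = 0; g < J; ++g) {
          X(g, 0) = eta_b(g, 0); X(g, 1) = Zc(g);
          r(g) = eta_b(g, 1);
        }
        vec beta = draw_reg(X, r, res_Mb, m0, v0, lik_on);
        a_b = beta(0); bMZb = beta(1);
      }
      if (up_str_b) {
        mat X(J, 3);
        vec r(J);
        for (uword g = 0; g < J; ++g) {
          X(g, 0) = eta_b(g, 1); X(g, 1) = eta_b(g, 0); X(g, 2) = Zc(g);
          r(g) = eta_b(g, 2);
        }
        vec beta = draw_reg(X, r, res_Yb, m0, v0, lik_on);
        b_b = beta(0); c_b = beta(1); bYZb = beta(2);
      }
      // moderator grand mean: appears in the Zb prior and, through
      // centering, in every equation where Zc is a predictor
      if (up_mu) {
        double prec = 1.0 / v0, lin = m0 / v0;
        if (lik_on) {
          prec += J / psi_Zb; lin += accu(Zb) / psi_Zb;
          for (uword g = 0; g < J; ++g) {
            double rMb = eta_b(g, 1) - a_b * eta_b(g, 0) - bMZb * Zc(g);
            prec += bMZb * bMZb / res_Mb;
            lin -= bMZb * rMb / res_Mb;
            double rYb = eta_b(g, 2) - b_b * eta_b(g, 1) - c_b * eta_b(g, 0)
                         - bYZb * Zc(g);
            prec += bYZb * bYZb / res_Yb;
            lin -= bYZb * rYb / res_Yb;
          }
          for (uword i = 0; i < N; ++i) {
            uword g = gidx(i);
            double x = eta_w(i, 0), m = eta_w(i, 1);
            double rM = m - s_a(g) * x - bMZw * zw(i);
            prec += mod_a * mod_a * x * x / res_Mw;
            lin -= mod_a * x * rM / res_Mw;
            double rY = eta_w(i, 2) - s_b(g) * m - c_w * x - bYZw * zw(i);
            prec += mod_b * mod_b * m * m / res_Yw;
            lin -= mod_b * m * rY / res_Yw;
          }
        }
        mu_Z = draw_norm_prec(prec, lin);
        Zc = Zb - mu_Z;
        s_a = g_a0 + mod_a * Zc + u.col(0);
        s_b = g_b0 + mod_b * Zc + u.col(1);
      }
    }

    // ---------------- variances ----------------
    if (up_var) {
      auto ig = [&](double ss, double n) {
        if (!lik_on) return rinvgamma(ig_a, ig_b);
        return rinvgamma(ig_a + n / 2.0, ig_b + std::max(ss, 0.0) / 2.0);
      };
      double ssM = 0, ssY = 0, ssZw = 0;
      for (uword i = 0; i < N; ++i) {
        uword g = gidx(i);
        double zwi = Zobs(i) - Zb(g);
        double rM = eta_w(i, 1) - s_a(g) * eta_w(i, 0) - bMZw * zwi;
        double rY = eta_w(i, 2) - s_b(g) * eta_w(i, 1) - c_w * eta_w(i, 0)
                    - bYZw * zwi;
        ssM += rM * rM; ssY += rY * rY; ssZw += zwi * zwi;
      }
      psi_Xw = ig(dot(eta_w.col(0), eta_w.col(0)), (double)N);
      res_Mw = ig(ssM, (double)N);
      res_Yw = ig(ssY, (double)N);
      psi_Zw = ig(ssZw, (double)N);

      double ssMb = 0, ssYb = 0, ssZb = 0;
      for (uword g = 0; g < J; ++g) {
        double rM = eta_b(g, 1) - a_b * eta_b(g, 0) - bMZb * Zc(g);
        double rY = eta_b(g, 2) - b_b * eta_b(g, 1) - c_b * eta_b(g, 0)
                    - bYZb * Zc(g);
        ssMb += rM * rM; ssYb += rY * rY;
        ssZb += Zc(g) * Zc(g);
      }
      psi_Xb = ig(dot(eta_b.col(0), eta_b.col(0)), (double)J);
      res_Mb = ig(ssMb, (double)J);
      res_Yb = ig(ssYb, (double)J);
      psi_Zb = ig(ssZb, (double)J);

      // indicator residual variances from sufficient sums:
      // ss_k = sum_i (R_ki - c_kg)^2, R = y - lam_w eta_w,
      // c_kg = nu + lam_b eta_b + delta
      refresh_SXW();
      mat XY = eta_w.t() * Y;
      vec SXX(3);
      for (int f = 0; f < 3; ++f) SXX(f) = dot(eta_w.col(f), eta_w.col(f));
      for (uword k = 0; k < K; ++k) {
        int f = fac(k);
        double ssR = SUMY2(k) - 2.0 * lam_w(k) * XY(f, k)
                     + lam_w(k) * lam_w(k) * SXX(f);
        double ss = ssR;
        for (uword g = 0; g < J; ++g) {
          double cg = nu(k) + lam_b(k) * eta_b(g, f) + delta(g, k);
          double SRg = SUMY(g, k) - lam_w(k) * SXW(g, f);
          ss += -2.0 * cg * SRg + ngv(g) * cg * cg;
        }
        th_w(k) = ig(ss, (double)N);
        th_b(k) = ig(dot(delta.col(k), delta.col(k)), (double)J);
      }
    }

    // ---------------- slope covariance T ----------------
    if (up_T) {
      mat S = S0;
      double df = iw_df;
      if (lik_on) { S += u.t() * u; df += (double)J; }
      T = riwish(S, df);
    }

    // ---------------- store ----------------
    if (it >= n_burn) {
      uword r = it - n_burn, c = 0;
      for (uword k = 0; k < K; ++k) out(r, c++) = nu(k);
      for (uword k = 0; k < K; ++k) out(r, c++) = lam_w(k);
      for (uword k = 0; k < K; ++k) out(r, c++) = lam_b(k);
      for (uword k = 0; k < K; ++k) out(r, c++) = th_w(k);
      for (uword k = 0; k < K; ++k) out(r, c++) = th_b(k);
      double sc[] = { psi_Xw, res_Mw, res_Yw, psi_Xb, res_Mb, res_Yb,
                      c_w, bMZw, bYZw, g_a0, g_b0, mod_a, mod_b,
                      T(0,0), T(0,1), T(1,1),
                      a_b, b_b, c_b, bMZb, bYZb,
                      mu_Z, psi_Zw, psi_Zb,
                      g_a0, g_b0 };   // a_w, b_w: slope means at the
                                      // moderator's between-level mean
      for (int s = 0; s < 26; ++s) out(r, c++) = sc[s];
    }
  }

  Rcpp::List state = Rcpp::List::create(
    Rcpp::Named("nu") = nu, Rcpp::Named("lam_w") = lam_w,
    Rcpp::Named("lam_b") = lam_b, Rcpp::Named("th_w") = th_w,
    Rcpp::Named("th_b") = th_b,
    Rcpp::Named("psi_Xw") = psi_Xw, Rcpp::Named("res_Mw") = res_Mw,
    Rcpp::Named("res_Yw") = res_Yw, Rcpp::Named("psi_Xb") = psi_Xb,
    Rcpp::Named("res_Mb") = res_Mb, Rcpp::Named("res_Yb") = res_Yb,
    Rcpp::Named("c_w") = c_w, Rcpp::Named("beta_MZw") = bMZw,
    Rcpp::Named("beta_YZw") = bYZw, Rcpp::Named("gamma_a0") = g_a0,
    Rcpp::Named("gamma_b0") = g_b0, Rcpp::Named("mod_a") = mod_a,
    Rcpp::Named("mod_b") = mod_b, Rcpp::Named("Tmat") = T);
  state.push_back(a_b, "a_b"); state.push_back(b_b, "b_b");
  state.push_back(c_b, "c_b"); state.push_back(bMZb, "beta_MZb");
  state.push_back(bYZb, "beta_YZb"); state.push_back(mu_Z, "mu_Z");
  state.push_back(psi_Zw, "psi_Zw"); state.push_back(psi_Zb, "psi_Zb");
  state.push_back(eta_w, "eta_w"); state.push_back(eta_b, "eta_b");
  state.push_back(delta, "delta"); state.push_back(Zb, "Zb");
  state.push_back(u, "u");

  return Rcpp::List::create(Rcpp::Named("draws") = out,
                            Rcpp::Named("state") = state);
}
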