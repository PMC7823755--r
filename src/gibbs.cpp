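#include <Rcpp.h>
using namespace Rcpp;

// Single-site Gibbs sampler for the single-step BayesC model
//   y = F beta + M alpha + Z u + Z_n eps + e
// where F collects all flat-prior effects (fixed effects, breed fractions,
// J covariates), M holds centered/imputed marker covariates at the record
// level, u is the residual polygenic effect with prior N(0, A w sg2) handled
// through the sparse A-inverse, and eps is the imputation residual for
// non-genotyped animals with prior N(0, (Ann - Ang Agg^-1 Agn)(1-w) sg2),
// whose precision is exactly the nn block of A-inverse.
// Marker effects follow the BayesC two-component mixture with common
// variance sigma_a2 and fixed null probability pi. Variances may be fixed
// or sampled from scaled-inverse-chi-square full conditionals.
// All randomness flows through R's RNG so set.seed() governs the chain.

static inline double rinvchisq(double df, double scale_sum) {
  // draw from scale_sum / chisq_df
  return scale_sum / R::rchisq(df);
}

// forward/back solves in the lower-triangular Cholesky factor L (F'F = LL')
static void chol_solve_lower(const NumericMatrix& L, std::vector<double>& x) {
  const int n = L.ncol();
  for (int i = 0; i < n; ++i) {
    double s = x[i];
    for (int j = 0; j < i; ++j) s -= L(i, j) * x[j];
    x[i] = s / L(i, i);
  }
}
static void chol_solve_upper(const NumericMatrix& L, std::vector<double>& x) {
  const int n = L.ncol();
  for (int i = n - 1; i >= 0; --i) {
    double s = x[i];
    for (int j = i + 1; j < n; ++j) s -= L(j, i) * x[j];
    x[i] = s / L(i, i);
  }
}

// [[Rcpp::export(".gibbs_cpp")]]
List gibbs_cpp(NumericVector y, NumericMatrix F, NumericMatrix M,
               IntegerVector rec_anim, int n_anim, IntegerVector ng_idx,
               IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
               IntegerVector Np, IntegerVector Ni, NumericVector Nx,
               double pi_, double sigma_e2, double sigma_g2,
               double sigma_a2, double w,
               bool update_sigma_e, bool update_sigma_g, bool update_sigma_a,
               double nu_e, double Se2, double nu_g, double Sg2,
               double nu_a, double Sa2,
               int n_iter, int burn_in, int thin,
               NumericMatrix Lchol, bool block_fixed) {
  const int n_obs = y.size();
  const int nf = F.ncol();
  const int p = M.ncol();
  const double *Fp = F.begin();
  const double *Mp = M.begin();
  const int n_ng = ng_idx.size();
  const bool use_u = (w > 0.0);
  const bool use_eps = (w < 1.0) && (n_ng > 0);

  // record index per animal (-1 = no phenotype)
  std::vector<int> rec_of(n_anim, -1);
  for (int r = 0; r < n_obs; ++r) rec_of[rec_anim[r] - 1] = r;

  // column sums of squares
  std::vector<double> cF(nf), cM(p);
  for (int j = 0; j < nf; ++j) {
    const double *fj = Fp + (size_t)j * n_obs;
    double s = 0; for (int r = 0; r < n_obs; ++r) s += fj[r] * fj[r];
    cF[j] = s;
  }
  for (int k = 0; k < p; ++k) {
    const double *mk = Mp + (size_t)k * n_obs;
    double s = 0; for (int r = 0; r < n_obs; ++r) s += mk[r] * mk[r];
    cM[k] = s;
  }

  std::vector<double> beta(nf, 0.0), alpha(p, 0.0);
  std::vector<int> delta(p, 0);
  std::vector<double> u(n_anim, 0.0), eps(n_ng, 0.0);
  std::vector<double> e(y.begin(), y.end());

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix beta_d(n_keep, nf), alpha_d(n_keep, p);
  NumericMatrix u_d(n_keep, n_anim), eps_d(n_keep, std::max(n_ng, 1));
  NumericVector se_d(n_keep), sg_d(n_keep), sa_d(n_keep);
  NumericVector incl(p);
  int kept = 0;

  for (int it = 1; it <= n_iter; ++it) {
    // ---- flat-prior effects ----
    if (block_fixed) {
      // joint draw beta ~ N((F'F)^-1 F'(e + F beta), sigma_e2 (F'F)^-1)
      for (int j = 0; j < nf; ++j) {
        const double *fj = Fp + (size_t)j * n_obs;
        const double bj = beta[j];
        for (int r = 0; r < n_obs; ++r) e[r] += fj[r] * bj;
      }
      std::vector<double> rhs(nf, 0.0);
      for (int j = 0; j < nf; ++j) {
        const double *fj = Fp + (size_t)j * n_obs;
        double s = 0;
        for (int r = 0; r < n_obs; ++r) s += fj[r] * e[r];
        rhs[j] = s;
      }
      chol_solve_lower(Lchol, rhs);
      chol_solve_upper(Lchol, rhs);  // rhs = mean
      std::vector<double> z(nf);
      double sde = std::sqrt(sigma_e2);
      for (int j = 0; j < nf; ++j) z[j] = sde * R::norm_rand();
      chol_solve_upper(Lchol, z);    // z ~ N(0, sigma_e2 (F'F)^-1)
      for (int j = 0; j < nf; ++j) beta[j] = rhs[j] + z[j];
      for (int j = 0; j < nf; ++j) {
        const double *fj = Fp + (size_t)j * n_obs;
        const double bj = beta[j];
        for (int r = 0; r < n_obs; ++r) e[r] -= fj[r] * bj;
      }
    } else {
      for (int j = 0; j < nf; ++j) {
        if (cF[j] <= 0) continue;
        const double *fj = Fp + (size_t)j * n_obs;
        double old = beta[j], rhs = 0;
        for (int r = 0; r < n_obs; ++r) {
          e[r] += fj[r] * old;
          rhs += fj[r] * e[r];
        }
        double bn = rhs / cF[j] + R::rnorm(0.0, std::sqrt(sigma_e2 / cF[j]));
        for (int r = 0; r < n_obs; ++r) e[r] -= fj[r] * bn;
        beta[j] = bn;
      }
    }

    // ---- marker effects: BayesC mixture ----
    int m_in = 0;
    double ssa = 0.0;
    if (p > 0) {
      double lam = sigma_e2 / sigma_a2;
      double logit_pi = (pi_ > 0.0 && pi_ < 1.0)
        ? std::log((1.0 - pi_) / pi_) : 0.0;
      for (int k = 0; k < p; ++k) {
        if (cM[k] <= 0) { alpha[k] = 0; delta[k] = 0; continue; }
        const double *mk = Mp + (size_t)k * n_obs;
        double old = alpha[k], rhs = 0;
        if (old != 0.0) {
          for (int r = 0; r < n_obs; ++r) { e[r] += mk[r] * old; rhs += mk[r] * e[r]; }
        } else {
          for (int r = 0; r < n_obs; ++r) rhs += mk[r] * e[r];
        }
        double cl = cM[k] + lam;
        int d_new;
        if (pi_ <= 0.0) d_new = 1;
        else if (pi_ >= 1.0) d_new = 0;
        else {
          double lo = logit_pi + 0.5 * std::log(lam / cl)
            + rhs * rhs / (2.0 * sigma_e2 * cl);
          double pr = 1.0 / (1.0 + std::exp(-lo));
          d_new = (R::unif_rand() < pr) ? 1 : 0;
        }
        double a_new = 0.0;
        if (d_new == 1) {
          a_new = rhs / cl + R::rnorm(0.0, std::sqrt(sigma_e2 / cl));
          ++m_in; ssa += a_new * a_new;
        }
        if (a_new != 0.0) {
          for (int r = 0; r < n_obs; ++r) e[r] -= mk[r] * a_new;
        }
        alpha[k] = a_new;
        delta[k] = d_new;
      }
    }

    // ---- residual polygenic effects via sparse A-inverse ----
    if (use_u) {
      double ku = 1.0 / (w * sigma_g2);
      for (int i = 0; i < n_anim; ++i) {
        int r = rec_of[i];
        if (r >= 0) e[r] += u[i];
        double aii = 0.0, off = 0.0;
        for (int t = Ap[i]; t < Ap[i + 1]; ++t) {
          int j = Ai[t];
          if (j == i) aii += Ax[t]; else off += Ax[t] * u[j];
        }
        double prec = (r >= 0 ? 1.0 / sigma_e2 : 0.0) + aii * ku;
        double mu = ((r >= 0 ? e[r] / sigma_e2 : 0.0) - ku * off) / prec;
        u[i] = mu + R::rnorm(0.0, std::sqrt(1.0 / prec));
        if (r >= 0) e[r] -= u[i];
      }
    }

    // ---- imputation residuals for non-genotyped animals ----
    if (use_eps) {
      double ke = 1.0 / ((1.0 - w) * sigma_g2);
      for (int jn = 0; jn < n_ng; ++jn) {
        int r = rec_of[ng_idx[jn] - 1];
        if (r >= 0) e[r] += eps[jn];
        double kjj = 0.0, off = 0.0;
        for (int t = Np[jn]; t < Np[jn + 1]; ++t) {
          int j2 = Ni[t];
          if (j2 == jn) kjj += Nx[t]; else off += Nx[t] * eps[j2];
        }
        double prec = (r >= 0 ? 1.0 / sigma_e2 : 0.0) + kjj * ke;
        double mu = ((r >= 0 ? e[r] / sigma_e2 : 0.0) - ke * off) / prec;
        eps[jn] = mu + R::rnorm(0.0, std::sqrt(1.0 / prec));
        if (r >= 0) e[r] -= eps[jn];
      }
    }

    // ---- variances ----
    if (update_sigma_a && p > 0) {
      sigma_a2 = rinvchisq(nu_a + m_in, ssa + nu_a * Sa2);
    }
    if (update_sigma_g && (use_u || use_eps)) {
      double q = 0.0; int nq = 0;
      if (use_u) {
        double quad = 0.0;
        for (int i = 0; i < n_anim; ++i) {
          for (int t = Ap[i]; t < Ap[i + 1]; ++t)
            quad += u[i] * Ax[t] * u[Ai[t]];
        }
        q += quad / w; nq += n_anim;
      }
      if (use_eps) {
        double quad = 0.0;
        for (int jn = 0; jn < n_ng; ++jn) {
          for (int t = Np[jn]; t < Np[jn + 1]; ++t)
            quad += eps[jn] * Nx[t] * eps[Ni[t]];
        }
        q += quad / (1.0 - w); nq += n_ng;
      }
      sigma_g2 = rinvchisq(nu_g + nq, q + nu_g * Sg2);
    }
    if (update_sigma_e) {
      double sse = 0.0;
      for (int r = 0; r < n_obs; ++r) sse += e[r] * e[r];
      sigma_e2 = rinvchisq(nu_e + n_obs, sse + nu_e * Se2);
    }
    if (!std::isfinite(sigma_e2) || sigma_e2 <= 0.0)
      stop("divergent residual variance at iteration %d", it);

    // ---- storage ----
    if (it > burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < nf; ++j) beta_d(kept, j) = beta[j];
      for (int k = 0; k < p; ++k) {
        alpha_d(kept, k) = alpha[k];
        incl[k] += delta[k];
      }
      for (int i = 0; i < n_anim; ++i) u_d(kept, i) = u[i];
      for (int jn = 0; jn < n_ng; ++jn) eps_d(kept, jn) = eps[jn];
      se_d[kept] = sigma_e2; sg_d[kept] = sigma_g2; sa_d[kept] = sigma_a2;
      ++kept;
    }
  }
  if (kept > 0) for (int k = 0; k < p; ++k) incl[k] /= kept;

  return List::create(
    _["beta"] = beta_d, _["alpha"] = alpha_d, _["u"] = u_d,
    _["eps"] = eps_d, _["sigma_e2"] = se_d, _["sigma_g2"] = sg_d,
    _["sigma_a2"] = sa_d, _["inclusion"] = incl, _["n_kept"] = kept);
}
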