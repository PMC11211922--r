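// Gibbs sampler for the multivariate animal model
//
//   y_u = X_u B + a_{ped(u)} + f_{fam(u)} + e_u
//
// with breeding values a ~ N(0, G (x) A), family effects f ~ N(0, F (x) I),
// and residuals grouped into residual-independent blocks (units of a group
// observe exactly that group's trait set; covariances across groups are
// structural zeros).  Covariance matrices carry Huang-Wand hierarchical
// inverse-Wishart priors (marginal half-t with nu df on each SD; nu = 1
// gives half-Cauchy), which keeps every full conditional conjugate.
// Breeding values are updated single-site over pedigree ids using the
// sparse A-inverse.  Bulk normal draws come from an internal fast
// generator seeded from R's RNG (Wishart/gamma draws use R's RNG
// directly), so whole chains are reproducible from set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double rnorm1() { return R::rnorm(0.0, 1.0); }

// Fast normal generator for the bulk effect updates: xoshiro256++ uniforms
// + polar Box-Muller.  Seeded from R's RNG on entry, so the whole chain
// remains a deterministic function of set.seed().
struct FastRng {
  uint64_t s[4];
  bool has_cache = false;
  double cache = 0.0;
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo ^ (0x9E3779B97F4A7C15ULL * (i + 1));
    }
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 0x9E3779B97F4A7C15ULL;
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_cache) { has_cache = false; return cache; }
    double u, v, w;
    do {
      u = 2.0 * unif() - 1.0; v = 2.0 * unif() - 1.0;
      w = u * u + v * v;
    } while (w >= 1.0 || w == 0.0);
    const double m = std::sqrt(-2.0 * std::log(w) / w);
    cache = v * m; has_cache = true;
    return u * m;
  }
};
static FastRng g_rng;

// draw from Wishart(df, S) via Bartlett; S must be SPD
static mat rwishart(double df, const mat& S) {
  const unsigned d = S.n_rows;
  mat L = chol(S, "lower");
  mat A(d, d, fill::zeros);
  for (unsigned i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (unsigned j = 0; j < i; ++j) A(i, j) = rnorm1();
  }
  mat LA = L * A;
  return LA * LA.t();
}

// draw from inverse-Wishart(df, S)
static mat rinvwishart(double df, const mat& S) {
  mat Sinv = inv_sympd(symmatu(S));
  return inv_sympd(symmatu(rwishart(df, Sinv)));
}

// draw from inverse-gamma(shape, rate)
static double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// --- tiny dense kernels (row-major, d <= MAXD) for the hot loops --------
#define MAXD 8

// lower Cholesky of symmetric P (row-major d x d)
static inline void chol_small(int d, const double* P, double* L) {
  for (int i = 0; i < d; ++i) {
    for (int j = 0; j <= i; ++j) {
      double s = P[i * d + j];
      for (int k = 0; k < j; ++k) s -= L[i * d + k] * L[j * d + k];
      if (i == j)
        L[i * d + i] = std::sqrt(s > 1e-300 ? s : 1e-300);
      else
        L[i * d + j] = s / L[j * d + j];
    }
    for (int j = i + 1; j < d; ++j) L[i * d + j] = 0.0;
  }
}

// draw x ~ N(P^-1 h, P^-1) given precision P (row-major); overwrites x
static inline void rmvn_canonical_small(int d, const double* P, const double* h,
                                        double* x) {
  double L[MAXD * MAXD], w[MAXD];
  chol_small(d, P, L);
  // w = L^-1 h ; mu = L^-T w ; x = mu + L^-T z  =>  x = L^-T (w + z)
  for (int i = 0; i < d; ++i) {
    double s = h[i];
    for (int k = 0; k < i; ++k) s -= L[i * d + k] * w[k];
    w[i] = s / L[i * d + i];
  }
  for (int i = 0; i < d; ++i) w[i] += g_rng.norm();
  for (int i = d - 1; i >= 0; --i) {
    double s = w[i];
    for (int k = i + 1; k < d; ++k) s -= L[k * d + i] * x[k];
    x[i] = s / L[i * d + i];
  }
}

// [[Rcpp::export]]
Rcpp::List cpp_gibbs_animal(
    const arma::mat& y,                 // n_units x d, non-observed = 0
    const Rcpp::IntegerVector& unit_group,   // 0-based residual group per unit
    const Rcpp::List& group_traits,     // per group: 0-based trait indices
    const Rcpp::List& group_xcols,      // per group: 0-based columns of X
    const arma::mat& X,                 // n_units x q fixed design
    const Rcpp::IntegerVector& unit_ped,
    const Rcpp::IntegerVector& unit_fam,
    const arma::vec& ainv_diag,         // n_ped
    const Rcpp::IntegerVector& nb_ptr,  // CSR of off-diagonal A-inverse
    const Rcpp::IntegerVector& nb_idx,
    const arma::vec& nb_val,
    const int n_fam,
    const double nu,
    const arma::vec& scale_G,
    const arma::vec& scale_F,
    const Rcpp::List& scale_R,          // per group: prior scale per trait
    const bool fam_diag,
    const int n_iter, const int burnin, const int thin,
    const arma::mat& G0, const arma::mat& F0, const Rcpp::List& R0) {

  g_rng.seed_from_R();
  g_rng.has_cache = false;
  const unsigned d = y.n_cols, n_units = y.n_rows;
  const unsigned n_ped = ainv_diag.n_elem;
  const unsigned n_grp = group_traits.size();
  const unsigned q = X.n_cols;

  // unpack group structures
  std::vector<uvec> gtr(n_grp), gxc(n_grp), gunits(n_grp);
  std::vector<vec> rscale(n_grp);
  for (unsigned g = 0; g < n_grp; ++g) {
    gtr[g] = Rcpp::as<uvec>(group_traits[g]);
    gxc[g] = Rcpp::as<uvec>(group_xcols[g]);
    rscale[g] = Rcpp::as<vec>(scale_R[g]);
    std::vector<unsigned> us;
    for (unsigned u = 0; u < n_units; ++u)
      if ((unsigned)unit_group[u] == g) us.push_back(u);
    gunits[g] = uvec(us);
  }
  // per-group precomputed OLS pieces
  std::vector<mat> XtXinv(n_grp), Lxx(n_grp), Xg(n_grp);
  for (unsigned g = 0; g < n_grp; ++g) {
    Xg[g] = X.submat(gunits[g], gxc[g]);
    XtXinv[g] = inv_sympd(symmatu(Xg[g].t() * Xg[g]));
    Lxx[g] = chol(XtXinv[g], "lower");
  }
  // units per pedigree id / family
  std::vector<std::vector<unsigned>> ped_units(n_ped), fam_units(n_fam);
  for (unsigned u = 0; u < n_units; ++u) {
    ped_units[unit_ped[u]].push_back(u);
    fam_units[unit_fam[u]].push_back(u);
  }

  // state
  mat G = G0, Fm = F0;
  std::vector<mat> Rg(n_grp), Rg_inv(n_grp);
  for (unsigned g = 0; g < n_grp; ++g) {
    Rg[g] = Rcpp::as<mat>(R0[g]);
    Rg_inv[g] = inv_sympd(symmatu(Rg[g]));
  }
  mat a(n_ped, d, fill::zeros), f(n_fam, d, fill::zeros);
  mat B(q, d, fill::zeros), mu(n_units, d, fill::zeros);
  vec ag(d), af(d);
  std::vector<vec> ar(n_grp);
  for (unsigned j = 0; j < d; ++j) {
    ag(j) = 1.0; af(j) = 1.0;
  }
  for (unsigned g = 0; g < n_grp; ++g) ar[g] = vec(gtr[g].n_elem, fill::ones);

  mat Ginv = inv_sympd(symmatu(G)), Finv = inv_sympd(symmatu(Fm));

  const int n_keep = (n_iter - burnin) / thin;
  cube Gs(d, d, n_keep), Fs(d, d, n_keep), Rs(d, d, n_keep);
  mat Bs(n_keep, q * d);
  vec lls(n_keep);
  int kept = 0;

  // flat scratch for the hot loops
  std::vector<std::vector<double>> Rinv_flat(n_grp);  // row-major dg x dg
  for (unsigned g = 0; g < n_grp; ++g)
    Rinv_flat[g].resize(gtr[g].n_elem * gtr[g].n_elem);
  const int nb_ptr0 = 0; (void)nb_ptr0;

  for (int it = 1; it <= n_iter; ++it) {
    if (it % 4096 == 0) Rcpp::checkUserInterrupt();

    // refresh flat copies of the residual precisions
    for (unsigned g = 0; g < n_grp; ++g) {
      const unsigned dg = gtr[g].n_elem;
      for (unsigned t = 0; t < dg; ++t)
        for (unsigned t2 = 0; t2 < dg; ++t2)
          Rinv_flat[g][t * dg + t2] = Rg_inv[g](t, t2);
    }
    double* amem = a.memptr();
    double* fmem = f.memptr();
    const double* ymem = y.memptr();
    double* mumem = mu.memptr();
    const double* Gi = Ginv.memptr();   // symmetric: col-major == row-major
    const double* Fi = Finv.memptr();
    double s_[MAXD], h_[MAXD], P_[MAXD * MAXD], x_[MAXD], r_[MAXD], hr_[MAXD];

    // --- breeding values, single site over pedigree ids ----------------
    for (unsigned i = 0; i < n_ped; ++i) {
      for (unsigned t = 0; t < d; ++t) s_[t] = 0.0;
      for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
        const double v = nb_val(k);
        const unsigned j = nb_idx[k];
        for (unsigned t = 0; t < d; ++t) s_[t] += v * amem[t * n_ped + j];
      }
      const double aii = ainv_diag(i);
      for (unsigned t = 0; t < d; ++t) {
        double acc = 0.0;
        for (unsigned c = 0; c < d; ++c) acc += Gi[c * d + t] * s_[c];
        h_[t] = -acc;
        for (unsigned c = 0; c < d; ++c) P_[t * d + c] = aii * Gi[c * d + t];
      }
      for (unsigned uix = 0; uix < ped_units[i].size(); ++uix) {
        const unsigned u = ped_units[i][uix];
        const unsigned g = unit_group[u];
        const uvec& T = gtr[g];
        const unsigned dg = T.n_elem;
        const unsigned fam = unit_fam[u];
        for (unsigned t = 0; t < dg; ++t) {
          const unsigned tc = T(t);
          r_[t] = ymem[tc * n_units + u] - mumem[tc * n_units + u] -
                  fmem[tc * n_fam + fam];
        }
        const double* Rf = Rinv_flat[g].data();
        for (unsigned t = 0; t < dg; ++t) {
          double acc = 0.0;
          for (unsigned t2 = 0; t2 < dg; ++t2) acc += Rf[t * dg + t2] * r_[t2];
          hr_[t] = acc;
        }
        for (unsigned t = 0; t < dg; ++t) {
          h_[T(t)] += hr_[t];
          for (unsigned t2 = 0; t2 < dg; ++t2)
            P_[T(t) * d + T(t2)] += Rf[t * dg + t2];
        }
      }
      rmvn_canonical_small(d, P_, h_, x_);
      for (unsigned t = 0; t < d; ++t) amem[t * n_ped + i] = x_[t];
    }

    // --- family effects -------------------------------------------------
    for (int k = 0; k < n_fam; ++k) {
      for (unsigned t = 0; t < d; ++t) {
        h_[t] = 0.0;
        for (unsigned c = 0; c < d; ++c) P_[t * d + c] = Fi[c * d + t];
      }
      for (unsigned uix = 0; uix < fam_units[k].size(); ++uix) {
        const unsigned u = fam_units[k][uix];
        const unsigned g = unit_group[u];
        const uvec& T = gtr[g];
        const unsigned dg = T.n_elem;
        const unsigned pid = unit_ped[u];
        for (unsigned t = 0; t < dg; ++t) {
          const unsigned tc = T(t);
          r_[t] = ymem[tc * n_units + u] - mumem[tc * n_units + u] -
                  amem[tc * n_ped + pid];
        }
        const double* Rf = Rinv_flat[g].data();
        for (unsigned t = 0; t < dg; ++t) {
          double acc = 0.0;
          for (unsigned t2 = 0; t2 < dg; ++t2) acc += Rf[t * dg + t2] * r_[t2];
          hr_[t] = acc;
        }
        for (unsigned t = 0; t < dg; ++t) {
          h_[T(t)] += hr_[t];
          for (unsigned t2 = 0; t2 < dg; ++t2)
            P_[T(t) * d + T(t2)] += Rf[t * dg + t2];
        }
      }
      rmvn_canonical_small(d, P_, h_, x_);
      for (unsigned t = 0; t < d; ++t) fmem[t * n_fam + k] = x_[t];
    }

    // --- fixed effects, residual covariances, per residual group --------
    for (unsigned g = 0; g < n_grp; ++g) {
      const uvec& T = gtr[g];
      const uvec& C = gxc[g];
      const uvec& U = gunits[g];
      const unsigned dg = T.n_elem, ng = U.n_elem;
      // Ytil = y - a - f on this group's units/traits
      mat Ytil(ng, dg);
      for (unsigned ui = 0; ui < ng; ++ui) {
        unsigned u = U(ui);
        for (unsigned t = 0; t < dg; ++t)
          Ytil(ui, t) = y(u, T(t)) - a(unit_ped[u], T(t)) - f(unit_fam[u], T(t));
      }
      // B | rest : flat prior, homoscedastic within group => matrix normal
      mat Bhat = XtXinv[g] * (Xg[g].t() * Ytil);
      mat Z(C.n_elem, dg);
      for (unsigned i = 0; i < Z.n_elem; ++i) Z(i) = g_rng.norm();
      mat Bg = Bhat + Lxx[g] * Z * chol(symmatu(Rg[g]));
      for (unsigned c = 0; c < C.n_elem; ++c)
        for (unsigned t = 0; t < dg; ++t)
          B(C(c), T(t)) = Bg(c, t);
      // refresh mu on this group's units/traits
      mat Mg = Xg[g] * Bg;
      for (unsigned ui = 0; ui < ng; ++ui)
        for (unsigned t = 0; t < dg; ++t)
          mu(U(ui), T(t)) = Mg(ui, t);
      // residual covariance (Huang-Wand)
      mat E = Ytil - Mg;
      mat Se = E.t() * E;
      mat S = Se;
      for (unsigned t = 0; t < dg; ++t) S(t, t) += 2.0 * nu / ar[g](t);
      Rg[g] = rinvwishart(nu + dg - 1 + ng, S);
      Rg_inv[g] = inv_sympd(symmatu(Rg[g]));
      for (unsigned t = 0; t < dg; ++t)
        ar[g](t) = rinvgamma(0.5 * (nu + dg),
                             nu * Rg_inv[g](t, t) +
                               1.0 / (rscale[g](t) * rscale[g](t)));
    }

    // --- G | a (quadratic form through sparse A-inverse) ----------------
    double Sa_[MAXD * MAXD];
    for (unsigned t = 0; t < d * d; ++t) Sa_[t] = 0.0;
    for (unsigned i = 0; i < n_ped; ++i) {
      const double aii = ainv_diag(i);
      for (unsigned t = 0; t < d; ++t) x_[t] = amem[t * n_ped + i];
      for (unsigned t = 0; t < d; ++t)
        for (unsigned t2 = 0; t2 < d; ++t2)
          Sa_[t * d + t2] += aii * x_[t] * x_[t2];
      for (int k = nb_ptr[i]; k < nb_ptr[i + 1]; ++k) {
        const double v = nb_val(k);
        const unsigned j = nb_idx[k];
        for (unsigned t = 0; t < d; ++t)
          for (unsigned t2 = 0; t2 < d; ++t2)
            Sa_[t * d + t2] += v * x_[t] * amem[t2 * n_ped + j];
      }
    }
    mat Sa(d, d);
    for (unsigned t = 0; t < d; ++t)
      for (unsigned t2 = 0; t2 < d; ++t2)
        Sa(t, t2) = Sa_[t * d + t2];
    Sa = symmatu(0.5 * (Sa + Sa.t()));
    mat SG = Sa;
    for (unsigned j = 0; j < d; ++j) SG(j, j) += 2.0 * nu / ag(j);
    G = rinvwishart(nu + d - 1 + n_ped, SG);
    Ginv = inv_sympd(symmatu(G));
    for (unsigned j = 0; j < d; ++j)
      ag(j) = rinvgamma(0.5 * (nu + d),
                        nu * Ginv(j, j) + 1.0 / (scale_G(j) * scale_G(j)));

    // --- F | f -----------------------------------------------------------
    mat Sf = f.t() * f;
    if (fam_diag) {
      vec fd(d);
      for (unsigned j = 0; j < d; ++j)
        fd(j) = rinvgamma(0.5 * (nu + n_fam),
                          0.5 * (Sf(j, j) + 2.0 * nu / af(j)));
      Fm.zeros();
      Fm.diag() = fd;
    } else {
      mat SF = Sf;
      for (unsigned j = 0; j < d; ++j) SF(j, j) += 2.0 * nu / af(j);
      Fm = rinvwishart(nu + d - 1 + n_fam, SF);
    }
    Finv = inv_sympd(symmatu(Fm));
    for (unsigned j = 0; j < d; ++j)
      af(j) = rinvgamma(0.5 * (nu + (fam_diag ? 1 : d)),
                        nu * Finv(j, j) + 1.0 / (scale_F(j) * scale_F(j)));

    // --- store -----------------------------------------------------------
    if (it > burnin && (it - burnin) % thin == 0) {
      double ll = 0.0;
      for (unsigned g = 0; g < n_grp; ++g) {
        const uvec& T = gtr[g];
        const uvec& U = gunits[g];
        const unsigned dg = T.n_elem;
        double ldet, sign;
        log_det(ldet, sign, Rg[g]);
        for (unsigned ui = 0; ui < U.n_elem; ++ui) {
          unsigned u = U(ui);
          vec e(dg);
          for (unsigned t = 0; t < dg; ++t)
            e(t) = y(u, T(t)) - mu(u, T(t)) - a(unit_ped[u], T(t)) -
                   f(unit_fam[u], T(t));
          ll += -0.5 * (dg * std::log(2.0 * M_PI) + ldet +
                        dot(e, Rg_inv[g] * e));
        }
      }
      mat Rfull(d, d, fill::zeros);
      for (unsigned g = 0; g < n_grp; ++g)
        for (unsigned t = 0; t < gtr[g].n_elem; ++t)
          for (unsigned t2 = 0; t2 < gtr[g].n_elem; ++t2)
            Rfull(gtr[g](t), gtr[g](t2)) = Rg[g](t, t2);
      Gs.slice(kept) = G;
      Fs.slice(kept) = Fm;
      Rs.slice(kept) = Rfull;
      Bs.row(kept) = vectorise(B).t();
      lls(kept) = ll;
      ++kept;
    }
  }

  return Rcpp::List::create(
      Rcpp::Named("G") = Gs, Rcpp::Named("Fna") = Fs, Rcpp::Named("R") = Rs,
      Rcpp::Named("B") = Bs, Rcpp::Named("loglik") = lls);
}
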