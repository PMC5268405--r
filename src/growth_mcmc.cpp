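// Metropolis-within-Gibbs sampler for the joint model of juvenile growth
// and overwinter viability selection.
//
// Each juvenile i carries a monomolecular growth curve
//   m(t) = a_i (1 - exp(-k_i (t - t0))),
// where t0 is the conception-scale birth date of its litter. Litters are
// latent: every mother-year group maintains 5 candidate litter dates
// (ordered, >= 20 days apart, inside the season window), juveniles are
// assigned to litters by a discrete Gibbs step, and litter dates move by
// Metropolis steps respecting the order/spacing constraints (empty litters
// drift freely, which makes the number of occupied litters itself
// inferred, up to the maximum of 5). Observed masses have fixed
// measurement-error SD. Overwinter survival is Bernoulli with logit
// intercept + sex + a_i [+ days-to-first-snowfall + a_i x days], where
// days = first snowfall - t0. (a_i, log k_i) are exchangeable draws from a
// bivariate normal whose mean and covariance get conjugate updates.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NLIT = 5;
static const double SPACING = 20.0;

struct GrowthData {
  // records
  std::vector<double> rec_day, rec_mass;
  std::vector<int> rec_j;
  // juveniles
  std::vector<int> jgroup, jsex, jsurv;
  std::vector<double> jmin_day, jmean_day;
  std::vector<std::vector<int>> recs_of;  // record idx per juvenile
  std::vector<std::vector<int>> juvs_of;  // juvenile idx per group
  std::vector<double> glo, ghi, gsnow, gmax_age;  // per-group windows
  double ca, cd;                          // covariate centering constants
};

static double mass_loglik_i(const GrowthData& D, int i, double a, double k,
                            double t0, double sd) {
  double ll = 0.0;
  for (int r : D.recs_of[i]) {
    double dt = D.rec_day[r] - t0;
    double mu = a * (1.0 - std::exp(-k * dt));
    double e = (D.rec_mass[r] - mu) / sd;
    ll += -0.5 * e * e;
  }
  return ll;
}

// steep soft penalty for litter dates earlier than the detection window
// allows (capture probability per session is ~1 and sessions are at most a
// few weeks apart, so a juvenile cannot have been trappable long before
// its first capture); soft rather than hard so infeasible transients can
// escape
static double age_penalty(double t0, double min_day, double max_age) {
  double v = (min_day - max_age) - t0;
  if (v <= 0) return 0.0;
  return -0.5 * (v / 2.0) * (v / 2.0);
}

// survival linear predictor uses centred covariates (a - ca), (days - cd);
// the R wrapper transforms the coefficients back to the raw scale
static double surv_loglik_i(const GrowthData& D, int i, double a, double t0,
                            const double* g, bool use_snow) {
  double ac = a - D.ca;
  double eta = g[0] + g[1] * D.jsex[i] + g[2] * ac;
  if (use_snow) {
    double dc = (D.gsnow[D.jgroup[i]] - t0) - D.cd;
    eta += g[3] * dc + g[4] * ac * dc;
  }
  // log Bernoulli(logit^-1(eta))
  if (D.jsurv[i] == 1) return -std::log1p(std::exp(-eta));
  return -std::log1p(std::exp(eta));
}

// [[Rcpp::export]]
List growth_gibbs_cpp(NumericVector rec_day, NumericVector rec_mass,
                      IntegerVector rec_j,
                      IntegerVector jgroup, IntegerVector jsex,
                      IntegerVector jsurv,
                      NumericVector grp_lo, NumericVector grp_hi,
                      NumericVector grp_snow,
                      double meas_sd,
                      bool use_snow,
                      NumericVector grp_max_age,  // per-group detection window
                      double center_a, double center_d,
                      NumericVector hyper,   // mu_a0, va0, mu_lk0, vlk0
                      NumericVector sig0,    // V11, V22, nu0 for Sigma IW
                      double gamma_sd,       // prior sd of survival coefs
                      int n_iter, int burnin, int thin,
                      Nullable<List> init = R_NilValue) {
  const int nrec = rec_day.size();
  const int nj = jgroup.size();
  const int ng = grp_lo.size();

  GrowthData D;
  D.rec_day.assign(rec_day.begin(), rec_day.end());
  D.rec_mass.assign(rec_mass.begin(), rec_mass.end());
  D.rec_j.resize(nrec);
  D.recs_of.resize(nj);
  for (int r = 0; r < nrec; ++r) {
    D.rec_j[r] = rec_j[r] - 1;
    D.recs_of[D.rec_j[r]].push_back(r);
  }
  D.jgroup.resize(nj); D.jsex.resize(nj); D.jsurv.resize(nj);
  D.jmin_day.assign(nj, 1e300);
  D.juvs_of.resize(ng);
  for (int i = 0; i < nj; ++i) {
    D.jgroup[i] = jgroup[i] - 1;
    D.jsex[i] = jsex[i];
    D.jsurv[i] = jsurv[i];
    D.juvs_of[D.jgroup[i]].push_back(i);
    for (int r : D.recs_of[i]) D.jmin_day[i] = std::min(D.jmin_day[i], D.rec_day[r]);
  }
  D.glo.assign(grp_lo.begin(), grp_lo.end());
  D.ghi.assign(grp_hi.begin(), grp_hi.end());
  D.gsnow.assign(grp_snow.begin(), grp_snow.end());
  D.gmax_age.assign(grp_max_age.begin(), grp_max_age.end());
  D.ca = center_a;
  D.cd = center_d;
  D.jmean_day.assign(nj, 0.0);
  for (int i = 0; i < nj; ++i) {
    for (int r : D.recs_of[i]) D.jmean_day[i] += D.rec_day[r];
    if (!D.recs_of[i].empty()) D.jmean_day[i] /= D.recs_of[i].size();
  }

  // --- state ---
  std::vector<double> a(nj), lk(nj);
  std::vector<int> z(nj, 0);                    // litter assignment
  std::vector<std::array<double, NLIT>> tau(ng);
  double gam[5] = {0, 0, 0, 0, 0};
  double mu_a = 0, mu_lk = 0;
  arma::mat Sigma(2, 2, arma::fill::zeros);
  Sigma(0, 0) = sig0[0]; Sigma(1, 1) = sig0[1];
  const double nu0 = sig0[2];

  // initialisation: per group, profile a shared growth rate and a shared
  // capture offset (days from conception to first capture) over a coarse
  // grid; asymptotes follow in closed form by least squares. The (t0, k, a)
  // surface is ridge-shaped for sparsely captured juveniles, so starting in
  // the data-preferred basin matters.
  double psum = 0;
  for (int i = 0; i < nj; ++i) psum += D.jsurv[i];
  double pbar = std::min(std::max(psum / nj, 0.05), 0.95);
  gam[0] = std::log(pbar / (1 - pbar));
  const double kgrid[] = {0.012, 0.016, 0.020, 0.026, 0.034};
  const double dgrid[] = {25, 30, 35, 40, 45, 50};
  for (int g = 0; g < ng; ++g) {
    double mn = 1e300;
    for (int i : D.juvs_of[g]) mn = std::min(mn, D.jmin_day[i]);
    double best_sse = 1e300, best_k = 0.02, best_off = 35;
    for (double kk : kgrid) {
      for (double off : dgrid) {
        double t1 = std::max(D.glo[g], mn - off);
        if (t1 >= mn - 5) t1 = mn - 5;
        double sse = 0;
        for (int i : D.juvs_of[g]) {
          // member assigned to the latest candidate litter before its
          // first capture (offset-consistent)
          double t0i = t1;
          for (int l = 1; l < NLIT; ++l) {
            double tl = t1 + SPACING * l;
            if (tl <= D.jmin_day[i] - off / 2) t0i = tl; else break;
          }
          double num = 0, den = 0;
          for (int r : D.recs_of[i]) {
            double f = 1.0 - std::exp(-kk * (D.rec_day[r] - t0i));
            num += D.rec_mass[r] * f;
            den += f * f;
          }
          double ai = den > 0 ? num / den : hyper[0];
          ai = std::min(std::max(ai, 15.0), hyper[0] + 10.0);
          for (int r : D.recs_of[i]) {
            double e = D.rec_mass[r] -
                       ai * (1.0 - std::exp(-kk * (D.rec_day[r] - t0i)));
            sse += e * e;
          }
          // pull toward the asymptote anchor (weak, init only)
          sse += 0.1 * (ai - hyper[0]) * (ai - hyper[0]);
        }
        if (sse < best_sse) { best_sse = sse; best_k = kk; best_off = off; }
      }
    }
    double t1 = std::max(D.glo[g], mn - best_off);
    if (t1 >= mn - 5) t1 = mn - 5;
    for (int l = 0; l < NLIT; ++l) tau[g][l] = t1 + SPACING * l;
    double over = tau[g][NLIT - 1] - D.ghi[g];
    if (over > 0) for (int l = 0; l < NLIT; ++l) tau[g][l] -= over;
    for (int i : D.juvs_of[g]) {
      int zi = 0;
      for (int l = 1; l < NLIT; ++l) {
        if (tau[g][l] <= D.jmin_day[i] - best_off / 2) zi = l; else break;
      }
      if (tau[g][zi] >= D.jmin_day[i] - 1) {
        zi = 0;
        for (int l = 1; l < NLIT; ++l)
          if (tau[g][l] < D.jmin_day[i] - 1) zi = l;
      }
      z[i] = zi;
      double num = 0, den = 0;
      for (int r : D.recs_of[i]) {
        double f = 1.0 - std::exp(-best_k * (D.rec_day[r] - tau[g][zi]));
        num += D.rec_mass[r] * f;
        den += f * f;
      }
      double ai = den > 0 ? num / den : hyper[0];
      a[i] = std::min(std::max(ai, 15.0), hyper[0] + 15.0);
      lk[i] = std::log(best_k);
    }
  }
  if (init.isNotNull()) {
    List in_(init);
    NumericVector ia = in_["a"], ilk = in_["logk"], it0 = in_["t0"];
    IntegerVector iz = in_["litter"];
    NumericMatrix itau = in_["tau"];
    for (int i = 0; i < nj; ++i) {
      a[i] = ia[i]; lk[i] = ilk[i]; z[i] = iz[i] - 1;
    }
    for (int g = 0; g < ng; ++g)
      for (int l = 0; l < NLIT; ++l) tau[g][l] = itau(g, l);
    (void)it0;
  }
  mu_a = 0; mu_lk = 0;
  for (int i = 0; i < nj; ++i) {
    mu_a += a[i] / nj;
    mu_lk += lk[i] / nj;
  }

  // adaptive RW scales
  std::vector<double> sc_a(nj, 1.0), sc_lk(nj, 0.1), sc_j(nj, 0.5),
      sc_r(nj, 0.3);
  std::vector<double> sc_tau(ng, 3.0), sc_shift(ng, 8.0);
  double sc_gam[5] = {0.5, 0.3, 0.02, 0.02, 5e-4};
  const double tgt = 0.44, adapt_rate = 0.05;

  const int n_keep = (n_iter - burnin) / thin;
  arma::mat s_a(nj, n_keep), s_k(nj, n_keep), s_t0(nj, n_keep);
  arma::imat s_z(nj, n_keep);
  arma::mat s_gam(5, n_keep), s_mu(2, n_keep), s_sig(3, n_keep);
  arma::cube s_tau(ng, NLIT, n_keep);
  int keep = 0;

  auto bvn_logprior = [&](double ai, double lki) {
    double d0 = ai - mu_a, d1 = lki - mu_lk;
    double det = Sigma(0, 0) * Sigma(1, 1) - Sigma(0, 1) * Sigma(0, 1);
    double q = (d0 * d0 * Sigma(1, 1) - 2 * d0 * d1 * Sigma(0, 1) +
                d1 * d1 * Sigma(0, 0)) / det;
    return -0.5 * q;
  };

  for (int it = 0; it < n_iter; ++it) {
    if ((it & 255) == 0) Rcpp::checkUserInterrupt();
    const bool adapting = it < burnin;

    // --- (a_i, log k_i) random-walk updates ---
    for (int i = 0; i < nj; ++i) {
      int g = D.jgroup[i];
      double t0 = tau[g][z[i]];
      // a_i
      {
        double prop = a[i] + R::norm_rand() * sc_a[i];
        double lr = -1e300;
        if (prop > 0.1) {
          lr = mass_loglik_i(D, i, prop, std::exp(lk[i]), t0, meas_sd) +
               surv_loglik_i(D, i, prop, t0, gam, use_snow) +
               bvn_logprior(prop, lk[i]) -
               mass_loglik_i(D, i, a[i], std::exp(lk[i]), t0, meas_sd) -
               surv_loglik_i(D, i, a[i], t0, gam, use_snow) -
               bvn_logprior(a[i], lk[i]);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) a[i] = prop;
        if (adapting) sc_a[i] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - tgt));
      }
      // log k_i (survival does not involve k)
      {
        double prop = lk[i] + R::norm_rand() * sc_lk[i];
        double lr = mass_loglik_i(D, i, a[i], std::exp(prop), t0, meas_sd) +
                    bvn_logprior(a[i], prop) -
                    mass_loglik_i(D, i, a[i], std::exp(lk[i]), t0, meas_sd) -
                    bvn_logprior(a[i], lk[i]);
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) lk[i] = prop;
        if (adapting) sc_lk[i] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - tgt));
      }
      // joint (a, log k) move shaped by the population covariance: the
      // per-individual likelihood is ridge-shaped, so coordinate moves mix
      // slowly along it
      {
        double s11 = Sigma(0, 0), s12 = Sigma(0, 1), s22 = Sigma(1, 1);
        double l11 = std::sqrt(s11);
        double l21 = s12 / l11;
        double l22 = std::sqrt(std::max(s22 - l21 * l21, 1e-12));
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        double pa = a[i] + sc_j[i] * l11 * z1;
        double plk = lk[i] + sc_j[i] * (l21 * z1 + l22 * z2);
        double lr = -1e300;
        if (pa > 0.1) {
          lr = mass_loglik_i(D, i, pa, std::exp(plk), t0, meas_sd) +
               surv_loglik_i(D, i, pa, t0, gam, use_snow) +
               bvn_logprior(pa, plk) -
               mass_loglik_i(D, i, a[i], std::exp(lk[i]), t0, meas_sd) -
               surv_loglik_i(D, i, a[i], t0, gam, use_snow) -
               bvn_logprior(a[i], lk[i]);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) { a[i] = pa; lk[i] = plk; }
        if (adapting) sc_j[i] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - 0.3));
      }
      // ridge move: random walk in log k holding the fitted mass at the
      // individual's mean capture day fixed (reparameterised MH; the
      // Jacobian of a = mbar / (1 - exp(-k dbar)) enters the ratio). The
      // per-individual (a, k) likelihood is a near-flat ridge, and this
      // move walks along it so the posterior honestly spans it.
      {
        double dbar = D.jmean_day[i] - t0;
        if (dbar > 0) {
          double gk = 1.0 - std::exp(-std::exp(lk[i]) * dbar);
          double mbar = a[i] * gk;
          double plk = lk[i] + R::norm_rand() * sc_r[i];
          double gkp = 1.0 - std::exp(-std::exp(plk) * dbar);
          double pa = mbar / gkp;
          double lr = -1e300;
          if (pa > 0.1 && gkp > 1e-10) {
            lr = mass_loglik_i(D, i, pa, std::exp(plk), t0, meas_sd) +
                 surv_loglik_i(D, i, pa, t0, gam, use_snow) +
                 bvn_logprior(pa, plk) + std::log(gk) -
                 mass_loglik_i(D, i, a[i], std::exp(lk[i]), t0, meas_sd) -
                 surv_loglik_i(D, i, a[i], t0, gam, use_snow) -
                 bvn_logprior(a[i], lk[i]) - std::log(gkp);
          }
          bool acc = std::log(R::unif_rand()) < lr;
          if (acc) { a[i] = pa; lk[i] = plk; }
          if (adapting)
            sc_r[i] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - tgt));
        }
      }
    }

    // --- litter assignments: discrete Gibbs ---
    for (int i = 0; i < nj; ++i) {
      int g = D.jgroup[i];
      double w[NLIT];
      double wmax = -1e300;
      for (int l = 0; l < NLIT; ++l) {
        double t0 = tau[g][l];
        if (t0 >= D.jmin_day[i]) { w[l] = -1e300; continue; }
        w[l] = mass_loglik_i(D, i, a[i], std::exp(lk[i]), t0, meas_sd) +
               surv_loglik_i(D, i, a[i], t0, gam, use_snow) +
               age_penalty(t0, D.jmin_day[i], D.gmax_age[g]);
        wmax = std::max(wmax, w[l]);
      }
      if (wmax <= -1e299) continue;  // no feasible litter: keep current
      double cum[NLIT], tot = 0;
      for (int l = 0; l < NLIT; ++l) {
        tot += std::exp(std::max(w[l] - wmax, -700.0));
        cum[l] = tot;
      }
      double u = R::unif_rand() * tot;
      int pick = NLIT - 1;
      for (int l = 0; l < NLIT; ++l) if (u <= cum[l]) { pick = l; break; }
      z[i] = pick;
    }

    // --- litter dates: Metropolis within order/spacing constraints ---
    for (int g = 0; g < ng; ++g) {
      for (int l = 0; l < NLIT; ++l) {
        double lo = (l == 0) ? D.glo[g] : tau[g][l - 1] + SPACING;
        double hi = (l == NLIT - 1) ? D.ghi[g] : tau[g][l + 1] - SPACING;
        if (hi <= lo) continue;
        double prop = tau[g][l] + R::norm_rand() * sc_tau[g];
        bool acc = false;
        if (prop >= lo && prop <= hi) {
          double lr = 0.0;
          bool feasible = true;
          for (int i : D.juvs_of[g]) {
            if (z[i] != l) continue;
            if (prop >= D.jmin_day[i]) { feasible = false; break; }
            lr += mass_loglik_i(D, i, a[i], std::exp(lk[i]), prop, meas_sd) +
                  surv_loglik_i(D, i, a[i], prop, gam, use_snow) +
                  age_penalty(prop, D.jmin_day[i], D.gmax_age[g]) -
                  mass_loglik_i(D, i, a[i], std::exp(lk[i]), tau[g][l], meas_sd) -
                  surv_loglik_i(D, i, a[i], tau[g][l], gam, use_snow) -
                  age_penalty(tau[g][l], D.jmin_day[i], D.gmax_age[g]);
          }
          if (feasible && std::log(R::unif_rand()) < lr) {
            tau[g][l] = prop;
            acc = true;
          }
        }
        if (adapting)
          sc_tau[g] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - tgt) / NLIT);
      }
      // compensated shift: move a litter date while adjusting each assigned
      // juvenile's growth rate so its fitted mass at its mean capture day is
      // preserved (an additive shift in log k, hence Jacobian 1). This
      // traverses the (t0, k) ridge that defeats local moves.
      for (int l = 0; l < NLIT; ++l) {
        double lo = (l == 0) ? D.glo[g] : tau[g][l - 1] + SPACING;
        double hi = (l == NLIT - 1) ? D.ghi[g] : tau[g][l + 1] - SPACING;
        if (hi <= lo) continue;
        double old = tau[g][l];
        double prop = old + R::norm_rand() * sc_shift[g];
        bool acc = false;
        if (prop >= lo && prop <= hi) {
          bool feasible = true;
          double lr = 0.0;
          std::vector<std::pair<int, double>> newlk;
          for (int i : D.juvs_of[g]) {
            if (z[i] != l) continue;
            if (prop >= D.jmin_day[i] - 1.0) { feasible = false; break; }
            double num = D.jmean_day[i] - old;
            double den = D.jmean_day[i] - prop;
            if (num <= 0 || den <= 0) { feasible = false; break; }
            double lki = lk[i] + std::log(num / den);
            newlk.push_back({i, lki});
            lr += mass_loglik_i(D, i, a[i], std::exp(lki), prop, meas_sd) +
                  surv_loglik_i(D, i, a[i], prop, gam, use_snow) +
                  bvn_logprior(a[i], lki) +
                  age_penalty(prop, D.jmin_day[i], D.gmax_age[g]) -
                  mass_loglik_i(D, i, a[i], std::exp(lk[i]), old, meas_sd) -
                  surv_loglik_i(D, i, a[i], old, gam, use_snow) -
                  bvn_logprior(a[i], lk[i]) -
                  age_penalty(old, D.jmin_day[i], D.gmax_age[g]);
          }
          if (feasible && std::log(R::unif_rand()) < lr) {
            tau[g][l] = prop;
            for (auto& pr_ : newlk) lk[pr_.first] = pr_.second;
            acc = true;
          }
        }
        if (adapting)
          sc_shift[g] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - 0.3) / NLIT);
      }
      // global compensated move: an independence proposal uniform over the
      // feasible date range (same compensation), able to jump between
      // basins of the (t0, k) ridge that local steps cannot cross
      for (int l = 0; l < NLIT; ++l) {
        double lo = (l == 0) ? D.glo[g] : tau[g][l - 1] + SPACING;
        double hi = (l == NLIT - 1) ? D.ghi[g] : tau[g][l + 1] - SPACING;
        double old = tau[g][l];
        double hieff = hi;
        for (int i : D.juvs_of[g])
          if (z[i] == l) hieff = std::min(hieff, D.jmin_day[i] - 1.0);
        if (hieff <= lo) continue;
        double prop = lo + R::unif_rand() * (hieff - lo);
        bool feasible = true;
        double lr = 0.0;
        std::vector<std::pair<int, double>> newlk;
        for (int i : D.juvs_of[g]) {
          if (z[i] != l) continue;
          double num = D.jmean_day[i] - old;
          double den = D.jmean_day[i] - prop;
          if (num <= 0 || den <= 0) { feasible = false; break; }
          double lki = lk[i] + std::log(num / den);
          newlk.push_back({i, lki});
          lr += mass_loglik_i(D, i, a[i], std::exp(lki), prop, meas_sd) +
                surv_loglik_i(D, i, a[i], prop, gam, use_snow) +
                bvn_logprior(a[i], lki) +
                age_penalty(prop, D.jmin_day[i], D.gmax_age[g]) -
                mass_loglik_i(D, i, a[i], std::exp(lk[i]), old, meas_sd) -
                surv_loglik_i(D, i, a[i], old, gam, use_snow) -
                bvn_logprior(a[i], lk[i]) -
                age_penalty(old, D.jmin_day[i], D.gmax_age[g]);
        }
        if (feasible && std::log(R::unif_rand()) < lr) {
          tau[g][l] = prop;
          for (auto& pr_ : newlk) lk[pr_.first] = pr_.second;
        }
      }
    }

    // --- survival coefficients: per-coordinate Metropolis ---
    {
      int ncoef = use_snow ? 5 : 3;
      for (int c = 0; c < ncoef; ++c) {
        double old = gam[c];
        double prop = old + R::norm_rand() * sc_gam[c];
        double lr = -0.5 * (prop * prop - old * old) / (gamma_sd * gamma_sd);
        for (int i = 0; i < nj; ++i) {
          double t0 = tau[D.jgroup[i]][z[i]];
          gam[c] = prop;
          lr += surv_loglik_i(D, i, a[i], t0, gam, use_snow);
          gam[c] = old;
          lr -= surv_loglik_i(D, i, a[i], t0, gam, use_snow);
        }
        bool acc = std::log(R::unif_rand()) < lr;
        if (acc) gam[c] = prop;
        if (adapting) sc_gam[c] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - tgt));
      }
    }

    // --- hyperparameters: conjugate Normal / inverse-Wishart ---
    {
      arma::mat Si = arma::inv_sympd(arma::symmatu(Sigma));
      // mean
      arma::mat prior_prec(2, 2, arma::fill::zeros);
      prior_prec(0, 0) = 1.0 / hyper[1];
      prior_prec(1, 1) = 1.0 / hyper[3];
      arma::vec prior_mean = {hyper[0], hyper[2]};
      arma::mat C = prior_prec + nj * Si;
      arma::vec sums = {0, 0};
      for (int i = 0; i < nj; ++i) { sums(0) += a[i]; sums(1) += lk[i]; }
      arma::vec lvec = prior_prec * prior_mean + Si * sums;
      arma::mat Cl = arma::chol(arma::symmatu(C));
      arma::vec mu = arma::solve(arma::trimatu(Cl),
                                 arma::solve(arma::trimatl(Cl.t()), lvec));
      arma::vec zz = {R::norm_rand(), R::norm_rand()};
      arma::vec draw = mu + arma::solve(arma::trimatu(Cl), zz);
      mu_a = draw(0); mu_lk = draw(1);
      // covariance
      arma::mat SS(2, 2, arma::fill::zeros);
      for (int i = 0; i < nj; ++i) {
        arma::vec d = {a[i] - mu_a, lk[i] - mu_lk};
        SS += d * d.t();
      }
      arma::mat V0(2, 2, arma::fill::zeros);
      V0(0, 0) = sig0[0]; V0(1, 1) = sig0[1];
      arma::mat Psi = nu0 * V0 + SS;
      double df = nu0 + nj;
      arma::mat L = arma::chol(arma::inv_sympd(arma::symmatu(Psi)), "lower");
      arma::mat Ab(2, 2, arma::fill::zeros);
      Ab(0, 0) = std::sqrt(R::rchisq(df));
      Ab(1, 1) = std::sqrt(R::rchisq(df - 1));
      Ab(1, 0) = R::norm_rand();
      arma::mat LA = L * Ab;
      Sigma = arma::inv_sympd(arma::symmatu(LA * LA.t()));
    }

    if (it >= burnin && (it - burnin) % thin == 0 && keep < n_keep) {
      for (int i = 0; i < nj; ++i) {
        s_a(i, keep) = a[i];
        s_k(i, keep) = std::exp(lk[i]);
        s_t0(i, keep) = tau[D.jgroup[i]][z[i]];
        s_z(i, keep) = z[i] + 1;
      }
      for (int c = 0; c < 5; ++c) s_gam(c, keep) = gam[c];
      s_mu(0, keep) = mu_a; s_mu(1, keep) = mu_lk;
      s_sig(0, keep) = Sigma(0, 0);
      s_sig(1, keep) = Sigma(0, 1);
      s_sig(2, keep) = Sigma(1, 1);
      for (int g = 0; g < ng; ++g)
        for (int l = 0; l < NLIT; ++l) s_tau(g, l, keep) = tau[g][l];
      ++keep;
    }
  }

  return List::create(_["a"] = s_a, _["k"] = s_k, _["t0"] = s_t0,
                      _["litter"] = s_z, _["gamma"] = s_gam,
                      _["mu"] = s_mu, _["Sigma"] = s_sig,
                      _["tau"] = s_tau, _["n_samples"] = keep);
}
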