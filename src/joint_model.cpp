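// Joint total-count (negative binomial) + allelic-count (beta binomial)
// cis-effect likelihood, profiled over the allelic effect pi.
//
// Model, per sample j with dosage g_j at the candidate variant:
//   y_j ~ NB(mu_j, phi),  mu_j = s_j * lambda * exp(x_j' gamma) * m_j,
//   m_j = (2 - g_j) * (1 - pi) + g_j * pi
//   a_j | het ~ BetaBin(d_j, p', theta),
//   p  = pi (1 - psi) / (pi (1 - psi) + (1 - pi) psi)
//   p' = p (1 - 2 delta) + delta
// phi is the NB overdispersion (variance mu + phi mu^2), theta the
// beta-binomial overdispersion (binomial as theta -> 0).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

// Brent's golden-section/parabolic minimizer on [ax, bx]
double brent_fmin(double ax, double bx, double (*f)(double, void *),
                  void *info, double tol) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  const double eps = std::sqrt(DBL_EPSILON);
  double a = ax, b = bx;
  double v = a + c * (b - a), w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = f(x, info), fv = fx, fw = fx;
  for (int it = 0; it < 200; ++it) {
    double xm = (a + b) * 0.5;
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - (b - a) * 0.5) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      if (std::fabs(p) < std::fabs(0.5 * q * e) && p > q * (a - x) &&
          p < q * (b - x)) {
        golden = false;
        e = d;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
      }
    }
    if (golden) { e = (x < xm) ? b - x : a - x; d = c * e; }
    double u = (std::fabs(d) >= tol1) ? x + d
                                      : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = f(u, info);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; fv = fw; w = u; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

struct ModelData {
  const double *y, *s, *g;     // length n
  const double *X;             // n x k, column major (may be null)
  int n, k;
  const double *a_alt, *d_tot; // length n_het
  int n_het;
  bool pop_only;
  // shrinkage priors keeping psi/delta identifiable from a single variant:
  // psi ~ Beta(psi_a, psi_a), delta ~ Beta(1, delta_b)
  double psi_a, delta_b;
  // current parameter state
  double pi;
  double eta0;                 // log lambda
  std::vector<double> gamma;
  double lphi;                 // log phi
  double lpsi;                 // logit psi
  double delta;
  double ltheta;               // log theta
};

inline double expit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

double nb_loglik(const ModelData &dm) {
  const double phi = std::exp(dm.lphi);
  const double size = 1.0 / phi;
  double ll = 0.0;
  for (int j = 0; j < dm.n; ++j) {
    double eta = dm.eta0 + std::log(dm.s[j]);
    for (int c = 0; c < dm.k; ++c) eta += dm.X[j + c * dm.n] * dm.gamma[c];
    double m = (2.0 - dm.g[j]) * (1.0 - dm.pi) + dm.g[j] * dm.pi;
    double mu = std::exp(eta) * m;
    if (mu < 1e-12) mu = 1e-12;
    ll += R::dnbinom_mu(dm.y[j], size, mu, 1);
  }
  return ll;
}

double bb_loglik(const ModelData &dm) {
  if (dm.pop_only || dm.n_het == 0) return 0.0;
  const double psi = expit(dm.lpsi);
  const double num = dm.pi * (1.0 - psi);
  double p = num / (num + (1.0 - dm.pi) * psi);
  double pp = p * (1.0 - 2.0 * dm.delta) + dm.delta;
  pp = std::min(std::max(pp, 1e-10), 1.0 - 1e-10);
  const double theta = std::exp(dm.ltheta);
  const double al = pp / theta, be = (1.0 - pp) / theta;
  double ll = 0.0;
  for (int r = 0; r < dm.n_het; ++r) {
    double a = dm.a_alt[r], d = dm.d_tot[r];
    ll += R::lchoose(d, a) + R::lbeta(a + al, d - a + be) - R::lbeta(al, be);
  }
  ll += (dm.psi_a - 1.0) * (std::log(psi) + std::log(1.0 - psi));
  ll += (dm.delta_b - 1.0) * std::log(1.0 - dm.delta);
  return ll;
}

// pointers used by the 1-D Brent coordinate steps
struct CoordCtx {
  ModelData *dm;
  double *coord;
  bool nb_part; // which component this coordinate affects
};

double neg_coord(double x, void *info) {
  CoordCtx *cc = static_cast<CoordCtx *>(info);
  *(cc->coord) = x;
  return cc->nb_part ? -nb_loglik(*(cc->dm)) : -bb_loglik(*(cc->dm));
}

double brent_coord(ModelData &dm, double *coord, bool nb_part,
                   double lo, double hi, double tol) {
  CoordCtx cc{&dm, coord, nb_part};
  double xopt = brent_fmin(lo, hi, neg_coord, &cc, tol);
  *coord = xopt;
  return xopt;
}

// maximize NB component over eta0, gamma, lphi at fixed pi
double max_nb(ModelData &dm, double tol) {
  double prev = nb_loglik(dm);
  for (int it = 0; it < 25; ++it) {
    brent_coord(dm, &dm.eta0, true, dm.eta0 - 6.0, dm.eta0 + 6.0, tol);
    for (int c = 0; c < dm.k; ++c)
      brent_coord(dm, &dm.gamma[c], true, -8.0, 8.0, tol);
    brent_coord(dm, &dm.lphi, true, std::log(1e-4), std::log(50.0), tol);
    double cur = nb_loglik(dm);
    if (cur - prev < 1e-8) { prev = cur; break; }
    prev = cur;
  }
  return prev;
}

// maximize BB component over psi, delta, theta at fixed pi
double max_bb(ModelData &dm, double tol, bool psi_free) {
  if (dm.pop_only || dm.n_het == 0) return 0.0;
  double prev = bb_loglik(dm);
  const double lpsi_lo = std::log(0.001 / 0.999), lpsi_hi = -lpsi_lo;
  for (int it = 0; it < 25; ++it) {
    if (psi_free)
      brent_coord(dm, &dm.lpsi, false, lpsi_lo, lpsi_hi, tol);
    brent_coord(dm, &dm.delta, false, 0.0, 0.45, tol);
    brent_coord(dm, &dm.ltheta, false, std::log(1e-6), std::log(50.0), tol);
    double cur = bb_loglik(dm);
    if (cur - prev < 1e-8) { prev = cur; break; }
    prev = cur;
  }
  return prev;
}

struct ProfCtx { ModelData *dm; double tol; bool psi_free; };

double neg_profile(double pi, void *info) {
  ProfCtx *pc = static_cast<ProfCtx *>(info);
  pc->dm->pi = pi;
  return -(max_nb(*(pc->dm), pc->tol) + max_bb(*(pc->dm), pc->tol, pc->psi_free));
}

} // namespace

// [[Rcpp::export(name = ".cpp_fit_joint")]]
List cpp_fit_joint(NumericVector y, NumericVector s, NumericVector g,
                   NumericMatrix X, NumericVector a_alt, NumericVector d_tot,
                   bool pop_only,
                   double fix_pi = NA_REAL, bool psi_free = true,
                   double psi_prior = 10.0, double delta_prior = 19.0,
                   double tol = 1e-6) {
  ModelData dm;
  dm.y = REAL(y); dm.s = REAL(s); dm.g = REAL(g);
  dm.n = y.size();
  dm.k = X.ncol();
  dm.X = dm.k > 0 ? REAL(X) : nullptr;
  dm.a_alt = REAL(a_alt); dm.d_tot = REAL(d_tot);
  dm.n_het = a_alt.size();
  dm.pop_only = pop_only;
  dm.psi_a = psi_prior;
  dm.delta_b = delta_prior;

  // fixed documented starting point: pi=.5, psi=.5, delta=.01, phi=theta=.1
  dm.pi = 0.5;
  double tot_y = 0.0, tot_sm = 0.0;
  for (int j = 0; j < dm.n; ++j) { tot_y += dm.y[j]; tot_sm += dm.s[j]; }
  dm.eta0 = std::log(std::max(tot_y, 0.5) / tot_sm);
  dm.gamma.assign(dm.k, 0.0);
  dm.lphi = std::log(0.1);
  dm.lpsi = 0.0;
  dm.delta = 0.01;
  dm.ltheta = std::log(0.1);

  ProfCtx pc{&dm, tol, psi_free};
  double pi_hat, ll;
  if (R_IsNA(fix_pi)) {
    pi_hat = brent_fmin(0.001, 0.999, neg_profile, &pc, 1e-5);
    // Brent can sit in a local basin when the surface is flat near .5;
    // re-evaluate at the boundary-of-attraction candidates and keep the best
    ll = -neg_profile(pi_hat, &pc);
    double st[5] = {0.5, 0.1, 0.9, 0.25, 0.75};
    for (double p0 : st) {
      double l0 = -neg_profile(p0, &pc);
      if (l0 > ll + 1e-9) {
        double lo = std::max(0.001, p0 - 0.25), hi = std::min(0.999, p0 + 0.25);
        double pc2 = brent_fmin(lo, hi, neg_profile, &pc, 1e-5);
        double lc2 = -neg_profile(pc2, &pc);
        if (lc2 > ll) { ll = lc2; pi_hat = pc2; }
      }
    }
    dm.pi = pi_hat;
    ll = -neg_profile(pi_hat, &pc);
  } else {
    pi_hat = fix_pi;
    ll = -neg_profile(fix_pi, &pc);
  }

  double prior = 0.0;
  if (!dm.pop_only && dm.n_het > 0) {
    double psi = expit(dm.lpsi);
    prior = (dm.psi_a - 1.0) * (std::log(psi) + std::log(1.0 - psi)) +
            (dm.delta_b - 1.0) * std::log(1.0 - dm.delta);
  }
  return List::create(
      _["pi"] = pi_hat,
      _["lambda"] = std::exp(dm.eta0),
      _["phi"] = std::exp(dm.lphi),
      _["psi"] = expit(dm.lpsi),
      _["delta"] = dm.delta,
      _["theta"] = std::exp(dm.ltheta),
      _["gamma"] = NumericVector(dm.gamma.begin(), dm.gamma.end()),
      _["objective"] = ll,
      _["loglik"] = ll - prior);
}
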