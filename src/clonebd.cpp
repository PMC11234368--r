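#include <Rcpp.h>
using namespace Rcpp;

// (1 - exp(-g * d)) / g, stable as g -> 0
static inline double expint(double g, double d) {
  if (d <= 0.0) return 0.0;
  double x = g * d;
  if (std::fabs(x) < 1e-12) return d;
  return -expm1(-x) / g;
}

// Kendall-type propagation of a linear birth-death process with
// piecewise-constant per-cell rates in clonal age.  One founder cell of
// clonal age a0, observed after chase t:
//   rho(t) = int (lambda - mu) over ages a0..a0+t
//   I(t)   = int_0^t mu(a0+s) exp(-rho(s)) ds
//   M = exp(rho); alpha = I/(1+I); nbar = M*(1+I)
// [[Rcpp::export]]
NumericMatrix bd_propagate_cpp(NumericVector starts, NumericVector lam,
                               NumericVector mu, NumericVector a0,
                               NumericVector tt) {
  const int K = starts.size();
  const int n = a0.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("M", "alpha", "nbar");
  for (int i = 0; i < n; ++i) {
    const double a = a0[i], t = tt[i];
    double rho = 0.0, I = 0.0;
    for (int j = 0; j < K; ++j) {
      const double lo = starts[j];
      const double hi = (j + 1 < K) ? starts[j + 1] : R_PosInf;
      // elapsed-time window during which the clone's age lies in phase j
      double u = lo - a; if (u < 0.0) u = 0.0;
      double v = (hi == R_PosInf) ? t : hi - a; if (v > t) v = t;
      if (v <= u) continue;
      const double g = lam[j] - mu[j], d = v - u;
      I += mu[j] * std::exp(-rho) * expint(g, d);
      rho += g * d;
    }
    const double M = std::exp(rho);
    out(i, 0) = M;
    out(i, 1) = I / (1.0 + I);
    out(i, 2) = M * (1.0 + I);
  }
  return out;
}

// Exact Gillespie simulation of one clone per row: founder is a single
// basal cell of clonal age a0, observed after chase t.  Per-basal-cell
// events: birth (BL+1), death/delamination (BL-1, sBL+1), neutral division
// (sBL+1); per-suprabasal-cell: shedding (sBL-1).  Rates are piecewise
// constant in clonal age; waiting times are capped at phase boundaries.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix sim_clones_cpp(NumericVector starts, NumericVector lam,
                             NumericVector mu, NumericVector sig, double shed,
                             NumericVector a0, NumericVector tt) {
  const int K = starts.size();
  const int n = a0.size();
  IntegerMatrix out(n, 2);
  colnames(out) = CharacterVector::create("basal", "suprabasal");
  for (int i = 0; i < n; ++i) {
    double age = a0[i];
    const double age_end = a0[i] + tt[i];
    int b = 1, s = 0;
    int j = K - 1;
    for (int k = 0; k < K; ++k) {
      double hi = (k + 1 < K) ? starts[k + 1] : R_PosInf;
      if (age < hi) { j = k; break; }
    }
    while (age < age_end) {
      if (b == 0 && s == 0) break;
      const double bound = (j + 1 < K) ? starts[j + 1] : R_PosInf;
      const double rate_b = b * (lam[j] + mu[j] + sig[j]);
      const double rate = rate_b + s * shed;
      const double cap = (bound < age_end) ? bound : age_end;
      if (rate <= 0.0) { age = cap; if (cap == bound) ++j; continue; }
      const double w = exp_rand() / rate;
      if (age + w >= cap) { age = cap; if (cap == bound) ++j; continue; }
      age += w;
      const double u = unif_rand() * rate;
      if (u < b * lam[j]) ++b;
      else if (u < b * (lam[j] + mu[j])) { --b; ++s; }
      else if (u < rate_b) ++s;
      else --s;
    }
    out(i, 0) = b;
    out(i, 1) = s;
  }
  return out;
}

// As sim_clones_cpp for a single clone, but returns the full event log
// (event type and the increments to basal, suprabasal and total counts).
// [[Rcpp::export]]
List sim_clone_audit_cpp(NumericVector starts, NumericVector lam,
                         NumericVector mu, NumericVector sig, double shed,
                         double a0, double t_obs) {
  const int K = starts.size();
  std::vector<double> ev_t;
  std::vector<int> ev_type, ev_db, ev_ds;
  double age = a0;
  const double age_end = a0 + t_obs;
  int b = 1, s = 0;
  int j = K - 1;
  for (int k = 0; k < K; ++k) {
    double hi = (k + 1 < K) ? starts[k + 1] : R_PosInf;
    if (age < hi) { j = k; break; }
  }
  while (age < age_end) {
    if (b == 0 && s == 0) break;
    const double bound = (j + 1 < K) ? starts[j + 1] : R_PosInf;
    const double rate_b = b * (lam[j] + mu[j] + sig[j]);
    const double rate = rate_b + s * shed;
    const double cap = (bound < age_end) ? bound : age_end;
    if (rate <= 0.0) { age = cap; if (cap == bound) ++j; continue; }
    const double w = exp_rand() / rate;
    if (age + w >= cap) { age = cap; if (cap == bound) ++j; continue; }
    age += w;
    const double u = unif_rand() * rate;
    int type, db, ds;
    if (u < b * lam[j]) { type = 1; db = 1; ds = 0; }
    else if (u < b * (lam[j] + mu[j])) { type = 2; db = -1; ds = 1; }
    else if (u < rate_b) { type = 3; db = 0; ds = 1; }
    else { type = 4; db = 0; ds = -1; }
    b += db; s += ds;
    ev_t.push_back(age - a0); ev_type.push_back(type);
    ev_db.push_back(db); ev_ds.push_back(ds);
    if (ev_t.size() > 2000000) stop("event log overflow");
  }
  return List::create(_["basal"] = b, _["suprabasal"] = s,
                      _["time"] = wrap(ev_t), _["type"] = wrap(ev_type),
                      _["d_basal"] = wrap(ev_db), _["d_suprabasal"] = wrap(ev_ds));
}

// Labeled-cohort observables for a biphasic schedule (rates l1,m1 before
// transition age T, subcritical l2,m2 after), under one of three labeling
// models: 0 = equal (density prop. to homeostatic abundance m(a)),
// 1 = pre-transition only, 2 = post-transition only.  Pre-transition
// founder ages are integrated by composite Gauss-Legendre quadrature
// (nodes/weights on [0,1] supplied); the post-transition region is handled
// in closed form since rates there are constant.  Returns per chase time:
// f_basal (normalised to 1 at t = 0), survival, mean basal size.
// [[Rcpp::export]]
NumericMatrix gbdm_predict_cpp(double l1, double m1, double l2, double m2,
                               double T, NumericVector tt, int labeling,
                               NumericVector glx, NumericVector glw) {
  const int nt = tt.size(), ng = glx.size();
  const double g1 = l1 - m1, g2 = l2 - m2;
  NumericMatrix out(nt, 3);
  colnames(out) = CharacterVector::create("f_basal", "survival", "mean_basal_size");
  const bool need_post = (labeling != 1);
  if (need_post && g2 >= 0.0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  // steady-state age-profile masses: m(a) = exp(g1*a) for a<T, m(T)exp(g2(a-T)) after
  const double mT = std::exp(g1 * T);
  const double mass_pre = expint(-g1, T);          // int_0^T exp(g1 a) da
  const double mass_post = need_post ? mT / (-g2) : 0.0;
  double w_pre = (labeling == 2) ? 0.0 : mass_pre;
  double w_post = (labeling == 1) ? 0.0 : mass_post;
  const double W = w_pre + w_post;
  for (int it = 0; it < nt; ++it) {
    const double t = tt[it];
    double f = 0.0, sv = 0.0;
    if (w_post > 0.0) {
      const double M2 = std::exp(g2 * t);
      const double I2 = m2 * expint(g2, t);
      f += w_post * M2;
      sv += w_post / (1.0 + I2);
    }
    if (w_pre > 0.0) {
      // founder age a0 in [0,T): phase 1 for d1 = min(t, T-a0), then phase 2
      double c = T - t; if (c < 0.0) c = 0.0; if (c > T) c = T;
      const double seg_lo[2] = {0.0, c}, seg_hi[2] = {c, T};
      for (int sgi = 0; sgi < 2; ++sgi) {
        const double len = seg_hi[sgi] - seg_lo[sgi];
        if (len <= 0.0) continue;
        for (int k = 0; k < ng; ++k) {
          const double a0 = seg_lo[sgi] + len * glx[k];
          const double wq = len * glw[k] * std::exp(g1 * a0);
          double d1 = T - a0; if (d1 > t) d1 = t;
          const double d2 = t - d1;
          const double rho = g1 * d1 + g2 * d2;
          const double I = m1 * expint(g1, d1) +
            m2 * std::exp(-g1 * d1) * expint(g2, d2);
          f += wq * std::exp(rho);
          sv += wq / (1.0 + I);
        }
      }
    }
    f /= W; sv /= W;
    out(it, 0) = f;
    out(it, 1) = sv;
    out(it, 2) = f / sv;
  }
  return out;
}

// Exact count/size negative log-likelihood for the biphasic model.
// Per chase day t: the number of surviving labeled clones K_t is Poisson
// with mean c * A_t * S(t) (Poisson labeling thinned by survival; the
// scale c is profiled out analytically), and each surviving basal clone
// size follows the founder-age mixture of geometric laws — for fixed
// founder age the surviving-clone size is exactly geometric (neutral
// competition), and the labeling model mixes founder ages with density
// m(a0) restricted to its window.  theta = (l1, m1, l2, d2),
// m2 = l2 + d2; labeling as in gbdm_predict_cpp.
// [[Rcpp::export]]
double gbdm_counts_negloglik_cpp(NumericVector theta, double T, int labeling,
                                 NumericVector t_days, NumericVector K,
                                 NumericVector A, IntegerVector size_day,
                                 IntegerVector size_val,
                                 NumericVector glx, NumericVector glw) {
  const double l1 = theta[0], m1 = theta[1], l2 = theta[2], m2 = theta[2] + theta[3];
  const double g1 = l1 - m1, g2 = l2 - m2;
  const int nd = t_days.size(), ns = size_val.size(), ng = glx.size();
  const bool need_post = (labeling != 1);
  if (need_post && g2 >= 0.0) return 1e10;
  const double mT = std::exp(g1 * T);
  const double mass_pre = expint(-g1, T);
  const double mass_post = need_post ? mT / (-g2) : 0.0;
  const double w_pre = (labeling == 2) ? 0.0 : mass_pre;
  const double w_post = (labeling == 1) ? 0.0 : mass_post;
  const double W = w_pre + w_post;
  // mixture components per day: weights w*(1-alpha) and means nbar
  std::vector<double> comp_w(2 * ng + 1), comp_nb(2 * ng + 1);
  double ll = 0.0, sumK = 0.0, sumAS = 0.0;
  std::vector<double> Sday(nd);
  int si = 0;
  for (int d = 0; d < nd; ++d) {
    const double t = t_days[d];
    int ncomp = 0;
    double surv = 0.0;
    if (w_post > 0.0) {
      const double I2 = m2 * expint(g2, t);
      comp_w[ncomp] = w_post / (1.0 + I2);
      comp_nb[ncomp] = std::exp(g2 * t) * (1.0 + I2);
      surv += comp_w[ncomp];
      ++ncomp;
    }
    if (w_pre > 0.0) {
      double c = T - t; if (c < 0.0) c = 0.0; if (c > T) c = T;
      const double seg_lo[2] = {0.0, c}, seg_hi[2] = {c, T};
      for (int sgi = 0; sgi < 2; ++sgi) {
        const double len = seg_hi[sgi] - seg_lo[sgi];
        if (len <= 0.0) continue;
        for (int k = 0; k < ng; ++k) {
          const double a0 = seg_lo[sgi] + len * glx[k];
          const double wq = len * glw[k] * std::exp(g1 * a0);
          double d1 = T - a0; if (d1 > t) d1 = t;
          const double d2t = t - d1;
          const double rho = g1 * d1 + g2 * d2t;
          const double I = m1 * expint(g1, d1) +
            m2 * std::exp(-g1 * d1) * expint(g2, d2t);
          comp_w[ncomp] = wq / (1.0 + I);
          comp_nb[ncomp] = std::exp(rho) * (1.0 + I);
          surv += comp_w[ncomp];
          ++ncomp;
        }
      }
    }
    const double S = surv / W;
    if (!R_finite(S) || S <= 0.0) return 1e10;
    Sday[d] = S;
    sumK += K[d];
    sumAS += A[d] * S;
    // size likelihood: mixture of geometrics weighted by survival
    while (si < ns && size_day[si] == d) {
      const int n = size_val[si];
      double pmf = 0.0;
      for (int cidx = 0; cidx < ncomp; ++cidx) {
        const double nb = comp_nb[cidx];
        if (nb < 1.0) return 1e10;
        const double p = 1.0 / nb;
        double g = p;
        if (n > 1) {
          if (nb <= 1.0) { g = 0.0; }
          else g = p * std::exp((n - 1) * std::log1p(-p));
        }
        pmf += comp_w[cidx] * g;
      }
      pmf /= surv;
      if (!(pmf > 0.0)) return 1e10;
      ll += std::log(pmf);
      ++si;
    }
  }
  const double chat = sumK / sumAS;
  for (int d = 0; d < nd; ++d)
    ll += K[d] * std::log(chat * A[d] * Sday[d]) - chat * A[d] * Sday[d];
  if (!R_finite(ll)) return 1e10;
  return -ll;
}

// Gaussian negative log-likelihood of observed labeled-basal-fraction and
// mean-basal-clone-size series against the biphasic model, with the
// fraction series anchored to the baseline chase day.  theta =
// (l1, m1, l2, d2) with m2 = l2 + d2; for the monophasic model the caller
// passes l1 = l2, m1 = m2 and labeling = 2.
// [[Rcpp::export]]
double gbdm_negloglik_cpp(NumericVector theta, double T, int labeling,
                          NumericVector t_f, NumericVector y_f, NumericVector se_f,
                          NumericVector t_n, NumericVector y_n, NumericVector se_n,
                          double t_baseline,
                          NumericVector glx, NumericVector glw) {
  const double l1 = theta[0], m1 = theta[1], l2 = theta[2], m2 = theta[2] + theta[3];
  const int nf = t_f.size(), nn = t_n.size();
  NumericVector tt(1 + nf + nn);
  tt[0] = t_baseline;
  for (int i = 0; i < nf; ++i) tt[1 + i] = t_f[i];
  for (int i = 0; i < nn; ++i) tt[1 + nf + i] = t_n[i];
  NumericMatrix pr = gbdm_predict_cpp(l1, m1, l2, m2, T, tt, labeling, glx, glw);
  const double f0 = pr(0, 0);
  if (!R_finite(f0) || f0 <= 0.0) return 1e10;
  const double LOG2PI = 1.8378770664093453;
  // weights act as relative precisions; a common variance scale is
  // profiled out, so the likelihood ratio between nested fits does not
  // depend on a uniform rescaling of all weights
  double ssq = 0.0, logse = 0.0;
  const int ntot = nf + nn;
  for (int i = 0; i < nf; ++i) {
    const double p = pr(1 + i, 0) / f0;
    if (!R_finite(p)) return 1e10;
    const double z = (y_f[i] - p) / se_f[i];
    ssq += z * z;
    logse += std::log(se_f[i]);
  }
  for (int i = 0; i < nn; ++i) {
    const double p = pr(1 + nf + i, 2);
    if (!R_finite(p)) return 1e10;
    const double z = (y_n[i] - p) / se_n[i];
    ssq += z * z;
    logse += std::log(se_n[i]);
  }
  if (!R_finite(ssq) || ssq <= 0.0) return 1e10;
  const double nll = 0.5 * ntot * (std::log(ssq / ntot) + 1.0 + LOG2PI) + logse;
  if (!R_finite(nll)) return 1e10;
  return nll;
}
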