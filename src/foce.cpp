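#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-compartment piecewise-constant infusion model, FOCE-I (Laplace at the
// conditional eta mode, with interaction: residual variance depends on eta)
// for a single exponential random effect on CL and a proportional residual
// error whose variance is chosen per observation by error group.
//
// Data layout (built once per fit on the R side):
//   y         observed concentrations (ng/mL), analysis set only
//   obs_pat   0-based patient index per observation (observations sorted by
//             patient)
//   obs_grp   0 = normal error group, 1 = outlier error group
//   pair_*    one row per (observation, dose) pair, sorted by observation:
//             t1 = time - start, t2 = time - start - duration, dur, rate
//   pair_obs  0-based observation index of each pair

static const double LOG2PI = 1.8378770664093454836;

struct Engine {
  const double *y;
  const int *obs_grp;
  const int *pair_obs;
  const double *t1, *t2, *dur, *rate;
  int pfirst_obs, plast_obs;          // observation range of current patient
  const int *obs_pair_start;          // pair offsets per observation
  double v, sig2[2];
  double log_tvcl;

  // -2 log-likelihood data part (up to n*log(2pi)) at individual CL
  double l_data(double eta) const {
    double cl = std::exp(log_tvcl + eta);
    double k = cl / v;
    double acc = 0.0;
    for (int j = pfirst_obs; j < plast_obs; ++j) {
      double f = 0.0;
      for (int p = obs_pair_start[j]; p < obs_pair_start[j + 1]; ++p) {
        if (t1[p] < 0) continue;                 // dose not started yet
        if (t2[p] <= 0) {                        // during infusion
          f += rate[p] / cl * (1.0 - std::exp(-k * t1[p]));
        } else {                                 // after stop
          f += rate[p] / cl * (1.0 - std::exp(-k * dur[p])) *
               std::exp(-k * t2[p]);
        }
      }
      f *= 1000.0;                               // mg/L -> ng/mL
      if (!(f > 0.0) || !std::isfinite(f)) return R_PosInf;
      double vj = sig2[obs_grp[j]] * f * f;
      double r = y[j] - f;
      acc += std::log(vj) + r * r / vj;
    }
    return acc;
  }
};

// [[Rcpp::export]]
List cpp_foce(NumericVector y, IntegerVector obs_pat, IntegerVector obs_grp,
              IntegerVector pair_obs, NumericVector pair_t1,
              NumericVector pair_t2, NumericVector pair_dur,
              NumericVector pair_rate, NumericVector log_tvcl, double v,
              double omega2, double sig2n, double sig2o) {
  int nobs = y.size(), npat = log_tvcl.size(), npair = pair_obs.size();
  for (int j = 0; j < nobs; ++j)
    if (obs_pat[j] < 0 || obs_pat[j] >= npat)
      stop("obs_pat index out of range for log_tvcl");

  // offsets: pairs per observation, observations per patient
  std::vector<int> obs_pair_start(nobs + 1, 0);
  for (int p = 0; p < npair; ++p) obs_pair_start[pair_obs[p] + 1]++;
  for (int j = 0; j < nobs; ++j) obs_pair_start[j + 1] += obs_pair_start[j];
  std::vector<int> pat_obs_start(npat + 1, 0);
  for (int j = 0; j < nobs; ++j) pat_obs_start[obs_pat[j] + 1]++;
  for (int i = 0; i < npat; ++i) pat_obs_start[i + 1] += pat_obs_start[i];

  Engine eng;
  eng.y = REAL(y);
  eng.obs_grp = INTEGER(obs_grp);
  eng.pair_obs = INTEGER(pair_obs);
  eng.t1 = REAL(pair_t1);
  eng.t2 = REAL(pair_t2);
  eng.dur = REAL(pair_dur);
  eng.rate = REAL(pair_rate);
  eng.obs_pair_start = obs_pair_start.data();
  eng.v = v;
  eng.sig2[0] = sig2n;
  eng.sig2[1] = sig2o;

  NumericVector etas(npat), ofv_i(npat);
  double ofv = 0.0;
  bool bad = false;
  // h: Newton derivative step; hc: curvature step for the Laplace term
  // (larger, to keep the second difference clear of cancellation noise)
  const double h = 1e-4, hc = 1e-3;

  for (int i = 0; i < npat && !bad; ++i) {
    eng.pfirst_obs = pat_obs_start[i];
    eng.plast_obs = pat_obs_start[i + 1];
    int ni = eng.plast_obs - eng.pfirst_obs;
    eng.log_tvcl = log_tvcl[i];
    if (ni == 0) { etas[i] = 0.0; ofv_i[i] = 0.0; continue; }

    if (omega2 < 1e-12) {                        // no IIV: exact pooled -2LL
      double ld = eng.l_data(0.0);
      if (!std::isfinite(ld)) { bad = true; break; }
      etas[i] = 0.0;
      ofv_i[i] = ni * LOG2PI + ld;
      ofv += ofv_i[i];
      continue;
    }

    // joint -2 log density in eta (up to constants)
    auto l = [&](double e) { return eng.l_data(e) + e * e / omega2; };

    // safeguarded Newton from eta = 0, numerical derivatives
    double e = 0.0, le = l(0.0);
    if (!std::isfinite(le)) { bad = true; break; }
    for (int it = 0; it < 60; ++it) {
      double lp = l(e + h), lm = l(e - h);
      if (!std::isfinite(lp) || !std::isfinite(lm)) break;
      double g = (lp - lm) / (2 * h);
      double H = (lp - 2 * le + lm) / (h * h);
      double step = (H > 1e-10) ? (-g / H) : ((g > 0) ? -0.1 : 0.1);
      if (step > 2.0) step = 2.0;
      if (step < -2.0) step = -2.0;
      double lnew = l(e + step);
      int bt = 0;
      while ((!std::isfinite(lnew) || lnew > le + 1e-12) && bt < 40) {
        step *= 0.5;
        lnew = l(e + step);
        ++bt;
      }
      if (!std::isfinite(lnew) || lnew > le) break;
      e += step;
      le = lnew;
      if (std::fabs(step) < 1e-10) break;
      if (e > 8.0) e = 8.0;
      if (e < -8.0) e = -8.0;
    }

    // Laplace: H_joint = 0.5 * l''(ehat)
    double lpp = (l(e + hc) - 2 * le + l(e - hc)) / (hc * hc);
    double Hj = 0.5 * lpp;
    if (!(Hj > 0.0) || !std::isfinite(Hj)) Hj = 1.0 / omega2;
    double ld = eng.l_data(e);
    double o = ni * LOG2PI + ld + std::log(omega2) + e * e / omega2 +
               std::log(Hj);
    if (!std::isfinite(o)) { bad = true; break; }
    etas[i] = e;
    ofv_i[i] = o;
    ofv += o;
  }

  if (bad) ofv = R_PosInf;
  return List::create(_["ofv"] = ofv, _["etas"] = etas, _["ofv_i"] = ofv_i,
                      _["ok"] = !bad);
}
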