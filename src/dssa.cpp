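// Delayed stochastic simulation engine for the minimal Gal4p/Gal2p energy
// model. One routine serves both the single-step interface (step_dssa) and
// whole-lineage simulation (simulate_cell): time-varying propensities are
// handled by freezing them within a step and capping the step length, and
// production is delayed by a fixed maturation time. Volume grows as
// dV/dt = E * gamma * V with E frozen per step, so division times (V = 2)
// are solved exactly within each step.

#include <Rcpp.h>
#include <deque>
#include <cmath>
#include <limits>
using namespace Rcpp;

static inline double glu_at(double t, double hold, double td, double gs) {
  if (t <= hold) return gs;
  double u = t - hold;
  if (td <= 0.0 || u >= td) return 0.0;
  return gs * (1.0 - u / td);
}

static inline double energy_at(double glu, double g2, double eps,
                               double Eglu, double Egal,
                               double thglu, double thgal) {
  double a = Eglu * std::min(glu / thglu, 1.0);
  double b = Egal * std::min(g2 / thgal, 1.0);
  return std::max(std::max(a, b), eps);
}

// Advance one cell from time t to t_end (or by a single step).
// Stop kinds: 0 capped advance (max_step or t_end), 1 reaction initiation,
// 2 delayed completion, 3 division, 4 record-grid stop.
// [[Rcpp::export]]
List dssa_advance_cpp(double t, int g4, int g2, double volume,
                      NumericVector pending_time, IntegerVector pending_species,
                      NumericVector division_times,
                      double c4, double eps,
                      double alpha4, double alpha2, double n4, double n2,
                      double c2, double E_glu_max, double E_gal_max,
                      double th_glu, double th_gal,
                      double gamma, double delay, double max_step,
                      double hold, double td, double gs,
                      double t_end, bool single_step,
                      double cadence, bool record) {
  const double INF = std::numeric_limits<double>::infinity();
  std::deque< std::pair<double,int> > pending;
  for (int i = 0; i < pending_time.size(); ++i)
    pending.push_back(std::make_pair(pending_time[i], (int) pending_species[i]));
  std::vector<double> divs(division_times.begin(), division_times.end());

  std::vector<double> rt, rg4, rg2, rV, rE;
  double V = volume;

  if (record) {
    double glu0 = glu_at(t, hold, td, gs);
    rt.push_back(t); rg4.push_back(g4); rg2.push_back(g2); rV.push_back(V);
    rE.push_back(energy_at(glu0, g2, eps, E_glu_max, E_gal_max, th_glu, th_gal));
  }

  long iter = 0;
  const long iter_max = 500000000L;
  while (t < t_end - 1e-12) {
    if (++iter > iter_max) stop("dSSA iteration limit exceeded");

    double glu = glu_at(t, hold, td, gs);
    double E = energy_at(glu, g2, eps, E_glu_max, E_gal_max, th_glu, th_gal);
    double b4 = alpha4 / (1.0 + std::pow(glu / c4, n4));
    double b2 = 0.0;
    if (g4 > 0) {
      double h = std::pow((double) g4 / c2, n2);
      b2 = alpha2 * h / (1.0 + h);
    }
    double a4 = E * b4, a2 = E * b2, a0 = a4 + a2;

    double w = (a0 > 0.0) ? (exp_rand() / a0) : INF;

    double t_next = t + std::min(w, max_step);
    int what = (w <= max_step) ? 1 : 0;

    if (!pending.empty() && pending.front().first <= t_next) {
      t_next = pending.front().first;
      what = 2;
    }

    double Eg = E * gamma;
    if (V >= 2.0) {                       // already at the division threshold
      t_next = t; what = 3;
    } else if (Eg > 0.0) {
      double t_div = t + std::log(2.0 / V) / Eg;
      if (t_div <= t_next) { t_next = t_div; what = 3; }
    }

    double t_rec = INF;
    if (record && cadence > 0.0) {
      t_rec = (std::floor(t / cadence + 1e-9) + 1.0) * cadence;
      if (t_rec < t_next - 1e-12) { t_next = t_rec; what = 4; }
    }

    if (t_next > t_end) { t_next = t_end; what = 0; }

    V *= std::exp(Eg * (t_next - t));
    t = t_next;

    if (what == 2) {
      int sp = pending.front().second;
      pending.pop_front();
      if (sp == 4) ++g4; else ++g2;
    } else if (what == 3) {
      // binomial partitioning: each mature molecule and each pending entry
      // goes to the (discarded) daughter with probability 1/2
      if (g4 > 0) g4 -= (int) R::rbinom((double) g4, 0.5);
      if (g2 > 0) g2 -= (int) R::rbinom((double) g2, 0.5);
      std::deque< std::pair<double,int> > keep;
      for (size_t i = 0; i < pending.size(); ++i)
        if (unif_rand() >= 0.5) keep.push_back(pending[i]);
      pending.swap(keep);
      V = 1.0;
      divs.push_back(t);
    } else if (what == 1) {
      int sp = (unif_rand() < a4 / a0) ? 4 : 2;
      if (delay > 0.0) pending.push_back(std::make_pair(t + delay, sp));
      else { if (sp == 4) ++g4; else ++g2; }
    }

    if (record && cadence > 0.0 &&
        std::fabs(t - t_rec) <= 1e-9) {   // grid point reached (any stop kind)
      double glu2 = glu_at(t, hold, td, gs);
      rt.push_back(t); rg4.push_back(g4); rg2.push_back(g2); rV.push_back(V);
      rE.push_back(energy_at(glu2, g2, eps, E_glu_max, E_gal_max,
                             th_glu, th_gal));
    }

    if (single_step) break;
  }

  int np = (int) pending.size();
  NumericVector pt(np); IntegerVector ps(np);
  for (int i = 0; i < np; ++i) {
    pt[i] = pending[i].first; ps[i] = pending[i].second;
  }

  List trace = R_NilValue;
  if (record)
    trace = List::create(_["time"] = NumericVector(rt.begin(), rt.end()),
                         _["g4"] = NumericVector(rg4.begin(), rg4.end()),
                         _["g2"] = NumericVector(rg2.begin(), rg2.end()),
                         _["volume"] = NumericVector(rV.begin(), rV.end()),
                         _["energy"] = NumericVector(rE.begin(), rE.end()));

  return List::create(_["t"] = t, _["g4"] = g4, _["g2"] = g2,
                      _["volume"] = V,
                      _["pending_time"] = pt, _["pending_species"] = ps,
                      _["division_times"] = NumericVector(divs.begin(), divs.end()),
                      _["trace"] = trace);
}
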