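// Stochastic simulation core: exact direct-method SSA and explicit tau-leaping
// with exact fallback at low copy numbers. Uses R's RNG so set.seed() in R
// fully determines a trajectory.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rate-law codes (kept in sync with the R encoder in reaction-system.R):
// 0 mass_action: params = {k}
// 1 michaelis_menten: params = {k_cat, K_m, substrate_index (0-based)}
// 2 hill: params = {V_max, K, n, regulator_index, repressor (0/1)}
// 3 hill_or: params = {V_max, K1, n1, K2, n2, regA_index, regB_index}

struct Reaction {
  int law;
  std::vector<double> par;
  std::vector<int> ridx;   // reactant species indices
  std::vector<int> rst;    // reactant stoichiometries
  std::vector<int> midx;   // linear scale modifiers (enzymes, promoter states)
};

struct System {
  int nsp;
  double omega;
  std::vector<Reaction> rxn;
  std::vector<std::vector<int> > nu; // net change per reaction (clamped rows zeroed)
};

static System decode(const List& enc) {
  System s;
  s.nsp = as<int>(enc["nsp"]);
  s.omega = as<double>(enc["omega"]);
  IntegerMatrix nu = enc["nu"]; // nsp x nr
  List rx = enc["rxn"];
  int nr = rx.size();
  s.rxn.resize(nr);
  s.nu.resize(nr);
  for (int j = 0; j < nr; ++j) {
    List r = rx[j];
    Reaction& R = s.rxn[j];
    R.law = as<int>(r["law"]);
    R.par = as<std::vector<double> >(r["par"]);
    R.ridx = as<std::vector<int> >(r["ridx"]);
    R.rst  = as<std::vector<int> >(r["rst"]);
    R.midx = as<std::vector<int> >(r["midx"]);
    s.nu[j].resize(s.nsp);
    for (int i = 0; i < s.nsp; ++i) s.nu[j][i] = nu(i, j);
    if (R.law == 0) { // fold the volume factor into the rate constant
      int order = (int)R.midx.size();
      for (size_t q = 0; q < R.rst.size(); ++q) order += R.rst[q];
      if (order > 1) R.par[0] /= std::pow(s.omega, order - 1);
    }
  }
  return s;
}

static inline double hill_term(double x, double K, double n) {
  if (x <= 0.0) return 0.0;
  double xn = std::pow(x, n);
  return xn / (std::pow(K, n) + xn);
}

// discrete = true: combinatorial (falling-factorial) kinetics for SSA;
// discrete = false: macroscopic rates x^s/s! for mean-field / LNA use.
static double propensity(const System& s, const Reaction& R,
                         const double* x, bool discrete) {
  double a = 0.0;
  switch (R.law) {
  case 0: { // mass action (volume factor folded into par[0] at decode)
    a = R.par[0];
    for (size_t q = 0; q < R.ridx.size(); ++q) {
      double xi = x[R.ridx[q]];
      int st = R.rst[q];
      if (discrete) {
        for (int u = 0; u < st; ++u) a *= (xi - u) > 0.0 ? (xi - u) : 0.0;
      } else {
        for (int u = 0; u < st; ++u) a *= xi > 0.0 ? xi : 0.0;
      }
      for (int u = 2; u <= st; ++u) a /= (double)u;
    }
    for (size_t q = 0; q < R.midx.size(); ++q)
      a *= x[R.midx[q]] > 0.0 ? x[R.midx[q]] : 0.0;
    break;
  }
  case 1: { // Michaelis-Menten
    double sub = x[(int)R.par[2]];
    if (sub <= 0.0) return 0.0;
    a = R.par[0] * sub / (R.par[1] + sub);
    for (size_t q = 0; q < R.midx.size(); ++q)
      a *= x[R.midx[q]] > 0.0 ? x[R.midx[q]] : 0.0;
    break;
  }
  case 2: { // Hill (activator or repressor)
    double reg = x[(int)R.par[3]];
    double h = hill_term(reg, R.par[1], R.par[2]);
    if (R.par[4] > 0.5) h = 1.0 - h;
    a = R.par[0] * h;
    for (size_t q = 0; q < R.midx.size(); ++q)
      a *= x[R.midx[q]] > 0.0 ? x[R.midx[q]] : 0.0;
    break;
  }
  case 3: { // probabilistic-OR of two Hill activators
    double hA = hill_term(x[(int)R.par[5]], R.par[1], R.par[2]);
    double hB = hill_term(x[(int)R.par[6]], R.par[3], R.par[4]);
    a = R.par[0] * (1.0 - (1.0 - hA) * (1.0 - hB));
    for (size_t q = 0; q < R.midx.size(); ++q)
      a *= x[R.midx[q]] > 0.0 ? x[R.midx[q]] : 0.0;
    break;
  }
  default:
    stop("unknown rate-law code");
  }
  // zero whenever any required reactant is absent (guards MM/Hill laws whose
  // consumed species is not the kinetic substrate)
  for (size_t q = 0; q < R.ridx.size(); ++q)
    if (x[R.ridx[q]] < R.rst[q]) return discrete ? 0.0 : a;
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_propensities(List enc, NumericVector state, bool discrete) {
  System s = decode(enc);
  int nr = s.rxn.size();
  NumericVector out(nr);
  for (int j = 0; j < nr; ++j)
    out[j] = propensity(s, s.rxn[j], state.begin(), discrete);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ssa(List enc, NumericVector x0, NumericVector times,
                      double max_events) {
  System s = decode(enc);
  int nr = s.rxn.size(), nt = times.size();
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(nt, s.nsp);
  RNGScope scope;
  double t = times[0];
  int it = 0;
  // record initial state at the first sampling time
  for (int i = 0; i < s.nsp; ++i) out(0, i) = x[i];
  it = 1;
  std::vector<double> a(nr);
  double events = 0.0;
  while (it < nt) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) { a[j] = propensity(s, s.rxn[j], &x[0], true); a0 += a[j]; }
    if (a0 <= 0.0 || events >= max_events) { // frozen trajectory
      for (; it < nt; ++it) for (int i = 0; i < s.nsp; ++i) out(it, i) = x[i];
      break;
    }
    double dt = -std::log(unif_rand()) / a0;
    double tnext = t + dt;
    while (it < nt && times[it] <= tnext) {
      for (int i = 0; i < s.nsp; ++i) out(it, i) = x[i];
      ++it;
    }
    if (it >= nt) break;
    t = tnext;
    double u = unif_rand() * a0, c = 0.0;
    int j = nr - 1;
    for (int q = 0; q < nr; ++q) { c += a[q]; if (u <= c) { j = q; break; } }
    for (int i = 0; i < s.nsp; ++i) x[i] += s.nu[j][i];
    events += 1.0;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_tau_leap(List enc, NumericVector x0, NumericVector times,
                           double epsilon, double exact_threshold) {
  System s = decode(enc);
  int nr = s.rxn.size(), nt = times.size(), nsp = s.nsp;
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(nt, nsp);
  RNGScope scope;
  double t = times[0];
  for (int i = 0; i < nsp; ++i) out(0, i) = x[i];
  int it = 1;
  std::vector<double> a(nr), mu(nsp), var(nsp), xnew(nsp);
  while (it < nt) {
    double a0 = 0.0;
    for (int j = 0; j < nr; ++j) { a[j] = propensity(s, s.rxn[j], &x[0], true); a0 += a[j]; }
    if (a0 <= 0.0) {
      for (; it < nt; ++it) for (int i = 0; i < nsp; ++i) out(it, i) = x[i];
      break;
    }
    // exact fallback whenever any reactant anywhere is scarce (including
    // reactions currently shut off by a zero count: leaping over them would
    // decouple, e.g., monomer production from binding at titration points)
    bool exact = false;
    for (int j = 0; j < nr && !exact; ++j)
      for (size_t q = 0; q < s.rxn[j].ridx.size(); ++q)
        if (x[s.rxn[j].ridx[q]] < exact_threshold) { exact = true; break; }
    if (!exact) {
      // epsilon-bounded expected relative change per species (Cao et al. criterion)
      std::fill(mu.begin(), mu.end(), 0.0);
      std::fill(var.begin(), var.end(), 0.0);
      for (int j = 0; j < nr; ++j) {
        if (a[j] <= 0.0) continue;
        for (int i = 0; i < nsp; ++i) {
          double nuji = s.nu[j][i];
          if (nuji != 0.0) { mu[i] += nuji * a[j]; var[i] += nuji * nuji * a[j]; }
        }
      }
      double tau = R_PosInf;
      for (int i = 0; i < nsp; ++i) {
        double bound = epsilon * x[i];
        if (bound < 1.0) bound = 1.0;
        if (mu[i] != 0.0) tau = std::min(tau, bound / std::fabs(mu[i]));
        if (var[i] > 0.0) tau = std::min(tau, bound * bound / var[i]);
      }
      if (tau < 10.0 / a0) exact = true; // leap not worthwhile
      else {
        bool accepted = false;
        while (!accepted) {
          for (int i = 0; i < nsp; ++i) xnew[i] = x[i];
          for (int j = 0; j < nr; ++j) {
            if (a[j] <= 0.0) continue;
            double kfire = ::Rf_rpois(a[j] * tau);
            if (kfire > 0.0)
              for (int i = 0; i < nsp; ++i) xnew[i] += s.nu[j][i] * kfire;
          }
          accepted = true;
          for (int i = 0; i < nsp; ++i)
            if (xnew[i] < 0.0) { accepted = false; break; }
          if (!accepted) tau *= 0.5; // reject negative proposal, halve leap
          if (tau < 10.0 / a0) { exact = true; break; }
        }
        if (!exact) {
          double tnext = t + tau;
          while (it < nt && times[it] <= tnext) {
            for (int i = 0; i < nsp; ++i) out(it, i) = x[i];
            ++it;
          }
          t = tnext;
          for (int i = 0; i < nsp; ++i) x[i] = xnew[i];
          continue;
        }
      }
    }
    // exact SSA step
    double dt = -std::log(unif_rand()) / a0;
    double tnext = t + dt;
    while (it < nt && times[it] <= tnext) {
      for (int i = 0; i < nsp; ++i) out(it, i) = x[i];
      ++it;
    }
    if (it >= nt) break;
    t = tnext;
    double u = unif_rand() * a0, c = 0.0;
    int j = nr - 1;
    for (int q = 0; q < nr; ++q) { c += a[q]; if (u <= c) { j = q; break; } }
    for (int i = 0; i < nsp; ++i) x[i] += s.nu[j][i];
  }
  return out;
}
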