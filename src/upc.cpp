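// Steady-state continuation for the two-compartment population-control
// (UPC) module with positive feedback.
//
// The receptor and its inducer-bound complex share the turnover rate dR, so
// at steady state the model reduces exactly to a scalar balance g(A) = 0 in
// the intracellular inducer concentration A:
//   Cpx*(A) = kon A (kR/dR) / (dR + koff + kon A)        (saturating)
//   pB*     = Cpx*^2 / (Cpx*^2 + (koffP/konP))           (pairwise binding)
//   Syn*    = (bS + kfb pB*) / dS,
//   g(A)    = ksyn Syn* + ktr (kN N + ktr A)/(ktr + d1m)
//             - (ktr + d1c) A - dR Cpx*(A).
// The last term is the net inducer consumption by receptor turnover.
// Stable branches are downward crossings of g; hysteresis appears when an
// ascending and a descending density sweep settle on different branches.
// Depending on whether kon A is small or large against (dR + koff) at the
// operating point, hysteresis is controlled by the binding/dissociation
// rates or by receptor production/decay - the two sensitivity regimes.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct UpcPars {
  double kR, dR, kon, koff, konP, koffP, kY, dY, kfb;
  double bS, dS, ksyn, ktr, d1m, d1c, kN;
};

static UpcPars upc_pars(const NumericVector& p) {
  if (p.size() != 16) stop("UPC parameter vector must have 16 elements");
  UpcPars u;
  u.kR = p[0]; u.dR = p[1]; u.kon = p[2]; u.koff = p[3];
  u.konP = p[4]; u.koffP = p[5]; u.kY = p[6]; u.dY = p[7]; u.kfb = p[8];
  u.bS = p[9]; u.dS = p[10]; u.ksyn = p[11]; u.ktr = p[12];
  u.d1m = p[13]; u.d1c = p[14]; u.kN = p[15];
  return u;
}

static inline double cpx_of_A(const UpcPars& u, double A) {
  return u.kon * A * (u.kR / u.dR) / (u.dR + u.koff + u.kon * A);
}

static inline double pB_of_A(const UpcPars& u, double A) {
  double cpx = cpx_of_A(u, A);
  double c2 = cpx * cpx;
  double KP = u.koffP / u.konP;
  return c2 / (c2 + KP);
}

static inline double g_of_A(const UpcPars& u, double A, double N) {
  double syn = (u.bS + u.kfb * pB_of_A(u, A)) / u.dS;
  return u.ksyn * syn + u.ktr * (u.kN * N + u.ktr * A) / (u.ktr + u.d1m) -
         (u.ktr + u.d1c) * A - u.dR * cpx_of_A(u, A);
}

// all stable steady states (downward crossings of g) for one density
static void stable_roots(const UpcPars& u, double N, std::vector<double>& out) {
  out.clear();
  double loss = (u.ktr + u.d1c) - u.ktr * u.ktr / (u.ktr + u.d1m);
  double Amax = 2.0 * (u.ksyn * (u.bS + u.kfb) / u.dS +
                       u.ktr * u.kN * N / (u.ktr + u.d1m)) / loss + 1e-9;
  const int M = 240;
  double lo = 1e-9;
  double prev_A = lo, prev_g = g_of_A(u, lo, N);
  for (int i = 1; i <= M; ++i) {
    double A = lo * std::pow(Amax / lo, (double)i / M);
    double g = g_of_A(u, A, N);
    if (prev_g > 0 && g <= 0) {   // downward crossing: stable branch
      double a = prev_A, b = A;
      for (int it = 0; it < 60; ++it) {
        double m = 0.5 * (a + b);
        if (g_of_A(u, m, N) > 0) a = m; else b = m;
      }
      out.push_back(0.5 * (a + b));
    }
    prev_A = A; prev_g = g;
  }
  if (out.empty()) out.push_back(Amax);  // numerical guard; g(0) > 0 always
}

// [[Rcpp::export]]
List cpp_upc_transfer(NumericVector pars, NumericVector density,
                      bool ascending) {
  UpcPars u = upc_pars(pars);
  int n = density.size();
  NumericVector A_out(n), Y_out(n), pB_out(n);
  IntegerVector order(n);
  for (int i = 0; i < n; ++i) order[i] = ascending ? i : (n - 1 - i);
  std::vector<double> roots;
  double A_prev = -1.0;
  for (int k = 0; k < n; ++k) {
    int i = order[k];
    stable_roots(u, density[i], roots);
    double A;
    if (A_prev < 0) {
      // sweep entry: lowest branch ascending, highest branch descending
      A = ascending ? roots.front() : roots.back();
    } else {
      // continuation: stay on the branch nearest the previous state
      double best = 1e300;
      A = roots[0];
      for (double r : roots) {
        double d = std::fabs(std::log(r + 1e-12) - std::log(A_prev + 1e-12));
        if (d < best) { best = d; A = r; }
      }
    }
    A_prev = A;
    A_out[i] = A;
    pB_out[i] = pB_of_A(u, A);
    Y_out[i] = u.kY * pB_out[i] / u.dY;
  }
  return List::create(_["density"] = density, _["A"] = A_out,
                      _["pB"] = pB_out, _["output"] = Y_out);
}

// [[Rcpp::export]]
NumericVector cpp_upc_stable_branches(NumericVector pars, double density) {
  UpcPars u = upc_pars(pars);
  std::vector<double> roots;
  stable_roots(u, density, roots);
  return NumericVector(roots.begin(), roots.end());
}
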