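#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Direct-method Gillespie kernel over a compiled network representation.
//
// Propensity of reaction r at state x:
//   a_r(x) = rate[r] * prod_s ff(x[s], order[r,s]) * prod_hill h(x[s]; K, n)
// where ff is the falling factorial (mass-action combinatorics; order 1 is
// the plain count) and h is a Hill activation x^n/(K^n+x^n) or repression
// 1/(1+(x/K)^n) factor. Reactions with all-zero order rows are zero-order
// (constitutive) and carry no count factor.

struct HillTerm {
  int species;
  double K, n;
  bool repress;
};

struct CompiledReaction {
  double rate;
  std::vector<int> dep_species;   // species with order > 0
  std::vector<int> dep_order;
  std::vector<HillTerm> hill;
};

static inline double hill_factor(const HillTerm &h, double x) {
  double u;
  if (h.n == 2.0) {
    double r = x / h.K;
    u = r * r;
  } else {
    u = std::pow(x / h.K, h.n);
  }
  return h.repress ? 1.0 / (1.0 + u) : u / (1.0 + u);
}

static inline double propensity(const CompiledReaction &cr,
                                const std::vector<double> &x) {
  double a = cr.rate;
  for (size_t i = 0; i < cr.dep_species.size(); ++i) {
    double c = x[cr.dep_species[i]];
    int m = cr.dep_order[i];
    for (int k = 0; k < m; ++k) a *= (c - k > 0.0 ? c - k : 0.0);
  }
  for (size_t i = 0; i < cr.hill.size(); ++i)
    a *= hill_factor(cr.hill[i], x[cr.hill[i].species]);
  return a;
}

static std::vector<CompiledReaction> compile_reactions(
    const NumericVector &rate, const IntegerMatrix &order,
    const NumericMatrix &hill) {
  int n_r = rate.size(), n_s = order.ncol();
  std::vector<CompiledReaction> out(n_r);
  for (int r = 0; r < n_r; ++r) {
    out[r].rate = rate[r];
    for (int s = 0; s < n_s; ++s) {
      if (order(r, s) > 0) {
        out[r].dep_species.push_back(s);
        out[r].dep_order.push_back(order(r, s));
      }
    }
  }
  for (int i = 0; i < hill.nrow(); ++i) {
    HillTerm h;
    h.species = (int)hill(i, 1) - 1;
    h.K = hill(i, 2);
    h.n = hill(i, 3);
    h.repress = hill(i, 4) != 0.0;
    out[(int)hill(i, 0) - 1].hill.push_back(h);
  }
  return out;
}

// One SSA run; returns the state at t_end. Uses R's RNG (honours set.seed()).
// [[Rcpp::export]]
IntegerVector ssa_endpoint_cpp(IntegerVector init, IntegerMatrix stoich,
                               NumericVector rate, IntegerMatrix order,
                               NumericMatrix hill, double t_end) {
  int n_s = init.size(), n_r = rate.size();
  std::vector<CompiledReaction> cr = compile_reactions(rate, order, hill);
  std::vector<double> x(n_s);
  for (int s = 0; s < n_s; ++s) x[s] = init[s];
  std::vector<double> a(n_r);
  double t = 0.0;
  R_CheckUserInterrupt();
  long long iter = 0;
  while (true) {
    double a0 = 0.0;
    for (int r = 0; r < n_r; ++r) {
      a[r] = propensity(cr[r], x);
      if (!(a[r] >= 0.0) || !std::isfinite(a[r]))
        stop("propensity of reaction %d is negative or non-finite", r + 1);
      a0 += a[r];
    }
    if (a0 <= 0.0) break;  // frozen system: state holds until t_end
    t += -std::log(unif_rand()) / a0;
    if (t >= t_end) break;
    double u = unif_rand() * a0, cum = 0.0;
    int r = n_r - 1;
    for (int j = 0; j < n_r; ++j) {
      cum += a[j];
      if (u <= cum) { r = j; break; }
    }
    for (int s = 0; s < n_s; ++s) x[s] += stoich(r, s);
    if (++iter % 65536 == 0) R_CheckUserInterrupt();
  }
  IntegerVector out(n_s);
  for (int s = 0; s < n_s; ++s) out[s] = (int)x[s];
  return out;
}

// One SSA run recording every event (time, state) up to max_steps events.
// [[Rcpp::export]]
List ssa_trajectory_cpp(IntegerVector init, IntegerMatrix stoich,
                        NumericVector rate, IntegerMatrix order,
                        NumericMatrix hill, double t_end, int max_steps) {
  int n_s = init.size(), n_r = rate.size();
  std::vector<CompiledReaction> cr = compile_reactions(rate, order, hill);
  std::vector<double> x(n_s);
  for (int s = 0; s < n_s; ++s) x[s] = init[s];
  std::vector<double> a(n_r), times;
  std::vector<int> states;
  times.push_back(0.0);
  for (int s = 0; s < n_s; ++s) states.push_back((int)x[s]);
  double t = 0.0;
  bool truncated = false;
  while (true) {
    double a0 = 0.0;
    for (int r = 0; r < n_r; ++r) {
      a[r] = propensity(cr[r], x);
      if (!(a[r] >= 0.0) || !std::isfinite(a[r]))
        stop("propensity of reaction %d is negative or non-finite", r + 1);
      a0 += a[r];
    }
    if (a0 <= 0.0) break;
    t += -std::log(unif_rand()) / a0;
    if (t >= t_end) break;
    double u = unif_rand() * a0, cum = 0.0;
    int r = n_r - 1;
    for (int j = 0; j < n_r; ++j) {
      cum += a[j];
      if (u <= cum) { r = j; break; }
    }
    for (int s = 0; s < n_s; ++s) x[s] += stoich(r, s);
    times.push_back(t);
    for (int s = 0; s < n_s; ++s) states.push_back((int)x[s]);
    if ((int)times.size() > max_steps) { truncated = true; break; }
    if (times.size() % 65536 == 0) R_CheckUserInterrupt();
  }
  int n_t = times.size();
  IntegerMatrix sm(n_t, n_s);
  for (int i = 0; i < n_t; ++i)
    for (int s = 0; s < n_s; ++s) sm(i, s) = states[(size_t)i * n_s + s];
  IntegerVector endpoint(n_s);
  for (int s = 0; s < n_s; ++s) endpoint[s] = (int)x[s];
  return List::create(_["time"] = NumericVector(times.begin(), times.end()),
                      _["state"] = sm, _["endpoint"] = endpoint,
                      _["truncated"] = truncated);
}
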