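// Compiled inner loop of the deterministic lifecycle recursion.
//
// Genotype coding (fixed): index g in 0..5,
//   chromosome = g / 3 (0 noncoop, 1 coop), plasmid = g % 3 (0 none, 1 coopP, 2 defP).
//
// A generation is an expectation over multinomial founder compositions of the
// post-transfer, fitness-weighted patch output, normalised by mean fitness,
// followed by segregation loss, cooperator->defector mutation and global
// dispersal (complete mixing).  Compositions are enumerated over genotypes at
// nonzero frequency only; the enumeration is rebuilt whenever the active set
// changes (loss and transfer can re-activate genotypes, clamping can remove
// them).

#include <Rcpp.h>
#include <array>
#include <vector>
using namespace Rcpp;

static const double FREQ_CLAMP = 1e-15;

struct Comps {
  int mask = -1;                                // active-set bitmask
  std::vector<std::array<int, 6>> counts;       // founder counts per composition
  std::vector<double> lcoef;                    // log multinomial coefficients
  std::vector<int> act;                         // active genotype indices
};

static void enum_rec(std::vector<std::array<int, 6>> &out,
                     const std::vector<int> &act, std::array<int, 6> &cur,
                     int pos, int left) {
  if (pos == (int)act.size() - 1) {
    cur[act[pos]] = left;
    out.push_back(cur);
    cur[act[pos]] = 0;
    return;
  }
  for (int n = 0; n <= left; ++n) {
    cur[act[pos]] = n;
    enum_rec(out, act, cur, pos + 1, left - n);
    cur[act[pos]] = 0;
  }
}

static void build_comps(Comps &c, int mask, int N, const double *x) {
  c.mask = mask;
  c.act.clear();
  for (int g = 0; g < 6; ++g)
    if (mask & (1 << g)) c.act.push_back(g);
  c.counts.clear();
  std::array<int, 6> cur{};
  enum_rec(c.counts, c.act, cur, 0, N);
  c.lcoef.assign(c.counts.size(), 0.0);
  double lgN = std::lgamma(N + 1.0);
  for (size_t i = 0; i < c.counts.size(); ++i) {
    double l = lgN;
    for (int g : c.act) l -= std::lgamma(c.counts[i][g] + 1.0);
    c.lcoef[i] = l;
  }
  (void)x;
}

// One full generation; x (length 6) is replaced by the next state.
// Returns the population mean fitness of the survival episode.
static double step_once(double *x, int N, double beta, double s, double B,
                        double CG, double CC, double mu, Comps &comps) {
  int mask = 0;
  for (int g = 0; g < 6; ++g)
    if (x[g] > 0) mask |= (1 << g);
  if (mask != comps.mask) build_comps(comps, mask, N, x);

  double logx[6];
  for (int g : comps.act) logx[g] = std::log(x[g]);

  double contrib[6] = {0, 0, 0, 0, 0, 0};
  double wbar = 0.0;
  const size_t nc = comps.counts.size();
  for (size_t i = 0; i < nc; ++i) {
    const std::array<int, 6> &n = comps.counts[i];
    double lw = comps.lcoef[i];
    for (int g : comps.act) lw += n[g] * logx[g];
    double wgt = std::exp(lw);

    double f[6];
    for (int g = 0; g < 6; ++g) f[g] = (double)n[g] / N;

    // mass-action transfer within the patch
    double fC = f[1] + f[4], fD = f[2] + f[5], P = fC + fD;
    double post[6];
    for (int k = 0; k < 2; ++k) {
      int i0 = 3 * k;
      double f0 = f[i0];
      post[i0] = f0 * (1 - beta * P);
      post[i0 + 1] = f[i0 + 1] + beta * f0 * fC;
      post[i0 + 2] = f[i0 + 2] + beta * f0 * fD;
    }

    // public goods and survival
    double coopfrac = post[1] + post[3] + post[4] + post[5];
    double base = 1 + B * coopfrac;
    double w[6];
    for (int g = 0; g < 6; ++g) {
      bool coop = (g >= 3) || (g % 3 == 1);
      bool bearer = (g % 3) != 0;
      w[g] = base - (coop ? CG : 0.0) - (bearer ? CC : 0.0);
    }
    double patchsum = 0.0;
    for (int g = 0; g < 6; ++g) patchsum += post[g] * w[g];
    for (int g = 0; g < 6; ++g) contrib[g] += wgt * post[g] * w[g];
    wbar += wgt * patchsum;
  }
  if (!(wbar > 0)) stop("non-positive population mean fitness");

  double nxt[6];
  for (int g = 0; g < 6; ++g) nxt[g] = contrib[g] / wbar;

  // segregation loss, then cooperator->defector mutation
  for (int k = 0; k < 2; ++k) {
    int i0 = 3 * k;
    double lost = s * (nxt[i0 + 1] + nxt[i0 + 2]);
    nxt[i0] += lost;
    nxt[i0 + 1] *= (1 - s);
    nxt[i0 + 2] *= (1 - s);
    double d = mu * nxt[i0 + 1];
    nxt[i0 + 1] -= d;
    nxt[i0 + 2] += d;
  }

  double tot = 0.0;
  for (int g = 0; g < 6; ++g) {
    if (nxt[g] < FREQ_CLAMP) nxt[g] = 0.0;
    tot += nxt[g];
  }
  for (int g = 0; g < 6; ++g) x[g] = nxt[g] / tot;
  return wbar;
}

// [[Rcpp::export]]
List cpp_generation_step(NumericVector state, int N, double beta, double s,
                         double B, double CG, double CC, double mu) {
  double x[6];
  for (int g = 0; g < 6; ++g) x[g] = state[g];
  Comps comps;
  double wbar = step_once(x, N, beta, s, B, CG, CC, mu, comps);
  NumericVector out(6);
  for (int g = 0; g < 6; ++g) out[g] = x[g];
  return List::create(_["state"] = out, _["mean_fitness"] = wbar);
}

// [[Rcpp::export]]
NumericMatrix cpp_run_recursion(NumericVector state, int N, double beta,
                                double s, double B, double CG, double CC,
                                double mu, int generations) {
  NumericMatrix out(generations + 1, 7);
  double x[6];
  for (int g = 0; g < 6; ++g) x[g] = state[g];
  for (int g = 0; g < 6; ++g) out(0, g) = x[g];
  out(0, 6) = NA_REAL;
  Comps comps;
  for (int t = 1; t <= generations; ++t) {
    double wbar = step_once(x, N, beta, s, B, CG, CC, mu, comps);
    for (int g = 0; g < 6; ++g) out(t, g) = x[g];
    out(t, 6) = wbar;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_iterate(NumericVector state, int N, double beta, double s, double B,
                 double CG, double CC, double mu, double tol, int max_gen,
                 int consec_required) {
  double x[6], prev[6];
  for (int g = 0; g < 6; ++g) x[g] = state[g];
  Comps comps;
  int consec = 0, t = 0;
  double delta = R_PosInf, wbar = NA_REAL;
  while (t < max_gen) {
    for (int g = 0; g < 6; ++g) prev[g] = x[g];
    wbar = step_once(x, N, beta, s, B, CG, CC, mu, comps);
    ++t;
    delta = 0.0;
    for (int g = 0; g < 6; ++g) {
      double d = std::fabs(x[g] - prev[g]);
      if (d > delta) delta = d;
    }
    consec = (delta < tol) ? consec + 1 : 0;
    if (consec >= consec_required) break;
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  NumericVector out(6);
  for (int g = 0; g < 6; ++g) out[g] = x[g];
  return List::create(_["state"] = out, _["generations"] = t,
                      _["converged"] = (consec >= consec_required),
                      _["max_delta"] = delta, _["mean_fitness"] = wbar);
}
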