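// Compiled inner loops: Gillespie direct method and Euler-Maruyama.
// Both consume R's RNG stream (set.seed on the R side gives reproducibility).
#include <Rcpp.h>
using namespace Rcpp;

// count-form rate vector layout (see count_rates()):
enum { B1, B2, D1, D2, BETA, MU_A, MU_F, D_F, LAM_IN, D_IN, ALPHA, P1, P2,
       LAM_R, D_R, RHO1, RHO2, RHO3, D_N, D_A, DELTA, SIG1, SIG2, D_I,
       OMEGA };

static inline void props17(const double *n, const double *r, double *q) {
  q[0]  = r[B1] * n[0] + r[B2] * n[0] * n[0];
  q[1]  = r[D1] * n[0] + r[D2] * n[0] * n[0] + r[MU_A] * n[0] * n[5];
  q[2]  = r[BETA] * n[0] * n[1];
  q[3]  = r[LAM_IN];
  q[4]  = r[D_IN] * n[2];
  double act = r[ALPHA] * n[1] * n[2];
  q[5]  = r[P1] * act;
  q[6]  = r[P2] * act;
  q[7]  = (1.0 - r[P1] - r[P2]) * act;
  q[8]  = (r[D_F] + r[MU_F] * n[4] + r[MU_A] * n[5]) * n[1];
  q[9]  = r[LAM_R] + r[RHO1] * n[3] * n[6];
  q[10] = r[D_R] * n[3];
  q[11] = r[RHO2] * n[4] * n[6];
  q[12] = r[D_N] * n[4];
  q[13] = r[RHO3] * n[5] * n[6];
  q[14] = (r[D_A] + r[DELTA] * n[3]) * n[5];
  q[15] = r[SIG1] * n[4] + r[SIG2] * n[5];
  q[16] = r[D_I] * n[6];
}

// stoichiometry: reaction j changes compartment sub1[j] by sgn1[j], and
// (optionally) sub2[j] by +1 (the conversion reactions 3,6,7,8).
static const int sub1[17] = {0,0,0,2,2,2,2,2,1,3,3,4,4,5,5,6,6};
static const int sgn1[17] = {1,-1,-1,1,-1,-1,-1,-1,-1,1,-1,1,-1,1,-1,1,-1};
static const int sub2[17] = {-1,-1,1,-1,-1,3,4,5,-1,-1,-1,-1,-1,-1,-1,-1,-1};

// [[Rcpp::export]]
List cpp_ssa_grid(NumericVector n0, NumericVector rates,
                  NumericVector times) {
  const int K = times.size();
  NumericMatrix states(K, 7);
  double n[7], q[17];
  const double *r = REAL(rates);
  for (int i = 0; i < 7; ++i) n[i] = n0[i];
  double t = 0.0;
  int k = 0;
  const double tend = times[K - 1];
  while (true) {
    props17(n, r, q);
    double tot = 0.0;
    for (int j = 0; j < 17; ++j) tot += q[j];
    double tnext = (tot > 0.0) ? t + exp_rand() / tot : R_PosInf;
    while (k < K && times[k] <= tnext) {       // state holds until tnext
      for (int i = 0; i < 7; ++i) states(k, i) = n[i];
      ++k;
    }
    if (k >= K || tnext > tend || !R_FINITE(tnext)) break;
    t = tnext;
    double u = unif_rand() * tot, acc = 0.0;
    int j = 0;
    for (; j < 16; ++j) { acc += q[j]; if (u <= acc) break; }
    n[sub1[j]] += sgn1[j];
    if (sub2[j] >= 0) n[sub2[j]] += 1.0;
  }
  return List::create(_["states"] = states);
}

// [[Rcpp::export]]
List cpp_ssa_events(NumericVector n0, NumericVector rates, double t_max,
                    int max_events) {
  std::vector<double> tt;
  std::vector<int> rj;
  std::vector<double> st;
  double n[7], q[17];
  const double *r = REAL(rates);
  for (int i = 0; i < 7; ++i) n[i] = n0[i];
  tt.push_back(0.0);
  rj.push_back(0);
  for (int i = 0; i < 7; ++i) st.push_back(n[i]);
  double t = 0.0;
  while ((int)tt.size() - 1 < max_events) {
    props17(n, r, q);
    double tot = 0.0;
    for (int j = 0; j < 17; ++j) tot += q[j];
    if (tot <= 0.0) break;
    t += exp_rand() / tot;
    if (t > t_max) break;
    double u = unif_rand() * tot, acc = 0.0;
    int j = 0;
    for (; j < 16; ++j) { acc += q[j]; if (u <= acc) break; }
    n[sub1[j]] += sgn1[j];
    if (sub2[j] >= 0) n[sub2[j]] += 1.0;
    tt.push_back(t);
    rj.push_back(j + 1);
    for (int i = 0; i < 7; ++i) st.push_back(n[i]);
  }
  const int m = tt.size();
  NumericMatrix states(m, 7);
  for (int a = 0; a < m; ++a)
    for (int i = 0; i < 7; ++i) states(a, i) = st[(size_t)a * 7 + i];
  return List::create(_["times"] = wrap(tt), _["states"] = states,
                      _["reactions"] = wrap(rj));
}

// [[Rcpp::export]]
List cpp_em_grid(NumericVector y0, NumericVector rates, NumericVector times,
                 double dt, double noise_scale) {
  const int K = times.size();
  NumericMatrix states(K, 7);
  double y[7], q[17], mu[7];
  const double *r = REAL(rates);
  for (int i = 0; i < 7; ++i) y[i] = y0[i];
  const double tend = times[K - 1];
  const double sq = std::sqrt(dt);
  double t = 0.0;
  int k = 0;
  double blowup = -1.0;
  while (k < K && times[k] <= t) {
    for (int i = 0; i < 7; ++i) states(k, i) = y[i];
    ++k;
  }
  while (k < K && t < tend) {
    props17(y, r, q);
    mu[0] = q[0] - q[1] - q[2];
    mu[1] = q[2] - q[8];
    mu[2] = q[3] - q[4] - q[5] - q[6] - q[7];
    mu[3] = q[5] + q[9] - q[10];
    mu[4] = q[6] + q[11] - q[12];
    mu[5] = q[7] + q[13] - q[14];
    mu[6] = q[15] - q[16];
    if (noise_scale != 0.0) {
      const double w1 = norm_rand() * sq, w2 = norm_rand() * sq,
                   w3 = norm_rand() * sq, w4 = norm_rand() * sq,
                   w5 = norm_rand() * sq, w6 = norm_rand() * sq,
                   w7 = norm_rand() * sq, w8 = norm_rand() * sq,
                   w9 = norm_rand() * sq, w10 = norm_rand() * sq,
                   w11 = norm_rand() * sq;
      const double s = noise_scale;
      y[0] += mu[0] * dt + s * (std::sqrt(q[0] + q[1]) * w1 -
                                std::sqrt(q[2]) * w2);
      y[1] += mu[1] * dt + s * (std::sqrt(q[2]) * w2 +
                                std::sqrt(q[8]) * w3);
      y[2] += mu[2] * dt + s * (std::sqrt(q[3] + q[4]) * w4 -
                                std::sqrt(q[5]) * w5 -
                                std::sqrt(q[6]) * w6 -
                                std::sqrt(q[7]) * w7);
      y[3] += mu[3] * dt + s * (std::sqrt(q[5]) * w5 +
                                std::sqrt(q[9] + q[10]) * w8);
      y[4] += mu[4] * dt + s * (std::sqrt(q[6]) * w6 +
                                std::sqrt(q[11] + q[12]) * w9);
      y[5] += mu[5] * dt + s * (std::sqrt(q[7]) * w7 +
                                std::sqrt(q[13] + q[14]) * w10);
      y[6] += mu[6] * dt + s * std::sqrt(q[15] + q[16]) * w11;
    } else {
      for (int i = 0; i < 7; ++i) y[i] += mu[i] * dt;
    }
    bool bad = false;
    for (int i = 0; i < 7; ++i) {
      if (!R_FINITE(y[i])) bad = true;
      if (y[i] < 0.0) y[i] = 0.0;                 // reflecting clamp at zero
    }
    t += dt;
    if (bad) { blowup = t; break; }
    while (k < K && times[k] <= t + 1e-12) {
      for (int i = 0; i < 7; ++i) states(k, i) = y[i];
      ++k;
    }
  }
  return List::create(_["states"] = states, _["blowup"] = blowup);
}
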