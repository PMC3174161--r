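// Beeler-Reuter-Pumir (BRP) neonatal myocyte kinetics and explicit tissue
// stepping.  The BRP cell is the 1977 Beeler-Reuter ventricular model with
// reduced fast- and slow-inward maximum permeabilities and a suppressed
// inward rectifier; the excitability parameter `alpha` scales the rectifier
// further as k_K1_base * (1 - alpha).
//
// State layout everywhere: V, Ca, m, h, j, d, f, x1  (voltage mV, calcium
// in model units, six Hodgkin-Huxley gates).  Gate updates use the
// Rush-Larsen exponential scheme, so gates stay in [0,1] for any dt.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double V_MIN = -120.0, V_MAX = 80.0;

// Beeler-Reuter generic rate function
//   C(V) = (c1*exp(c2*(V+c3)) + c4*(V+c5)) / (exp(c6*(V+c3)) + c7)
// with the removable singularity of alpha_m handled explicitly.
struct RateCoef { double c1, c2, c3, c4, c5, c6, c7; };

// order: m, h, j, d, f, x1; (alpha, beta) pairs
static const RateCoef RC[12] = {
  {0.0,   0.0,    47.0, -1.0, 47.0, -0.1,   -1.0}, // alpha_m
  {40.0, -0.056,  72.0,  0.0,  0.0,  0.0,    0.0}, // beta_m
  {0.126,-0.25,   77.0,  0.0,  0.0,  0.0,    0.0}, // alpha_h
  {1.7,   0.0,    22.5,  0.0,  0.0, -0.082,  1.0}, // beta_h
  {0.055,-0.25,   78.0,  0.0,  0.0, -0.2,    1.0}, // alpha_j
  {0.3,   0.0,    32.0,  0.0,  0.0, -0.1,    1.0}, // beta_j
  {0.095,-0.01,   -5.0,  0.0,  0.0, -0.072,  1.0}, // alpha_d
  {0.07, -0.017,  44.0,  0.0,  0.0,  0.05,   1.0}, // beta_d
  {0.012,-0.008,  28.0,  0.0,  0.0,  0.15,   1.0}, // alpha_f
  {0.0065,-0.02,  30.0,  0.0,  0.0, -0.2,    1.0}, // beta_f
  {0.0005, 0.083, 50.0,  0.0,  0.0,  0.057,  1.0}, // alpha_x1
  {0.0013,-0.06,  20.0,  0.0,  0.0, -0.04,   1.0}  // beta_x1
};

static inline double rate_fun(int k, double V) {
  if (k == 0) { // alpha_m: -(V+47)/(exp(-0.1(V+47)) - 1)
    double x = V + 47.0;
    if (std::fabs(x) < 1e-7) return 10.0;
    return -x / (std::exp(-0.1 * x) - 1.0);
  }
  const RateCoef &r = RC[k];
  double num = 0.0;
  if (r.c1 != 0.0) num += r.c1 * std::exp(r.c2 * (V + r.c3));
  if (r.c4 != 0.0) num += r.c4 * (V + r.c5);
  double den = r.c7;
  if (r.c6 != 0.0) den += std::exp(r.c6 * (V + r.c3));
  else den += 1.0;
  return num / den;
}

// Unscaled Beeler-Reuter inward rectifier (time independent)
static inline double ik1_br(double V) {
  double t1 = 4.0 * (std::exp(0.04 * (V + 85.0)) - 1.0) /
              (std::exp(0.08 * (V + 53.0)) + std::exp(0.04 * (V + 53.0)));
  double x = 0.04 * (V + 23.0);
  double t2 = (std::fabs(x) < 1e-7) ? 5.0
              : 0.2 * (V + 23.0) / (1.0 - std::exp(-x));
  return 0.35 * (t1 + t2);
}

// voltage-dependent factor of i_x1 (multiplied by gate x1)
static inline double ix1_coef(double V) {
  return 0.8 * (std::exp(0.04 * (V + 77.0)) - 1.0) / std::exp(0.04 * (V + 35.0));
}

// ---- exported scalar/vector kinetics (reference + tables) ------------------

// [[Rcpp::export]]
NumericMatrix brp_rates_cpp(NumericVector V) {
  int n = V.size();
  NumericMatrix out(n, 12);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 12; ++k) out(i, k) = rate_fun(k, V[i]);
  colnames(out) = CharacterVector::create(
    "alpha_m","beta_m","alpha_h","beta_h","alpha_j","beta_j",
    "alpha_d","beta_d","alpha_f","beta_f","alpha_x1","beta_x1");
  return out;
}

// [[Rcpp::export]]
NumericVector ik1_br_cpp(NumericVector V) {
  int n = V.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = ik1_br(V[i]);
  return out;
}

// Full right-hand side of one BRP cell.  params: gNa, gNaC, ENa, gs, kK1,
// alpha.  Returns d/dt of (V, Ca, m, h, j, d, f, x1).
// [[Rcpp::export]]
NumericVector cell_rhs_cpp(NumericVector state, NumericVector params,
                           double Iext) {
  double V = state[0], Ca = state[1];
  double gNa = params[0], gNaC = params[1], ENa = params[2],
         gs = params[3], kK1 = params[4], alpha = params[5];
  if (!R_finite(V) || !R_finite(Ca) || Ca <= 0.0)
    stop("non-finite or non-positive state in cell_rhs");
  double m = state[2], h = state[3], j = state[4],
         d = state[5], f = state[6], x1 = state[7];
  double iK1 = kK1 * (1.0 - alpha) * ik1_br(V);
  double ix1 = x1 * ix1_coef(V);
  double iNa = (gNa * m * m * m * h * j + gNaC) * (V - ENa);
  double Es  = -82.3 - 13.0287 * std::log(Ca);
  double is  = gs * d * f * (V - Es);
  NumericVector out(8);
  out[0] = -(iK1 + ix1 + iNa + is) + Iext;
  out[1] = -1e-7 * is + 0.07 * (1e-7 - Ca);
  double g[6] = {m, h, j, d, f, x1};
  for (int k = 0; k < 6; ++k) {
    double a = rate_fun(2 * k, V), b = rate_fun(2 * k + 1, V);
    out[2 + k] = a * (1.0 - g[k]) - b * g[k];
  }
  return out;
}

// ---- rate tables -----------------------------------------------------------

// Table over V in [V_MIN, V_MAX]; columns: for each gate, exp(-dt*(a+b)) and
// ginf, then ik1_br(V), ix1_coef(V).  Linear interpolation.
struct RateTable {
  double v0, dv;
  int n;
  std::vector<double> egate[6], ginf[6], ik1, ix1c;
  void build(double dt, int npts) {
    n = npts; v0 = V_MIN; dv = (V_MAX - V_MIN) / (n - 1);
    for (int k = 0; k < 6; ++k) { egate[k].resize(n); ginf[k].resize(n); }
    ik1.resize(n); ix1c.resize(n);
    for (int i = 0; i < n; ++i) {
      double V = v0 + i * dv;
      for (int k = 0; k < 6; ++k) {
        double a = rate_fun(2 * k, V), b = rate_fun(2 * k + 1, V);
        egate[k][i] = std::exp(-dt * (a + b));
        ginf[k][i]  = a / (a + b);
      }
      ik1[i]  = ik1_br(V);
      ix1c[i] = ix1_coef(V);
    }
  }
};

static inline double lerp(const std::vector<double> &t, double w, int i) {
  return t[i] + w * (t[i + 1] - t[i]);
}

// ---- single-cell integration ----------------------------------------------

// Integrate one cell with Rush-Larsen gates / forward-Euler V and Ca.
// Iext: external current, applied on [t_on, t_off).  Records every `stride`
// steps.  Returns list(state, trace) where trace is (nrec x 9): t + state.
// [[Rcpp::export]]
List cell_run_cpp(NumericVector state0, NumericVector params, double dt,
                  int nsteps, double Iamp, double t_on, double t_off,
                  int stride) {
  double gNa = params[0], gNaC = params[1], ENa = params[2],
         gs = params[3], kK1 = params[4], alpha = params[5];
  double kk = kK1 * (1.0 - alpha);
  double V = state0[0], Ca = state0[1];
  double g[6] = {state0[2], state0[3], state0[4], state0[5], state0[6],
                 state0[7]};
  int nrec = (stride > 0) ? nsteps / stride + 1 : 0;
  NumericMatrix trace(nrec > 0 ? nrec : 1, 9);
  int ir = 0;
  for (int s = 0; s <= nsteps; ++s) {
    if (stride > 0 && s % stride == 0 && ir < nrec) {
      trace(ir, 0) = s * dt;
      trace(ir, 1) = V; trace(ir, 2) = Ca;
      for (int k = 0; k < 6; ++k) trace(ir, 3 + k) = g[k];
      ++ir;
    }
    if (s == nsteps) break;
    double t = s * dt;
    double Iext = (t >= t_on && t < t_off) ? Iamp : 0.0;
    if (V < V_MIN || V > V_MAX || !R_finite(V))
      stop("voltage out of [-120, 80] mV at step %d (V = %g)", s, V);
    double iK1 = kk * ik1_br(V);
    double ix1 = g[5] * ix1_coef(V);
    double iNa = (gNa * g[0] * g[0] * g[0] * g[1] * g[2] + gNaC) * (V - ENa);
    double Es  = -82.3 - 13.0287 * std::log(Ca);
    double is  = gs * g[3] * g[4] * (V - Es);
    double Vn  = V + dt * (-(iK1 + ix1 + iNa + is) + Iext);
    double Can = Ca + dt * (-1e-7 * is + 0.07 * (1e-7 - Ca));
    for (int k = 0; k < 6; ++k) {
      double a = rate_fun(2 * k, V), b = rate_fun(2 * k + 1, V);
      double gi = a / (a + b);
      g[k] = gi + (g[k] - gi) * std::exp(-dt * (a + b));
    }
    V = Vn; Ca = Can;
  }
  NumericVector out(8);
  out[0] = V; out[1] = Ca;
  for (int k = 0; k < 6; ++k) out[2 + k] = g[k];
  colnames(trace) = CharacterVector::create("t", "V", "Ca", "m", "h", "j",
                                            "d", "f", "x1");
  return List::create(_["state"] = out, _["trace"] = trace);
}

// ---- tissue stepping -------------------------------------------------------

// One chunk of explicit steps on an nx x ny x nz grid (nz = 1 for 2D).
// fields: list of 8 numeric arrays (V, Ca, m, h, j, d, f, x1), column-major
// with x fastest.  D, alphav: per-cell diffusivity (mm^2/ms) and
// excitability.  Interface conductance: arithmetic mean, but 0 whenever
// either side has D <= 0 (full isolation of uncoupled cells).  No-flux outer
// boundaries.  E adds an advection term E * dV/dx (central differences,
// reflecting ghosts).  stim: per-cell current added to dV/dt while
// stim_on != 0.  probes: 0-based linear indices whose V is recorded every
// step.  Modifies fields in place (they are duplicated on the R side).
// [[Rcpp::export]]
List tissue_run_cpp(List fields, NumericVector D, NumericVector alphav,
                    int nx, int ny, int nz, double h, double dt, int nsteps,
                    NumericVector params, double E, NumericVector stim,
                    int stim_on, IntegerVector probes) {
  NumericVector Vr = fields["V"], Car = fields["Ca"];
  NumericVector Gr[6] = {fields["m"], fields["h"], fields["j"],
                         fields["d"], fields["f"], fields["x1"]};
  const int N = nx * ny * nz;
  if (Vr.size() != N || D.size() != N || alphav.size() != N)
    stop("field/grid size mismatch");
  const bool use_stim = (stim_on != 0) && (stim.size() == N);
  const double gNa = params[0], gNaC = params[1], ENa = params[2],
               gs = params[3], kK1 = params[4];
  const double inv2h = 1.0 / (2.0 * h);
  const int sx = 1, sy = nx, sz = nx * ny;

  double *V = REAL(Vr), *Ca = REAL(Car);
  double *G[6];
  for (int q = 0; q < 6; ++q) G[q] = REAL(Gr[q]);
  const double *Dp = REAL(D), *stimp = use_stim ? REAL(stim) : nullptr;

  RateTable tab;
  tab.build(dt, 4001);
  const double inv_dv = 1.0 / tab.dv;
  const double *t_ik1 = tab.ik1.data(), *t_ix1 = tab.ix1c.data();
  const double *t_eg[6], *t_gi[6];
  for (int q = 0; q < 6; ++q) {
    t_eg[q] = tab.egate[q].data();
    t_gi[q] = tab.ginf[q].data();
  }

  std::vector<double> Vold(N);
  // per-cell rectifier scale (alpha frozen within the chunk) and interface
  // conductances, premultiplied by dt/h^2; gx[id] couples id and id+sx, 0 on
  // boundary faces or when either side is uncoupled (D <= 0)
  std::vector<double> kk(N), gxv(N, 0.0), gyv(N, 0.0), gzv(N, 0.0);
  const double dth2 = 1.0 / (h * h);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int id = i + j * sy + k * sz;
        kk[id] = kK1 * (1.0 - alphav[id]);
        double Di = Dp[id];
        if (Di <= 0.0) continue;
        if (i < nx - 1 && Dp[id + sx] > 0.0)
          gxv[id] = 0.5 * (Di + Dp[id + sx]) * dth2;
        if (j < ny - 1 && Dp[id + sy] > 0.0)
          gyv[id] = 0.5 * (Di + Dp[id + sy]) * dth2;
        if (nz > 1 && k < nz - 1 && Dp[id + sz] > 0.0)
          gzv[id] = 0.5 * (Di + Dp[id + sz]) * dth2;
      }
  const double *gx = gxv.data(), *gy = gyv.data(), *gz = gzv.data();

  int np = probes.size();
  NumericMatrix ptrace((np > 0) ? nsteps : 0, np);

  for (int s = 0; s < nsteps; ++s) {
    std::copy(V, V + N, Vold.begin());
    const double *vo = Vold.data();
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        const int base = j * sy + k * sz;
        for (int i = 0; i < nx; ++i) {
          const int id = base + i;
          const double v = vo[id];
          if (!(v >= V_MIN && v <= V_MAX))
            stop("voltage out of bounds at step %d, cell (%d,%d,%d): V = %g",
                 s, i + 1, j + 1, k + 1, v);
          double w = (v - tab.v0) * inv_dv;
          int iv = (int)w; if (iv > tab.n - 2) iv = tab.n - 2;
          w -= iv;
          double cup = 0.0;
          if (i > 0)      cup += gx[id - sx] * (vo[id - sx] - v);
          if (i < nx - 1) cup += gx[id]      * (vo[id + sx] - v);
          if (j > 0)      cup += gy[id - sy] * (vo[id - sy] - v);
          if (j < ny - 1) cup += gy[id]      * (vo[id + sy] - v);
          if (nz > 1) {
            if (k > 0)      cup += gz[id - sz] * (vo[id - sz] - v);
            if (k < nz - 1) cup += gz[id]      * (vo[id + sz] - v);
          }
          double adv = 0.0;
          if (E != 0.0) {
            const int ip = (i < nx - 1) ? id + sx : id - sx;
            const int im = (i > 0) ? id - sx : id + sx;
            adv = E * (vo[ip] - vo[im]) * inv2h;
          }
          const double m = G[0][id], hh = G[1][id], jj = G[2][id];
          const double iK1 = kk[id] * (t_ik1[iv] + w * (t_ik1[iv+1] - t_ik1[iv]));
          const double ix1 = G[5][id] * (t_ix1[iv] + w * (t_ix1[iv+1] - t_ix1[iv]));
          const double iNa = (gNa * m * m * m * hh * jj + gNaC) * (v - ENa);
          const double Es  = -82.3 - 13.0287 * std::log(Ca[id]);
          const double is  = gs * G[3][id] * G[4][id] * (v - Es);
          double dV  = -(iK1 + ix1 + iNa + is) + cup + adv;
          if (use_stim) dV += stimp[id];
          V[id]  = v + dt * dV;
          Ca[id] = Ca[id] + dt * (-1e-7 * is + 0.07 * (1e-7 - Ca[id]));
          for (int q = 0; q < 6; ++q) {
            const double gi = t_gi[q][iv] + w * (t_gi[q][iv+1] - t_gi[q][iv]);
            const double eg = t_eg[q][iv] + w * (t_eg[q][iv+1] - t_eg[q][iv]);
            G[q][id] = gi + (G[q][id] - gi) * eg;
          }
        }
      }
    for (int p = 0; p < np; ++p) ptrace(s, p) = V[probes[p]];
  }
  return List::create(_["fields"] = fields, _["probe_V"] = ptrace);
}
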