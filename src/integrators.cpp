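#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Parameter vector layout shared with R side (see circuit_params()):
// [0]=a [1]=a1 [2]=b [3]=b1 [4]=b2 [5]=A [6]=R [7]=k [8]=S [9]=n [10]=k_selfact
// Model codes: 1 = MRSA, 2 = SA, 3 = MR, 4 = MRSA_CROSS.

// fast integer power (Hill coefficients are small integers)
static inline double powi(double u, int n) {
  double r = 1.0;
  while (n) { if (n & 1) r *= u; u *= u; n >>= 1; }
  return r;
}

static inline double hillA(double u, double Sn, int n) {
  if (u <= 0.0) return 0.0;
  double un = powi(u, n);
  return un / (Sn + un);
}

static inline void drift_xy(int model, const double* p, double X, double Y,
                            double M1, double M2, double& fx, double& fy) {
  const double a = p[0], a1 = p[1], b = p[2], b1 = p[3], b2 = p[4];
  const double A = p[5], R = p[6], k = p[7], S = p[8], ks = p[10];
  const int n = (int)(p[9] + 0.5);
  const double Sn = powi(S, n);
  const double hx = hillA(X, Sn, n), hy = hillA(Y, Sn, n);
  const double gx = 1.0 - hx, gy = 1.0 - hy;
  const double hm1 = hillA(M1, Sn, n);
  switch (model) {
  case 1: // mutual repression + self-activation, one shared morphogen input
    fx = a * (b / A + hx) * (1.0 - R + R * gy) + a1 * hm1 - k * X;
    fy = a * (b + hy) * (1.0 - R + R * gx) + a1 * hm1 - k * Y;
    break;
  case 2: // self-activation on Y only; X keeps the printed Y->X repression
    fx = a * b1 * (1.0 - R + R * gy) + a1 * hm1 - k * X;
    fy = a * (b2 + ks * hy) + a1 * hm1 - k * Y;
    break;
  case 3: // pure mutual repression
    fx = a * (b / A) * (1.0 - R + R * gy) + a1 * hm1 - k * X;
    fy = a * b * (1.0 - R + R * gx) + a1 * hm1 - k * Y;
    break;
  default: { // MRSA with independent morphogen inputs M1 -> X, M2 -> Y
    const double hm2 = hillA(M2, Sn, n);
    fx = a * (b / A + hx) * (1.0 - R + R * gy) + a1 * hm1 - k * X;
    fy = a * (b + hy) * (1.0 - R + R * gx) + a1 * hm2 - k * Y;
  }
  }
}

// [[Rcpp::export(name = ".cpp_drift")]]
List cpp_drift(int model, NumericVector params, NumericVector X, NumericVector Y,
               NumericVector M1, NumericVector M2) {
  R_xlen_t nn = X.size();
  NumericVector fx(nn), fy(nn);
  for (R_xlen_t i = 0; i < nn; ++i) {
    double a, b;
    drift_xy(model, params.begin(), X[i], Y[i],
             M1[i % M1.size()], M2[i % M2.size()], a, b);
    fx[i] = a; fy[i] = b;
  }
  return List::create(_["fx"] = fx, _["fy"] = fy);
}

// Euler-Maruyama on the cell grid. Morphogen values are piecewise-constant in
// time between the field's rows. In per-column mode all rows of the tissue
// share a column's (pre-realized) field value; in per-cell mode each cell
// senses the column's deterministic level with its own multiplicative noise
// max(0, 1 + m_eps * xi), redrawn at every morphogen time step.
// Multiplicative gene noise d*x*dW per cell and gene. Uses R's RNG.
// [[Rcpp::export(name = ".cpp_simulate_tissue")]]
List cpp_simulate_tissue(int model, NumericVector params,
                         NumericMatrix M1field, NumericMatrix M2field,
                         NumericVector m_times,
                         NumericMatrix X0, NumericMatrix Y0,
                         double d, double dt, NumericVector save_times,
                         bool per_cell, double m_eps) {
  const int nr = X0.nrow(), nc = X0.ncol();
  const int n_save = save_times.size();
  const int n_mt = m_times.size();
  std::vector<double> X(X0.begin(), X0.end()), Y(Y0.begin(), Y0.end());
  std::vector<double> Mc1(nr * nc), Mc2(nr * nc);
  NumericVector Xout(n_save * nr * nc), Yout(n_save * nr * nc);
  const double t_end = save_times[n_save - 1];
  const long n_steps = (long)std::ceil(t_end / dt - 1e-9);
  const double sdt = std::sqrt(dt);
  int isave = 0, imt = -1;
  double fx, fy;
  RNGScope scope;
  // save_times[i] == 0 allowed: snapshot initial state
  while (isave < n_save && save_times[isave] <= 1e-12) {
    for (int j = 0; j < nr * nc; ++j) {
      Xout[isave + n_save * j] = X[j];
      Yout[isave + n_save * j] = Y[j];
    }
    ++isave;
  }
  for (long s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    int imt_new = imt < 0 ? 0 : imt;
    while (imt_new + 1 < n_mt && m_times[imt_new + 1] <= t) ++imt_new;
    if (imt_new != imt) {
      imt = imt_new;
      for (int c = 0; c < nc; ++c) {
        const double m1 = M1field(imt % M1field.nrow(), c);
        const double m2 = M2field(imt % M2field.nrow(), c);
        for (int r = 0; r < nr; ++r) {
          const int j = r + nr * c;
          if (per_cell) {
            double f1 = 1.0 + m_eps * norm_rand();
            double f2 = 1.0 + m_eps * norm_rand();
            Mc1[j] = m1 * (f1 > 0.0 ? f1 : 0.0);
            Mc2[j] = m2 * (f2 > 0.0 ? f2 : 0.0);
          } else {
            Mc1[j] = m1;
            Mc2[j] = m2;
          }
        }
      }
    }
    for (int j = 0; j < nr * nc; ++j) {
      drift_xy(model, params.begin(), X[j], Y[j], Mc1[j], Mc2[j], fx, fy);
      double xn = X[j] + fx * dt + d * X[j] * sdt * norm_rand();
      double yn = Y[j] + fy * dt + d * Y[j] * sdt * norm_rand();
      X[j] = xn > 0.0 ? xn : 0.0;
      Y[j] = yn > 0.0 ? yn : 0.0;
    }
    const double tnext = (s + 1) * dt;
    while (isave < n_save && save_times[isave] <= tnext + 1e-9) {
      for (int j = 0; j < nr * nc; ++j) {
        Xout[isave + n_save * j] = X[j];
        Yout[isave + n_save * j] = Y[j];
      }
      ++isave;
    }
  }
  Xout.attr("dim") = IntegerVector::create(n_save, nr, nc);
  Yout.attr("dim") = IntegerVector::create(n_save, nr, nc);
  return List::create(_["X"] = Xout, _["Y"] = Yout);
}

// First passage times from (x0, y0) into the max-norm ball of radius r around
// (tx, ty), one value per run; NA when censored at t_max.
// [[Rcpp::export(name = ".cpp_fpt")]]
NumericVector cpp_fpt(int model, NumericVector params, double M1, double M2,
                      double d, double x0, double y0, double tx, double ty,
                      double r, int n_runs, double dt, double t_max) {
  NumericVector out(n_runs, NA_REAL);
  const double sdt = std::sqrt(dt);
  const long n_steps = (long)std::ceil(t_max / dt);
  double fx, fy;
  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    double X = x0, Y = y0;
    if (std::max(std::abs(X - tx), std::abs(Y - ty)) <= r) { out[run] = 0.0; continue; }
    for (long s = 0; s < n_steps; ++s) {
      drift_xy(model, params.begin(), X, Y, M1, M2, fx, fy);
      X += fx * dt + d * X * sdt * norm_rand();
      Y += fy * dt + d * Y * sdt * norm_rand();
      if (X < 0.0) X = 0.0;
      if (Y < 0.0) Y = 0.0;
      if (std::max(std::abs(X - tx), std::abs(Y - ty)) <= r) {
        out[run] = (s + 1) * dt;
        break;
      }
    }
  }
  return out;
}

// 1-D overdamped double-well benchmark dx = -U'(x) dt + sqrt(2 D) dW with
// U = (x^2 - 1)^2; passage from the left well into |x - 1| <= r.
// [[Rcpp::export(name = ".cpp_fpt_doublewell")]]
NumericVector cpp_fpt_doublewell(double D, int n_runs, double dt, double t_max,
                                 double x0, double target, double r) {
  NumericVector out(n_runs, NA_REAL);
  const double amp = std::sqrt(2.0 * D), sdt = std::sqrt(dt);
  const long n_steps = (long)std::ceil(t_max / dt);
  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    double x = x0;
    for (long s = 0; s < n_steps; ++s) {
      x += -4.0 * x * (x * x - 1.0) * dt + amp * sdt * norm_rand();
      if (std::abs(x - target) <= r) { out[run] = (s + 1) * dt; break; }
    }
  }
  return out;
}

// Long-run Euler-Maruyama ensemble with ADDITIVE noise of intensity D per
// gene (amplitude sqrt(2 D)), matching the constant-diffusion probability
// evolution operator. Returns n_samples (X, Y) pairs after burn-in, thinned.
// [[Rcpp::export(name = ".cpp_sample_additive")]]
NumericMatrix cpp_sample_additive(int model, NumericVector params,
                                  double M1, double M2, double D,
                                  int n_samples, double burnin, double thin,
                                  double dt, double x0, double y0) {
  NumericMatrix out(n_samples, 2);
  const double amp = std::sqrt(2.0 * D), sdt = std::sqrt(dt);
  const long nburn = (long)std::ceil(burnin / dt);
  const long nthin = std::max(1L, (long)std::ceil(thin / dt));
  double X = x0, Y = y0, fx, fy;
  RNGScope scope;
  for (long s = 0; s < nburn; ++s) {
    drift_xy(model, params.begin(), X, Y, M1, M2, fx, fy);
    X += fx * dt + amp * sdt * norm_rand();
    Y += fy * dt + amp * sdt * norm_rand();
    if (X < 0.0) X = -X;  // reflect at the axes, as the zero-flux operator does
    if (Y < 0.0) Y = -Y;
  }
  for (int i = 0; i < n_samples; ++i) {
    for (long s = 0; s < nthin; ++s) {
      drift_xy(model, params.begin(), X, Y, M1, M2, fx, fy);
      X += fx * dt + amp * sdt * norm_rand();
      Y += fy * dt + amp * sdt * norm_rand();
      if (X < 0.0) X = -X;
      if (Y < 0.0) Y = -Y;
    }
    out(i, 0) = X; out(i, 1) = Y;
  }
  return out;
}

struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int a) { while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; } return a; }
  void unite(int a, int b) { parent[find(a)] = find(b); }
};

// Exact minimax saddle between two grid cells: activate cells in increasing U,
// union-find over 8-neighbour adjacency, stop when the two cells connect. The
// cell whose activation merges them is the saddle.
// [[Rcpp::export(name = ".cpp_minimax_saddle")]]
List cpp_minimax_saddle(NumericMatrix U, int ia, int ja, int ib, int jb) {
  const int nx = U.nrow(), ny = U.ncol(), n = nx * ny;
  const int A = ia + nx * ja, B = ib + nx * jb;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return U[a] < U[b]; });
  std::vector<char> active(n, 0);
  DSU dsu(n);
  for (int t = 0; t < n; ++t) {
    const int c = ord[t];
    const int ci = c % nx, cj = c / nx;
    active[c] = 1;
    for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
      if (di == 0 && dj == 0) continue;
      const int ni = ci + di, nj = cj + dj;
      if (ni < 0 || ni >= nx || nj < 0 || nj >= ny) continue;
      const int nb = ni + nx * nj;
      if (active[nb]) dsu.unite(c, nb);
    }
    if (dsu.find(A) == dsu.find(B)) {
      return List::create(_["i"] = ci + 1, _["j"] = cj + 1, _["U"] = U[c]);
    }
  }
  return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER, _["U"] = NA_REAL);
}
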