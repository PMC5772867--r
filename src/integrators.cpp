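#include <Rcpp.h>
using namespace Rcpp;

// Euler-Maruyama on the (Y, ln S) decomposition of the abundance SDE.
//
// dY = (diag(Y) - Y Y^T) Gamma^T dB + D^T Y dt
//      + (diag(Y) - Y Y^T)(a - Sigma Y - b(S Y)) dt
// d lnS = ([a - b(S Y)]^T Y - 0.5 Y^T Sigma Y) dt + Y^T Gamma^T dB
//
// With use_comp = false (b = 0) this integrates the competition-free simplex
// process, and lnS is the log-total of the linearized system.
//
// (diag(y) - y y^T) v = y * (v - <y, v>) componentwise, which keeps the row
// sum of the Euler increment exactly zero; only negativity needs projection.
//
// dB: K x k matrix of Brownian increments (sd sqrt(dt) each).
// Gamma: k x n loading matrix; Sigma = Gamma^T Gamma precomputed in R.
// Returns thinned Y path (rows at steps 0, thin, 2*thin, ..., K), thinned
// lnS, and the time average of f(y) = a^T y - 0.5 y^T Sigma y over steps
// k >= burn_steps (left endpoints).
// [[Rcpp::export]]
List cpp_sim_ys(NumericVector a, NumericMatrix D, NumericMatrix Gamma,
                NumericMatrix Sigma, NumericVector kappa, bool use_comp,
                NumericVector y0, double lns0, double dt, NumericMatrix dB,
                int thin, int burn_steps) {
  const int n = a.size(), k = Gamma.nrow(), K = dB.nrow();
  const int nkeep = K / thin + 1;
  NumericMatrix Yout(nkeep, n);
  NumericVector lnSout(nkeep);
  std::vector<double> y(y0.begin(), y0.end()), dE(n), v(n), Sy(n);
  double lns = lns0, fsum = 0.0;
  int nf = 0, row = 0;

  for (int j = 0; j < n; ++j) Yout(0, j) = y[j];
  lnSout[0] = lns;
  ++row;

  for (int step = 0; step < K; ++step) {
    // Sigma y and f(y)
    double f = 0.0, ySy = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += Sigma(i, j) * y[j];
      Sy[i] = s;
      ySy += y[i] * s;
      f += a[i] * y[i];
    }
    f -= 0.5 * ySy;
    if (step >= burn_steps) { fsum += f; ++nf; }

    // dE = Gamma^T dB_row
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int m = 0; m < k; ++m) s += Gamma(m, i) * dB(step, m);
      dE[i] = s;
    }

    // drift vector v = a - Sigma y - b(S y)
    double S = std::exp(lns);
    for (int i = 0; i < n; ++i) {
      v[i] = a[i] - Sy[i];
      if (use_comp) v[i] -= kappa[i] * S * y[i];
    }

    double yv = 0.0, ydE = 0.0, yb = 0.0;
    for (int i = 0; i < n; ++i) {
      yv += y[i] * v[i];
      ydE += y[i] * dE[i];
      if (use_comp) yb += y[i] * kappa[i] * S * y[i];
    }

    // ln S update (Ito-corrected)
    lns += (f - yb) * dt + ydE;

    // Y update: D^T y dt + y*(v - <y,v>) dt + y*(dE - <y,dE>)
    double tot = 0.0;
    std::vector<double> ynew(n);
    for (int i = 0; i < n; ++i) {
      double disp = 0.0;
      for (int j = 0; j < n; ++j) disp += D(j, i) * y[j];
      double yi = y[i] + disp * dt + y[i] * ((v[i] - yv) * dt + dE[i] - ydE);
      if (yi < 0.0) yi = 0.0;
      ynew[i] = yi;
      tot += yi;
    }
    if (tot <= 0.0) { // degenerate projection: keep previous point
      for (int i = 0; i < n; ++i) ynew[i] = y[i];
      tot = 1.0;
    }
    for (int i = 0; i < n; ++i) y[i] = ynew[i] / tot;

    if ((step + 1) % thin == 0) {
      for (int j = 0; j < n; ++j) Yout(row, j) = y[j];
      lnSout[row] = lns;
      ++row;
    }
  }

  return List::create(_["Y"] = Yout, _["lnS"] = lnSout,
                      _["favg"] = nf > 0 ? fsum / nf : NA_REAL);
}

// Direct Euler-Maruyama on abundances with negative proposals clamped to 0.
//
// dX_i = (X_i (a_i - b_i(X_i)) + sum_j D_ji X_j) dt + X_i dE_i
//
// use_comp = false drops the competition term (linearized system; may
// overflow on long horizons -- intended for short cross-checks).
// [[Rcpp::export]]
NumericMatrix cpp_sim_x_em(NumericVector a, NumericVector kappa, bool use_comp,
                           NumericMatrix D, NumericMatrix Gamma,
                           NumericVector x0, double dt, NumericMatrix dB,
                           int thin) {
  const int n = a.size(), k = Gamma.nrow(), K = dB.nrow();
  const int nkeep = K / thin + 1;
  NumericMatrix Xout(nkeep, n);
  std::vector<double> x(x0.begin(), x0.end()), dE(n), xnew(n);
  int row = 0;
  for (int j = 0; j < n; ++j) Xout(0, j) = x[j];
  ++row;

  for (int step = 0; step < K; ++step) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int m = 0; m < k; ++m) s += Gamma(m, i) * dB(step, m);
      dE[i] = s;
    }
    for (int i = 0; i < n; ++i) {
      double drift = x[i] * a[i];
      if (use_comp) drift -= x[i] * kappa[i] * x[i];
      for (int j = 0; j < n; ++j) drift += D(j, i) * x[j];
      double xi = x[i] + drift * dt + x[i] * dE[i];
      xnew[i] = xi < 0.0 ? 0.0 : xi;
    }
    for (int i = 0; i < n; ++i) x[i] = xnew[i];
    if ((step + 1) % thin == 0) {
      for (int j = 0; j < n; ++j) Xout(row, j) = x[j];
      ++row;
    }
  }
  return Xout;
}
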