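// Compiled core of the eleutheroembryo PBPK model: closed-form ontogeny,
// the 14-state ODE right-hand side (10 tissues + water + polymer + air +
// metabolized sink) and an adaptive Dormand-Prince RK5(4) integrator with
// exact stops at output/event times. All quantities nmol, volumes uL,
// concentrations nmol/uL, time h.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_TISSUE = 10;   // yolk, liver, skeleton, gut, eye, brain,
                                  // heart, skin, muscle, other
static const int N_STATE  = 14;   // + Q_water, Q_polymer, Q_air, Q_met
static const int I_WATER = 10, I_POLY = 11, I_AIR = 12, I_MET = 13;
static const int I_YOLK = 0, I_LIVER = 1;

struct ZfePars {
  // ontogeny
  double TA, TR, T, t_fec, hatch, arr;
  double yolk_V0, yolk_k, V120;
  double Kg[9], tau[9];            // liver..other, reference-temperature
  // compound
  double P_eff[N_TISSUE];          // f_pc-scaled tissue:water partition
  double phi, phi_chorion, Sat50;  // Sat50 in nmol/uL, Inf disables
  int chorion_on, sat_on, met_kind; // met_kind 0 none, 1 linear, 2 MM
  double K_met, Vmax, KM, V_liver_cell;
  // design + medium
  double V_water, V_air, S_pw, S_aw, n_emb;
  double F_polymer, P_pw, F_air, P_aw;
};

static ZfePars unpack(const List& p) {
  ZfePars z;
  z.TA = p["TA"]; z.TR = p["TR"]; z.T = p["T"];
  z.t_fec = p["t_fec"]; z.hatch = p["hatch"];
  z.arr = std::exp(z.TA / z.TR - z.TA / z.T);
  z.yolk_V0 = p["yolk_V0"]; z.yolk_k = p["yolk_k"]; z.V120 = p["V120"];
  NumericVector Kg = p["Kg"], tau = p["tau"], P = p["P_eff"];
  for (int i = 0; i < 9; ++i) { z.Kg[i] = Kg[i]; z.tau[i] = tau[i]; }
  for (int i = 0; i < N_TISSUE; ++i) z.P_eff[i] = P[i];
  z.phi = p["phi"]; z.phi_chorion = p["phi_chorion"]; z.Sat50 = p["Sat50"];
  z.chorion_on = as<int>(p["chorion_on"]);
  z.sat_on = as<int>(p["sat_on"]);
  z.met_kind = as<int>(p["met_kind"]);
  z.K_met = p["K_met"]; z.Vmax = p["Vmax"]; z.KM = p["KM"];
  z.V_liver_cell = p["V_liver_cell"];
  z.V_water = p["V_water"]; z.V_air = p["V_air"];
  z.S_pw = p["S_pw"]; z.S_aw = p["S_aw"]; z.n_emb = p["n_emb"];
  z.F_polymer = p["F_polymer"]; z.P_pw = p["P_pw"];
  z.F_air = p["F_air"]; z.P_aw = p["P_aw"];
  return z;
}

// organ volumes at time t; returns total embryo volume (incl. yolk)
static double volumes(double t, const ZfePars& z, double* V) {
  V[I_YOLK] = z.yolk_V0 * std::exp(-z.yolk_k * z.arr * (t - z.t_fec));
  double tot = V[I_YOLK];
  for (int k = 0; k < 9; ++k) {
    double KT = z.Kg[k] * z.arr;          // growth rate, Arrhenius-scaled
    double tauT = z.tau[k] / z.arr;       // onset advances with temperature
    double dt = t - tauT - z.t_fec;
    V[k + 1] = dt > 0.0 ? z.V120 * (std::exp(KT * dt) - 1.0) : 0.0;
    tot += V[k + 1];
  }
  return tot;
}

static void rhs(double t, const double* y, double* dy, const ZfePars& z) {
  double V[N_TISSUE];
  double Vemb = volumes(t, z, V);
  double Cw = y[I_WATER] / z.V_water;

  double Few = (z.chorion_on && t < z.hatch)
                 ? z.phi_chorion
                 : z.phi * std::cbrt(Vemb * Vemb);   // phi * V^(2/3)
  double sat = 1.0;
  if (z.sat_on && R_finite(z.Sat50) && z.Sat50 > 0.0)
    sat = 1.0 / (1.0 + Cw / z.Sat50);

  double uptake = 0.0;
  for (int i = 0; i < N_TISSUE; ++i) {
    if (V[i] > 0.0 && z.P_eff[i] > 0.0) {
      double Ci = y[i] / V[i];
      double fl = Few * (V[i] / Vemb) * (sat * Cw - Ci / z.P_eff[i]);
      dy[i] = fl;
      uptake += fl;
    } else dy[i] = 0.0;
  }

  double dmet = 0.0;
  if (z.met_kind > 0 && V[I_LIVER] > 0.0) {
    double Cl = y[I_LIVER] / V[I_LIVER];
    double ncell = V[I_LIVER] / z.V_liver_cell;
    dmet = (z.met_kind == 1) ? ncell * Cl * z.K_met
                             : ncell * Cl * z.Vmax / (z.KM + Cl);
    dy[I_LIVER] -= dmet;
  }
  dy[I_MET] = dmet;

  double dpoly = (z.F_polymer > 0.0 && z.P_pw > 0.0)
                   ? z.F_polymer * (z.S_pw * Cw - y[I_POLY] / z.P_pw)
                   : 0.0;
  double aexch = z.F_air * z.S_aw, dair = 0.0;
  if (aexch > 0.0)
    dair = (z.P_aw > 0.0) ? aexch * (Cw - (y[I_AIR] / z.V_air) / z.P_aw)
                          : aexch * Cw;   // one-way convention when P_aw -> 0
  dy[I_POLY] = dpoly;
  dy[I_AIR]  = dair;
  dy[I_WATER] = -dpoly - dair - z.n_emb * uptake;
}

// Dormand-Prince RK5(4) coefficients
static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
static const double a21 = 1.0/5;
static const double a31 = 3.0/40, a32 = 9.0/40;
static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                    a53 = 64448.0/6561, a54 = -212.0/729;
static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                    a64 = 49.0/176, a65 = -5103.0/18656;
static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                    b5 = -2187.0/6784, b6 = 11.0/84;
static const double e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
                    e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40;

// integrate y in place from t0 to t1, h carried between calls
static void march(double t0, double t1, double* y, double& h,
                  const ZfePars& z, double rtol, double atol) {
  if (t1 <= t0) return;
  double k1[N_STATE], k2[N_STATE], k3[N_STATE], k4[N_STATE],
         k5[N_STATE], k6[N_STATE], k7[N_STATE], yt[N_STATE], yn[N_STATE];
  double t = t0;
  double hmin = 1e-10 * (t1 - t0) + 1e-12;
  if (h <= 0.0) h = (t1 - t0) / 100.0;
  int nreject = 0;
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    rhs(t, y, k1, z);
    for (int i = 0; i < N_STATE; ++i) yt[i] = y[i] + h * a21 * k1[i];
    rhs(t + c2 * h, yt, k2, z);
    for (int i = 0; i < N_STATE; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(t + c3 * h, yt, k3, z);
    for (int i = 0; i < N_STATE; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(t + c4 * h, yt, k4, z);
    for (int i = 0; i < N_STATE; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                          a54 * k4[i]);
    rhs(t + c5 * h, yt, k5, z);
    for (int i = 0; i < N_STATE; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    rhs(t + h, yt, k6, z);
    for (int i = 0; i < N_STATE; ++i)
      yn[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    rhs(t + h, yn, k7, z);
    // embedded 4th-order error estimate
    double err = 0.0;
    for (int i = 0; i < N_STATE; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yn[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / N_STATE);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < N_STATE; ++i) y[i] = yn[i];
      double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
      nreject = 0;
    } else {
      h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
      if (++nreject > 50 || h < hmin)
        stop("ODE solver failed near t = %g (step %g, err %g)", t, h, err);
    }
  }
}

//' @name zfe_ode_backend
//' @title Compiled PBPK backend (internal)
//' @description Internal compiled routines behind the user-facing
//'   simulator.
//' @keywords internal
// [[Rcpp::export]]
NumericVector zfe_volumes_cpp(double t, List pars) {
  ZfePars z = unpack(pars);
  double V[N_TISSUE];
  double tot = volumes(t, z, V);
  NumericVector out(N_TISSUE + 1);
  for (int i = 0; i < N_TISSUE; ++i) out[i] = V[i];
  out[N_TISSUE] = tot;
  return out;
}

// [[Rcpp::export]]
NumericVector zfe_rhs_cpp(double t, NumericVector y, List pars) {
  if (y.size() != N_STATE) stop("state vector must have length 14");
  ZfePars z = unpack(pars);
  NumericVector dy(N_STATE);
  rhs(t, REAL(y), REAL(dy), z);
  return dy;
}

// events: matrix with columns time, kind, value, flag
//   kind 0: set water concentration to `value` (nmol/uL)
//   kind 1: add `value` nmol to water
//   kind 2: renewal to set-point `value`; flag 1 also empties the polymer
//   kind 3: pure integration breakpoint (hatching)
// [[Rcpp::export]]
NumericMatrix zfe_integrate_cpp(NumericVector y0, NumericVector times,
                                NumericMatrix events, List pars,
                                double rtol, double atol) {
  if (y0.size() != N_STATE) stop("state vector must have length 14");
  int nt = times.size();
  for (int i = 1; i < nt; ++i)
    if (times[i] <= times[i - 1]) stop("output times must be increasing");
  ZfePars z = unpack(pars);
  double y[N_STATE];
  for (int i = 0; i < N_STATE; ++i) y[i] = y0[i];

  // merge output times and event times into ordered stop points;
  // at equal times events are applied before the output is recorded
  struct Stop { double t; int pri; int id; };   // pri 0 = event, 1 = output
  int ne = events.nrow();
  std::vector<Stop> stops;
  for (int i = 0; i < nt; ++i) stops.push_back(Stop{times[i], 1, i});
  for (int j = 0; j < ne; ++j) {
    double te = events(j, 0);
    if (te < times[0] - 1e-12 || te > times[nt - 1] + 1e-12)
      stop("event time %g outside simulation window", te);
    stops.push_back(Stop{te, 0, j});
  }
  std::stable_sort(stops.begin(), stops.end(),
                   [](const Stop& a, const Stop& b) {
                     if (a.t != b.t) return a.t < b.t;
                     return a.pri < b.pri;
                   });

  NumericMatrix out(nt, N_STATE);
  double t = times[0], h = -1.0;
  int irow = 0;
  for (size_t s = 0; s < stops.size(); ++s) {
    double ts = stops[s].t;
    if (ts > t + 1e-12) { march(t, ts, y, h, z, rtol, atol); t = ts; }
    if (stops[s].pri == 0) {   // apply event jump
      int ev = stops[s].id;
      int kind = (int) events(ev, 1);
      double val = events(ev, 2);
      int flag = (int) events(ev, 3);
      if (kind == 0) y[I_WATER] = val * z.V_water;
      else if (kind == 1) y[I_WATER] += val;
      else if (kind == 2) {
        y[I_WATER] = val * z.V_water;
        y[I_AIR] = 0.0;
        if (flag) y[I_POLY] = 0.0;
      }                                   // kind 3: breakpoint only
      h = -1.0;                           // restart step size after a jump
    } else {
      for (int i = 0; i < N_STATE; ++i) out(irow, i) = y[i];
      ++irow;
    }
  }
  if (irow != nt) stop("internal error: %d of %d output rows filled",
                       irow, nt);
  return out;
}
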