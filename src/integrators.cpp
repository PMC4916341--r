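// Fixed-step RK4 integrators for the single-neuron models and the E-I network.
//
// Discrete events (delta-pulse charge injections, synaptic-train arrivals) are
// grid-aligned: the R wrappers adjust dt so that the inter-pulse interval is an
// integer multiple of dt, and arrivals are applied exactly at step boundaries.
// Synaptic gating s(t) decays exponentially between arrivals and is advanced by
// its closed form (s *= exp(-h/tau_d)), never by ODE stepping, so RK4 stage
// values of s are exact.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// drive description (one stimulus family per simulation)

struct Drive {
  int family;       // 0 none, 1 alpha pulse, 2 delta train, 3 synaptic train,
                    // 4 constant, 5 ramp
  double r, eps;    // alpha pulse: I_eps(t) = (r/eps)(t/eps)exp(-t/eps)
  double w;         // delta train: jump size per pulse
  double delta;     // inter-pulse interval (delta/synaptic/ramp families)
  double n_pulses;  // count, R_PosInf for unbounded
  double gbar, tau_d, v_rev;  // synaptic train
  double amp;       // constant drive
  double c;         // ramp drive: I(t) = (c/delta) t
  int m;            // steps per inter-pulse interval (0 if no events)
};

static Drive parse_drive(const List& d) {
  Drive dr;
  dr.family   = as<int>(d["family"]);
  dr.r        = as<double>(d["r"]);
  dr.eps      = as<double>(d["eps"]);
  dr.w        = as<double>(d["w"]);
  dr.delta    = as<double>(d["delta"]);
  dr.n_pulses = as<double>(d["n_pulses"]);
  dr.gbar     = as<double>(d["gbar"]);
  dr.tau_d    = as<double>(d["tau_d"]);
  dr.v_rev    = as<double>(d["v_rev"]);
  dr.amp      = as<double>(d["amp"]);
  dr.c        = as<double>(d["c"]);
  dr.m        = as<int>(d["m"]);
  return dr;
}

static inline double drive_current(const Drive& d, double t) {
  switch (d.family) {
    case 1: return t <= 0.0 ? 0.0 : (d.r / d.eps) * (t / d.eps) * std::exp(-t / d.eps);
    case 4: return d.amp;
    case 5: return (d.c / d.delta) * t;
    default: return 0.0;
  }
}

// arrival at step index i (time i*dt)?  arrivals at k*delta, k = 1, 2, ...
static inline bool arrival_at(const Drive& d, long i) {
  if (d.m <= 0 || i <= 0) return false;
  if (i % d.m != 0) return false;
  double k = (double)(i / d.m);
  return k <= d.n_pulses;
}

static void integration_failure(const char* model, double t) {
  stop("%s integration produced a non-finite state at t = %g ms", model, t);
}

// ---------------------------------------------------------------------------
// LIF: dv/dt = -v/tau + I(t) + gbar s(t) (v_rev - v); threshold 1, reset 0

// [[Rcpp::export]]
List sim_lif_cpp(double tau, List drive, double t_end, double dt, double v0,
                 bool reset, bool record) {
  Drive d = parse_drive(drive);
  long n = (long)std::llround(t_end / dt);
  bool syn = (d.family == 3);
  double ehalf = syn ? std::exp(-0.5 * dt / d.tau_d) : 1.0;
  double efull = syn ? std::exp(-dt / d.tau_d) : 1.0;

  double v = v0, s = 0.0, vmax = v0, vprev = v0;
  std::vector<double> spikes;
  NumericVector tr_t, tr_v;
  if (record) { tr_t = NumericVector(n + 1); tr_v = NumericVector(n + 1); }

  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    // events at the step boundary
    if (arrival_at(d, i)) {
      if (d.family == 2) {
        double vnew = v + d.w;
        if (v < 1.0 && vnew >= 1.0) {
          spikes.push_back(t);
          if (reset) vnew = 0.0;
        }
        v = vnew;
      } else if (syn) {
        s += 1.0;
      }
    }
    if (v > vmax) vmax = v;
    if (record) { tr_t[i] = t; tr_v[i] = v; }
    if (i == n) break;

    double g0 = syn ? d.gbar * s : 0.0;
    double gh = g0 * ehalf, g1 = g0 * efull;
    double i0 = drive_current(d, t);
    double ih = drive_current(d, t + 0.5 * dt);
    double i1 = drive_current(d, t + dt);

    double k1 = -v / tau + i0 + g0 * (d.v_rev - v);
    double va = v + 0.5 * dt * k1;
    double k2 = -va / tau + ih + gh * (d.v_rev - va);
    double vb = v + 0.5 * dt * k2;
    double k3 = -vb / tau + ih + gh * (d.v_rev - vb);
    double vc = v + dt * k3;
    double k4 = -vc / tau + i1 + g1 * (d.v_rev - vc);
    double vnew = v + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!std::isfinite(vnew)) integration_failure("LIF", t + dt);

    if (v < 1.0 && vnew >= 1.0) {
      double ts = t + dt * (1.0 - v) / (vnew - v);
      spikes.push_back(ts);
      if (reset) {
        // restart from v = 0 at the interpolated crossing and integrate the
        // remainder of the step, so the reset does not lose O(dt) of time
        double h = t + dt - ts;
        double s0 = syn ? s * std::exp(-(ts - t) / d.tau_d) : 0.0;
        double gh0 = d.gbar * s0, ghh = gh0 * std::exp(-0.5 * h / d.tau_d),
               gh1 = gh0 * std::exp(-h / d.tau_d);
        double j0 = drive_current(d, ts);
        double jh = drive_current(d, ts + 0.5 * h);
        double j1 = drive_current(d, ts + h);
        double r1 = j0 + gh0 * d.v_rev;   // derivative at v = 0
        double ra = 0.5 * h * r1;
        double r2 = -ra / tau + jh + ghh * (d.v_rev - ra);
        double rb = 0.5 * h * r2;
        double r3 = -rb / tau + jh + ghh * (d.v_rev - rb);
        double rc = h * r3;
        double r4 = -rc / tau + j1 + gh1 * (d.v_rev - rc);
        vnew = h / 6.0 * (r1 + 2.0 * r2 + 2.0 * r3 + r4);
      }
    }
    vprev = v;
    v = vnew;
    s *= efull;
    if (v > vmax) vmax = v;
  }

  List out = List::create(
    _["spike_times"] = wrap(spikes), _["v_end"] = v, _["v_prev"] = vprev,
    _["v_max"] = vmax, _["s_end"] = s);
  if (record) { out["times"] = tr_t; out["v"] = tr_v; }
  return out;
}

// ---------------------------------------------------------------------------
// Theta model, integrated in the phase variable:
//   dtheta/dt = -cos(theta)/tau + 2 I (1 + cos(theta)) + conductance term
// with v = (1 + tan(theta/2))/2; firing = upward crossing of theta = pi,
// after which theta wraps to the -pi side and integration continues.

static inline double theta_rhs(double th, double tau, double I, double G,
                               double vrev) {
  double ct = std::cos(th);
  double rhs = -ct / tau + 2.0 * I * (1.0 + ct);
  if (G != 0.0)
    rhs += 2.0 * G * ((vrev - 0.5) * (1.0 + ct) - 0.5 * std::sin(th));
  return rhs;
}

static inline double theta_from_v(double v) { return 2.0 * std::atan(2.0 * v - 1.0); }
static inline double v_from_theta(double th) { return 0.5 * (1.0 + std::tan(0.5 * th)); }

// [[Rcpp::export]]
List sim_theta_cpp(double tau, List drive, double t_end, double dt, double theta0,
                   bool record) {
  Drive d = parse_drive(drive);
  long n = (long)std::llround(t_end / dt);
  bool syn = (d.family == 3);
  double ehalf = syn ? std::exp(-0.5 * dt / d.tau_d) : 1.0;
  double efull = syn ? std::exp(-dt / d.tau_d) : 1.0;

  double th = theta0, s = 0.0, thmax = theta0, thprev = theta0;
  bool blew_up = false;
  std::vector<double> spikes;
  NumericVector tr_t, tr_th;
  if (record) { tr_t = NumericVector(n + 1); tr_th = NumericVector(n + 1); }

  const double PI_ = M_PI;
  for (long i = 0; i <= n; ++i) {
    double t = i * dt;
    if (arrival_at(d, i) && d.family == 2) {
      // instantaneous charge injection: jump in v, mapped through the phase
      double v = v_from_theta(th);
      th = theta_from_v(v + d.w);
    } else if (arrival_at(d, i) && syn) {
      s += 1.0;
    }
    if (th > thmax) thmax = th;
    if (record) { tr_t[i] = t; tr_th[i] = th; }
    if (i == n) break;

    double g0 = syn ? d.gbar * s : 0.0;
    double gh = g0 * ehalf, g1 = g0 * efull;
    double i0 = drive_current(d, t);
    double ih = drive_current(d, t + 0.5 * dt);
    double i1 = drive_current(d, t + dt);

    double k1 = theta_rhs(th, tau, i0, g0, d.v_rev);
    double k2 = theta_rhs(th + 0.5 * dt * k1, tau, ih, gh, d.v_rev);
    double k3 = theta_rhs(th + 0.5 * dt * k2, tau, ih, gh, d.v_rev);
    double k4 = theta_rhs(th + dt * k3, tau, i1, g1, d.v_rev);
    double thnew = th + dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (!std::isfinite(thnew)) integration_failure("theta", t + dt);

    if (th < PI_ && thnew >= PI_) {
      double ts = t + dt * (PI_ - th) / (thnew - th);
      spikes.push_back(ts);
      blew_up = true;
      thnew -= 2.0 * PI_;
    }
    thprev = th;
    th = thnew;
    s *= efull;
    if (th > thmax) thmax = th;
  }

  List out = List::create(
    _["spike_times"] = wrap(spikes), _["theta_end"] = th, _["theta_prev"] = thprev,
    _["theta_max"] = thmax, _["blew_up"] = blew_up, _["s_end"] = s);
  if (record) { out["times"] = tr_t; out["theta"] = tr_th; }
  return out;
}

// ---------------------------------------------------------------------------
// Hodgkin-Huxley-type models: WB (Wang-Buzsaki fast-firing interneuron) and
// RTM (reduced Traub-Miles pyramidal cell).  Sodium activation m is
// instantaneous (m = m_inf(v)); state is (v, h, n).

struct HHPars { double gna, gk, gl, vna, vk, vl, phi; };

static inline HHPars hh_pars(int id) {
  HHPars p;
  if (id == 0) {            // WB
    p.gna = 35.0;  p.gk = 9.0;  p.gl = 0.1;
    p.vna = 55.0;  p.vk = -90.0; p.vl = -65.0; p.phi = 5.0;
  } else {                  // RTM
    p.gna = 100.0; p.gk = 80.0; p.gl = 0.1;
    p.vna = 50.0;  p.vk = -100.0; p.vl = -67.0; p.phi = 1.0;
  }
  return p;
}

// x / (1 - exp(-x/y)), with its limit y + x/2 near x = 0
static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-7) return y + 0.5 * x;
  return x / (1.0 - std::exp(-x / y));
}

static inline void hh_gates(int id, double v, double& minf,
                            double& ah, double& bh, double& an, double& bn) {
  if (id == 0) {            // WB
    double am = 0.1 * vtrap(v + 35.0, 10.0);
    double bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
    minf = am / (am + bm);
    ah = 0.07 * std::exp(-(v + 58.0) / 20.0);
    bh = 1.0 / (1.0 + std::exp(-0.1 * (v + 28.0)));
    an = 0.01 * vtrap(v + 34.0, 10.0);
    bn = 0.125 * std::exp(-(v + 44.0) / 80.0);
  } else {                  // RTM
    double am = 0.32 * vtrap(v + 54.0, 4.0);
    double bm = 0.28 * vtrap(-(v + 27.0), 5.0);
    minf = am / (am + bm);
    ah = 0.128 * std::exp(-(v + 50.0) / 18.0);
    bh = 4.0 / (1.0 + std::exp(-(v + 27.0) / 5.0));
    an = 0.032 * vtrap(v + 52.0, 5.0);
    bn = 0.5 * std::exp(-(v + 57.0) / 40.0);
  }
}

static inline void hh_deriv(int id, const HHPars& p, double v, double h, double n,
                            double Iext, double G, double vrev,
                            double& dv, double& dh, double& dn) {
  double minf, ah, bh, an, bn;
  hh_gates(id, v, minf, ah, bh, an, bn);
  double m3 = minf * minf * minf;
  double n4 = n * n * n * n;
  dv = p.gna * m3 * h * (p.vna - v) + p.gk * n4 * (p.vk - v) +
       p.gl * (p.vl - v) + Iext + G * (vrev - v);
  dh = p.phi * (ah * (1.0 - h) - bh * h);
  dn = p.phi * (an * (1.0 - n) - bn * n);
}

// membrane current balance at (v, h_inf(v), n_inf(v)) with zero drive;
// the zero of this residual is the resting potential
// [[Rcpp::export]]
double hh_rest_residual_cpp(int model_id, double v) {
  HHPars p = hh_pars(model_id);
  double minf, ah, bh, an, bn;
  hh_gates(model_id, v, minf, ah, bh, an, bn);
  double h = ah / (ah + bh), n = an / (an + bn);
  double dv, dh, dn;
  hh_deriv(model_id, p, v, h, n, 0.0, 0.0, 0.0, dv, dh, dn);
  return dv;
}

// [[Rcpp::export]]
NumericVector hh_inf_state_cpp(int model_id, double v) {
  double minf, ah, bh, an, bn;
  hh_gates(model_id, v, minf, ah, bh, an, bn);
  return NumericVector::create(_["v"] = v, _["h"] = ah / (ah + bh),
                               _["n"] = an / (an + bn));
}

// [[Rcpp::export]]
NumericVector hh_deriv_cpp(int model_id, NumericVector state, double I) {
  HHPars p = hh_pars(model_id);
  double dv, dh, dn;
  hh_deriv(model_id, p, state[0], state[1], state[2], I, 0.0, 0.0, dv, dh, dn);
  return NumericVector::create(_["dv"] = dv, _["dh"] = dh, _["dn"] = dn);
}

// [[Rcpp::export]]
List sim_hh_cpp(int model_id, List drive, double t_end, double dt,
                NumericVector init, double detect, bool record) {
  Drive d = parse_drive(drive);
  HHPars p = hh_pars(model_id);
  long n_steps = (long)std::llround(t_end / dt);
  bool syn = (d.family == 3);
  double ehalf = syn ? std::exp(-0.5 * dt / d.tau_d) : 1.0;
  double efull = syn ? std::exp(-dt / d.tau_d) : 1.0;

  double v = init[0], h = init[1], nn = init[2], s = 0.0;
  double vmax = v, vprev = v;
  std::vector<double> spikes;
  NumericVector tr_t, tr_v, tr_h, tr_n;
  if (record) {
    tr_t = NumericVector(n_steps + 1); tr_v = NumericVector(n_steps + 1);
    tr_h = NumericVector(n_steps + 1); tr_n = NumericVector(n_steps + 1);
  }

  for (long i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (arrival_at(d, i)) {
      if (d.family == 2) {
        double vnew = v + d.w;
        if (v < detect && vnew >= detect) spikes.push_back(t);
        v = vnew;
      } else if (syn) {
        s += 1.0;
      }
    }
    if (v > vmax) vmax = v;
    if (record) { tr_t[i] = t; tr_v[i] = v; tr_h[i] = h; tr_n[i] = nn; }
    if (i == n_steps) break;

    double g0 = syn ? d.gbar * s : 0.0;
    double gh_ = g0 * ehalf, g1 = g0 * efull;
    double i0 = drive_current(d, t);
    double ih_ = drive_current(d, t + 0.5 * dt);
    double i1 = drive_current(d, t + dt);

    double dv1, dh1, dn1, dv2, dh2, dn2, dv3, dh3, dn3, dv4, dh4, dn4;
    hh_deriv(model_id, p, v, h, nn, i0, g0, d.v_rev, dv1, dh1, dn1);
    hh_deriv(model_id, p, v + 0.5 * dt * dv1, h + 0.5 * dt * dh1,
             nn + 0.5 * dt * dn1, ih_, gh_, d.v_rev, dv2, dh2, dn2);
    hh_deriv(model_id, p, v + 0.5 * dt * dv2, h + 0.5 * dt * dh2,
             nn + 0.5 * dt * dn2, ih_, gh_, d.v_rev, dv3, dh3, dn3);
    hh_deriv(model_id, p, v + dt * dv3, h + dt * dh3, nn + dt * dn3,
             i1, g1, d.v_rev, dv4, dh4, dn4);

    double vnew = v + dt / 6.0 * (dv1 + 2.0 * dv2 + 2.0 * dv3 + dv4);
    double hnew = h + dt / 6.0 * (dh1 + 2.0 * dh2 + 2.0 * dh3 + dh4);
    double nnew = nn + dt / 6.0 * (dn1 + 2.0 * dn2 + 2.0 * dn3 + dn4);
    if (!std::isfinite(vnew) || !std::isfinite(hnew) || !std::isfinite(nnew))
      integration_failure(model_id == 0 ? "WB" : "RTM", t + dt);

    if (v < detect && vnew >= detect)
      spikes.push_back(t + dt * (detect - v) / (vnew - v));
    vprev = v;
    v = vnew; h = hnew; nn = nnew;
    s *= efull;
    if (v > vmax) vmax = v;
  }

  List out = List::create(
    _["spike_times"] = wrap(spikes), _["v_end"] = v, _["v_prev"] = vprev,
    _["v_max"] = vmax, _["h_end"] = h, _["n_end"] = nn, _["s_end"] = s);
  if (record) {
    out["times"] = tr_t; out["v"] = tr_v; out["h"] = tr_h; out["n"] = tr_n;
  }
  return out;
}

// ---------------------------------------------------------------------------
// PING network: nE RTM E-cells + nI WB I-cells, all-to-all.
// Per-cell state (v, h, n, s); s is the presynaptic gating variable with
//   ds/dt = ((1 + tanh(v/10))/2) (1 - s)/tau_R - s/tau_D.
// Synaptic conductance totals are divided by the presynaptic population size.

struct NetPars {
  int nE, nI;
  double gEI, gIE, gII, gEE;          // per-synapse conductances
  double vrevE, vrevI;
  double tauRE, tauDE, tauRI, tauDI;
  double gtonic, vtonic, driveI;
  const double* driveE;
};

// presynaptic activation of the synaptic gating variable
static inline double gate_rho(double v) {
  return 0.5 * (1.0 + std::tanh(v / 10.0));
}
static void net_deriv(const NetPars& np, const std::vector<double>& y,
                      std::vector<double>& dy) {
  int nE = np.nE, nI = np.nI;
  double sumSE = 0.0, sumSI = 0.0;
  for (int j = 0; j < nE; ++j) sumSE += y[4 * j + 3];
  for (int j = 0; j < nI; ++j) sumSI += y[4 * (nE + j) + 3];
  HHPars pe = hh_pars(1), pi = hh_pars(0);

  for (int j = 0; j < nE; ++j) {
    const double* yj = &y[4 * j];
    double* dj = &dy[4 * j];
    double v = yj[0];
    double Isyn = np.gIE * sumSI * (np.vrevI - v) + np.gEE * sumSE * (np.vrevE - v) +
                  np.gtonic * (np.vtonic - v);
    hh_deriv(1, pe, v, yj[1], yj[2], np.driveE[j] + Isyn, 0.0, 0.0,
             dj[0], dj[1], dj[2]);
    dj[3] = gate_rho(v) * (1.0 - yj[3]) / np.tauRE - yj[3] / np.tauDE;
  }
  for (int j = 0; j < nI; ++j) {
    const double* yj = &y[4 * (nE + j)];
    double* dj = &dy[4 * (nE + j)];
    double v = yj[0];
    double Isyn = np.gEI * sumSE * (np.vrevE - v) + np.gII * sumSI * (np.vrevI - v);
    hh_deriv(0, pi, v, yj[1], yj[2], np.driveI + Isyn, 0.0, 0.0,
             dj[0], dj[1], dj[2]);
    dj[3] = gate_rho(v) * (1.0 - yj[3]) / np.tauRI - yj[3] / np.tauDI;
  }
}

// [[Rcpp::export]]
List sim_ping_cpp(int nE, int nI, NumericVector driveE, double driveI,
                  double gEI_total, double gIE_total, double gII_total,
                  double gEE_total, double vrevE, double vrevI,
                  double tauRE, double tauDE, double tauRI, double tauDI,
                  double gtonic, double vtonic, double t_end, double dt,
                  double detect, NumericMatrix initE, NumericMatrix initI) {
  NetPars np;
  np.nE = nE; np.nI = nI;
  np.gEI = gEI_total / nE; np.gIE = gIE_total / nI;
  np.gII = gII_total / nI; np.gEE = gEE_total / nE;
  np.vrevE = vrevE; np.vrevI = vrevI;
  np.tauRE = tauRE; np.tauDE = tauDE; np.tauRI = tauRI; np.tauDI = tauDI;
  np.gtonic = gtonic; np.vtonic = vtonic; np.driveI = driveI;
  np.driveE = REAL(driveE);

  int dim = 4 * (nE + nI);
  std::vector<double> y(dim), k1(dim), k2(dim), k3(dim), k4(dim), ytmp(dim);
  bool has_s_e = initE.ncol() > 3, has_s_i = initI.ncol() > 3;
  for (int j = 0; j < nE; ++j) {
    y[4 * j] = initE(j, 0); y[4 * j + 1] = initE(j, 1);
    y[4 * j + 2] = initE(j, 2); y[4 * j + 3] = has_s_e ? initE(j, 3) : 0.0;
  }
  for (int j = 0; j < nI; ++j) {
    int o = 4 * (nE + j);
    y[o] = initI(j, 0); y[o + 1] = initI(j, 1); y[o + 2] = initI(j, 2);
    y[o + 3] = has_s_i ? initI(j, 3) : 0.0;
  }

  long n_steps = (long)std::llround(t_end / dt);
  std::vector<double> vold(nE + nI);
  std::vector<int> sp_cell;
  std::vector<double> sp_time;
  NumericVector gate_t(n_steps / 10 + 1), gateE(n_steps / 10 + 1),
      gateI(n_steps / 10 + 1);
  int gi = 0;

  for (long i = 0; i < n_steps; ++i) {
    double t = i * dt;
    for (int c = 0; c < nE + nI; ++c) vold[c] = y[4 * c];

    net_deriv(np, y, k1);
    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + 0.5 * dt * k1[k];
    net_deriv(np, ytmp, k2);
    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + 0.5 * dt * k2[k];
    net_deriv(np, ytmp, k3);
    for (int k = 0; k < dim; ++k) ytmp[k] = y[k] + dt * k3[k];
    net_deriv(np, ytmp, k4);
    for (int k = 0; k < dim; ++k)
      y[k] += dt / 6.0 * (k1[k] + 2.0 * k2[k] + 2.0 * k3[k] + k4[k]);

    for (int c = 0; c < nE + nI; ++c) {
      double vn = y[4 * c];
      if (!std::isfinite(vn))
        stop("network integration produced a non-finite state for cell %d at t = %g ms",
             c < nE ? nI + c + 1 : c - nE + 1, t + dt);
      if (vold[c] < detect && vn >= detect) {
        // Fig.-1 labeling: I-cells 1..nI first, j-th E-cell is nI + j
        sp_cell.push_back(c < nE ? nI + c + 1 : c - nE + 1);
        sp_time.push_back(t + dt * (detect - vold[c]) / (vn - vold[c]));
      }
    }
    if (i % 10 == 0 && gi < gate_t.size()) {
      double se = 0.0, si = 0.0;
      for (int j = 0; j < nE; ++j) se += y[4 * j + 3];
      for (int j = 0; j < nI; ++j) si += y[4 * (nE + j) + 3];
      gate_t[gi] = t + dt; gateE[gi] = se; gateI[gi] = si; ++gi;
    }
    if (i % 5000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finE(nE, 4), finI(nI, 4);
  for (int j = 0; j < nE; ++j)
    for (int k = 0; k < 4; ++k) finE(j, k) = y[4 * j + k];
  for (int j = 0; j < nI; ++j)
    for (int k = 0; k < 4; ++k) finI(j, k) = y[4 * (nE + j) + k];
  return List::create(_["cell"] = wrap(sp_cell), _["time"] = wrap(sp_time),
                      _["gate_time"] = gate_t, _["gate_e"] = gateE,
                      _["gate_i"] = gateI, _["final_e"] = finE,
                      _["final_i"] = finI);
}
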