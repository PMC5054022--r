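// Compiled core: gate-law evaluation and the fixed-step integrator.
//
// Units are fixed package-wide: mV, ms, pA, nS, pF. With these, the membrane
// equation c_m dV/dt = I_inj - I_mem needs no conversion factors
// (pA / pF * ms = mV), and nS * mV = pA.
//
// Gate kinetics use the exponential-Euler closed form
//   x <- x_inf - (x_inf - x) * exp(-dt / tau)
// evaluated at the instantaneous V, which is exact for piecewise-constant V
// (the whole of voltage clamp) and unconditionally stable in current clamp.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---- gate-law primitives ----------------------------------------------------

static inline double boltzmann_base(double v, double vhalf, double k, int dir) {
  // dir +1: rising with depolarization; dir -1: falling.
  double arg = (dir > 0) ? (vhalf - v) / k : (v - vhalf) / k;
  return 1.0 / (1.0 + std::exp(arg));
}

// tau branch matrix columns: type, vlo, vhi, p1, p2, p3
//   type 1: exp-offset  p1*exp(-v/p2) + p3   (p2 may be negative)
//   type 2: quadratic   p1 + p2*v + p3*v^2
static inline double tau_branch_eval(const NumericMatrix& br, int row, double v) {
  int type = (int)br(row, 0);
  if (type == 1) return br(row, 3) * std::exp(-v / br(row, 4)) + br(row, 5);
  return br(row, 3) + br(row, 4) * v + br(row, 5) * v * v;
}

static double tau_eval_one(const NumericMatrix& br, double floor_, double v) {
  int n = br.nrow();
  double tau = NA_REAL;
  if (n == 1) {
    tau = tau_branch_eval(br, 0, v);
  } else {
    if (v < br(0, 1)) {
      tau = tau_branch_eval(br, 0, v);
    } else if (v > br(n - 1, 2)) {
      tau = tau_branch_eval(br, n - 1, v);
    } else {
      bool done = false;
      for (int i = 0; i < n && !done; ++i) {
        if (v >= br(i, 1) && v <= br(i, 2)) { tau = tau_branch_eval(br, i, v); done = true; }
      }
      if (!done) {
        // v lies in a declared gap: linear bridge between flanking branches
        for (int i = 0; i + 1 < n; ++i) {
          if (v > br(i, 2) && v < br(i + 1, 1)) {
            double x0 = br(i, 2), x1 = br(i + 1, 1);
            double y0 = tau_branch_eval(br, i, x0);
            double y1 = tau_branch_eval(br, i + 1, x1);
            tau = y0 + (y1 - y0) * (v - x0) / (x1 - x0);
            done = true;
            break;
          }
        }
      }
    }
  }
  return (tau < floor_) ? floor_ : tau;
}

// [[Rcpp::export]]
NumericVector boltzmann_eval_cpp(NumericVector v, double vhalf, double k,
                                 int dir, double amplitude) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = amplitude * boltzmann_base(v[i], vhalf, k, dir);
  return out;
}

// [[Rcpp::export]]
NumericVector gate_ss_cpp(NumericVector v, double vhalf, double k,
                          int dir, double root) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double b = boltzmann_base(v[i], vhalf, k, dir);
    out[i] = (root == 1.0) ? b : std::pow(b, 1.0 / root);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector tau_eval_cpp(NumericVector v, NumericMatrix branches, double floor_) {
  int n = v.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tau_eval_one(branches, floor_, v[i]);
  return out;
}

// ---- integrator -------------------------------------------------------------

struct GateC {
  double p;          // exponent on the gate variable
  double vhalf, k, root;
  int dir;
  NumericMatrix tau_br;
  double tau_floor;
  double x;          // state
};

struct ChanC {
  double g_max, e_rev;
  std::vector<GateC> gates;
};

// model: list(c_m, g_leak, e_leak, channels = list(list(g_max, e_rev,
//   gates = list(list(p, ss = c(vhalf, k, dir, root),
//                     tau_branches = matrix, tau_floor = dbl)))))
// mode: 0 = current clamp (levels are pA), 1 = voltage clamp (levels are mV)
// v0: initial membrane potential; gates start at steady state for v0
// [[Rcpp::export]]
List simulate_cpp(List model, int mode, NumericVector seg_dur,
                  NumericVector seg_level, double dt, double v0,
                  bool record_gates) {
  double c_m = as<double>(model["c_m"]);
  double g_leak = as<double>(model["g_leak"]);
  double e_leak = as<double>(model["e_leak"]);
  List channels = model["channels"];
  int n_chan = channels.size();

  std::vector<ChanC> ch(n_chan);
  std::vector<std::string> gate_names;
  for (int c = 0; c < n_chan; ++c) {
    List cl = channels[c];
    ch[c].g_max = as<double>(cl["g_max"]);
    ch[c].e_rev = as<double>(cl["e_rev"]);
    List gl = cl["gates"];
    for (int g = 0; g < gl.size(); ++g) {
      List gg = gl[g];
      GateC gc;
      gc.p = as<double>(gg["p"]);
      NumericVector ss = gg["ss"];
      gc.vhalf = ss[0]; gc.k = ss[1]; gc.dir = (int)ss[2]; gc.root = ss[3];
      gc.tau_br = as<NumericMatrix>(gg["tau_branches"]);
      gc.tau_floor = as<double>(gg["tau_floor"]);
      double b = boltzmann_base(v0, gc.vhalf, gc.k, gc.dir);
      gc.x = (gc.root == 1.0) ? b : std::pow(b, 1.0 / gc.root);
      ch[c].gates.push_back(gc);
      gate_names.push_back(as<std::string>(gg["name"]));
    }
  }
  int n_gates_tot = gate_names.size();

  // segment boundaries in steps (cumulative rounding keeps totals exact)
  int n_seg = seg_dur.size();
  std::vector<long> bound(n_seg);
  double cum = 0.0;
  for (int s = 0; s < n_seg; ++s) {
    cum += seg_dur[s];
    bound[s] = (long)std::llround(cum / dt);
  }
  long n_steps = bound[n_seg - 1];
  long n_samp = n_steps + 1;

  NumericVector t_out(n_samp), v_out(n_samp), i_out(n_samp), i_leak_out(n_samp);
  NumericMatrix i_chan(n_samp, n_chan);
  NumericMatrix gates_out =
      record_gates ? NumericMatrix(n_samp, n_gates_tot) : NumericMatrix(0, 0);

  double V = v0;
  int seg = 0;
  for (long i = 0; i <= n_steps; ++i) {
    while (seg < n_seg - 1 && i >= bound[seg]) ++seg;
    double level = seg_level[seg];
    if (mode == 1) V = level;  // ideal clamp: V equals command at every sample

    // record sample i
    t_out[i] = i * dt;
    v_out[i] = V;
    double il = g_leak * (V - e_leak);
    i_leak_out[i] = il;
    double i_mem = il;
    int gidx = 0;
    for (int c = 0; c < n_chan; ++c) {
      double open = 1.0;
      for (size_t g = 0; g < ch[c].gates.size(); ++g) {
        double x = ch[c].gates[g].x;
        double p = ch[c].gates[g].p;
        open *= (p == 1.0) ? x : std::pow(x, p);
        if (record_gates) gates_out(i, gidx) = x;
        ++gidx;
      }
      double ic = ch[c].g_max * open * (V - ch[c].e_rev);
      i_chan(i, c) = ic;
      i_mem += ic;
    }
    i_out[i] = (mode == 1) ? i_mem : level;  // VC: total membrane current
    if (i == n_steps) break;

    // advance gates (exponential Euler at current V)
    for (int c = 0; c < n_chan; ++c) {
      for (size_t g = 0; g < ch[c].gates.size(); ++g) {
        GateC& gc = ch[c].gates[g];
        double b = boltzmann_base(V, gc.vhalf, gc.k, gc.dir);
        double xinf = (gc.root == 1.0) ? b : std::pow(b, 1.0 / gc.root);
        double tau = tau_eval_one(gc.tau_br, gc.tau_floor, V);
        gc.x = xinf - (xinf - gc.x) * std::exp(-dt / tau);
      }
    }
    // advance V (forward Euler) in current clamp
    if (mode == 0) V += dt * (level - i_mem) / c_m;
  }

  List out = List::create(
      _["time"] = t_out, _["v"] = v_out, _["i"] = i_out,
      _["i_leak"] = i_leak_out, _["i_chan"] = i_chan);
  if (record_gates) {
    out["gates"] = gates_out;
    out["gate_names"] = wrap(gate_names);
  }
  return out;
}
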