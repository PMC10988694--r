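// Multicompartment cable solver for the Ia afferent model.
//
// Theta-method integration with operator splitting: channel states are
// advanced first (HH gates by exact exponential update -- staggered, so
// the scheme is second order at theta = 0.5; Markov occupancies by a
// theta-weighted implicit solve on the generator, SK by exponential
// relaxation toward its Hill steady state), then the voltage system is
// solved implicitly over the compartment tree with a Hines-ordered
// elimination.  theta = 0.5 is Crank-Nicolson (default), theta = 1 is
// backward Euler.
//
// Units: mV, ms, nA, uS, nF, uM.  Channel kinetics are supplied from R as
// voltage lookup tables so that the R-level channel library and this solver
// share a single definition of every rate function.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double tab_interp(const std::vector<double>& tab, double v,
                                double v0, double inv_dv) {
  double u = (v - v0) * inv_dv;
  int n = (int)tab.size();
  if (u <= 0.0) return tab[0];
  if (u >= n - 1) return tab[n - 1];
  int i = (int)u;
  double f = u - i;
  return tab[i] * (1.0 - f) + tab[i + 1] * f;
}

// dense Gaussian elimination with partial pivoting, n <= 16
static void solve_small(double* A, double* b, int n) {
  for (int k = 0; k < n; ++k) {
    int piv = k;
    double amax = std::fabs(A[k * n + k]);
    for (int i = k + 1; i < n; ++i) {
      double a = std::fabs(A[i * n + k]);
      if (a > amax) { amax = a; piv = i; }
    }
    if (piv != k) {
      for (int j = 0; j < n; ++j) std::swap(A[k * n + j], A[piv * n + j]);
      std::swap(b[k], b[piv]);
    }
    double d = A[k * n + k];
    if (d == 0.0) stop("singular Markov step matrix");
    for (int i = k + 1; i < n; ++i) {
      double f = A[i * n + k] / d;
      if (f == 0.0) continue;
      for (int j = k; j < n; ++j) A[i * n + j] -= f * A[k * n + j];
      b[i] -= f * b[k];
    }
  }
  for (int k = n - 1; k >= 0; --k) {
    double s = b[k];
    for (int j = k + 1; j < n; ++j) s -= A[k * n + j] * b[j];
    b[k] = s / A[k * n + k];
  }
}

struct HHGateTab {
  std::vector<double> inf, expfac;  // expfac = exp(-dt/tau(V))
  int power;
};

struct ChanCpp {
  int kind;                 // 0 = hh, 1 = markov, 2 = sk
  double e_rev;
  bool is_na;
  std::vector<int> comps;   // compartments where density > 0
  std::vector<double> g;    // max conductance per active comp (uS)
  // hh
  std::vector<HHGateTab> gates;
  std::vector<double> xstate;         // ngates * nactive
  // markov
  int ns = 0, nt = 0;
  std::vector<int> from, to, conducting;
  std::vector<std::vector<double>> rate_tab;  // per transition
  std::vector<double> pstate;         // ns * nactive
  // sk
  double k_half = 0.4, hill = 4.0, sk_expfac = 1.0;
  std::vector<double> astate;
};

// [[Rcpp::export]]
List cpp_simulate_afferent(List neuron, List channels, List vgrid,
                           List drive, List sim, List ca_cfg) {
  const IntegerVector parent = neuron["parent"];
  const NumericVector g_ax = neuron["g_axial_uS"];
  const NumericVector area = neuron["area_cm2"];
  const NumericVector cm = neuron["cm_nF"];
  const NumericVector g_leak = neuron["g_leak_uS"];
  const double e_leak = as<double>(neuron["e_leak"]);
  const int n = parent.size();

  const double v0 = as<double>(vgrid["v0"]);
  const double dv = as<double>(vgrid["dv"]);
  const double inv_dv = 1.0 / dv;

  const double dt = as<double>(sim["dt_ms"]);
  const double theta = as<double>(sim["theta"]);
  const int n_steps = as<int>(sim["n_steps"]);
  const int n_settle = as<int>(sim["n_settle"]);
  const double v_init = as<double>(sim["v_init"]);
  const IntegerVector record = sim["record"];
  const int nrec = record.size();

  const NumericVector drive_g = drive["g_uS"];
  const double drive_dt = as<double>(drive["dt_ms"]);
  const NumericVector drive_w = drive["weight"];
  const double e_drive = as<double>(drive["e_rev"]);
  const NumericVector i_inj = drive["i_inj_nA"];
  const int nd = drive_g.size();

  const double ca_tau = as<double>(ca_cfg["tau_ms"]);
  const double ca_phi = as<double>(ca_cfg["phi"]);
  const double ca0 = as<double>(ca_cfg["ca0"]);

  // parse channels
  const int nch = channels.size();
  std::vector<ChanCpp> ch(nch);
  for (int c = 0; c < nch; ++c) {
    List L = channels[c];
    ChanCpp& C = ch[c];
    std::string kind = as<std::string>(L["kind"]);
    C.kind = (kind == "hh") ? 0 : (kind == "markov" ? 1 : 2);
    C.e_rev = as<double>(L["e_rev"]);
    C.is_na = as<bool>(L["is_na"]);
    IntegerVector comps = L["comps"];
    NumericVector g = L["g_uS"];
    C.comps.assign(comps.begin(), comps.end());
    C.g.assign(g.begin(), g.end());
    int na = C.comps.size();
    if (C.kind == 0) {
      List gl = L["gates"];
      NumericVector x0 = L["init"];
      int ng = gl.size();
      C.gates.resize(ng);
      for (int gi = 0; gi < ng; ++gi) {
        List G = gl[gi];
        NumericVector inf = G["inf"], tau = G["tau"];
        C.gates[gi].inf.assign(inf.begin(), inf.end());
        C.gates[gi].expfac.resize(tau.size());
        for (int k = 0; k < tau.size(); ++k)
          C.gates[gi].expfac[k] = std::exp(-dt / tau[k]);
        C.gates[gi].power = as<int>(G["power"]);
      }
      C.xstate.resize((size_t)ng * na);
      for (int a = 0; a < na; ++a)
        for (int gi = 0; gi < ng; ++gi)
          C.xstate[(size_t)gi * na + a] = x0[gi];
    } else if (C.kind == 1) {
      C.ns = as<int>(L["n_states"]);
      IntegerVector from = L["from"], to = L["to"], cond = L["conducting"];
      C.from.assign(from.begin(), from.end());
      C.to.assign(to.begin(), to.end());
      C.conducting.assign(cond.begin(), cond.end());
      C.nt = C.from.size();
      NumericMatrix rt = L["rate_tab"];   // nt x nV
      C.rate_tab.resize(C.nt);
      for (int k = 0; k < C.nt; ++k) {
        C.rate_tab[k].resize(rt.ncol());
        for (int j = 0; j < rt.ncol(); ++j) C.rate_tab[k][j] = rt(k, j);
      }
      NumericVector p0 = L["init"];
      C.pstate.resize((size_t)C.ns * na);
      for (int a = 0; a < na; ++a)
        for (int s = 0; s < C.ns; ++s)
          C.pstate[(size_t)s * na + a] = p0[s];
    } else {
      C.k_half = as<double>(L["k_half"]);
      C.hill = as<double>(L["hill"]);
      C.sk_expfac = std::exp(-dt / as<double>(L["tau_ms"]));
      C.astate.assign(na, 0.0);
    }
  }

  std::vector<double> V(n, v_init), Ca(n, ca0);
  std::vector<double> gsum(n), gE(n), d(n), rhs(n);
  std::vector<double> gna(n), gnaE(n), j_prev(n, 0.0);
  const double ca_ef = std::exp(-dt / ca_tau);

  NumericMatrix Vrec(n_steps, nrec), Carec(n_steps, nrec);
  NumericVector t_ms(n_steps);

  const double kh = 1.0; // placeholder to keep compilers happy
  (void)kh;

  std::vector<double> A(16 * 16), pb(16);

  const int total_steps = n_settle + n_steps;
  double max_occ_err = 0.0;

  for (int step = 0; step < total_steps; ++step) {
    const bool settling = step < n_settle;
    const double t_rel = settling ? 0.0 : (step - n_settle) * dt;

    // drive conductance (linear interpolation on the stimulus grid)
    double gd = 0.0;
    if (!settling && nd > 0) {
      double u = (t_rel + 0.5 * dt) / drive_dt;
      int i = (int)u;
      if (i >= nd - 1) gd = drive_g[nd - 1];
      else {
        double f = u - i;
        gd = drive_g[i] * (1.0 - f) + drive_g[i + 1] * f;
      }
    }

    for (int i = 0; i < n; ++i) {
      gsum[i] = g_leak[i];
      gE[i] = g_leak[i] * e_leak;
      gna[i] = 0.0;
      gnaE[i] = 0.0;
    }
    if (gd > 0.0) {
      for (int i = 0; i < n; ++i) {
        double gw = gd * drive_w[i];
        if (gw > 0.0) { gsum[i] += gw; gE[i] += gw * e_drive; }
      }
    }

    // channel updates at V from the previous step
    for (int c = 0; c < nch; ++c) {
      ChanCpp& C = ch[c];
      const int na = (int)C.comps.size();
      if (C.kind == 0) {
        const int ng = (int)C.gates.size();
        for (int a = 0; a < na; ++a) {
          const int ic = C.comps[a];
          const double v = V[ic];
          double open = 1.0;
          for (int gi = 0; gi < ng; ++gi) {
            HHGateTab& G = C.gates[gi];
            double xinf = tab_interp(G.inf, v, v0, inv_dv);
            double ef = tab_interp(G.expfac, v, v0, inv_dv);
            double& x = C.xstate[(size_t)gi * na + a];
            x = xinf + (x - xinf) * ef;
            double xp = x;
            for (int p = 1; p < G.power; ++p) xp *= x;
            open *= xp;
          }
          double gc = C.g[a] * open;
          gsum[ic] += gc;
          gE[ic] += gc * C.e_rev;
        }
      } else if (C.kind == 1) {
        const int ns = C.ns;
        for (int a = 0; a < na; ++a) {
          const int ic = C.comps[a];
          const double v = V[ic];
          // theta-weighted step: (I - theta dt Q^T) p+ =
          //   (I + (1-theta) dt Q^T) p   (mass conserved exactly)
          for (int k = 0; k < ns * ns; ++k) A[k] = 0.0;
          for (int s = 0; s < ns; ++s) {
            A[s * ns + s] = 1.0;
            pb[s] = C.pstate[(size_t)s * na + a];
          }
          for (int k = 0; k < C.nt; ++k) {
            double r = tab_interp(C.rate_tab[k], v, v0, inv_dv);
            int f = C.from[k], t2 = C.to[k];
            A[t2 * ns + f] -= theta * dt * r;
            A[f * ns + f] += theta * dt * r;
            double flux = (1.0 - theta) * dt * r *
              C.pstate[(size_t)f * na + a];
            pb[t2] += flux;
            pb[f] -= flux;
          }
          solve_small(A.data(), pb.data(), ns);
          double ssum = 0.0;
          for (int s = 0; s < ns; ++s) {
            if (pb[s] < 0.0) pb[s] = 0.0;
            ssum += pb[s];
          }
          double err = std::fabs(ssum - 1.0);
          if (err > max_occ_err) max_occ_err = err;
          if (err > 1e-3) stop("Markov occupancy left the simplex");
          double open = 0.0;
          for (int s = 0; s < ns; ++s) {
            double ps = pb[s] / ssum;
            C.pstate[(size_t)s * na + a] = ps;
          }
          for (size_t k = 0; k < C.conducting.size(); ++k)
            open += C.pstate[(size_t)C.conducting[k] * na + a];
          double gc = C.g[a] * open;
          gsum[ic] += gc;
          gE[ic] += gc * C.e_rev;
          if (C.is_na) { gna[ic] += gc; gnaE[ic] += gc * C.e_rev; }
        }
      } else {
        for (int a = 0; a < na; ++a) {
          const int ic = C.comps[a];
          double cav = Ca[ic];
          double cah = std::pow(cav, C.hill);
          double ainf = (cav <= 0.0) ? 0.0
            : cah / (cah + std::pow(C.k_half, C.hill));
          double& x = C.astate[a];
          x = ainf + (x - ainf) * C.sk_expfac;
          double gc = C.g[a] * x;
          gsum[ic] += gc;
          gE[ic] += gc * C.e_rev;
        }
      }
    }

    // theta-method voltage solve over the tree (parent[i] < i):
    // c (V+ - V)/dt = theta I(V+) + (1-theta) I(V)
    for (int i = 0; i < n; ++i) {
      d[i] = cm[i] / dt + theta * gsum[i];
      rhs[i] = cm[i] / dt * V[i] + theta * gE[i] + i_inj[i] +
        (1.0 - theta) * (gE[i] - gsum[i] * V[i]);
    }
    for (int i = 1; i < n; ++i) {
      const int p = parent[i];
      d[i] += theta * g_ax[i];
      d[p] += theta * g_ax[i];
      const double iax = (1.0 - theta) * g_ax[i] * (V[p] - V[i]);
      rhs[i] += iax;
      rhs[p] -= iax;
    }
    for (int i = n - 1; i >= 1; --i) {
      const int p = parent[i];
      const double f = theta * g_ax[i] / d[i];
      d[p] -= f * theta * g_ax[i];
      rhs[p] += f * rhs[i];
    }
    V[0] = rhs[0] / d[0];
    for (int i = 1; i < n; ++i)
      V[i] = (rhs[i] + theta * g_ax[i] * V[parent[i]]) / d[i];

    // calcium pool: exponential decay with trapezoidal influx, using
    // the sodium current evaluated at the freshly solved voltage
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 200.0)
        stop("voltage diverged (|V| > 200 mV); reduce dt_ms");
      double ina_now = gna[i] * V[i] - gnaE[i];
      double j_now = ina_now < 0.0
        ? ca_phi * (-ina_now) / area[i] * 1e-6 : 0.0;
      double j_avg = 0.5 * (j_prev[i] + j_now);
      Ca[i] = Ca[i] * ca_ef + j_avg * ca_tau * (1.0 - ca_ef);
      j_prev[i] = j_now;
    }

    if (!settling) {
      const int k = step - n_settle;
      t_ms[k] = t_rel + dt;
      for (int j = 0; j < nrec; ++j) {
        Vrec(k, j) = V[record[j]];
        Carec(k, j) = Ca[record[j]];
      }
    }
  }

  NumericVector vfin(n);
  for (int i = 0; i < n; ++i) vfin[i] = V[i];

  return List::create(_["t_ms"] = t_ms, _["V"] = Vrec, _["Ca"] = Carec,
                      _["V_final"] = vfin,
                      _["max_occupancy_error"] = max_occ_err);
}
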