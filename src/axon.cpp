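// Double-cable myelinated axon (MRG-type) driven by extracellular potentials.
//
// Per compartment i the states are the axolemma membrane potential Vm_i and
// the periaxonal potential U_i (relative to the local extracellular value
// Ve_i).  Backward-Euler step on the coupled linear cable system (2x2 block
// tridiagonal, solved by block Thomas); nodal gating advanced by Rush-Larsen
// exponential updates at the previous voltage.
//
// Units: mV, ms, uS, nF (so currents are nA).  Nodal kinetics at 36 C with
// the published Q10 corrections folded in.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// A*u/(1 - exp(-u/C)) and A*(-u)/(1 - exp(u/C)); both tend to A*C at u = 0
static inline double vtrap_pos(double A, double u, double C) {
  if (std::fabs(u / C) < 1e-6) return A * C;
  return A * u / (1.0 - std::exp(-u / C));
}
static inline double vtrap_neg(double A, double u, double C) {
  if (std::fabs(u / C) < 1e-6) return A * C;
  return A * (-u) / (1.0 - std::exp(u / C));
}

struct Rates { double am, bm, ah, bh, ap, bp, as, bs; };

static Rates node_rates(double v) {
  const double q10_1 = std::pow(2.2, (36.0 - 20.0) / 10.0);
  const double q10_2 = std::pow(2.9, (36.0 - 20.0) / 10.0);
  const double q10_3 = 1.0; // 3.0^((36-36)/10)
  Rates r;
  r.am = q10_1 * vtrap_pos(6.57, v + 20.4, 10.3);
  r.bm = q10_1 * vtrap_neg(0.304, v + 25.7, 9.16);
  r.ah = q10_2 * vtrap_neg(0.34, v + 114.0, 11.0);
  r.bh = q10_2 * 12.6 / (1.0 + std::exp(-(v + 31.8) / 13.4));
  r.ap = q10_1 * vtrap_pos(0.0353, v + 27.0, 10.2);
  r.bp = q10_1 * vtrap_neg(0.000883, v + 34.0, 10.0);
  r.as = q10_3 * 0.3 / (1.0 + std::exp((v + 53.0) / -5.0));
  r.bs = q10_3 * 0.03 / (1.0 + std::exp((v + 90.0) / -1.0));
  return r;
}

// steady-state gating at a voltage (for initialisation / leak balancing)
// [[Rcpp::export(name = ".cpp_node_gates_inf")]]
NumericVector cpp_node_gates_inf(double v) {
  Rates r = node_rates(v);
  return NumericVector::create(_["m"] = r.am / (r.am + r.bm),
                               _["h"] = r.ah / (r.ah + r.bh),
                               _["p"] = r.ap / (r.ap + r.bp),
                               _["s"] = r.as / (r.as + r.bs));
}

// [[Rcpp::export(name = ".cpp_mrg_integrate")]]
List cpp_mrg_integrate(IntegerVector is_node, NumericVector C, NumericVector gpas,
                       NumericVector epas, NumericVector gnaf, NumericVector gnap,
                       NumericVector gks, NumericVector gl,
                       double ena, double ek, double el, double vrest,
                       NumericVector Cmy, NumericVector gmy,
                       NumericVector ga, NumericVector gp,
                       NumericVector drive, NumericVector a_t,
                       double amplitude, double dt,
                       IntegerVector record_idx) {
  const int n = is_node.size();
  const int nt = a_t.size();
  const int nrec = record_idx.size();

  std::vector<double> Vm(n, vrest), U(n, 0.0), m(n), h(n), p(n), s(n);
  {
    Rates r = node_rates(vrest);
    for (int i = 0; i < n; ++i) {
      m[i] = r.am / (r.am + r.bm); h[i] = r.ah / (r.ah + r.bh);
      p[i] = r.ap / (r.ap + r.bp); s[i] = r.as / (r.as + r.bs);
    }
  }

  NumericMatrix Vrec(nt + 1, nrec);
  for (int k = 0; k < nrec; ++k) Vrec(0, k) = vrest;

  // block Thomas workspaces
  std::vector<double> D11(n), D12(n), D22(n), b1(n), b2(n);
  std::vector<double> G11(n), G12(n), G21(n), G22(n), y1(n), y2(n);

  bool blown = false;
  double maxV = std::fabs(vrest);

  for (int step = 0; step < nt; ++step) {
    const double a_now = a_t[step];

    // gating (Rush-Larsen at V^n), linearised ionic term g_ion, g_ion*E_eff
    for (int i = 0; i < n; ++i) {
      double gion, gE;
      if (is_node[i]) {
        Rates r = node_rates(Vm[i]);
        double tm = 1.0 / (r.am + r.bm), th = 1.0 / (r.ah + r.bh);
        double tp = 1.0 / (r.ap + r.bp), ts = 1.0 / (r.as + r.bs);
        m[i] = r.am * tm + (m[i] - r.am * tm) * std::exp(-dt / tm);
        h[i] = r.ah * th + (h[i] - r.ah * th) * std::exp(-dt / th);
        p[i] = r.ap * tp + (p[i] - r.ap * tp) * std::exp(-dt / tp);
        s[i] = r.as * ts + (s[i] - r.as * ts) * std::exp(-dt / ts);
        double gna = gnaf[i] * m[i] * m[i] * m[i] * h[i];
        double gnp = gnap[i] * p[i] * p[i] * p[i];
        double gk = gks[i] * s[i];
        gion = gna + gnp + gk + gl[i];
        gE = (gna + gnp) * ena + gk * ek + gl[i] * el;
      } else {
        gion = gpas[i];
        gE = gpas[i] * epas[i];
      }
      // diagonal blocks and RHS (axial sums added below)
      D11[i] = C[i] / dt + gion;
      D12[i] = 0.0;
      D22[i] = Cmy[i] / dt + gmy[i];
      b1[i] = C[i] / dt * Vm[i] + gE;
      b2[i] = Cmy[i] / dt * U[i];
    }
    for (int i = 0; i < n - 1; ++i) {
      const double dVe = amplitude * a_now * (drive[i + 1] - drive[i]);
      // couple i and i+1
      D11[i] += ga[i];      D11[i + 1] += ga[i];
      D12[i] += ga[i];      D12[i + 1] += ga[i];
      D22[i] += ga[i] + gp[i]; D22[i + 1] += ga[i] + gp[i];
      b1[i] += ga[i] * dVe;          b1[i + 1] -= ga[i] * dVe;
      b2[i] += (ga[i] + gp[i]) * dVe; b2[i + 1] -= (ga[i] + gp[i]) * dVe;
    }

    // forward elimination: blocks are [[D11, D12],[D12, D22]], off-diagonal
    // O_i = -[[ga, ga],[ga, ga+gp]] between i and i+1 (symmetric)
    {
      double E11 = D11[0], E12 = D12[0], E22 = D22[0];
      double f1 = b1[0], f2 = b2[0];
      G11[0] = E11; G12[0] = E12; G21[0] = E12; G22[0] = E22;
      y1[0] = f1; y2[0] = f2;
      for (int i = 1; i < n; ++i) {
        const double o11 = -ga[i - 1], o12 = -ga[i - 1];
        const double o21 = -ga[i - 1], o22 = -(ga[i - 1] + gp[i - 1]);
        // inv of previous eliminated block
        double det = G11[i - 1] * G22[i - 1] - G12[i - 1] * G21[i - 1];
        double i11 = G22[i - 1] / det, i12 = -G12[i - 1] / det;
        double i21 = -G21[i - 1] / det, i22 = G11[i - 1] / det;
        // L = O * inv(prev)
        double L11 = o11 * i11 + o12 * i21, L12 = o11 * i12 + o12 * i22;
        double L21 = o21 * i11 + o22 * i21, L22 = o21 * i12 + o22 * i22;
        // new diagonal block = D_i - L * O (O symmetric, O_{i-1,i} = O)
        G11[i] = D11[i] - (L11 * o11 + L12 * o21);
        G12[i] = D12[i] - (L11 * o12 + L12 * o22);
        G21[i] = D12[i] - (L21 * o11 + L22 * o21);
        G22[i] = D22[i] - (L21 * o12 + L22 * o22);
        y1[i] = b1[i] - (L11 * y1[i - 1] + L12 * y2[i - 1]);
        y2[i] = b2[i] - (L21 * y1[i - 1] + L22 * y2[i - 1]);
      }
      // back substitution
      double det = G11[n - 1] * G22[n - 1] - G12[n - 1] * G21[n - 1];
      Vm[n - 1] = (G22[n - 1] * y1[n - 1] - G12[n - 1] * y2[n - 1]) / det;
      U[n - 1] = (-G21[n - 1] * y1[n - 1] + G11[n - 1] * y2[n - 1]) / det;
      for (int i = n - 2; i >= 0; --i) {
        const double o11 = -ga[i], o12 = -ga[i];
        const double o21 = -ga[i], o22 = -(ga[i] + gp[i]);
        double r1 = y1[i] - (o11 * Vm[i + 1] + o12 * U[i + 1]);
        double r2 = y2[i] - (o21 * Vm[i + 1] + o22 * U[i + 1]);
        det = G11[i] * G22[i] - G12[i] * G21[i];
        Vm[i] = (G22[i] * r1 - G12[i] * r2) / det;
        U[i] = (-G21[i] * r1 + G11[i] * r2) / det;
      }
    }

    for (int k = 0; k < nrec; ++k) Vrec(step + 1, k) = Vm[record_idx[k] - 1];
    for (int i = 0; i < n; ++i) {
      if (std::fabs(Vm[i]) > maxV) maxV = std::fabs(Vm[i]);
      if (std::fabs(Vm[i]) > 500.0) { blown = true; break; }
    }
    if (blown) {
      for (int st = step + 2; st <= nt; ++st)
        for (int k = 0; k < nrec; ++k) Vrec(st, k) = NA_REAL;
      break;
    }
  }

  return List::create(_["V"] = Vrec, _["blown_up"] = blown, _["max_abs_Vm"] = maxV);
}
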