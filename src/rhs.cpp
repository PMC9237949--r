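// Compiled right-hand side for flattened composite models.
//
// Mass-action / Hill reactions are table-driven; the packaged non-reaction
// modules (calcium-oscillator gating, NFAT futile cycle, PLC-scaled IP3
// synthesis, calcium-driven calcineurin activation) are available as named
// kernels. Models using only these pieces integrate through this path; any
// other custom rate falls back to the interpreted R evaluator.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

struct ReactionC {
  int type;                 // 1 irreversible, 2 reversible, 3 hill
  double k1, k2, k3;        // k | kf,kr | vmax,khalf,n
  std::vector<int> fidx;    // forward concentration factors (0-based)
  std::vector<int> pidx;    // reverse factors (reversible only)
  std::vector<int> net_idx; // species receiving net stoichiometry
  std::vector<double> net_coef;
};

struct KernelC {
  int type;                 // 1 dupont_ca, 2 nfat_cooling, 3 plc_ip3, 4 ca_nfat
  std::vector<double> par;  // kernel parameters, fixed order
  std::vector<int> sidx;    // kernel state indices (0-based)
  std::vector<int> oidx;    // kernel output indices (0-based)
};

struct ModelC {
  int nsp;
  std::vector<ReactionC> rx;
  std::vector<KernelC> kn;
  std::vector<int> clamped;
};

static inline double prod_at(const std::vector<int>& idx, const double* st) {
  double p = 1.0;
  for (size_t i = 0; i < idx.size(); ++i) p *= st[idx[i]];
  return p;
}

// [[Rcpp::export]]
SEXP rhs_build(int nsp, List reactions, List kernels, IntegerVector clamped) {
  ModelC* m = new ModelC();
  m->nsp = nsp;
  for (int i = 0; i < reactions.size(); ++i) {
    List r = reactions[i];
    ReactionC rc;
    rc.type = as<int>(r["type"]);
    NumericVector ks = r["k"];
    rc.k1 = ks[0];
    rc.k2 = ks.size() > 1 ? ks[1] : 0.0;
    rc.k3 = ks.size() > 2 ? ks[2] : 0.0;
    rc.fidx = as<std::vector<int> >(r["fidx"]);
    rc.pidx = as<std::vector<int> >(r["pidx"]);
    rc.net_idx = as<std::vector<int> >(r["net_idx"]);
    rc.net_coef = as<std::vector<double> >(r["net_coef"]);
    m->rx.push_back(rc);
  }
  for (int i = 0; i < kernels.size(); ++i) {
    List k = kernels[i];
    KernelC kc;
    kc.type = as<int>(k["type"]);
    kc.par = as<std::vector<double> >(k["par"]);
    kc.sidx = as<std::vector<int> >(k["sidx"]);
    kc.oidx = as<std::vector<int> >(k["oidx"]);
    m->kn.push_back(kc);
  }
  m->clamped = as<std::vector<int> >(clamped);
  XPtr<ModelC> ptr(m, true);
  return ptr;
}

static void eval_kernel(const KernelC& k, const double* st, double* d) {
  switch (k.type) {
  case 1: { // dupont_ca: states Ccyto, Catot, Ira, h_gate, IP3, IP4, stim
    // par: k_1 b alpha VMP Kp np K_act K_inh K_ip tau_a tau_h Vplc V3k
    //      K_d3k K_3k r_5p r_ip4
    const std::vector<double>& p = k.par;
    double C = std::max(st[k.sidx[0]], 0.0);
    double Catot = st[k.sidx[1]];
    double Ira = st[k.sidx[2]];
    double h = st[k.sidx[3]];
    double IP3 = std::max(st[k.sidx[4]], 0.0);
    double IP4 = std::max(st[k.sidx[5]], 0.0);
    double stim = std::max(st[k.sidx[6]], 0.0);
    double release = p[0] * (p[1] + Ira) * (Catot - C * (p[2] + 1.0));
    double Cn = std::pow(C, p[5]);
    double pump = (C > 0.0) ? p[3] * Cn / (std::pow(p[4], p[5]) + Cn) : 0.0;
    double a_inf = (IP3 * IP3 / (IP3 * IP3 + p[8] * p[8])) *
                   (C * C / (C * C + p[6] * p[6]));
    double h_inf = p[7] * p[7] / (p[7] * p[7] + C * C);
    double J3k = p[12] * (C * C / (C * C + p[13] * p[13])) * IP3 / (IP3 + p[14]);
    double Jsyn = p[11] * stim;
    d[k.oidx[0]] += release - pump;           // Ccyto
    d[k.oidx[1]] += (a_inf * h - Ira) / p[9]; // Ira
    d[k.oidx[2]] += (h_inf - h) / p[10];      // h_gate
    d[k.oidx[3]] += Jsyn - J3k - p[15] * IP3; // IP3
    d[k.oidx[4]] += J3k - p[16] * IP4;        // IP4
    break;
  }
  case 2: { // nfat_cooling: states NFATp_c NFATN_c NFATN_n NFATp_n act_N
    // par: kf_21 kr_21 kf_22 kf_23 kr_23 kf_24 N_tot
    const std::vector<double>& p = k.par;
    double a = st[k.sidx[4]];
    if (a < 0.0) a = 0.0;
    if (a > 1.0) a = 1.0;
    double J1 = p[0] * st[k.sidx[0]] * p[6] * a -
                p[1] * st[k.sidx[1]] * (1.0 - a);
    double J2 = p[2] * st[k.sidx[1]];
    double J3 = p[3] * st[k.sidx[2]] - p[4] * st[k.sidx[3]] * p[6] * a;
    double J4 = p[5] * st[k.sidx[3]];
    d[k.oidx[0]] += J4 - J1;
    d[k.oidx[1]] += J1 - J2;
    d[k.oidx[2]] += J2 - J3;
    d[k.oidx[3]] += J3 - J4;
    break;
  }
  case 3: { // plc_ip3: states plc_act; par: Vplc plc_tot
    double plc_act = std::max(st[k.sidx[0]], 0.0);
    d[k.oidx[0]] += k.par[0] * plc_act / k.par[1];
    break;
  }
  case 4: { // ca_nfat: states Ccyto act_N; par: k_f K_actN
    double C = std::max(st[k.sidx[0]], 0.0);
    double sat = C * C / (C * C + k.par[1] * k.par[1]);
    d[k.oidx[0]] += k.par[0] * (sat - st[k.sidx[1]]);
    break;
  }
  }
}

// [[Rcpp::export]]
NumericVector rhs_eval(SEXP ptr, double t, NumericVector y) {
  XPtr<ModelC> m(ptr);
  int n = m->nsp;
  std::vector<double> st(n);
  for (int i = 0; i < n; ++i) st[i] = y[i] > 0.0 ? y[i] : 0.0;
  NumericVector d(n);
  double* dp = REAL(d);
  const double* sp = &st[0];
  for (size_t r = 0; r < m->rx.size(); ++r) {
    const ReactionC& rc = m->rx[r];
    double J;
    if (rc.type == 1) {
      J = rc.k1 * prod_at(rc.fidx, sp);
    } else if (rc.type == 2) {
      J = rc.k1 * prod_at(rc.fidx, sp) - rc.k2 * prod_at(rc.pidx, sp);
    } else {
      double C = sp[rc.fidx[0]];
      J = (C > 0.0)
        ? rc.k1 * std::pow(C, rc.k3) /
            (std::pow(rc.k2, rc.k3) + std::pow(C, rc.k3))
        : 0.0;
    }
    for (size_t i = 0; i < rc.net_idx.size(); ++i) {
      dp[rc.net_idx[i]] += rc.net_coef[i] * J;
    }
  }
  for (size_t i = 0; i < m->kn.size(); ++i) eval_kernel(m->kn[i], sp, dp);
  for (size_t i = 0; i < m->clamped.size(); ++i) dp[m->clamped[i]] = 0.0;
  return d;
}
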