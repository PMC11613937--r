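// Marginal likelihood of the two-level latent trait model by nested
// Gauss-Hermite quadrature, with analytic gradients.
//
// Model, per subject:
//   Violence = omega'Z + xi,           xi ~ N(0,1)  (omega'Z = 0 if no covariates)
//   Cost     = gamma * Violence + eps, eps ~ N(0,1)
//   v_j = b_j * Violence + e_j,  e_j ~ N(0,1)   (violence-side factors)
//   c_l = th_l * Cost + e_l,     e_l ~ N(0,1)   (cost-side factors)
//   P(item category >= s | f) = logistic(a_i * f - tau_{i,s})   (2PL / graded)
//
// Conditional independence of items given their first-order factor lets the
// latent integral factor into a 2-D outer grid over (xi, eps) times independent
// 1-D inner grids, one per first-order factor.  Without covariates every
// quadrature cell is shared across subjects, so per-item category log-probs
// and their threshold partials are tabulated once per call.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double PCLAMP = 1e-12;
static const int MAXBLOCK = 32; // items per first-order factor

// log category probability and d/dtau1, d/dtau2 for one item at latent value v.
static inline void item_cell(int x, int ncat, double tau1, double tau2,
                             double a, double v,
                             double &logp, double &dt1, double &dt2) {
  double u1 = a * v - tau1;
  double p1 = 1.0 / (1.0 + std::exp(-u1));
  double g1 = p1 * (1.0 - p1);
  if (ncat == 2) {
    double p = (x == 1) ? p1 : (1.0 - p1);
    if (p < PCLAMP) p = PCLAMP;
    logp = std::log(p);
    dt1 = ((x == 1) ? -g1 : g1) / p;
    dt2 = 0.0;
  } else {
    double u2 = a * v - tau2;
    double p2 = 1.0 / (1.0 + std::exp(-u2));
    double g2 = p2 * (1.0 - p2);
    double p, d1, d2; // dP(cat)/dtau{1,2}
    if (x == 0)      { p = 1.0 - p1;    d1 = g1;  d2 = 0.0; }
    else if (x == 1) { p = p1 - p2;     d1 = -g1; d2 = g2;  }
    else             { p = p2;          d1 = 0.0; d2 = -g2; }
    if (p < PCLAMP) p = PCLAMP;
    logp = std::log(p);
    dt1 = d1 / p;
    dt2 = d2 / p;
  }
}

struct FactorBlock {
  std::vector<int> items;
  double b;   // structural loading (beta or theta)
  bool cost;
};

// [[Rcpp::export]]
List loglik_engine(IntegerMatrix X, IntegerVector item_fac, IntegerVector ncat,
                   NumericVector tau1, NumericVector tau2, NumericVector a,
                   IntegerVector fac_side, NumericVector bstr, double gamma,
                   NumericVector offset, NumericMatrix Z,
                   NumericVector nodes_out, NumericVector w_out,
                   NumericVector nodes_in, NumericVector w_in,
                   bool want_grad, bool want_persub) {
  const int n = X.nrow(), p = X.ncol(), nf = fac_side.size();
  const int T = nodes_out.size(), Q = nodes_in.size();
  const int ncov = Z.ncol();
  const bool has_offset = offset.size() == (R_xlen_t)n;

  std::vector<FactorBlock> fb(nf);
  bool has_cost = false;
  for (int j = 0; j < nf; ++j) {
    fb[j].b = bstr[j];
    fb[j].cost = fac_side[j] == 1;
    if (fb[j].cost) has_cost = true;
  }
  for (int i = 0; i < p; ++i) {
    fb[item_fac[i]].items.push_back(i);
  }
  for (int j = 0; j < nf; ++j)
    if ((int)fb[j].items.size() > MAXBLOCK)
      stop("factor block exceeds %d items", MAXBLOCK);
  const int U = has_cost ? T : 1;
  const int TQ = T * Q, TUQ = T * U * Q;

  // ---- tabulate item cells when every subject shares the latent grid ----
  const bool use_tab = !has_offset;
  std::vector<double> tabV, tabC, vvalV, vvalC;
  if (use_tab) {
    tabV.assign((size_t)p * TQ * 9, 0.0);
    vvalV.assign((size_t)p * TQ, 0.0);
    if (has_cost) {
      tabC.assign((size_t)p * TUQ * 9, 0.0);
      vvalC.assign((size_t)p * TUQ, 0.0);
    }
    for (int j = 0; j < nf; ++j) {
      const FactorBlock &F = fb[j];
      for (size_t ii = 0; ii < F.items.size(); ++ii) {
        int i = F.items[ii];
        if (!F.cost) {
          for (int t = 0; t < T; ++t)
            for (int q = 0; q < Q; ++q) {
              double v = F.b * nodes_out[t] + nodes_in[q];
              size_t cell = (size_t)t * Q + q;
              vvalV[(size_t)i * TQ + cell] = v;
              for (int x = 0; x < ncat[i]; ++x) {
                double lp, d1, d2;
                item_cell(x, ncat[i], tau1[i], tau2[i], a[i], v, lp, d1, d2);
                size_t base = ((size_t)i * TQ + cell) * 9 + (size_t)x * 3;
                tabV[base] = lp; tabV[base + 1] = d1; tabV[base + 2] = d2;
              }
            }
        } else {
          for (int t = 0; t < T; ++t)
            for (int u = 0; u < U; ++u) {
              double C = gamma * nodes_out[t] + nodes_out[u];
              for (int q = 0; q < Q; ++q) {
                double v = F.b * C + nodes_in[q];
                size_t cell = ((size_t)t * U + u) * Q + q;
                vvalC[(size_t)i * TUQ + cell] = v;
                for (int x = 0; x < ncat[i]; ++x) {
                  double lp, d1, d2;
                  item_cell(x, ncat[i], tau1[i], tau2[i], a[i], v, lp, d1, d2);
                  size_t base = ((size_t)i * TUQ + cell) * 9 + (size_t)x * 3;
                  tabC[base] = lp; tabC[base + 1] = d1; tabC[base + 2] = d2;
                }
              }
            }
        }
      }
    }
  }

  NumericVector g_t1(p), g_t2(p), g_a(p), g_b(nf), g_om(ncov);
  double g_gamma = 0.0;
  NumericVector persub(want_persub ? n : 0);

  double total = 0.0;

  // per-subject scratch
  std::vector<double> s_t1(p), s_t2(p), s_a(p), s_b(nf);
  std::vector<double> vA(T * (size_t)nf), vAdot(T * (size_t)nf);
  std::vector<double> vD1(T * (size_t)p), vD2(T * (size_t)p), vDa(T * (size_t)p);
  double bt1[MAXBLOCK], bt2[MAXBLOCK], ba[MAXBLOCK];
  double lt1[MAXBLOCK], lt2[MAXBLOCK];
  int ncf = 0;
  for (int j = 0; j < nf; ++j) if (fb[j].cost) ++ncf;
  if (ncf > 8) stop("at most 8 cost-side factors supported");
  double io_t1[8][MAXBLOCK], io_t2[8][MAXBLOCK], io_a[8][MAXBLOCK];

  for (int s = 0; s < n; ++s) {
    const double off = has_offset ? offset[s] : 0.0;
    double lik = 0.0, dlik_gamma = 0.0, dlik_vio = 0.0;
    if (want_grad) {
      std::fill(s_t1.begin(), s_t1.end(), 0.0);
      std::fill(s_t2.begin(), s_t2.end(), 0.0);
      std::fill(s_a.begin(), s_a.end(), 0.0);
      std::fill(s_b.begin(), s_b.end(), 0.0);
    }

    // violence-side inner integrals, cached over t
    for (int t = 0; t < T; ++t) {
      double vio = off + nodes_out[t];
      for (int j = 0; j < nf; ++j) {
        if (fb[j].cost) continue;
        const FactorBlock &F = fb[j];
        const size_t ni = F.items.size();
        double A = 0.0, adot = 0.0;
        if (want_grad)
          for (size_t ii = 0; ii < ni; ++ii) {
            int i = F.items[ii];
            vD1[t * (size_t)p + i] = 0.0;
            vD2[t * (size_t)p + i] = 0.0;
            vDa[t * (size_t)p + i] = 0.0;
          }
        for (int q = 0; q < Q; ++q) {
          double S = 0.0;
          bool anyobs = false;
          double vq = F.b * vio + nodes_in[q];
          for (size_t ii = 0; ii < ni; ++ii) {
            int i = F.items[ii];
            int x = X(s, i);
            if (x == NA_INTEGER) { lt1[ii] = 0.0; lt2[ii] = 0.0; continue; }
            anyobs = true;
            double lp, d1, d2;
            if (use_tab) {
              size_t base = ((size_t)i * TQ + (size_t)t * Q + q) * 9 + (size_t)x * 3;
              lp = tabV[base]; d1 = tabV[base + 1]; d2 = tabV[base + 2];
            } else {
              item_cell(x, ncat[i], tau1[i], tau2[i], a[i], vq, lp, d1, d2);
            }
            S += lp; lt1[ii] = d1; lt2[ii] = d2;
          }
          double E = w_in[q] * std::exp(S);
          A += E;
          if (want_grad && anyobs) {
            double sumdv = 0.0;
            for (size_t ii = 0; ii < ni; ++ii) {
              int i = F.items[ii];
              double d12 = lt1[ii] + lt2[ii];
              vD1[t * (size_t)p + i] += E * lt1[ii];
              vD2[t * (size_t)p + i] += E * lt2[ii];
              vDa[t * (size_t)p + i] += E * (-vq) * d12; // dlogp/da = -v*(dt1+dt2)
              sumdv += -a[i] * d12;                      // dlogp/dv
            }
            adot += E * sumdv;
          }
        }
        vA[t * (size_t)nf + j] = A;
        vAdot[t * (size_t)nf + j] = adot;
      }
    }

    for (int t = 0; t < T; ++t) {
      double vio = off + nodes_out[t];
      double P = 1.0;
      for (int j = 0; j < nf; ++j) if (!fb[j].cost) P *= vA[t * (size_t)nf + j];

      double Qs = 1.0, dQ_gamma = 0.0, dQ_vio = 0.0;
      if (has_cost) {
        Qs = 0.0;
        for (int u = 0; u < U; ++u) {
          double C = gamma * vio + nodes_out[u];
          double Bprod = 1.0;
          double Bj[8], Badot[8];
          int cj = 0;
          // first pass: inner integrals per cost factor
          for (int j = 0; j < nf; ++j) {
            if (!fb[j].cost) continue;
            const FactorBlock &F = fb[j];
            const size_t ni = F.items.size();
            double B = 0.0, ddot = 0.0;
            if (want_grad)
              for (size_t ii = 0; ii < ni; ++ii) { bt1[ii] = 0.0; bt2[ii] = 0.0; ba[ii] = 0.0; }
            for (int q = 0; q < Q; ++q) {
              double S = 0.0;
              bool anyobs = false;
              double vq = F.b * C + nodes_in[q];
              for (size_t ii = 0; ii < ni; ++ii) {
                int i = F.items[ii];
                int x = X(s, i);
                if (x == NA_INTEGER) { lt1[ii] = 0.0; lt2[ii] = 0.0; continue; }
                anyobs = true;
                double lp, d1, d2;
                if (use_tab) {
                  size_t base = ((size_t)i * TUQ + ((size_t)t * U + u) * Q + q) * 9
                                + (size_t)x * 3;
                  lp = tabC[base]; d1 = tabC[base + 1]; d2 = tabC[base + 2];
                } else {
                  item_cell(x, ncat[i], tau1[i], tau2[i], a[i], vq, lp, d1, d2);
                }
                S += lp; lt1[ii] = d1; lt2[ii] = d2;
              }
              double E = w_in[q] * std::exp(S);
              B += E;
              if (want_grad && anyobs) {
                double sumdv = 0.0;
                for (size_t ii = 0; ii < ni; ++ii) {
                  int i = F.items[ii];
                  double d12 = lt1[ii] + lt2[ii];
                  bt1[ii] += E * lt1[ii];
                  bt2[ii] += E * lt2[ii];
                  ba[ii]  += E * (-vq) * d12;
                  sumdv += -a[i] * d12;
                }
                ddot += E * sumdv;
              }
            }
            Bj[cj] = B; Badot[cj] = ddot;
            Bprod *= B;
            // partials get scaled once Bprod over all cost factors is known
            if (want_grad)
              for (size_t ii = 0; ii < ni; ++ii) {
                io_t1[cj][ii] = bt1[ii]; io_t2[cj][ii] = bt2[ii]; io_a[cj][ii] = ba[ii];
              }
            ++cj;
          }
          Qs += w_out[u] * Bprod;
          if (want_grad) {
            cj = 0;
            for (int j = 0; j < nf; ++j) {
              if (!fb[j].cost) continue;
              const FactorBlock &F = fb[j];
              double rest = (Bj[cj] > 0.0) ? w_out[u] * Bprod / Bj[cj] : 0.0;
              double sc = w_out[t] * P * rest;
              for (size_t ii = 0; ii < F.items.size(); ++ii) {
                int i = F.items[ii];
                s_t1[i] += sc * io_t1[cj][ii];
                s_t2[i] += sc * io_t2[cj][ii];
                s_a[i]  += sc * io_a[cj][ii];
              }
              s_b[j] += sc * Badot[cj] * C;              // d loc/d theta = C
              dQ_gamma += rest * Badot[cj] * F.b * vio;  // dC/dgamma = vio
              dQ_vio   += rest * Badot[cj] * F.b * gamma;
              ++cj;
            }
          }
        }
      }

      lik += w_out[t] * P * Qs;
      if (want_grad) {
        dlik_gamma += w_out[t] * P * dQ_gamma;
        double dP_vio = 0.0;
        for (int j = 0; j < nf; ++j) {
          if (fb[j].cost) continue;
          const FactorBlock &F = fb[j];
          double Aj = vA[t * (size_t)nf + j];
          double rest = (Aj > 0.0) ? P / Aj : 0.0;
          double sc = w_out[t] * Qs * rest;
          for (size_t ii = 0; ii < F.items.size(); ++ii) {
            int i = F.items[ii];
            s_t1[i] += sc * vD1[t * (size_t)p + i];
            s_t2[i] += sc * vD2[t * (size_t)p + i];
            s_a[i]  += sc * vDa[t * (size_t)p + i];
          }
          s_b[j] += sc * vAdot[t * (size_t)nf + j] * vio; // d loc/d beta = vio
          dP_vio += rest * vAdot[t * (size_t)nf + j] * F.b;
        }
        dlik_vio += w_out[t] * (Qs * dP_vio + P * dQ_vio);
      }
    }

    if (!std::isfinite(lik))
      stop("non-finite likelihood contribution at subject %d", s + 1);
    if (lik <= 0.0) {
      total += std::log(1e-300); // underflow guard; gradient contribution dropped
      if (want_persub) persub[s] = std::log(1e-300);
      continue;
    }
    total += std::log(lik);
    if (want_persub) persub[s] = std::log(lik);
    if (want_grad) {
      double inv = 1.0 / lik;
      for (int i = 0; i < p; ++i) {
        g_t1[i] += inv * s_t1[i];
        g_t2[i] += inv * s_t2[i];
        g_a[i]  += inv * s_a[i];
      }
      for (int j = 0; j < nf; ++j) g_b[j] += inv * s_b[j];
      g_gamma += inv * dlik_gamma;
      for (int m = 0; m < ncov; ++m) g_om[m] += inv * dlik_vio * Z(s, m);
    }
  }

  List out = List::create(_["loglik"] = total);
  if (want_grad) {
    out["grad_tau1"] = g_t1; out["grad_tau2"] = g_t2; out["grad_a"] = g_a;
    out["grad_b"] = g_b; out["grad_gamma"] = g_gamma; out["grad_omega"] = g_om;
  }
  if (want_persub) out["persub"] = persub;
  return out;
}
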