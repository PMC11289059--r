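#include <Rcpp.h>
#include "wfpt.h"
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs sampler for the hierarchical DDM.
//
// Parameter layout per individual (participant x block) unit, index j:
//   0 v_rich, 1 v_lean, 2 a_rich, 3 a_lean, 4 t_rich, 5 t_lean, 6 z_raw
// Each unit belongs to one group-level cell (feedback type x block) with a
// mean and SD for every j. Individual parameters are normal around the cell
// mean, truncated to the support below; the starting bias enters the
// likelihood as Phi(z_raw) on rich trials and 1 - Phi(z_raw) on lean trials
// (accuracy coding: the upper boundary is the correct response).

static const int NP = 7;
// individual-level truncation bounds
static const double IND_LO[NP] = {R_NegInf, R_NegInf, 0.0, 0.0, 0.0, 0.0, -4.0};
static const double IND_HI[NP] = {R_PosInf, R_PosInf, R_PosInf, R_PosInf,
                                  1.0, 1.0, 4.0};

struct Unit {
  std::vector<double> rt_rich, rt_lean;
  std::vector<int> up_rich, up_lean;  // 1 = upper (= correct) boundary
  int cell;
};

// log of the truncated-normal normalising constant Phi((hi-mu)/sd)-Phi((lo-mu)/sd)
static double log_trunc_const(double mu, double sd, double lo, double hi) {
  if (!R_FINITE(lo) && !R_FINITE(hi)) return 0.0;
  double phi_hi = R_FINITE(hi) ? R::pnorm(hi, mu, sd, 1, 0) : 1.0;
  double phi_lo = R_FINITE(lo) ? R::pnorm(lo, mu, sd, 1, 0) : 0.0;
  double z = phi_hi - phi_lo;
  return (z > 0.0) ? std::log(z) : R_NegInf;
}

static double cond_loglik(const Unit &u, bool rich, const double *th,
                          double s, double eps) {
  const std::vector<double> &rt = rich ? u.rt_rich : u.rt_lean;
  const std::vector<int> &up = rich ? u.up_rich : u.up_lean;
  double v = th[rich ? 0 : 1], a = th[rich ? 2 : 3], t0 = th[rich ? 4 : 5];
  double z = R::pnorm(th[6], 0.0, 1.0, 1, 0);
  double w = rich ? z : 1.0 - z;
  double ll = 0.0;
  for (size_t i = 0; i < rt.size(); ++i) {
    double dt = rt[i] - t0;
    double l = (dt > 0.0) ? wfpt_logf(dt, up[i], v, a, w, s, eps) : R_NegInf;
    if (!R_FINITE(l)) return R_NegInf;
    ll += l;
  }
  return ll;
}

// [[Rcpp::export(name = ".hddm_chain_cpp")]]
List hddm_chain_cpp(List unit_data, IntegerVector unit_cell, int n_cells,
                    NumericMatrix ind_init, NumericMatrix mu_init,
                    NumericMatrix sd_init, List prior,
                    int n_warmup, int n_draws, int n_thin,
                    double s, double eps) {
  int U = unit_data.size();
  std::vector<Unit> units(U);
  for (int u = 0; u < U; ++u) {
    List d = unit_data[u];
    NumericVector rt = d["rt"];
    IntegerVector up = d["upper"];
    IntegerVector rich = d["rich"];
    units[u].cell = unit_cell[u];
    for (int i = 0; i < rt.size(); ++i) {
      if (rich[i]) {
        units[u].rt_rich.push_back(rt[i]);
        units[u].up_rich.push_back(up[i]);
      } else {
        units[u].rt_lean.push_back(rt[i]);
        units[u].up_lean.push_back(up[i]);
      }
    }
  }

  double v_prior_sd = as<double>(prior["v_prior_sd"]);
  double sd_scale = as<double>(prior["sd_scale"]);
  NumericVector mu_lo = prior["mu_lo"];  // length 7, -Inf where normal prior
  NumericVector mu_hi = prior["mu_hi"];

  // state
  NumericMatrix ind(clone(ind_init));      // U x 7
  NumericMatrix mu(clone(mu_init));        // C x 7
  NumericMatrix sdp(clone(sd_init));       // C x 7
  std::vector<double> ll_rich(U), ll_lean(U);
  std::vector<std::vector<double> > th(U, std::vector<double>(NP));
  for (int u = 0; u < U; ++u)
    for (int j = 0; j < NP; ++j) th[u][j] = ind(u, j);
  std::vector<std::vector<double> > gmu(n_cells, std::vector<double>(NP)),
      gsd(n_cells, std::vector<double>(NP));
  for (int c = 0; c < n_cells; ++c)
    for (int j = 0; j < NP; ++j) {
      gmu[c][j] = mu(c, j);
      gsd[c][j] = sdp(c, j);
    }
  for (int u = 0; u < U; ++u) {
    ll_rich[u] = cond_loglik(units[u], true, th[u].data(), s, eps);
    ll_lean[u] = cond_loglik(units[u], false, th[u].data(), s, eps);
  }

  // adaptation state
  std::vector<std::vector<double> > step_ind(U, std::vector<double>(NP)),
      acc_ind(U, std::vector<double>(NP, 0.0));
  std::vector<std::vector<double> > step_mu(n_cells, std::vector<double>(NP, 0.2)),
      acc_mu(n_cells, std::vector<double>(NP, 0.0)),
      step_sd(n_cells, std::vector<double>(NP, 0.3)),
      acc_sd(n_cells, std::vector<double>(NP, 0.0));
  double init_step[NP] = {0.25, 0.25, 0.12, 0.12, 0.04, 0.04, 0.25};
  for (int u = 0; u < U; ++u)
    for (int j = 0; j < NP; ++j) step_ind[u][j] = init_step[j];

  // one stored draw corresponds to n_thin full Gibbs sweeps; warmup
  // counts stored-draw equivalents so the adaptation horizon scales too
  const int batch = 50;
  if (n_thin < 1) n_thin = 1;
  long warm_sweeps = (long)n_warmup * n_thin;
  long n_iter = warm_sweeps + (long)n_draws * n_thin;
  int P_total = U * NP + 2 * n_cells * NP;
  NumericMatrix draws(n_draws, P_total);

  for (long it = 0; it < n_iter; ++it) {
    // --- individual-level updates ---
    for (int u = 0; u < U; ++u) {
      int c = units[u].cell;
      for (int j = 0; j < NP; ++j) {
        double cur = th[u][j];
        double prop = cur + step_ind[u][j] * norm_rand();
        if (prop < IND_LO[j] || prop > IND_HI[j]) continue;  // prior = 0
        double dlp = R::dnorm(prop, gmu[c][j], gsd[c][j], 1) -
                     R::dnorm(cur, gmu[c][j], gsd[c][j], 1);
        double new_r = ll_rich[u], new_l = ll_lean[u], dll = 0.0;
        th[u][j] = prop;
        bool touches_rich = (j == 0 || j == 2 || j == 4 || j == 6);
        bool touches_lean = (j == 1 || j == 3 || j == 5 || j == 6);
        if (touches_rich) {
          new_r = cond_loglik(units[u], true, th[u].data(), s, eps);
          dll += new_r - ll_rich[u];
        }
        if (touches_lean) {
          new_l = cond_loglik(units[u], false, th[u].data(), s, eps);
          dll += new_l - ll_lean[u];
        }
        if (R_FINITE(dll) && std::log(unif_rand()) < dll + dlp) {
          ll_rich[u] = new_r;
          ll_lean[u] = new_l;
          acc_ind[u][j] += 1.0;
        } else {
          th[u][j] = cur;
        }
      }
    }

    // --- group-level updates ---
    for (int c = 0; c < n_cells; ++c) {
      for (int j = 0; j < NP; ++j) {
        // mean
        double cur = gmu[c][j];
        double prop = cur + step_mu[c][j] * norm_rand();
        bool ok = true;
        double dlp = 0.0;
        if (j <= 1) {  // drift means: normal prior
          dlp = R::dnorm(prop, 0.0, v_prior_sd, 1) -
                R::dnorm(cur, 0.0, v_prior_sd, 1);
        } else if (prop < mu_lo[j] || prop > mu_hi[j]) {
          ok = false;  // uniform prior support
        }
        if (ok) {
          double dll = 0.0;
          for (int u = 0; u < U; ++u) {
            if (units[u].cell != c) continue;
            dll += R::dnorm(th[u][j], prop, gsd[c][j], 1) -
                   log_trunc_const(prop, gsd[c][j], IND_LO[j], IND_HI[j]) -
                   (R::dnorm(th[u][j], cur, gsd[c][j], 1) -
                    log_trunc_const(cur, gsd[c][j], IND_LO[j], IND_HI[j]));
          }
          if (R_FINITE(dll) && std::log(unif_rand()) < dll + dlp) {
            gmu[c][j] = prop;
            acc_mu[c][j] += 1.0;
          }
        }
        // sd: random walk on log scale, half-Cauchy prior
        double cs = gsd[c][j];
        double ps = cs * std::exp(step_sd[c][j] * norm_rand());
        double dlps = -std::log1p((ps / sd_scale) * (ps / sd_scale)) +
                      std::log1p((cs / sd_scale) * (cs / sd_scale)) +
                      std::log(ps) - std::log(cs);  // Jacobian of log-walk
        double dll = 0.0;
        for (int u = 0; u < U; ++u) {
          if (units[u].cell != c) continue;
          dll += R::dnorm(th[u][j], gmu[c][j], ps, 1) -
                 log_trunc_const(gmu[c][j], ps, IND_LO[j], IND_HI[j]) -
                 (R::dnorm(th[u][j], gmu[c][j], cs, 1) -
                  log_trunc_const(gmu[c][j], cs, IND_LO[j], IND_HI[j]));
        }
        if (R_FINITE(dll) && std::log(unif_rand()) < dll + dlps) {
          gsd[c][j] = ps;
          acc_sd[c][j] += 1.0;
        }
      }
    }

    // --- step-size adaptation during warmup ---
    if (it < warm_sweeps && (it + 1) % batch == 0) {
      double delta = std::min(0.1, 1.0 / std::sqrt((it + 1.0) / batch));
      for (int u = 0; u < U; ++u)
        for (int j = 0; j < NP; ++j) {
          step_ind[u][j] *= std::exp(acc_ind[u][j] / batch > 0.44 ? delta : -delta);
          acc_ind[u][j] = 0.0;
        }
      for (int c = 0; c < n_cells; ++c)
        for (int j = 0; j < NP; ++j) {
          step_mu[c][j] *= std::exp(acc_mu[c][j] / batch > 0.44 ? delta : -delta);
          step_sd[c][j] *= std::exp(acc_sd[c][j] / batch > 0.44 ? delta : -delta);
          acc_mu[c][j] = 0.0;
          acc_sd[c][j] = 0.0;
        }
    }

    // --- store post-warmup draws (every n_thin-th sweep) ---
    if (it >= warm_sweeps && (it - warm_sweeps + 1) % n_thin == 0) {
      int row = (int)((it - warm_sweeps + 1) / n_thin) - 1, col = 0;
      for (int u = 0; u < U; ++u)
        for (int j = 0; j < NP; ++j) draws(row, col++) = th[u][j];
      for (int c = 0; c < n_cells; ++c)
        for (int j = 0; j < NP; ++j) draws(row, col++) = gmu[c][j];
      for (int c = 0; c < n_cells; ++c)
        for (int j = 0; j < NP; ++j) draws(row, col++) = gsd[c][j];
    }
    if ((it + 1) % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["draws"] = draws);
}
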