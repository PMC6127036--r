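#include <Rcpp.h>
using namespace Rcpp;

// Chang-Cooper weighting for cell Peclet number w = mu*de/D.
// delta -> 1/2 (central) as w -> 0, and to the upwind side as |w| grows,
// keeping the discrete flux positivity-preserving at any drift.
static inline double cc_delta(double w) {
  if (std::fabs(w) < 1e-8) return 0.5 - w / 12.0;
  return 1.0 / w - 1.0 / expm1(w);
}

// Propagate the evidence density for a bounded drift-diffusion process with
// drift mu, unit variance per second, and absorbing bounds at +/-A.
// Finite-volume discretisation on ne interior nodes (ne odd; a node sits at
// e = 0 where all mass starts), Crank-Nicolson stepping after a short
// implicit-Euler startup that damps the delta initial condition.
// The absorbed mass per step is split between the two bounds through the
// boundary column sums of the generator, which makes
//   interior + cumulative absorbed = 1
// exact up to rounding at every step.
// core propagation into caller-supplied buffers (column-major ne x nt)
static void fp_propagate_core(double mu, double A, int ne, double dt,
                              int nt, int n_startup, double *interior,
                              double *ftop, double *fbot) {
  const double D = 0.5;
  const double de = 2.0 * A / (ne + 1);
  const double w = mu * de / D;
  const double delta = cc_delta(w);
  // face flux F_{j+1/2} = a*p_j + b*p_{j+1}
  const double a = mu * (1.0 - delta) + D / de;
  const double b = mu * delta - D / de;
  // generator L: dp_j/dt = l*p_{j-1} + d0*p_j + u*p_{j+1}
  const double l = a / de, d0 = (b - a) / de, u = -b / de;

  std::vector<double> p(ne, 0.0), rhs(ne), pn(ne);
  p[(ne - 1) / 2] = 1.0 / de; // delta at e = 0 (density units)

  std::vector<double> cp(ne), inv_denom(ne);
  double md0 = 0.0, ml = 0.0, mu_ = 0.0;
  int factored_theta = -1;

  for (int k = 0; k < nt; ++k) {
    const double theta = (k < n_startup) ? 1.0 : 0.5;
    if ((int)(theta * 2) != factored_theta) {
      ml = -theta * dt * l;
      md0 = 1.0 - theta * dt * d0;
      mu_ = -theta * dt * u;
      cp[0] = mu_ / md0;
      inv_denom[0] = 1.0 / md0;
      for (int j = 1; j < ne; ++j) {
        const double den = md0 - ml * cp[j - 1];
        inv_denom[j] = 1.0 / den;
        cp[j] = mu_ * den != 0.0 ? mu_ / den : 0.0;
      }
      factored_theta = (int)(theta * 2);
    }
    const double om = (1.0 - theta) * dt;
    for (int j = 0; j < ne; ++j) {
      double acc = p[j] + om * d0 * p[j];
      if (j > 0) acc += om * l * p[j - 1];
      if (j < ne - 1) acc += om * u * p[j + 1];
      rhs[j] = acc;
    }
    // Thomas solve (I - theta*dt*L) pn = rhs
    pn[0] = rhs[0] * inv_denom[0];
    for (int j = 1; j < ne; ++j)
      pn[j] = (rhs[j] - ml * pn[j - 1]) * inv_denom[j];
    for (int j = ne - 2; j >= 0; --j)
      pn[j] -= cp[j] * pn[j + 1];

    const double w_top = (1.0 - theta) * p[ne - 1] + theta * pn[ne - 1];
    const double w_bot = (1.0 - theta) * p[0] + theta * pn[0];
    ftop[k] = dt * a * w_top;      // mass absorbed at +A during this step
    fbot[k] = dt * (-b) * w_bot;   // mass absorbed at -A during this step
    double *col = interior + (size_t)k * ne;
    for (int j = 0; j < ne; ++j) {
      col[j] = pn[j];
      p[j] = pn[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_fp_propagate(double mu, double A, int ne, double dt, int nt,
                      int n_startup = 3) {
  if (ne < 3 || ne % 2 == 0) stop("ne must be an odd integer >= 3");
  if (nt < 1) stop("nt must be >= 1");
  NumericMatrix interior(ne, nt);
  NumericVector ftop(nt), fbot(nt);
  fp_propagate_core(mu, A, ne, dt, nt, n_startup, interior.begin(),
                    ftop.begin(), fbot.begin());
  return List::create(_["interior"] = interior, _["ftop"] = ftop,
                      _["fbot"] = fbot, _["de"] = 2.0 * A / (ne + 1),
                      _["dt"] = dt);
}

// Build the full likelihood maps for one (kappa, A): per-magnitude joint
// densities, absorbed fluxes, and the marginal counterfactual-posterior
// maps, in a single pass (negative coherences follow by mirror symmetry).
// [[Rcpp::export]]
List cpp_build_maps(double kappa, double A, int ne, double dt, int nt,
                    NumericVector coh, bool include_zero_both) {
  if (ne < 3 || ne % 2 == 0) stop("ne must be an odd integer >= 3");
  const int nm = coh.size();
  NumericVector D(Dimension(ne, nt, nm));
  NumericMatrix ftop(nt, nm), fbot(nt, nm);
  for (int m = 0; m < nm; ++m) {
    fp_propagate_core(kappa * coh[m], A, ne, dt, nt, 3,
                      D.begin() + (size_t)m * ne * nt, &ftop(0, m),
                      &fbot(0, m));
  }
  const bool has_zero = coh[0] == 0.0;
  const int m0 = (has_zero && !include_zero_both) ? 1 : 0;
  const double wgt = 1.0 / (nm - m0);
  NumericMatrix pu(ne, nt);
  NumericVector putop(nt), pubot(nt);
  for (int k = 0; k < nt; ++k) {
    double FtR = 0.0, FbR = 0.0;
    for (int m = m0; m < nm; ++m) {
      FtR += ftop(k, m);
      FbR += fbot(k, m);
    }
    FtR *= wgt;
    FbR *= wgt;
    // under leftward motion the top flux is the mirrored bottom flux
    const double tt = FtR + FbR;
    putop[k] = tt > 0.0 ? FtR / tt : NA_REAL;
    pubot[k] = tt > 0.0 ? FbR / tt : NA_REAL;
    for (int j = 0; j < ne; ++j) {
      double pR = 0.0, pL = 0.0;
      for (int m = m0; m < nm; ++m) {
        const double *Dm = D.begin() + (size_t)m * ne * nt +
                           (size_t)k * ne;
        pR += Dm[j];
        pL += Dm[ne - 1 - j];
      }
      const double tot = pR + pL;
      pu(j, k) = tot > 0.0 ? pR / tot : NA_REAL;
    }
  }
  return List::create(_["D"] = D, _["ftop"] = ftop, _["fbot"] = fbot,
                      _["pu"] = pu, _["pu_top"] = putop,
                      _["pu_bot"] = pubot, _["de"] = 2.0 * A / (ne + 1));
}

// One Euler-Maruyama step with a Brownian-bridge correction for bound
// crossings inside the step (removes the O(sqrt(dt)) first-passage bias).
// Returns +1 / -1 when the walk is absorbed at the top / bottom bound.
static inline int em_step(double &x, double mu, double dt, double sdt,
                          double A) {
  const double x0 = x;
  x += mu * dt + sdt * norm_rand();
  if (x >= A) { x = A; return 1; }
  if (x <= -A) { x = -A; return -1; }
  // within-step excursion beyond a bound (bridge crossing probability)
  const double p_top = std::exp(-2.0 * (A - x0) * (A - x) / dt);
  if (unif_rand() < p_top) { x = A; return 1; }
  const double p_bot = std::exp(-2.0 * (A + x0) * (A + x) / dt);
  if (unif_rand() < p_bot) { x = -A; return -1; }
  return 0;
}

// Euler-Maruyama simulation of the accumulator for a set of trials.
// Bound crossings are assigned to the end of the step and e is clamped to
// +/-A; curtailed trials stop exactly at T with te = T.
// [[Rcpp::export]]
List cpp_sim_evidence(NumericVector mu, NumericVector Tdur, double A,
                      double dt) {
  const int n = mu.size();
  if (Tdur.size() != n) stop("mu and Tdur must have equal length");
  NumericVector e(n), te(n);
  IntegerVector hit(n);
  const double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    const int nstep = (int)std::lround(Tdur[i] / dt);
    double x = 0.0;
    int h = 0;
    double t = Tdur[i];
    for (int s = 1; s <= nstep; ++s) {
      if (em_step(x, mu[i], dt, sdt, A) != 0) {
        h = 1;
        t = s * dt;
        break;
      }
    }
    e[i] = x;
    te[i] = h ? t : Tdur[i];
    hit[i] = h;
  }
  return List::create(_["e"] = e, _["te"] = te, _["hit"] = hit);
}

struct PuMap {
  const double *pu;    // ne x nt interior counterfactual posterior
  const double *putop; // nt
  const double *pubot; // nt
  int ne, nt;
  double A, de, dt;
};

// bilinear interpolation of the interior counterfactual-posterior map
static double pu_lookup(const PuMap &m, double e, double te, bool at_top,
                        bool at_bot) {
  double tt = te / m.dt - 1.0; // 0-based continuous time index
  if (tt < 0) tt = 0;
  if (tt > m.nt - 1) tt = m.nt - 1;
  const int k0 = (int)std::floor(tt);
  const int k1 = std::min(k0 + 1, m.nt - 1);
  const double ft = tt - k0;
  if (at_top) return (1 - ft) * m.putop[k0] + ft * m.putop[k1];
  if (at_bot) return (1 - ft) * m.pubot[k0] + ft * m.pubot[k1];
  double x = (e + m.A) / m.de - 1.0;
  if (x < 0) x = 0;
  if (x > m.ne - 1) x = m.ne - 1;
  const int j0 = (int)std::floor(x);
  const int j1 = std::min(j0 + 1, m.ne - 1);
  const double fe = x - j0;
  const double v00 = m.pu[j0 + k0 * m.ne], v10 = m.pu[j1 + k0 * m.ne];
  const double v01 = m.pu[j0 + k1 * m.ne], v11 = m.pu[j1 + k1 * m.ne];
  const double v = (1 - ft) * ((1 - fe) * v00 + fe * v10) +
                   ft * ((1 - fe) * v01 + fe * v11);
  if (ISNAN(v))
    stop("counterfactual posterior requested at an unreachable grid node");
  return v;
}

static inline double clip01(double x, double eps) {
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// nu_r for the five update rules. conf is the (transformed) confidence in
// the chosen side; pu_hat the counterfactual posterior for rightward.
static double compute_nu_r(int model, int choice_r, double conf, double pu_hat,
                           double EB, double beta_mix,
                           const double *ebetas) {
  const double pR_rep = choice_r ? conf : 1.0 - conf;
  switch (model) {
  case 0: return pu_hat;                  // bayesian
  case 1: return choice_r ? 1.0 : 0.0;    // choice_only
  case 2: return pR_rep;                  // choice_confidence
  case 3: {                               // empirical (5-parameter logistic)
    const double pd = choice_r ? EB : 1.0 - EB;
    const double lin = ebetas[0] + ebetas[1] * conf + ebetas[2] * pd +
                       ebetas[3] * conf * pd + ebetas[4] * conf * conf * pd;
    const double nd = 1.0 / (1.0 + std::exp(-lin));
    return choice_r ? nd : 1.0 - nd;
  }
  case 4: return beta_mix * pu_hat + (1.0 - beta_mix) * pR_rep; // mixture
  default: stop("unknown model code");
  }
  return NA_REAL;
}

// Four-outcome masses {R,L} x {high,low} for one stimulus condition:
// integrate p(e,te | c, T) over the regions where the biased-prior posterior
// for the chosen side falls below / above the confidence criterion phi.
// Monotonicity of the posterior in pu reduces the regions to pu-thresholds.
static void outcome_masses(const double *Dcol, bool mirrored, int ne,
                           double de, const double *ftopm, const double *fbotm,
                           const PuMap &m, int kidx, double EB, double phi,
                           double out[4]) {
  // out: 0 = (R,high), 1 = (R,low), 2 = (L,high), 3 = (L,low)
  const double uR = 1.0 - EB;
  const double odds_phi = phi / (1.0 - phi);
  const double prior_ratio = (1.0 - EB) / EB;
  const double qRh = odds_phi * prior_ratio;
  const double uRh = qRh / (1.0 + qRh);
  const double qLl = prior_ratio / odds_phi;
  const double uLl = qLl / (1.0 + qLl);
  out[0] = out[1] = out[2] = out[3] = 0.0;
  const double *pucol = m.pu + (size_t)kidx * ne;
  for (int j = 0; j < ne; ++j) {
    const double d = mirrored ? Dcol[ne - 1 - j] : Dcol[j];
    if (d <= 0.0) continue;
    const double pu = pucol[j];
    const double mass = d * de;
    if (pu > uR) out[pu >= uRh ? 0 : 1] += mass;
    else out[pu <= uLl ? 2 : 3] += mass;
  }
  for (int t = 0; t <= kidx; ++t) {
    const double top = mirrored ? fbotm[t] : ftopm[t];
    const double bot = mirrored ? ftopm[t] : fbotm[t];
    if (top > 0.0) {
      const double pu = m.putop[t];
      if (pu > uR) out[pu >= uRh ? 0 : 1] += top;
      else out[pu <= uLl ? 2 : 3] += top;
    }
    if (bot > 0.0) {
      const double pu = m.pubot[t];
      if (pu > uR) out[pu >= uRh ? 0 : 1] += bot;
      else out[pu <= uLl ? 2 : 3] += bot;
    }
  }
}

static PuMap make_pumap(NumericMatrix pu, NumericVector putop,
                        NumericVector pubot, double A, double de, double dt) {
  PuMap m;
  m.pu = pu.begin();
  m.putop = putop.begin();
  m.pubot = pubot.begin();
  m.ne = pu.nrow();
  m.nt = pu.ncol();
  m.A = A;
  m.de = de;
  m.dt = dt;
  return m;
}

// Single-condition wrapper used by trial_joint_likelihood().
// [[Rcpp::export]]
NumericVector cpp_outcome_masses(NumericVector Darr, NumericMatrix ftop,
                                 NumericMatrix fbot, int mag_idx, int sgn,
                                 int kidx, NumericMatrix pu,
                                 NumericVector putop, NumericVector pubot,
                                 double A, double de, double dt, double EB,
                                 double phi) {
  IntegerVector dims = Darr.attr("dim");
  const int ne = dims[0], nt = dims[1];
  if (kidx < 0 || kidx >= nt) stop("time index out of range");
  PuMap m = make_pumap(pu, putop, pubot, A, de, dt);
  const double *Dm = Darr.begin() + (size_t)mag_idx * ne * nt;
  const double *Dcol = Dm + (size_t)kidx * ne;
  double out[4];
  outcome_masses(Dcol, sgn < 0, ne, de, &ftop(0, mag_idx), &fbot(0, mag_idx),
                 m, kidx, EB, phi, out);
  return NumericVector::create(_["R_high"] = out[0], _["R_low"] = out[1],
                               _["L_high"] = out[2], _["L_low"] = out[3]);
}

// Dataset log-likelihood: per block, start from the parametric prior over
// base rates, accumulate log of the observed (choice, confidence-category)
// mass, then propagate p(B) using nu_d computed from the observed choice and
// transformed confidence (Eq.-14-style inversion for the bayesian/mixture
// rules).
// [[Rcpp::export]]
List cpp_dataset_loglik(IntegerVector block, IntegerVector mag_idx,
                        IntegerVector sgn, IntegerVector kidx,
                        IntegerVector choice_r, IntegerVector conf_high,
                        NumericVector conf_trans, NumericVector Darr,
                        NumericMatrix ftop, NumericMatrix fbot,
                        NumericMatrix pu, NumericVector putop,
                        NumericVector pubot, double A, double de, double dt,
                        double phi, NumericVector prior0, NumericVector Bvals,
                        int model, double beta_mix, NumericVector ebetas,
                        double eps_clip, double log_floor,
                        double alpha_pB = 0.0) {
  const int n = block.size();
  IntegerVector dims = Darr.attr("dim");
  const int ne = dims[0], nt = dims[1];
  PuMap m = make_pumap(pu, putop, pubot, A, de, dt);
  const int nB = prior0.size();
  std::vector<double> pB(nB);
  NumericVector ll(n), EBv(n), nuv(n);
  double total = 0.0;
  int nfloor = 0;
  int cur_block = NA_INTEGER;
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) {
      cur_block = block[i];
      for (int b = 0; b < nB; ++b) pB[b] = prior0[b];
    }
    double EB = 0.0;
    for (int b = 0; b < nB; ++b) EB += Bvals[b] * pB[b];
    EBv[i] = EB;
    const int k = kidx[i];
    if (k < 0 || k >= nt) stop("time index out of range");
    const double *Dcol =
        Darr.begin() + (size_t)mag_idx[i] * ne * nt + (size_t)k * ne;
    double out[4];
    outcome_masses(Dcol, sgn[i] < 0, ne, de, &ftop(0, mag_idx[i]),
                   &fbot(0, mag_idx[i]), m, k, EB, phi, out);
    const int idx = choice_r[i] ? (conf_high[i] ? 0 : 1)
                                : (conf_high[i] ? 2 : 3);
    double li = std::log(out[idx]);
    if (!R_FINITE(li) || li < log_floor) {
      li = log_floor;
      ++nfloor;
    }
    ll[i] = li;
    total += li;
    // propagate p(B) from the observed report
    const double conf = clip01(conf_trans[i], eps_clip);
    const double pR_rep = choice_r[i] ? conf : 1.0 - conf;
    const double odds_pu = (pR_rep / (1.0 - pR_rep)) * ((1.0 - EB) / EB);
    const double pu_hat = odds_pu / (1.0 + odds_pu);
    const double nur = compute_nu_r(model, choice_r[i], conf, pu_hat, EB,
                                    beta_mix, ebetas.begin());
    nuv[i] = nur;
    double s = 0.0;
    std::vector<double> upd(nB);
    for (int b = 0; b < nB; ++b) {
      upd[b] = pB[b] * (Bvals[b] * nur + (1.0 - Bvals[b]) * (1.0 - nur));
      s += upd[b];
    }
    if (s <= 0.0) stop("degenerate base-rate update (all-zero posterior)");
    for (int b = 0; b < nB; ++b) {
      upd[b] /= s;
      pB[b] = (alpha_pB > 0.0)
                  ? pB[b] + (upd[b] - pB[b]) * (1.0 - alpha_pB)
                  : upd[b];
    }
  }
  return List::create(_["loglik"] = total, _["per_trial"] = ll,
                      _["n_floor"] = nfloor, _["EB"] = EBv, _["nu_r"] = nuv);
}

// End-to-end observer simulation on a stimulus sequence: simulate the
// accumulator, look up counterfactual confidence, apply the evolving prior,
// choose, report confidence, update p(B) under the requested rule, and emit
// the (optionally lagged) belief report. p(B) resets to the initial prior at
// each block boundary; the belief marker resets to 0.5.
// [[Rcpp::export]]
List cpp_observer_sim(IntegerVector block, NumericVector mu,
                      NumericVector Tdur, double A, double dt_sim,
                      NumericMatrix pu, NumericVector putop,
                      NumericVector pubot, double de, double dt_map,
                      NumericVector prior0, NumericVector Bvals, int model,
                      double beta_mix, NumericVector ebetas, double alpha_rep,
                      double alpha_pB) {
  const int n = block.size();
  PuMap m = make_pumap(pu, putop, pubot, A, de, dt_map);
  const int nB = prior0.size();
  std::vector<double> pB(nB), pB_new(nB);
  NumericVector e(n), te(n), conf(n), belief_b(n), belief_f(n), puv(n), EBv(n);
  IntegerVector choice(n), hit(n);
  const double sdt = std::sqrt(dt_sim);
  int cur_block = NA_INTEGER;
  double f_prev = 0.5;
  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) {
      cur_block = block[i];
      for (int b = 0; b < nB; ++b) pB[b] = prior0[b];
      f_prev = 0.5;
    }
    // accumulate evidence
    const int nstep = (int)std::lround(Tdur[i] / dt_sim);
    double x = 0.0;
    int h = 0;
    double t = Tdur[i];
    for (int s = 1; s <= nstep; ++s) {
      if (em_step(x, mu[i], dt_sim, sdt, A) != 0) {
        h = 1;
        t = s * dt_sim;
        break;
      }
    }
    e[i] = x;
    te[i] = h ? t : Tdur[i];
    hit[i] = h;
    const double pu_i = pu_lookup(m, x, te[i], h && x >= A, h && x <= -A);
    puv[i] = pu_i;
    double EB = 0.0;
    for (int b = 0; b < nB; ++b) EB += Bvals[b] * pB[b];
    EBv[i] = EB;
    const double num = EB * pu_i;
    const double den = num + (1.0 - EB) * (1.0 - pu_i);
    if (den <= 0.0) stop("undefined direction posterior (0/0)");
    const double pR = num / den;
    int ch;
    if (pR > 0.5) ch = 1;
    else if (pR < 0.5) ch = 0;
    else ch = (unif_rand() < 0.5) ? 1 : 0;
    choice[i] = ch;
    const double cf = ch ? pR : 1.0 - pR;
    conf[i] = cf;
    const double nur = compute_nu_r(model, ch, cf, pu_i, EB, beta_mix,
                                    ebetas.begin());
    double s = 0.0;
    for (int b = 0; b < nB; ++b) {
      pB_new[b] = pB[b] * (Bvals[b] * nur + (1.0 - Bvals[b]) * (1.0 - nur));
      s += pB_new[b];
    }
    if (s <= 0.0) stop("degenerate base-rate update (all-zero posterior)");
    for (int b = 0; b < nB; ++b) {
      pB_new[b] /= s;
      pB[b] = (alpha_pB > 0.0)
                  ? pB[b] + (pB_new[b] - pB[b]) * (1.0 - alpha_pB)
                  : pB_new[b];
    }
    double bb = 0.0;
    for (int b = 0; b < nB; ++b)
      if (Bvals[b] > 0.5) bb += pB[b];
    belief_b[i] = bb;
    f_prev = (alpha_rep > 0.0) ? f_prev + (bb - f_prev) * (1.0 - alpha_rep)
                               : bb;
    belief_f[i] = f_prev;
  }
  return List::create(_["choice_r"] = choice, _["confidence"] = conf,
                      _["belief"] = belief_b, _["belief_report"] = belief_f,
                      _["e"] = e, _["te"] = te, _["bound_hit"] = hit,
                      _["pu"] = puv, _["EB"] = EBv);
}
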