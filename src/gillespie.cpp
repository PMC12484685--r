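#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// Hybrid Gillespie simulation of the two-population birth-death process with
// piecewise-deterministic synaptic efficacies.  Propensities are frozen
// between jumps; the efficacies advance by their exact exponential update at
// the excitatory activation r_E of the elapsed interval.
//
// Returns state sampled (sample-and-hold) on a uniform grid of step dt_out,
// and optionally the full jump path.
// [[Rcpp::export]]
List markov_sim_cpp(int nE0, int nI0, int NE, int NI, double gain,
                    double jee, double jei, double jie, double jii,
                    double ie, double ii, double taui,
                    double tau_r, double tau_d, double m_rec, double beta,
                    double theta_ee, double theta_ie,
                    double pEE0, double pIE0,
                    double T, double dt_out,
                    bool record_path, bool freeze_plasticity,
                    double max_jumps) {
  int nE = nE0, nI = nI0;
  double pEE = pEE0, pIE = pIE0;
  double t = 0.0;
  double rE = (double)nE / NE, rI = (double)nI / NI;

  int nout = (int)std::floor(T / dt_out) + 1;
  NumericVector out_re(nout), out_ri(nout), out_pee(nout), out_pie(nout);
  int oi = 0;

  std::vector<double> pt_t, pt_pee, pt_pie;
  std::vector<int> pt_ne, pt_ni;
  if (record_path) {
    pt_t.push_back(0.0); pt_ne.push_back(nE); pt_ni.push_back(nI);
    pt_pee.push_back(pEE); pt_pie.push_back(pIE);
  }

  const double kr = 1.0 / tau_r;
  double jumps = 0.0;
  while (t < T) {
    double bE = (nE >= NE) ? 0.0
      : NE * sigmoid(gain * (jee * pEE * rE - jei * rI + ie));
    double dE = nE;
    double bI = (nI >= NI) ? 0.0
      : (NI / taui) * sigmoid(gain * (jie * pIE * rE - jii * rI + ii));
    double dI = nI / taui;
    double tot = bE + dE + bI + dI;
    if (!R_finite(tot) || tot <= 0.0)
      stop("propensity not finite/positive at t = %f", t);

    double dt = R::rexp(1.0 / tot);
    double aE = m_rec * sigmoid(beta * (rE - theta_ee));
    double aI = m_rec * sigmoid(beta * (rE - theta_ie));
    double lamE = kr + aE / tau_d, lamI = kr + aI / tau_d;
    double hatE = kr / lamE, hatI = kr / lamI;

    // emit grid samples in (t, t+dt]; plasticity evaluated exactly at the
    // grid time, counts held at their pre-jump values
    double tn = t + dt;
    while (oi < nout && oi * dt_out <= tn) {
      double tg = oi * dt_out;
      if (tg < t) { // can only occur for tg == t at start
        tg = t;
      }
      double el = tg - t;
      out_re[oi] = rE;
      out_ri[oi] = rI;
      if (freeze_plasticity) {
        out_pee[oi] = pEE; out_pie[oi] = pIE;
      } else {
        out_pee[oi] = hatE + (pEE - hatE) * std::exp(-lamE * el);
        out_pie[oi] = hatI + (pIE - hatI) * std::exp(-lamI * el);
      }
      ++oi;
    }

    if (!freeze_plasticity) {
      pEE = hatE + (pEE - hatE) * std::exp(-lamE * dt);
      pIE = hatI + (pIE - hatI) * std::exp(-lamI * dt);
    }
    t = tn;
    if (t >= T) break;

    double u = unif_rand() * tot;
    if (u < bE) ++nE;
    else if (u < bE + dE) --nE;
    else if (u < bE + dE + bI) ++nI;
    else --nI;
    rE = (double)nE / NE;
    rI = (double)nI / NI;

    if (record_path) {
      pt_t.push_back(t); pt_ne.push_back(nE); pt_ni.push_back(nI);
      pt_pee.push_back(pEE); pt_pie.push_back(pIE);
    }
    if (++jumps > max_jumps)
      stop("jump budget exceeded (%.0f jumps); shorten T", max_jumps);
  }
  while (oi < nout) {
    out_re[oi] = rE; out_ri[oi] = rI;
    out_pee[oi] = pEE; out_pie[oi] = pIE;
    ++oi;
  }

  List path = R_NilValue;
  if (record_path)
    path = List::create(_["t"] = wrap(pt_t), _["n_e"] = wrap(pt_ne),
                        _["n_i"] = wrap(pt_ni), _["p_ee"] = wrap(pt_pee),
                        _["p_ie"] = wrap(pt_pie));
  NumericVector tgrid(nout);
  for (int k = 0; k < nout; ++k) tgrid[k] = k * dt_out;
  return List::create(_["t"] = tgrid,
                      _["r_e"] = out_re, _["r_i"] = out_ri,
                      _["p_ee"] = out_pee, _["p_ie"] = out_pie,
                      _["n_jumps"] = jumps, _["path"] = path);
}
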