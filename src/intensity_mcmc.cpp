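#include <Rcpp.h>
using namespace Rcpp;

// One cell's log target: binomial likelihood for O successes out of N at
// pi = f1*f2*gamma with gamma = lam1*lam2 + mu, plus the per-cell Jeffreys
// term pi^(-1/2) (1-pi)^(-1/2). Inadmissible states (gamma < 0 or pi
// outside (0,1)) get -Inf so proposals into them are rejected.
static inline double cell_lp(double lam1, double lam2, double mu,
                             double ff, double O, double N) {
  double gamma = lam1 * lam2 + mu;
  if (gamma < 0.0) return R_NegInf;
  double pi = ff * gamma;
  if (pi <= 0.0 || pi >= 1.0) return R_NegInf;
  return O * std::log(pi) + (N - O) * std::log1p(-pi)
       - 0.5 * std::log(pi) - 0.5 * std::log1p(-pi);
}

static inline double trunc_pos_rnorm(double mean, double sd) {
  double x;
  do { x = R::rnorm(mean, sd); } while (x <= 0.0);
  return x;
}

static inline double trunc_neg_rnorm(double mean, double sd) {
  double x;
  do { x = R::rnorm(mean, sd); } while (x >= 0.0);
  return x;
}

// Metropolis-within-Gibbs sampler for the hierarchical binomial sharing
// intensity model. Random-walk moves on log marginal intensities (anchor
// fixed at 1), a Metropolized prior-proposal move switching each random
// effect between the point-mass/hot/cold mixture components, a
// random-walk refinement within the active component, and random-walk
// updates of the hot/cold means under bounded flat priors. Proposal
// scales adapt during burn-in only.
// [[Rcpp::export]]
List intensity_mcmc_cpp(NumericMatrix O, double N,
                        NumericVector f1, NumericVector f2,
                        int anchor,
                        double p0, double pH, double pC,
                        double sigma, double mu_bound,
                        int burnin, int n_keep, int thin,
                        NumericVector init_loglam1,
                        NumericVector init_loglam2,
                        double init_muH, double init_muC) {
  const int nr1 = O.nrow(), nr2 = O.ncol();
  const int ncell = nr1 * nr2;

  std::vector<double> loglam1(init_loglam1.begin(), init_loglam1.end());
  std::vector<double> loglam2(init_loglam2.begin(), init_loglam2.end());
  loglam1[anchor] = 0.0;
  std::vector<double> lam1(nr1), lam2(nr2);
  for (int i = 0; i < nr1; ++i) lam1[i] = std::exp(loglam1[i]);
  for (int j = 0; j < nr2; ++j) lam2[j] = std::exp(loglam2[j]);
  std::vector<double> mu(ncell, 0.0);
  std::vector<int> z(ncell, 0);
  double muH = init_muH, muC = init_muC;

  std::vector<double> ff(ncell);
  for (int j = 0; j < nr2; ++j)
    for (int i = 0; i < nr1; ++i)
      ff[i + nr1 * j] = f1[i] * f2[j];

  // adaptive proposal scales
  std::vector<double> s1(nr1, 0.3), s2(nr2, 0.3), smu(ncell, 0.3);
  double sH = 0.3, sC = 0.3;
  std::vector<int> acc1(nr1, 0), acc2(nr2, 0), accmu(ncell, 0);
  int accH = 0, accC = 0;
  const int batch = 50;

  NumericMatrix keep_gamma(n_keep, ncell);
  NumericMatrix keep_lam1(n_keep, nr1), keep_lam2(n_keep, nr2);
  NumericVector keep_muH(n_keep), keep_muC(n_keep);
  NumericVector hot_frac(ncell), cold_frac(ncell);

  const int total = burnin + n_keep * thin;
  int kept = 0;

  for (int it = 0; it < total; ++it) {
    bool adapting = it < burnin;

    // marginal intensities, species 1 (anchor skipped)
    for (int i = 0; i < nr1; ++i) {
      if (i == anchor) continue;
      double prop = loglam1[i] + R::rnorm(0.0, s1[i]);
      double lam_new = std::exp(prop);
      double d = 0.0;
      for (int j = 0; j < nr2; ++j) {
        int c = i + nr1 * j;
        d += cell_lp(lam_new, lam2[j], mu[c], ff[c], O(i, j), N)
           - cell_lp(lam1[i], lam2[j], mu[c], ff[c], O(i, j), N);
        if (d == R_NegInf) break;
      }
      if (std::log(R::unif_rand()) < d) {
        loglam1[i] = prop; lam1[i] = lam_new; acc1[i]++;
      }
    }
    // marginal intensities, species 2
    for (int j = 0; j < nr2; ++j) {
      double prop = loglam2[j] + R::rnorm(0.0, s2[j]);
      double lam_new = std::exp(prop);
      double d = 0.0;
      for (int i = 0; i < nr1; ++i) {
        int c = i + nr1 * j;
        d += cell_lp(lam1[i], lam_new, mu[c], ff[c], O(i, j), N)
           - cell_lp(lam1[i], lam2[j], mu[c], ff[c], O(i, j), N);
        if (d == R_NegInf) break;
      }
      if (std::log(R::unif_rand()) < d) {
        loglam2[j] = prop; lam2[j] = lam_new; acc2[j]++;
      }
    }

    // random effects: component switch by prior proposal, then RW refresh
    for (int j = 0; j < nr2; ++j) {
      for (int i = 0; i < nr1; ++i) {
        int c = i + nr1 * j;
        // (a) allocation move: propose the component uniformly and mu'
        // from that component's conditional prior; the component densities
        // cancel against the proposal, leaving the mixture weights in the
        // acceptance ratio. A uniform component proposal mixes into the
        // rare hot/cold states far faster than proposing from the prior
        // weights while targeting the same posterior.
        int z_new = (int)std::floor(R::unif_rand() * 3.0);
        if (z_new > 2) z_new = 2;
        double w_new = (z_new == 0) ? p0 : (z_new == 1 ? pH : pC);
        double w_old = (z[c] == 0) ? p0 : (z[c] == 1 ? pH : pC);
        if (w_new > 0.0) {
          double mu_new;
          if (z_new == 0) mu_new = 0.0;
          else if (z_new == 1) mu_new = trunc_pos_rnorm(muH, sigma);
          else mu_new = trunc_neg_rnorm(muC, sigma);
          double d = cell_lp(lam1[i], lam2[j], mu_new, ff[c], O(i, j), N)
                   - cell_lp(lam1[i], lam2[j], mu[c], ff[c], O(i, j), N)
                   + std::log(w_new) - std::log(w_old);
          if (std::log(R::unif_rand()) < d) { z[c] = z_new; mu[c] = mu_new; }
        }
        // (b) within-component random walk (active components only)
        if (z[c] != 0) {
          double m = (z[c] == 1) ? muH : muC;
          double prop = mu[c] + R::rnorm(0.0, smu[c]);
          bool ok = (z[c] == 1) ? (prop > 0.0) : (prop < 0.0);
          if (ok) {
            double d2 = cell_lp(lam1[i], lam2[j], prop, ff[c], O(i, j), N)
                      - cell_lp(lam1[i], lam2[j], mu[c], ff[c], O(i, j), N)
                      - 0.5 * ((prop - m) * (prop - m)
                             - (mu[c] - m) * (mu[c] - m)) / (sigma * sigma);
            if (std::log(R::unif_rand()) < d2) { mu[c] = prop; accmu[c]++; }
          }
        }
      }
    }

    // hot mean, flat on (0, mu_bound]
    {
      std::vector<int> hot;
      for (int c = 0; c < ncell; ++c) if (z[c] == 1) hot.push_back(c);
      if (hot.empty()) {
        muH = R::runif(0.0, mu_bound);
      } else {
        double prop = muH + R::rnorm(0.0, sH);
        if (prop > 0.0 && prop <= mu_bound) {
          double d = 0.0;
          for (int c : hot) {
            d += -0.5 * ((mu[c] - prop) * (mu[c] - prop)
                       - (mu[c] - muH) * (mu[c] - muH)) / (sigma * sigma);
          }
          // truncated-normal normalizer P(X > 0) = Phi(mean / sigma)
          d -= hot.size() * (std::log(R::pnorm(prop / sigma, 0, 1, 1, 0))
                           - std::log(R::pnorm(muH / sigma, 0, 1, 1, 0)));
          if (std::log(R::unif_rand()) < d) { muH = prop; accH++; }
        }
      }
    }
    // cold mean, flat on [-mu_bound, 0)
    {
      std::vector<int> cold;
      for (int c = 0; c < ncell; ++c) if (z[c] == 2) cold.push_back(c);
      if (cold.empty()) {
        muC = -R::runif(0.0, mu_bound);
      } else {
        double prop = muC + R::rnorm(0.0, sC);
        if (prop < 0.0 && prop >= -mu_bound) {
          double d = 0.0;
          for (int c : cold) {
            d += -0.5 * ((mu[c] - prop) * (mu[c] - prop)
                       - (mu[c] - muC) * (mu[c] - muC)) / (sigma * sigma);
          }
          // normalizer P(X < 0) = Phi(-mean / sigma)
          d -= cold.size() * (std::log(R::pnorm(-prop / sigma, 0, 1, 1, 0))
                            - std::log(R::pnorm(-muC / sigma, 0, 1, 1, 0)));
          if (std::log(R::unif_rand()) < d) { muC = prop; accC++; }
        }
      }
    }

    // scale adaptation toward ~0.44 acceptance, burn-in only
    if (adapting && ((it + 1) % batch == 0)) {
      double step = std::min(0.1, 1.0 / std::sqrt((double)(it + 1) / batch));
      for (int i = 0; i < nr1; ++i) {
        s1[i] *= std::exp(((double)acc1[i] / batch - 0.44) * step);
        acc1[i] = 0;
      }
      for (int j = 0; j < nr2; ++j) {
        s2[j] *= std::exp(((double)acc2[j] / batch - 0.44) * step);
        acc2[j] = 0;
      }
      for (int c = 0; c < ncell; ++c) {
        smu[c] *= std::exp(((double)accmu[c] / batch - 0.44) * step);
        accmu[c] = 0;
      }
      sH *= std::exp(((double)accH / batch - 0.44) * step); accH = 0;
      sC *= std::exp(((double)accC / batch - 0.44) * step); accC = 0;
    }

    if (!adapting && ((it - burnin + 1) % thin == 0) && kept < n_keep) {
      for (int j = 0; j < nr2; ++j) {
        for (int i = 0; i < nr1; ++i) {
          int c = i + nr1 * j;
          keep_gamma(kept, c) = lam1[i] * lam2[j] + mu[c];
          hot_frac[c] += (z[c] == 1);
          cold_frac[c] += (z[c] == 2);
        }
      }
      for (int i = 0; i < nr1; ++i) keep_lam1(kept, i) = lam1[i];
      for (int j = 0; j < nr2; ++j) keep_lam2(kept, j) = lam2[j];
      keep_muH[kept] = muH; keep_muC[kept] = muC;
      kept++;
    }
    if ((it & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  for (int c = 0; c < ncell; ++c) {
    hot_frac[c] /= n_keep; cold_frac[c] /= n_keep;
  }
  return List::create(_["gamma"] = keep_gamma,
                      _["lam1"] = keep_lam1, _["lam2"] = keep_lam2,
                      _["muH"] = keep_muH, _["muC"] = keep_muC,
                      _["hot_frac"] = hot_frac,
                      _["cold_frac"] = cold_frac);
}
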