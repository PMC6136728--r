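#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs kernel for the six-parameter ITC posterior.
// The chain runs in x-space x = (dG, dH, dH0, Ls, R0, ln sigma); the
// Jeffreys 1/sigma prior combined with the log-scale Jacobian makes the
// noise coordinate uniform on its bounds in x-space. Stored samples and
// log-posterior values are reported on the theta scale (sigma, not ln
// sigma) to match the R-level log_posterior().

namespace {

struct ItcModel {
  std::vector<double> q;      // observed heats, cal
  std::vector<double> v;      // injection volumes, L
  double V0;                  // cell volume, L
  double beta;                // 1 / (R_gas * T), mol/kcal
  // prior
  int conc_model;             // 0 general, 1 flat-r0, 2 comparison
  double dG_lo, dG_hi, dH_lo, dH_hi, dH0_lo, dH0_hi;
  double Ls_meanlog, Ls_sdlog;
  double R0_meanlog, R0_sdlog;    // general only
  double R0_lo, R0_hi;            // flat models
  double lsig_lo, lsig_hi;

  // log prior on the theta scale, without the Jacobian
  double log_prior_theta(const double* x) const {
    const double dG = x[0], dH = x[1], dH0 = x[2], Ls = x[3], R0 = x[4],
                 lsig = x[5];
    if (dG < dG_lo || dG > dG_hi || dH < dH_lo || dH > dH_hi ||
        dH0 < dH0_lo || dH0 > dH0_hi || Ls <= 0.0 || R0 <= 0.0 ||
        lsig < lsig_lo || lsig > lsig_hi)
      return R_NegInf;
    double lp = -lsig;  // Jeffreys
    double z = (std::log(Ls) - Ls_meanlog) / Ls_sdlog;
    lp += -std::log(Ls) - std::log(Ls_sdlog) - 0.918938533204672742 -
          0.5 * z * z;
    if (conc_model == 0) {
      double zr = (std::log(R0) - R0_meanlog) / R0_sdlog;
      lp += -std::log(R0) - std::log(R0_sdlog) - 0.918938533204672742 -
            0.5 * zr * zr;
    } else {
      if (R0 < R0_lo || R0 > R0_hi) return R_NegInf;
    }
    return lp;
  }

  double log_likelihood(const double* x) const {
    const double dH = x[1], dH0 = x[2], Ls = x[3], R0 = x[4], lsig = x[5];
    const double Ka = std::exp(-x[0] * beta);
    const double sigma = std::exp(lsig);
    const size_t N = q.size();
    double d = 1.0, c_prev = 0.0, ss = 0.0;
    for (size_t n = 0; n < N; ++n) {
      const double f = 1.0 - v[n] / V0;
      d *= f;
      const double Rn = R0 * d;
      const double Ln = Ls * (1.0 - d);
      const double b = Rn + Ln + 1.0 / Ka;
      double disc = b * b - 4.0 * Rn * Ln;
      if (disc < 0.0) disc = 0.0;
      double cn = 2.0 * Rn * Ln / (b + std::sqrt(disc));
      const double cap = Rn < Ln ? Rn : Ln;
      if (cn > cap) cn = cap;
      const double qstar = V0 * dH * 1e3 * (cn - c_prev * f) + dH0;
      const double r = q[n] - qstar;
      ss += r * r;
      c_prev = cn;
    }
    return -0.5 * N * 1.837877066409345484 - N * lsig -
           ss / (2.0 * sigma * sigma);
  }

  // target density in x-space (includes +lsig Jacobian)
  double log_target(const double* x) const {
    double lp = log_prior_theta(x);
    if (!R_finite(lp)) return R_NegInf;
    return lp + x[5] + log_likelihood(x);
  }
};

}  // namespace

// [[Rcpp::export]]
List itc_chain_cpp(NumericVector q, NumericVector v, double V0, double beta,
                   List prior, NumericVector init, NumericVector scales,
                   int n_samples, int thin, int tune) {
  ItcModel m;
  m.q = as<std::vector<double>>(q);
  m.v = as<std::vector<double>>(v);
  m.V0 = V0;
  m.beta = beta;
  m.conc_model = as<int>(prior["conc_model"]);
  NumericVector bG = prior["dG_bounds"], bH = prior["dH_bounds"],
                b0 = prior["dH0_bounds"], bs = prior["lsig_bounds"];
  m.dG_lo = bG[0]; m.dG_hi = bG[1];
  m.dH_lo = bH[0]; m.dH_hi = bH[1];
  m.dH0_lo = b0[0]; m.dH0_hi = b0[1];
  m.lsig_lo = bs[0]; m.lsig_hi = bs[1];
  m.Ls_meanlog = as<double>(prior["Ls_meanlog"]);
  m.Ls_sdlog = as<double>(prior["Ls_sdlog"]);
  if (m.conc_model == 0) {
    m.R0_meanlog = as<double>(prior["R0_meanlog"]);
    m.R0_sdlog = as<double>(prior["R0_sdlog"]);
    m.R0_lo = m.R0_hi = 0.0;
  } else {
    NumericVector bR = prior["R0_bounds"];
    m.R0_lo = bR[0]; m.R0_hi = bR[1];
    m.R0_meanlog = m.R0_sdlog = 0.0;
  }

  double x[6];
  for (int j = 0; j < 6; ++j) x[j] = init[j];
  double lt = m.log_target(x);
  if (!R_finite(lt))
    stop("Initial state has zero posterior density.");

  std::vector<double> sc(6);
  for (int j = 0; j < 6; ++j) sc[j] = scales[j];

  RNGScope rng;

  // optional discarded tuning phase: adjust scales toward a workable
  // acceptance rate, checking each coordinate every 60 of its proposals
  if (tune > 0) {
    std::vector<int> prop(6, 0), acc(6, 0);
    int j = 0;
    for (int t = 0; t < tune; ++t, j = (j + 1) % 6) {
      const double old = x[j];
      x[j] = old + R::rnorm(0.0, sc[j]);
      const double lt_new = m.log_target(x);
      ++prop[j];
      if (R_finite(lt_new) && std::log(R::runif(0.0, 1.0)) < lt_new - lt) {
        lt = lt_new;
        ++acc[j];
      } else {
        x[j] = old;
      }
      if (prop[j] == 60) {
        const double rate = static_cast<double>(acc[j]) / prop[j];
        if (rate < 0.2) sc[j] *= 0.7;
        else if (rate > 0.5) sc[j] *= 1.4;
        prop[j] = acc[j] = 0;
      }
    }
  }

  NumericMatrix out(n_samples, 7);
  std::vector<long> prop(6, 0), acc(6, 0);
  int j = 0;
  for (int s = 0; s < n_samples; ++s) {
    for (int t = 0; t < thin; ++t, j = (j + 1) % 6) {
      const double old = x[j];
      x[j] = old + R::rnorm(0.0, sc[j]);
      const double lt_new = m.log_target(x);
      ++prop[j];
      if (R_finite(lt_new) && std::log(R::runif(0.0, 1.0)) < lt_new - lt) {
        lt = lt_new;
        ++acc[j];
      } else {
        x[j] = old;
      }
    }
    for (int k = 0; k < 5; ++k) out(s, k) = x[k];
    out(s, 5) = std::exp(x[5]);   // sigma on the natural scale
    out(s, 6) = lt - x[5];        // theta-scale log posterior
  }

  NumericVector rates(6), final_scales(6);
  for (int k = 0; k < 6; ++k) {
    rates[k] = prop[k] > 0 ? static_cast<double>(acc[k]) / prop[k] : NA_REAL;
    final_scales[k] = sc[k];
  }
  return List::create(_["samples"] = out, _["acceptance"] = rates,
                      _["scales"] = final_scales);
}
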