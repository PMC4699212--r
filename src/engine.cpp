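#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Sequential element-by-element update loop for ABA- / ABAB sequences.
// The R-level mixture operations (posterior_probs(), update_centroid(),
// update_mixing(), add_class()) define the same arithmetic step by step;
// tests assert both paths agree to 1e-12.

static inline double gn_density(double x, double mu, double alpha,
                                double beta, double lognorm) {
  return std::exp(lognorm - std::pow(std::fabs((x - mu) / alpha), beta));
}

// [[Rcpp::export]]
List engine_run(int n_max, int pattern, double delta,
                NumericVector mu0, NumericVector pi0,
                double sigma, double beta,
                double gamma, double eta, double theta, double p_init,
                bool stochastic, int K,
                bool recompute_mixing, bool consecutive_counter,
                bool percept_updates,
                int target_switches, bool record_trace) {
  // alpha chosen so the class variance equals sigma^2
  const double alpha =
      sigma * std::exp(0.5 * (R::lgammafn(1.0 / beta) - R::lgammafn(3.0 / beta)));
  const double lognorm =
      std::log(beta) - std::log(2.0 * alpha) - R::lgammafn(1.0 / beta);

  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> pi(pi0.begin(), pi0.end());

  std::vector<int> sw_el, sw_to;
  std::vector<int> tr_k, tr_percept;
  std::vector<double> tr_post2, tr_pi2, tr_mu1, tr_mu2;
  if (record_trace) {
    tr_k.reserve(n_max); tr_percept.reserve(n_max);
    tr_post2.reserve(n_max); tr_pi2.reserve(n_max);
    tr_mu1.reserve(n_max); tr_mu2.reserve(n_max);
  }

  int percept = 1;            // 1 = integration, 2 = segregation
  int counter = 0;            // K-counter (stochastic mode)
  long clamped = 0;
  int created = 0;
  int n_used = n_max;

  std::vector<double> dens, post;

  for (int i = 0; i < n_max; ++i) {
    const bool is_b = (pattern == 0) ? (i % 3 == 1) : (i % 2 == 1);
    const double x = is_b ? delta : 0.0;

    size_t n = mu.size();
    dens.assign(n, 0.0);
    double px = 0.0;
    for (size_t k = 0; k < n; ++k) {
      dens[k] = gn_density(x, mu[k], alpha, beta, lognorm);
      px += pi[k] * dens[k];
    }

    // class creation: likelihood of the element below threshold
    if (theta > 0.0 && px < theta) {
      for (size_t k = 0; k < n; ++k) pi[k] *= (1.0 - p_init);
      mu.push_back(x);
      pi.push_back(p_init);
      ++created;
      n = mu.size();
      dens.assign(n, 0.0);
      px = 0.0;
      for (size_t k = 0; k < n; ++k) {
        dens[k] = gn_density(x, mu[k], alpha, beta, lognorm);
        px += pi[k] * dens[k];
      }
    }

    if (px < 1e-300)
      stop("degenerate input: total mixture density underflowed at element %d", i + 1);

    post.assign(n, 0.0);
    for (size_t k = 0; k < n; ++k) post[k] = pi[k] * dens[k] / px;

    // classification: argmax (ties -> lowest index) or posterior draw
    int ks = 0;
    if (stochastic) {
      const double u = unif_rand();
      double cum = 0.0;
      ks = static_cast<int>(n) - 1;
      for (size_t k = 0; k < n; ++k) {
        cum += post[k];
        if (u <= cum) { ks = static_cast<int>(k); break; }
      }
    } else {
      for (size_t k = 1; k < n; ++k) if (post[k] > post[ks]) ks = static_cast<int>(k);
    }

    const double post2 = (n >= 2) ? post[1] : NA_REAL;

    // optional variant: the class used for the parameter updates follows the
    // current perceptual interpretation (B -> percept's class, A -> class 1),
    // while the drawn class still drives the K counter
    int ku = ks;
    if (percept_updates && stochastic && n >= 2)
      ku = (is_b && percept == 2) ? 1 : 0;

    // centroid update, proportional to the a-posteriori probability
    mu[ku] += gamma * post[ku] * (x - mu[ku]);

    // mixing update, driven by the conditional likelihood
    if (recompute_mixing) {
      dens[ku] = gn_density(x, mu[ku], alpha, beta, lognorm);
      px = 0.0;
      for (size_t k = 0; k < n; ++k) px += pi[k] * dens[k];
    }
    bool any_clamped = false;
    for (size_t k = 0; k < n; ++k) {
      double f = 1.0 + eta * (dens[k] - px);
      if (f < 1e-12) { f = 1e-12; any_clamped = true; ++clamped; }
      pi[k] *= f;
      if (pi[k] < 1e-300) pi[k] = 1e-300;  // keep pi_k positive under underflow
    }
    if (any_clamped) {
      double s = 0.0;
      for (size_t k = 0; k < n; ++k) s += pi[k];
      for (size_t k = 0; k < n; ++k) pi[k] /= s;
    }

    // percept dynamics are driven solely by B classifications
    if (is_b) {
      const bool to_class2 = (ks == 1);
      if (!stochastic) {
        const int newp = to_class2 ? 2 : 1;
        if (newp != percept) {
          percept = newp;
          sw_el.push_back(i + 1);
          sw_to.push_back(newp);
        }
      } else {
        const bool opposite = (percept == 1) ? to_class2 : !to_class2;
        if (opposite) ++counter;
        else if (consecutive_counter) counter = 0;
        if (counter >= K) {
          percept = (percept == 1) ? 2 : 1;
          counter = 0;
          sw_el.push_back(i + 1);
          sw_to.push_back(percept);
        }
      }
    }

    if (record_trace) {
      tr_k.push_back(ks + 1);
      tr_percept.push_back(percept);
      tr_post2.push_back(post2);
      tr_pi2.push_back(n >= 2 ? pi[1] : NA_REAL);
      tr_mu1.push_back(mu[0]);
      tr_mu2.push_back(n >= 2 ? mu[1] : NA_REAL);
    }

    if (target_switches > 0 &&
        static_cast<int>(sw_el.size()) >= target_switches) {
      n_used = i + 1;
      break;
    }
  }

  List out = List::create(
      _["n_elements"] = n_used,
      _["switch_element"] = IntegerVector(sw_el.begin(), sw_el.end()),
      _["switch_to"] = IntegerVector(sw_to.begin(), sw_to.end()),
      _["mu"] = NumericVector(mu.begin(), mu.end()),
      _["pi"] = NumericVector(pi.begin(), pi.end()),
      _["clamped"] = static_cast<double>(clamped),
      _["created"] = created);
  if (record_trace) {
    out["k_star"] = IntegerVector(tr_k.begin(), tr_k.end());
    out["percept"] = IntegerVector(tr_percept.begin(), tr_percept.end());
    out["post2"] = NumericVector(tr_post2.begin(), tr_post2.end());
    out["pi2"] = NumericVector(tr_pi2.begin(), tr_pi2.end());
    out["mu1"] = NumericVector(tr_mu1.begin(), tr_mu1.end());
    out["mu2"] = NumericVector(tr_mu2.begin(), tr_mu2.end());
  }
  return out;
}
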