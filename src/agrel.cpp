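// Sequential training and online-adaptation loops of the attention-gated
// RL decoder.  These mirror the R reference operations exactly: same
// sigmoid clamp, same stable softmax, same inverse-CDF winner sampling from
// R's RNG, same pre-update feedback semantics.  Only the per-trial loops
// live here; everything user-facing stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double GCLAMP_LO = 1e-12;
static const double GCLAMP_HI = 1.0 - 1e-12;

static inline arma::vec sigmoid_vec(const arma::vec& h) {
  arma::vec g = 1.0 / (1.0 + arma::exp(-h));
  g.clamp(GCLAMP_LO, GCLAMP_HI);
  return g;
}

static inline arma::vec softmax_vec(const arma::vec& a) {
  arma::vec e = arma::exp(a - a.max());
  return e / arma::accu(e);
}

// class-probability matrix for a block of trials (rows of Xf incl. bias col)
static arma::mat probs_matrix(const arma::mat& Xf, const arma::mat& v,
                              const arma::mat& w) {
  arma::mat G = 1.0 / (1.0 + arma::exp(-(Xf * v)));
  G.clamp(GCLAMP_LO, GCLAMP_HI);
  arma::mat Gf = arma::join_horiz(arma::ones(G.n_rows, 1), G);
  arma::mat A = Gf * w;
  A.each_col() -= arma::max(A, 1);
  arma::mat E = arma::exp(A);
  E.each_col() /= arma::sum(E, 1);
  return E;
}

// inverse-CDF sampling of the winning unit; matches the R rule
// (smallest k with u < cumsum(p)[k])
static inline int sample_winner(const arma::rowvec& p) {
  double u = unif_rand();
  double c = 0.0;
  for (arma::uword k = 0; k < p.n_elem; ++k) {
    c += p[k];
    if (u < c) return (int)k;
  }
  return (int)p.n_elem - 1;
}

// expansive function with delta clipped so f <= f_max (dcap = f_max/(1+f_max))
static inline double f_expansive(double delta, double dcap) {
  if (delta < 0.0) return -1.0;
  double d = delta < dcap ? delta : dcap;
  return d / (1.0 - d);
}

// Confidence-gated initial training (optionally without the gate and
// without early stopping, for the epoch-wise RMS efficiency study).
// y holds 1-based labels.  Returns final weights, the best-epoch snapshot
// (highest training accuracy, earliest tie), and per-epoch history.
// [[Rcpp::export]]
List train_agrel_cpp(const arma::mat& X, const arma::ivec& y,
                     arma::mat v, arma::mat w, double beta, double k,
                     double conv_frac, int max_epochs, double reward_value,
                     double dcap, bool gate, bool early_stop) {
  const int n = X.n_rows;
  const int M = v.n_cols;
  arma::mat Xf = arma::join_horiz(arma::ones(n, 1), X);

  arma::vec frac_hist(max_epochs, arma::fill::zeros);
  arma::vec acc_hist(max_epochs, arma::fill::zeros);
  arma::vec rms_hist(max_epochs, arma::fill::zeros);

  arma::mat best_v = v, best_w = w;
  double best_acc = -1.0;
  int best_epoch = 0, epochs_run = 0;
  bool converged = false;
  std::vector<int> perm(n);

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle from R's RNG stream
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    for (int ti = 0; ti < n; ++ti) {
      const int t = perm[ti];
      arma::vec x = Xf.row(t).t();
      arma::vec g = sigmoid_vec(v.t() * x);
      arma::vec gf(M + 1);
      gf[0] = 1.0;
      gf.subvec(1, M) = g;
      arma::vec p = softmax_vec(w.t() * gf);
      const int lab = y[t] - 1;
      if (gate && p[lab] > k) continue; // confident trial: no update
      const int s = sample_winner(p.t());
      const bool rewarded = (s == lab);
      const double delta = rewarded ? reward_value * (1.0 - p[s]) : -1.0;
      const double f = f_expansive(delta, dcap);
      if (f != 0.0) {
        arma::vec w_s_pre = w.col(s);
        w.col(s) += (beta * f) * gf;
        arma::vec attn = g % (1.0 - g) % w_s_pre.subvec(1, M);
        v += (beta * f) * (x * attn.t());
      }
    }
    // epoch-level evaluation with the post-update weights
    arma::mat P = probs_matrix(Xf, v, w);
    double sum_pc = 0.0, n_above = 0.0, n_correct = 0.0, sum_sq = 0.0;
    for (int t = 0; t < n; ++t) {
      const double pc = P(t, y[t] - 1);
      sum_pc += pc;
      if (pc > k) n_above += 1.0;
      arma::uword pred;
      P.row(t).max(pred);
      if ((int)pred == y[t] - 1) n_correct += 1.0;
      sum_sq += arma::accu(arma::square(P.row(t)));
    }
    const double frac = n_above / n;
    const double acc = n_correct / n;
    const double rms =
        std::sqrt((sum_sq - 2.0 * sum_pc + n) / (n * (double)w.n_cols));
    frac_hist[epoch - 1] = frac;
    acc_hist[epoch - 1] = acc;
    rms_hist[epoch - 1] = rms;
    epochs_run = epoch;
    if (acc > best_acc) {
      best_acc = acc;
      best_epoch = epoch;
      best_v = v;
      best_w = w;
    }
    if (early_stop && frac >= conv_frac) {
      converged = true;
      break;
    }
  }
  return List::create(
      _["v"] = v, _["w"] = w, _["best_v"] = best_v, _["best_w"] = best_w,
      _["best_epoch"] = best_epoch, _["epochs_run"] = epochs_run,
      _["converged"] = converged,
      _["frac_hist"] = frac_hist.subvec(0, epochs_run - 1),
      _["acc_hist"] = acc_hist.subvec(0, epochs_run - 1),
      _["rms_hist"] = rms_hist.subvec(0, epochs_run - 1));
}

// One mini-batch update pass over a block of buffered samples, applied to
// (v, w) in place.  All samples are forwarded with the pass-entry weights,
// winners are sampled per sample (in buffer order), and the summed update
// is applied once.  Returns nothing; modifies v and w through references
// held by the caller.
static void mb_pass(const arma::mat& Bx, const arma::ivec& By, arma::mat& v,
                    arma::mat& w, double beta, double reward_value,
                    double dcap) {
  const int m = Bx.n_rows;
  const int M = v.n_cols;
  const int C = w.n_cols;
  arma::mat G = 1.0 / (1.0 + arma::exp(-(Bx * v)));
  G.clamp(GCLAMP_LO, GCLAMP_HI);
  arma::mat Gf = arma::join_horiz(arma::ones(m, 1), G);
  arma::mat A = Gf * w;
  A.each_col() -= arma::max(A, 1);
  arma::mat P = arma::exp(A);
  P.each_col() /= arma::sum(P, 1);

  arma::vec f(m);
  arma::mat Zf(m, C, arma::fill::zeros);
  arma::mat Wsel(m, M);
  for (int i = 0; i < m; ++i) {
    const int s = sample_winner(P.row(i));
    const bool rewarded = (s == By[i] - 1);
    const double delta = rewarded ? reward_value * (1.0 - P(i, s)) : -1.0;
    f[i] = f_expansive(delta, dcap);
    Zf(i, s) = f[i];
    Wsel.row(i) = w.col(s).subvec(1, M).t(); // pass-entry feedback weights
  }
  arma::mat Coef = G % (1.0 - G) % Wsel;
  Coef.each_col() %= f;
  w += beta * (Gf.t() * Zf);
  v += beta * (Bx.t() * Coef);
}

// Online testing with mini-batch adaptive updating.  The FIFO buffer of the
// latest J tested samples is the sliding window rows [t-J+1, t] of the test
// matrix.  With gate = true, a trial whose true-class probability exceeds k
// triggers no update; otherwise update passes repeat until conv_frac of the
// buffered samples are confidently correct or max_passes is hit.  With
// gate = false (the plain full-batch AGREL configuration) every trial
// triggers exactly one pass.  adapt = false never updates.
// [[Rcpp::export]]
List run_online_cpp(const arma::mat& X, const arma::ivec& y, arma::mat v,
                    arma::mat w, int J, double k, double conv_frac,
                    int max_passes, double beta, double reward_value,
                    double dcap, bool adapt, bool gate) {
  const int n = X.n_rows;
  const int M = v.n_cols;
  arma::mat Xf = arma::join_horiz(arma::ones(n, 1), X);

  IntegerVector pred(n), passes(n);
  NumericVector reward(n);
  LogicalVector gated(n);

  for (int t = 0; t < n; ++t) {
    arma::vec x = Xf.row(t).t();
    arma::vec g = sigmoid_vec(v.t() * x);
    arma::vec gf(M + 1);
    gf[0] = 1.0;
    gf.subvec(1, M) = g;
    arma::vec p = softmax_vec(w.t() * gf);
    const int s = sample_winner(p.t());
    pred[t] = s + 1;
    reward[t] = (s == y[t] - 1) ? reward_value : 0.0;
    const bool skip = gate && (p[y[t] - 1] > k);
    gated[t] = skip;
    int np = 0;
    if (adapt && !skip) {
      const int lo = t - J + 1 > 0 ? t - J + 1 : 0;
      arma::mat Bx = Xf.rows(lo, t);
      arma::ivec By = y.subvec(lo, t);
      while (np < max_passes) {
        mb_pass(Bx, By, v, w, beta, reward_value, dcap);
        ++np;
        if (!gate) break; // gating scheme off: single full-batch pass
        arma::mat P = probs_matrix(Bx, v, w);
        double n_above = 0.0;
        for (int i = 0; i <= t - lo; ++i) {
          if (P(i, By[i] - 1) > k) n_above += 1.0;
        }
        if (n_above / (t - lo + 1) >= conv_frac) break;
      }
    }
    passes[t] = np;
  }
  return List::create(_["pred"] = pred, _["reward"] = reward,
                      _["gated"] = gated, _["passes"] = passes, _["v"] = v,
                      _["w"] = w);
}
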