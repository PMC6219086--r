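// ZOOPS (zero-or-one occurrence per sequence) EM for motif discovery.
// Sequences arrive as integer vectors (A=0, C=1, G=2, T=3, N=-1); the PWM is
// a 4 x w column-stochastic matrix. Scores are natural-log odds against a
// fixed 0-order background, so the per-sequence log-likelihood computed here
// is the log-likelihood *ratio* against the background-only model.
//
// Performance notes: window scoring uses a 5-slot per-position table (slot 0
// absorbs N with a -1e30 score, removing the validity branch from the inner
// gather loop), and posterior/count accumulation skips windows more than
// EXP_CUTOFF nats below the per-sequence log-normalizer (their contribution
// is < 1e-13 of a site).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

const double NEG_BIG = -1e30;
const double EXP_CUTOFF = 30.0;

struct SeqData {
  std::vector<std::vector<int>> seqs;
  std::vector<std::vector<double>> erase_log;  // per forward window
};

SeqData unpack(const List& seqs, const List& erase_logs) {
  SeqData d;
  d.seqs.reserve(seqs.size());
  for (R_xlen_t t = 0; t < seqs.size(); ++t) {
    IntegerVector v = seqs[t];
    d.seqs.emplace_back(v.begin(), v.end());
  }
  if (erase_logs.size() == seqs.size()) {
    for (R_xlen_t t = 0; t < erase_logs.size(); ++t) {
      NumericVector e = erase_logs[t];
      d.erase_log.emplace_back(e.begin(), e.end());
    }
  }
  return d;
}

// 5-slot log-odds tables for both strands: lom5[j*5 + b + 1], slot 0 = N.
void make_lom(const double* pwm /*4 x w col-major*/, const NumericVector& bg,
              int w, std::vector<double>& lom5, std::vector<double>& lomrc5) {
  lom5.assign(5 * w, NEG_BIG);
  lomrc5.assign(5 * w, NEG_BIG);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) {
      double v = std::log(pwm[j * 4 + b] / bg[b]);
      lom5[j * 5 + b + 1] = v;
      lomrc5[(w - 1 - j) * 5 + (3 - b) + 1] = v;
    }
}

void score_windows(const std::vector<int>& s, const std::vector<double>& lom5,
                   const std::vector<double>& lomrc5, int w, bool both,
                   std::vector<double>& sf, std::vector<double>& sr) {
  int m = (int)s.size() - w + 1;
  sf.assign(m, 0.0);
  if (both) sr.assign(m, 0.0);
  for (int j = 0; j < w; ++j) {
    const double* lj = &lom5[j * 5 + 1];
    const int* sj = &s[j];
    for (int i = 0; i < m; ++i) sf[i] += lj[sj[i]];
    if (both) {
      const double* rj = &lomrc5[j * 5 + 1];
      for (int i = 0; i < m; ++i) sr[i] += rj[sj[i]];
    }
  }
}

// One E-step. Returns the total LLR; when counts != nullptr accumulates
// expected base counts (4 x w col-major) and site posteriors.
double e_step(const SeqData& d, const std::vector<double>& lom5,
              const std::vector<double>& lomrc5, int w, double gamma,
              bool both, std::vector<double>* counts, double* zsum,
              std::vector<double>* qsite) {
  double ll = 0.0;
  int nstr = both ? 2 : 1;
  if (counts) { counts->assign(4 * w, 0.0); *zsum = 0.0; }
  std::vector<double> sf, sr;
  for (size_t t = 0; t < d.seqs.size(); ++t) {
    const std::vector<int>& s = d.seqs[t];
    int m = (int)s.size() - w + 1;
    if (m < 1) { if (qsite) (*qsite)[t] = 0.0; continue; }
    score_windows(s, lom5, lomrc5, w, both, sf, sr);
    double lprior = std::log(gamma) - std::log((double)(nstr * m));
    double lnos = std::log1p(-gamma);
    const double* el = d.erase_log.empty() ? nullptr : d.erase_log[t].data();
    double best = lnos;
    for (int i = 0; i < m; ++i) {
      double e = el ? el[i] : 0.0;
      double a = lprior + sf[i] + e;
      if (a > best) best = a;
      if (both) {
        double b2 = lprior + sr[i] + e;
        if (b2 > best) best = b2;
      }
    }
    double acc = std::exp(lnos - best);
    double thr = best - EXP_CUTOFF;
    for (int i = 0; i < m; ++i) {
      double e = el ? el[i] : 0.0;
      double a = lprior + sf[i] + e;
      if (a > thr) acc += std::exp(a - best);
      if (both) {
        double b2 = lprior + sr[i] + e;
        if (b2 > thr) acc += std::exp(b2 - best);
      }
    }
    double lse = best + std::log(acc);
    ll += lse;
    if (qsite) (*qsite)[t] = 1.0 - std::exp(lnos - lse);
    if (counts) {
      double zthr = lse - EXP_CUTOFF;
      for (int i = 0; i < m; ++i) {
        double e = el ? el[i] : 0.0;
        double a = lprior + sf[i] + e;
        if (a > zthr) {
          double z = std::exp(a - lse);
          *zsum += z;
          for (int j = 0; j < w; ++j) (*counts)[j * 4 + s[i + j]] += z;
        }
        if (both) {
          double b2 = lprior + sr[i] + e;
          if (b2 > zthr) {
            double z = std::exp(b2 - lse);
            *zsum += z;
            for (int j = 0; j < w; ++j)
              (*counts)[(w - 1 - j) * 4 + (3 - s[i + j])] += z;
          }
        }
      }
    }
  }
  return ll;
}

void m_step(const std::vector<double>& counts, double zsum,
            const std::vector<double>& qsite, int nseq, int w,
            const NumericVector& bg, double pseudo, std::vector<double>& pwm,
            double& gamma) {
  for (int j = 0; j < w; ++j) {
    double tot = 0.0;
    for (int b = 0; b < 4; ++b) {
      pwm[j * 4 + b] = counts[j * 4 + b] + pseudo * bg[b];
      tot += pwm[j * 4 + b];
    }
    for (int b = 0; b < 4; ++b) pwm[j * 4 + b] /= tot;
  }
  double q = 0.0;
  for (int t = 0; t < nseq; ++t) q += qsite[t];
  gamma = q / nseq;
  if (gamma < 1e-3) gamma = 1e-3;
  if (gamma > 0.999) gamma = 0.999;
  (void)zsum;
}

// Full EM loop on a col-major 4 x w pwm; returns the LLR at the final model.
double em_loop(const SeqData& d, std::vector<double>& pwm, double& gamma,
               int w, const NumericVector& bg, bool both, int maxiter,
               double tol, double pseudo) {
  std::vector<double> lom5, lomrc5, counts;
  std::vector<double> qsite(d.seqs.size(), 0.0);
  double zsum = 0.0, ll = R_NegInf, ll_prev = R_NegInf;
  for (int it = 0; it <= maxiter; ++it) {
    make_lom(pwm.data(), bg, w, lom5, lomrc5);
    ll = e_step(d, lom5, lomrc5, w, gamma, both, &counts, &zsum, &qsite);
    if (it == maxiter || (it > 0 && std::fabs(ll - ll_prev) < tol)) break;
    ll_prev = ll;
    m_step(counts, zsum, qsite, (int)d.seqs.size(), w, bg, pseudo, pwm, gamma);
  }
  return ll;
}

NumericMatrix to_matrix(const std::vector<double>& pwm, int w) {
  NumericMatrix out(4, w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) out(b, j) = pwm[j * 4 + b];
  return out;
}

std::vector<double> from_matrix(const NumericMatrix& m) {
  int w = m.ncol();
  std::vector<double> pwm(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) pwm[j * 4 + b] = m(b, j);
  return pwm;
}

}  // namespace

// [[Rcpp::export]]
List zoops_em_cpp(List seqs, NumericMatrix pwm0, double gamma0,
                  NumericVector bg, List erase_logs, bool both_strands,
                  int maxiter, double tol, double pseudo) {
  SeqData d = unpack(seqs, erase_logs);
  int w = pwm0.ncol();
  std::vector<double> pwm = from_matrix(pwm0);
  double gamma = gamma0;
  double ll = em_loop(d, pwm, gamma, w, bg, both_strands, maxiter, tol, pseudo);
  return List::create(_["pwm"] = to_matrix(pwm, w), _["gamma"] = gamma,
                      _["llr"] = ll);
}

// Posterior site statistics for a fitted model: per sequence the full
// window-by-strand posterior matrix, the probability a site is present, and
// the best-scoring site (by log-odds alignment score).
// [[Rcpp::export]]
List zoops_posterior_cpp(List seqs, NumericMatrix pwm, double gamma,
                         NumericVector bg, List erase_logs, bool both_strands) {
  SeqData d = unpack(seqs, erase_logs);
  int w = pwm.ncol();
  int nstr = both_strands ? 2 : 1;
  std::vector<double> p = from_matrix(pwm);
  std::vector<double> lom5, lomrc5, sf, sr;
  make_lom(p.data(), bg, w, lom5, lomrc5);
  List zmats(d.seqs.size());
  NumericVector qsite(d.seqs.size()), best_score(d.seqs.size());
  IntegerVector best_pos(d.seqs.size()), best_strand(d.seqs.size());
  for (size_t t = 0; t < d.seqs.size(); ++t) {
    const std::vector<int>& s = d.seqs[t];
    int m = (int)s.size() - w + 1;
    if (m < 1) {
      zmats[t] = NumericMatrix(nstr, 0);
      qsite[t] = 0; best_pos[t] = NA_INTEGER; best_strand[t] = NA_INTEGER;
      best_score[t] = NA_REAL;
      continue;
    }
    score_windows(s, lom5, lomrc5, w, both_strands, sf, sr);
    double lprior = std::log(gamma) - std::log((double)(nstr * m));
    double lnos = std::log1p(-gamma);
    const double* el = d.erase_log.empty() ? nullptr : d.erase_log[t].data();
    double best = lnos, bsc = R_NegInf;
    int bpos = NA_INTEGER, bstr = NA_INTEGER;
    for (int i = 0; i < m; ++i) {
      double e = el ? el[i] : 0.0;
      double a = lprior + sf[i] + e;
      if (a > best) best = a;
      if (sf[i] > bsc && sf[i] > NEG_BIG / 2) { bsc = sf[i]; bpos = i; bstr = 1; }
      if (both_strands) {
        double b2 = lprior + sr[i] + e;
        if (b2 > best) best = b2;
        if (sr[i] > bsc && sr[i] > NEG_BIG / 2) { bsc = sr[i]; bpos = i; bstr = -1; }
      }
    }
    double acc = std::exp(lnos - best);
    for (int i = 0; i < m; ++i) {
      double e = el ? el[i] : 0.0;
      double a = lprior + sf[i] + e;
      if (a > best - EXP_CUTOFF) acc += std::exp(a - best);
      if (both_strands) {
        double b2 = lprior + sr[i] + e;
        if (b2 > best - EXP_CUTOFF) acc += std::exp(b2 - best);
      }
    }
    double lse = best + std::log(acc);
    NumericMatrix Z(nstr, m);
    for (int i = 0; i < m; ++i) {
      double e = el ? el[i] : 0.0;
      double a = lprior + sf[i] + e;
      Z(0, i) = a > lse - EXP_CUTOFF ? std::exp(a - lse) : 0.0;
      if (both_strands) {
        double b2 = lprior + sr[i] + e;
        Z(1, i) = b2 > lse - EXP_CUTOFF ? std::exp(b2 - lse) : 0.0;
      }
    }
    zmats[t] = Z;
    qsite[t] = 1.0 - std::exp(lnos - lse);
    best_pos[t] = bpos;
    best_strand[t] = bstr;
    best_score[t] = bsc == R_NegInf ? NA_REAL : bsc;
  }
  return List::create(_["z"] = zmats, _["qsite"] = qsite,
                      _["best_pos"] = best_pos, _["best_strand"] = best_strand,
                      _["best_score"] = best_score);
}

// Seeded single-width search. Stage 1: every stride-th forward w-mer becomes
// a seed PWM (probability p0 on the seed base) and is scored by the LLR of
// its own alignment (one E pass, no refit). Stage 2: the top `n_top` seeds
// get one EM step each; the best 1-step seed is refined to convergence.
// [[Rcpp::export]]
List zoops_seed_search_cpp(List seqs, int w, NumericVector bg, List erase_logs,
                           bool both_strands, int max_seeds, double p0,
                           double gamma0, int refine_maxiter, double tol,
                           double pseudo, int n_top = 20) {
  SeqData d = unpack(seqs, erase_logs);
  std::vector<std::pair<int, int>> sites;
  for (size_t t = 0; t < d.seqs.size(); ++t) {
    const std::vector<int>& s = d.seqs[t];
    int m = (int)s.size() - w + 1;
    for (int i = 0; i < m; ++i) {
      bool okw = true;
      for (int j = 0; j < w; ++j) if (s[i + j] < 0) { okw = false; break; }
      if (okw) sites.emplace_back((int)t, i);
    }
  }
  if (sites.empty())
    return List::create(_["llr"] = R_NegInf, _["ok"] = false);
  int stride = std::max(1, (int)((sites.size() + max_seeds - 1) / max_seeds));
  double off = (1.0 - p0) / 3.0;
  std::vector<double> seedpwm(4 * w), lom5, lomrc5;
  std::vector<std::pair<double, size_t>> ranked;  // (llr, site index)
  int n_seeds = 0;
  for (size_t k = 0; k < sites.size(); k += stride) {
    const std::vector<int>& s = d.seqs[sites[k].first];
    int pos = sites[k].second;
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b)
        seedpwm[j * 4 + b] = (s[pos + j] == b) ? p0 : off;
    make_lom(seedpwm.data(), bg, w, lom5, lomrc5);
    double ll = e_step(d, lom5, lomrc5, w, gamma0, both_strands,
                       nullptr, nullptr, nullptr);
    ranked.emplace_back(ll, k);
    ++n_seeds;
  }
  int keep = std::min((size_t)n_top, ranked.size());
  std::partial_sort(ranked.begin(), ranked.begin() + keep, ranked.end(),
                    [](const std::pair<double, size_t>& a,
                       const std::pair<double, size_t>& b) {
                      return a.first > b.first;
                    });
  std::vector<double> bestpwm(4 * w), p(4 * w);
  double best_ll = R_NegInf, best_gamma = gamma0;
  for (int r = 0; r < keep; ++r) {
    size_t k = ranked[r].second;
    const std::vector<int>& s = d.seqs[sites[k].first];
    int pos = sites[k].second;
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b)
        p[j * 4 + b] = (s[pos + j] == b) ? p0 : off;
    double g = gamma0;
    double ll = em_loop(d, p, g, w, bg, both_strands, 1, tol, pseudo);
    if (ll > best_ll) { best_ll = ll; bestpwm = p; best_gamma = g; }
  }
  double ll = em_loop(d, bestpwm, best_gamma, w, bg, both_strands,
                      refine_maxiter, tol, pseudo);
  return List::create(_["pwm"] = to_matrix(bestpwm, w),
                      _["gamma"] = best_gamma, _["llr"] = ll,
                      _["n_seeds"] = n_seeds, _["ok"] = true);
}
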