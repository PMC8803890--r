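#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

// Pearson correlation; returns 0 when either side has zero variance.
static double pearson_or_zero(const std::vector<double>& a,
                              const std::vector<double>& b) {
  const std::size_t n = a.size();
  if (n < 2) return 0.0;
  double ma = 0.0, mb = 0.0;
  for (std::size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0.0, saa = 0.0, sbb = 0.0;
  for (std::size_t i = 0; i < n; ++i) {
    const double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0.0 || sbb <= 0.0) return 0.0;
  double r = sab / std::sqrt(saa * sbb);
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// Simplex prediction of target[] at one query row from a library of rows.
// emb: n_points x E embedding matrix; lib: 0-based row indices of library
// points; q: 0-based query row (excluded from its own neighbourhood).
// k neighbours, exponential weights u_i = exp(-d_i/d_1); exact-tie
// zero-distance neighbours share equal weight.
static double simplex_one(const NumericMatrix& emb, const NumericVector& target,
                          const std::vector<int>& lib, int q, int k) {
  const int E = emb.ncol();
  std::vector<std::pair<double, int>> cand;
  cand.reserve(lib.size());
  for (std::size_t j = 0; j < lib.size(); ++j) {
    const int r = lib[j];
    if (r == q) continue;  // never use the query point itself
    double d2 = 0.0;
    for (int c = 0; c < E; ++c) {
      const double diff = emb(q, c) - emb(r, c);
      d2 += diff * diff;
    }
    cand.push_back(std::make_pair(d2, r));
  }
  const int kk = std::min<int>(k, (int)cand.size());
  if (kk < 1) return NA_REAL;
  std::partial_sort(cand.begin(), cand.begin() + kk, cand.end());
  const double d1 = std::sqrt(cand[0].first);
  double wsum = 0.0, pred = 0.0;
  if (d1 <= 0.0) {
    // all zero-distance neighbours get equal weight
    for (int j = 0; j < kk; ++j) {
      if (cand[j].first <= 0.0) { pred += target[cand[j].second]; wsum += 1.0; }
    }
  } else {
    for (int j = 0; j < kk; ++j) {
      const double w = std::exp(-std::sqrt(cand[j].first) / d1);
      pred += w * target[cand[j].second];
      wsum += w;
    }
  }
  return pred / wsum;
}

// [[Rcpp::export]]
NumericVector simplex_predict_cpp(NumericMatrix emb, NumericVector target,
                                  IntegerVector lib, IntegerVector pred,
                                  int k) {
  std::vector<int> lib0(lib.size());
  for (int i = 0; i < lib.size(); ++i) lib0[i] = lib[i] - 1;
  NumericVector out(pred.size());
  for (int i = 0; i < pred.size(); ++i)
    out[i] = simplex_one(emb, target, lib0, pred[i] - 1, k);
  return out;
}

// Cross-map skill over a grid of library sizes with repeated library
// resampling. Libraries are drawn from lib_pool (contiguous blocks or
// random subsets); skill is the Pearson correlation between target and
// its simplex estimate over the pred rows. Returns n_sizes x n_samples.
//
// The full pool ordering by distance is precomputed once per query;
// each library draw then only walks that ordering until k members of
// the drawn library are found.
// [[Rcpp::export]]
NumericMatrix ccm_skills_cpp(NumericMatrix emb, NumericVector target,
                             IntegerVector lib_pool, IntegerVector pred,
                             IntegerVector lib_sizes, int n_samples,
                             bool contiguous, int k, int seed) {
  const int npool = lib_pool.size(), npred = pred.size(),
            nsizes = lib_sizes.size();
  const int E = emb.ncol();
  std::vector<int> pool0(npool);
  for (int i = 0; i < npool; ++i) pool0[i] = lib_pool[i] - 1;
  std::vector<int> pred0(npred);
  for (int i = 0; i < npred; ++i) pred0[i] = pred[i] - 1;
  std::vector<double> obs(npred);
  for (int i = 0; i < npred; ++i) obs[i] = target[pred0[i]];

  // per query: pool positions sorted by distance, with distances
  std::vector<std::vector<int>> order(npred);
  std::vector<std::vector<double>> odist(npred);
  {
    std::vector<std::pair<double, int>> cand(npool);
    for (int i = 0; i < npred; ++i) {
      const int q = pred0[i];
      int m = 0;
      for (int j = 0; j < npool; ++j) {
        const int r = pool0[j];
        if (r == q) continue;  // never use the query point itself
        double d2 = 0.0;
        for (int c = 0; c < E; ++c) {
          const double diff = emb(q, c) - emb(r, c);
          d2 += diff * diff;
        }
        cand[m++] = std::make_pair(d2, j);
      }
      std::sort(cand.begin(), cand.begin() + m);
      order[i].resize(m);
      odist[i].resize(m);
      for (int j = 0; j < m; ++j) {
        order[i][j] = cand[j].second;
        odist[i][j] = std::sqrt(cand[j].first);
      }
    }
  }

  std::mt19937 rng((unsigned)seed);
  NumericMatrix out(nsizes, n_samples);
  std::vector<char> member(npool, 0);
  std::vector<int> idx(npool);
  for (int i = 0; i < npool; ++i) idx[i] = i;
  std::vector<double> nnd(k);
  std::vector<double> nnt(k);

  for (int s = 0; s < nsizes; ++s) {
    const int L = std::min(lib_sizes[s], npool);
    for (int rep = 0; rep < n_samples; ++rep) {
      int bstart = 0, bend = npool;  // contiguous block [bstart, bend)
      if (contiguous || L == npool) {
        std::uniform_int_distribution<int> ud(0, npool - L);
        bstart = (L == npool) ? 0 : ud(rng);
        bend = bstart + L;
      } else {
        // partial Fisher-Yates for a random subset without replacement
        std::fill(member.begin(), member.end(), 0);
        for (int j = 0; j < L; ++j) {
          std::uniform_int_distribution<int> ud(j, npool - 1);
          std::swap(idx[j], idx[ud(rng)]);
          member[idx[j]] = 1;
        }
        std::sort(idx.begin(), idx.end());
        bstart = -1;
      }
      std::vector<double> okobs, okest;
      okobs.reserve(npred);
      okest.reserve(npred);
      for (int i = 0; i < npred; ++i) {
        const std::vector<int>& ord = order[i];
        const std::vector<double>& dst = odist[i];
        int found = 0;
        for (std::size_t j = 0; j < ord.size() && found < k; ++j) {
          const int pos = ord[j];
          const bool in = (bstart >= 0) ? (pos >= bstart && pos < bend)
                                        : (member[pos] != 0);
          if (!in) continue;
          nnd[found] = dst[j];
          nnt[found] = target[pool0[pos]];
          ++found;
        }
        if (found < 1) continue;
        const double d1 = nnd[0];
        double wsum = 0.0, prd = 0.0;
        if (d1 <= 0.0) {
          for (int j = 0; j < found; ++j)
            if (nnd[j] <= 0.0) { prd += nnt[j]; wsum += 1.0; }
        } else {
          for (int j = 0; j < found; ++j) {
            const double w = std::exp(-nnd[j] / d1);
            prd += w * nnt[j];
            wsum += w;
          }
        }
        okest.push_back(prd / wsum);
        okobs.push_back(obs[i]);
      }
      out(s, rep) = pearson_or_zero(okest, okobs);
    }
  }
  return out;
}
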