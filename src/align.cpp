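// Affine-gap global alignment (Gotoh) of short atom sequences, and the
// all-against-all neighborhood alignment loop that accumulates atom-pair
// evidence. Sequences are index vectors into a precomputed atom-vs-atom
// score matrix, so the DP is position-specific.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Gotoh DP over a k1 x k2 position score matrix `s` (s(i,j) = score of
// matching position i of A with position j of B). Gap runs cost
// `open` for the first gapped position and `ext` for each additional one
// (both negative). End gaps are penalized (true global alignment).
// State preference on ties (scoring and traceback): match > gap-in-B > gap-in-A,
// which makes the traceback deterministic.
struct NWResult {
  double score;
  std::vector<std::pair<int, int> > pairs; // 0-based (i, j)
};

static NWResult nw_affine(const double* s, int k1, int k2,
                          double open, double ext, bool traceback) {
  const int W = k2 + 1;
  std::vector<double> M((k1 + 1) * W, NEG_INF), X(M), Y(M);
  // X: gap in B (A position consumed), Y: gap in A
  std::vector<signed char> tbM, tbX, tbY;
  if (traceback) {
    tbM.assign((k1 + 1) * W, -1);
    tbX.assign((k1 + 1) * W, -1);
    tbY.assign((k1 + 1) * W, -1);
  }
  M[0] = 0.0;
  for (int i = 1; i <= k1; ++i) {
    X[i * W] = open + ext * (i - 1);
    if (traceback) tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= k2; ++j) {
    Y[j] = open + ext * (j - 1);
    if (traceback) tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= k1; ++i) {
    for (int j = 1; j <= k2; ++j) {
      const int ij = i * W + j;
      const int d = (i - 1) * W + (j - 1);
      // match state
      double bestPrev = M[d];
      signed char arg = 0;
      if (X[d] > bestPrev) { bestPrev = X[d]; arg = 1; }
      if (Y[d] > bestPrev) { bestPrev = Y[d]; arg = 2; }
      if (bestPrev > NEG_INF) {
        M[ij] = bestPrev + s[(i - 1) + k1 * (j - 1)];
        if (traceback) tbM[ij] = arg;
      }
      // gap in B: consume A position i
      {
        const int up = (i - 1) * W + j;
        double vM = (M[up] > NEG_INF) ? M[up] + open : NEG_INF;
        double vX = (X[up] > NEG_INF) ? X[up] + ext : NEG_INF;
        double vY = (Y[up] > NEG_INF) ? Y[up] + open : NEG_INF;
        double best = vM; signed char a2 = 0;
        if (vX > best) { best = vX; a2 = 1; }
        if (vY > best) { best = vY; a2 = 2; }
        X[ij] = best;
        if (traceback) tbX[ij] = a2;
      }
      // gap in A: consume B position j
      {
        const int lf = i * W + (j - 1);
        double vM = (M[lf] > NEG_INF) ? M[lf] + open : NEG_INF;
        double vX = (X[lf] > NEG_INF) ? X[lf] + open : NEG_INF;
        double vY = (Y[lf] > NEG_INF) ? Y[lf] + ext : NEG_INF;
        double best = vM; signed char a2 = 0;
        if (vX > best) { best = vX; a2 = 1; }
        if (vY > best) { best = vY; a2 = 2; }
        Y[ij] = best;
        if (traceback) tbY[ij] = a2;
      }
    }
  }
  NWResult res;
  const int end = k1 * W + k2;
  int state = 0;
  res.score = M[end];
  if (X[end] > res.score) { res.score = X[end]; state = 1; }
  if (Y[end] > res.score) { res.score = Y[end]; state = 2; }
  if (traceback) {
    int i = k1, j = k2;
    while (i > 0 || j > 0) {
      const int ij = i * W + j;
      if (state == 0) {
        res.pairs.push_back(std::make_pair(i - 1, j - 1));
        state = tbM[ij];
        --i; --j;
      } else if (state == 1) {
        state = tbX[ij];
        --i;
      } else {
        state = tbY[ij];
        --j;
      }
    }
    std::reverse(res.pairs.begin(), res.pairs.end());
  }
  return res;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(NumericMatrix s, double gap_open, double gap_extend) {
  NWResult r = nw_affine(&s[0], s.nrow(), s.ncol(), gap_open, gap_extend, true);
  const int n = (int)r.pairs.size();
  IntegerMatrix pm(n, 2);
  for (int t = 0; t < n; ++t) {
    pm(t, 0) = r.pairs[t].first + 1;
    pm(t, 1) = r.pairs[t].second + 1;
  }
  return List::create(_["score"] = r.score, _["pairs"] = pm);
}

// All-against-all alignment of A-neighborhood sequences vs B-neighborhood
// sequences. nbrA (nA x k): 1-based atom indices (rows of S) forming each
// A sequence; nbrB likewise for columns of S. An alignment contributes when
// its score >= gate_frac * min(selfA, selfB); every matched atom pair then
// gains the full alignment score as evidence and +1 count.
// [[Rcpp::export(name = ".pair_evidence_cpp")]]
List pair_evidence_cpp(IntegerMatrix nbrA, IntegerMatrix nbrB,
                       NumericMatrix S, NumericVector selfA,
                       NumericVector selfB, double gate_frac,
                       double gap_open, double gap_extend) {
  const int nA = nbrA.nrow(), nB = nbrB.nrow();
  const int kA = nbrA.ncol(), kB = nbrB.ncol();
  const int a_atoms = S.nrow(), b_atoms = S.ncol();
  NumericMatrix evidence(a_atoms, b_atoms);
  IntegerMatrix counts(a_atoms, b_atoms);
  std::vector<int> seed_aln, seed_a, seed_b; // gated-alignment membership
  int n_gated = 0;
  std::vector<double> sub(kA * kB);
  for (int ia = 0; ia < nA; ++ia) {
    for (int ib = 0; ib < nB; ++ib) {
      // position score matrix of this sequence pair
      for (int q = 0; q < kB; ++q) {
        const int bj = nbrB(ib, q) - 1;
        for (int p = 0; p < kA; ++p) {
          sub[p + kA * q] = S(nbrA(ia, p) - 1, bj);
        }
      }
      const double gate = gate_frac * std::min(selfA[ia], selfB[ib]);
      NWResult r = nw_affine(&sub[0], kA, kB, gap_open, gap_extend, true);
      if (r.score < gate) continue;
      ++n_gated;
      for (size_t t = 0; t < r.pairs.size(); ++t) {
        const int ai = nbrA(ia, r.pairs[t].first) - 1;
        const int bi = nbrB(ib, r.pairs[t].second) - 1;
        evidence(ai, bi) += r.score;
        counts(ai, bi) += 1;
        seed_aln.push_back(n_gated);
        seed_a.push_back(ai + 1);
        seed_b.push_back(bi + 1);
      }
    }
  }
  return List::create(
    _["evidence"] = evidence, _["counts"] = counts,
    _["seed_alignment"] = wrap(seed_aln),
    _["seed_a"] = wrap(seed_a), _["seed_b"] = wrap(seed_b)
  );
}
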