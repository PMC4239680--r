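// Dynamic-programming core for the directed 3-star (median) problem.
//
// Genomes are encoded as signed integers: +f / -f for gene family f on the
// forward / reverse strand (f >= 1).  The table C(i,j,k) holds the minimum
// cost of a labeled alignment of the prefixes A[1..i], X[1..j], Y[1..k],
// where A is the ancestor of the (hidden) center M and X, Y are the two
// children of M.  Every cell is the minimum over the admissible
// interpretations of the last alignment column block; each interpretation
// consumes a suffix block of length m from one or more of the three
// prefixes and charges the cost of at most two events.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Genome {
  const int *g; // 1-based: g[1..n]
  int n;
  int operator[](int i) const { return g[i]; }
};

// In signed mode the reverse of a segment flips orientation; in unsigned
// mode it only reverses the order.
inline int rc(int v, bool signed_mode) { return signed_mode ? -v : v; }

// Is Q[q-m+1..q] the reverse of P[p-m+1..p]?
inline bool rev_match(const Genome &P, int p, const Genome &Q, int q, int m,
                      bool signed_mode) {
  for (int t = 0; t < m; ++t)
    if (Q[q - t] != rc(P[p - m + 1 + t], signed_mode)) return false;
  return true;
}

// Longest common suffix of P[1..p] and Q[1..q].
inline int common_suffix(const Genome &P, int p, const Genome &Q, int q) {
  int m = 0;
  while (m < p && m < q && P[p - m] == Q[q - m]) ++m;
  return m;
}

// Does src[sstart..sstart+m-1] occur anywhere in hay?
inline bool occurs_any(const Genome &hay, const Genome &src, int sstart,
                       int m) {
  for (int p = 1; p + m - 1 <= hay.n; ++p) {
    bool ok = true;
    for (int t = 0; t < m; ++t)
      if (hay[p + t] != src[sstart + t]) { ok = false; break; }
    if (ok) return true;
  }
  return false;
}

// Occurrence of src[sstart..sstart+m-1] inside src itself, disjoint from
// the interval [sstart, sstart+m-1] (a duplication source must not overlap
// its own copy).
inline bool occurs_disjoint(const Genome &src, int sstart, int m) {
  int send = sstart + m - 1;
  for (int p = 1; p + m - 1 <= src.n; ++p) {
    int pend = p + m - 1;
    if (pend >= sstart && p <= send) continue; // overlaps the copy
    bool ok = true;
    for (int t = 0; t < m; ++t)
      if (src[p + t] != src[sstart + t]) { ok = false; break; }
    if (ok) return true;
  }
  return false;
}

} // namespace

// Case identifiers (see backtrack_alignment() on the R side):
//  1 match [a,a,a]
//  2 reversal in M            [a,x,x]
//  3 reversal in X            [a,x,a]
//  4 reversal in Y            [a,a,y]
//  5 duplication in M         [-,x,x]
//  6 reversal in M + loss Y   [a,x,-]
//  7 reversal in M + loss X   [a,-,y]
//  8 duplication in M (=X) + reversal in Y   [-,x,y]
//  9 duplication in M (=Y) + reversal in X   [-,x,y]
// 10 loss in X                [a,-,a]
// 11 loss in Y                [a,a,-]
// 12 loss in M                [a,-,-]
// 13 duplication in X         [-,x,-]
// 14 duplication in Y         [-,-,y]

// [[Rcpp::export(name = ".star_dp_cpp")]]
List star_dp_cpp(IntegerVector Av, IntegerVector Xv, IntegerVector Yv,
                 NumericVector cd, NumericVector cl, NumericVector cr,
                 bool signed_mode) {
  const int nA = Av.size(), nX = Xv.size(), nY = Yv.size();
  // 1-based working copies
  std::vector<int> abuf(nA + 1), xbuf(nX + 1), ybuf(nY + 1);
  for (int i = 0; i < nA; ++i) abuf[i + 1] = Av[i];
  for (int i = 0; i < nX; ++i) xbuf[i + 1] = Xv[i];
  for (int i = 0; i < nY; ++i) ybuf[i + 1] = Yv[i];
  const Genome A{abuf.data(), nA}, X{xbuf.data(), nX}, Y{ybuf.data(), nY};

  const int d1 = nA + 1, d2 = nX + 1, d3 = nY + 1;
  const size_t sz = (size_t)d1 * d2 * d3;
  NumericVector C(sz, R_PosInf);
  IntegerVector CS(sz, 0), MMv(sz, 0);
  // R column-major layout so the result can carry a dim attribute directly
  auto idx = [&](int i, int j, int k) {
    return (size_t)i + (size_t)j * d1 + (size_t)k * d1 * d2;
  };
  C[idx(0, 0, 0)] = 0.0;

  // Tie-break priority: match > losses > shared duplication > reversals >
  // solo duplication > compound two-event cases.  Lower rank wins at equal
  // cost; within a rank the lower case id, then the longer block.
  int rank[15];
  rank[1] = 0;
  rank[10] = rank[11] = rank[12] = 1;
  rank[5] = 2;
  rank[2] = rank[3] = rank[4] = 3;
  rank[13] = rank[14] = 4;
  rank[6] = rank[7] = rank[8] = rank[9] = 5;

  const double EPS = 1e-9;
  // cost vectors are 1-based on the R side: cd[m-1] is the cost of D(m)
  auto cD = [&](int m) { return cd[m - 1]; };
  auto cL = [&](int m) { return cl[m - 1]; };
  auto cR = [&](int m) { return cr[m - 1]; };

  for (int k = 0; k <= nY; ++k)
    for (int j = 0; j <= nX; ++j)
      for (int i = 0; i <= nA; ++i) {
        if (i == 0 && j == 0 && k == 0) continue;
        double best = R_PosInf;
        int bc = 0, bm = 0;
        auto consider = [&](double cost, int cs, int m) {
          if (!R_finite(cost)) return;
          bool take = false;
          if (cost < best - EPS)
            take = true;
          else if (cost < best + EPS && bc != 0) {
            if (rank[cs] < rank[bc]) take = true;
            else if (rank[cs] == rank[bc] &&
                     (cs < bc || (cs == bc && m > bm)))
              take = true;
          } else if (bc == 0 && cost < best + EPS)
            take = true;
          if (take) { best = cost; bc = cs; bm = m; }
        };

        // 1: all match
        if (i && j && k && A[i] == X[j] && X[j] == Y[k])
          consider(C[idx(i - 1, j - 1, k - 1)], 1, 1);

        // 12: loss in M (gene block present in A only)
        for (int m = 1; m <= i; ++m)
          consider(C[idx(i - m, j, k)] + cL(m), 12, m);

        // 10: loss in X (A and Y share the block)
        if (i && k && A[i] == Y[k]) {
          int L = common_suffix(A, i, Y, k);
          for (int m = 1; m <= L; ++m)
            consider(C[idx(i - m, j, k - m)] + cL(m), 10, m);
        }
        // 11: loss in Y
        if (i && j && A[i] == X[j]) {
          int L = common_suffix(A, i, X, j);
          for (int m = 1; m <= L; ++m)
            consider(C[idx(i - m, j - m, k)] + cL(m), 11, m);
        }

        // 5: duplication in M; block shared by X and Y, source occurs in A
        if (j && k && X[j] == Y[k]) {
          int L = common_suffix(X, j, Y, k);
          for (int m = 1; m <= L; ++m) {
            if (!occurs_any(A, X, j - m + 1, m)) break;
            consider(C[idx(i, j - m, k - m)] + cD(m), 5, m);
          }
        }

        // 2: reversal in M (both children carry the reverse of A's block)
        {
          int lim = std::min(i, std::min(j, k));
          for (int m = 1; m <= lim; ++m)
            if (rev_match(A, i, X, j, m, signed_mode) &&
                rev_match(A, i, Y, k, m, signed_mode))
              consider(C[idx(i - m, j - m, k - m)] + cR(m), 2, m);
        }
        // 3: reversal in X (A matches Y, X carries the reverse)
        if (i && j && k) {
          int L = common_suffix(A, i, Y, k);
          int lim = std::min(L, j);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(A, i, X, j, m, signed_mode))
              consider(C[idx(i - m, j - m, k - m)] + cR(m), 3, m);
        }
        // 4: reversal in Y
        if (i && j && k) {
          int L = common_suffix(A, i, X, j);
          int lim = std::min(L, k);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(A, i, Y, k, m, signed_mode))
              consider(C[idx(i - m, j - m, k - m)] + cR(m), 4, m);
        }

        // 6: reversal in M + loss in Y (same block size for both events)
        {
          int lim = std::min(i, j);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(A, i, X, j, m, signed_mode))
              consider(C[idx(i - m, j - m, k)] + cR(m) + cL(m), 6, m);
        }
        // 7: reversal in M + loss in X
        {
          int lim = std::min(i, k);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(A, i, Y, k, m, signed_mode))
              consider(C[idx(i - m, j, k - m)] + cR(m) + cL(m), 7, m);
        }
        // 8: duplication in M with X's block (source occurs in A),
        //    reversal in Y
        {
          int lim = std::min(j, k);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(X, j, Y, k, m, signed_mode) &&
                occurs_any(A, X, j - m + 1, m))
              consider(C[idx(i, j - m, k - m)] + cD(m) + cR(m), 8, m);
        }
        // 9: duplication in M with Y's block, reversal in X
        {
          int lim = std::min(j, k);
          for (int m = 1; m <= lim; ++m)
            if (rev_match(Y, k, X, j, m, signed_mode) &&
                occurs_any(A, Y, k - m + 1, m))
              consider(C[idx(i, j - m, k - m)] + cD(m) + cR(m), 9, m);
        }

        // 13: duplication in X alone; the source block must occur in A, in
        // Y, or elsewhere in X (disjoint from the copy itself)
        if (j) {
          for (int m = 1; m <= j; ++m) {
            bool occ = occurs_any(A, X, j - m + 1, m) ||
                       occurs_disjoint(X, j - m + 1, m) ||
                       occurs_any(Y, X, j - m + 1, m);
            if (!occ) break;
            consider(C[idx(i, j - m, k)] + cD(m), 13, m);
          }
        }
        // 14: duplication in Y alone
        if (k) {
          for (int m = 1; m <= k; ++m) {
            bool occ = occurs_any(A, Y, k - m + 1, m) ||
                       occurs_disjoint(Y, k - m + 1, m) ||
                       occurs_any(X, Y, k - m + 1, m);
            if (!occ) break;
            consider(C[idx(i, j, k - m)] + cD(m), 14, m);
          }
        }

        C[idx(i, j, k)] = best;
        CS[idx(i, j, k)] = bc;
        MMv[idx(i, j, k)] = bm;
      }

  IntegerVector dim = IntegerVector::create(d1, d2, d3);
  C.attr("dim") = dim;
  CS.attr("dim") = dim;
  MMv.attr("dim") = dim;
  return List::create(_["cost"] = C, _["case"] = CS, _["m"] = MMv);
}

// ---- pairwise table fills ------------------------------------------------
// Case ids, directed (A ancestor, X descendant):
//  1 match, 2 loss of an A block, 3 reversal, 4 duplication of an X block
//  (source in A, or in X disjoint from the copy), 5 per-gene gain.
// Priority: match > loss > reversal > duplication > gain.

// [[Rcpp::export(name = ".pair_directed_dp_cpp")]]
List pair_directed_dp_cpp(IntegerVector Av, IntegerVector Xv,
                          NumericVector cd, NumericVector cl,
                          NumericVector cr, bool signed_mode,
                          bool allow_gain) {
  const int nA = Av.size(), nX = Xv.size();
  std::vector<int> abuf(nA + 1), xbuf(nX + 1);
  for (int i = 0; i < nA; ++i) abuf[i + 1] = Av[i];
  for (int i = 0; i < nX; ++i) xbuf[i + 1] = Xv[i];
  const Genome A{abuf.data(), nA}, X{xbuf.data(), nX};
  const int d1 = nA + 1, d2 = nX + 1;
  NumericMatrix C(d1, d2);
  IntegerMatrix CS(d1, d2), MM(d1, d2);
  std::fill(C.begin(), C.end(), R_PosInf);
  C(0, 0) = 0.0;
  int rank[6] = {0, 0, 1, 2, 3, 4};
  const double EPS = 1e-9;
  for (int j = 0; j <= nX; ++j)
    for (int i = 0; i <= nA; ++i) {
      if (i == 0 && j == 0) continue;
      double best = R_PosInf; int bc = 0, bm = 0;
      auto consider = [&](double cost, int cs, int m) {
        if (!R_finite(cost)) return;
        bool take = false;
        if (cost < best - EPS) take = true;
        else if (cost < best + EPS && bc != 0) {
          if (rank[cs] < rank[bc]) take = true;
          else if (rank[cs] == rank[bc] && (cs < bc || (cs == bc && m > bm)))
            take = true;
        } else if (bc == 0 && cost < best + EPS) take = true;
        if (take) { best = cost; bc = cs; bm = m; }
      };
      if (i && j && A[i] == X[j]) consider(C(i - 1, j - 1), 1, 1);
      for (int m = 1; m <= i; ++m) consider(C(i - m, j) + cl[m - 1], 2, m);
      {
        int lim = std::min(i, j);
        for (int m = 1; m <= lim; ++m)
          if (rev_match(A, i, X, j, m, signed_mode))
            consider(C(i - m, j - m) + cr[m - 1], 3, m);
      }
      if (j) {
        for (int m = 1; m <= j; ++m) {
          bool occ = occurs_any(A, X, j - m + 1, m) ||
                     occurs_disjoint(X, j - m + 1, m);
          if (!occ) break;
          consider(C(i, j - m) + cd[m - 1], 4, m);
        }
        if (allow_gain) consider(C(i, j - 1) + cd[0], 5, 1);
      }
      C(i, j) = best; CS(i, j) = bc; MM(i, j) = bm;
    }
  return List::create(_["cost"] = C, _["case"] = CS, _["m"] = MM);
}

// Case ids, siblings (hidden parent P of X and Y):
//  1 match, 2 loss in Y (parent keeps X's block), 3 loss in X,
//  4 reversal in X (parent reads as Y), 5 duplication in X, 6 in Y.
// Priority: match > losses > reversal > duplications.

// [[Rcpp::export(name = ".pair_siblings_dp_cpp")]]
List pair_siblings_dp_cpp(IntegerVector Xv, IntegerVector Yv,
                          NumericVector cd, NumericVector cl,
                          NumericVector cr, bool signed_mode) {
  const int nX = Xv.size(), nY = Yv.size();
  std::vector<int> xbuf(nX + 1), ybuf(nY + 1);
  for (int i = 0; i < nX; ++i) xbuf[i + 1] = Xv[i];
  for (int i = 0; i < nY; ++i) ybuf[i + 1] = Yv[i];
  const Genome X{xbuf.data(), nX}, Y{ybuf.data(), nY};
  NumericMatrix C(nX + 1, nY + 1);
  IntegerMatrix CS(nX + 1, nY + 1), MM(nX + 1, nY + 1);
  std::fill(C.begin(), C.end(), R_PosInf);
  C(0, 0) = 0.0;
  int rank[7] = {0, 0, 1, 1, 2, 3, 3};
  const double EPS = 1e-9;
  for (int k = 0; k <= nY; ++k)
    for (int j = 0; j <= nX; ++j) {
      if (j == 0 && k == 0) continue;
      double best = R_PosInf; int bc = 0, bm = 0;
      auto consider = [&](double cost, int cs, int m) {
        if (!R_finite(cost)) return;
        bool take = false;
        if (cost < best - EPS) take = true;
        else if (cost < best + EPS && bc != 0) {
          if (rank[cs] < rank[bc]) take = true;
          else if (rank[cs] == rank[bc] && (cs < bc || (cs == bc && m > bm)))
            take = true;
        } else if (bc == 0 && cost < best + EPS) take = true;
        if (take) { best = cost; bc = cs; bm = m; }
      };
      if (j && k && X[j] == Y[k]) consider(C(j - 1, k - 1), 1, 1);
      for (int m = 1; m <= j; ++m) consider(C(j - m, k) + cl[m - 1], 2, m);
      for (int m = 1; m <= k; ++m) consider(C(j, k - m) + cl[m - 1], 3, m);
      {
        int lim = std::min(j, k);
        for (int m = 1; m <= lim; ++m)
          if (rev_match(Y, k, X, j, m, signed_mode))
            consider(C(j - m, k - m) + cr[m - 1], 4, m);
      }
      if (j) for (int m = 1; m <= j; ++m) {
        bool occ = occurs_disjoint(X, j - m + 1, m) ||
                   occurs_any(Y, X, j - m + 1, m);
        if (!occ) break;
        consider(C(j - m, k) + cd[m - 1], 5, m);
      }
      if (k) for (int m = 1; m <= k; ++m) {
        bool occ = occurs_disjoint(Y, k - m + 1, m) ||
                   occurs_any(X, Y, k - m + 1, m);
        if (!occ) break;
        consider(C(j, k - m) + cd[m - 1], 6, m);
      }
      C(j, k) = best; CS(j, k) = bc; MM(j, k) = bm;
    }
  return List::create(_["cost"] = C, _["case"] = CS, _["m"] = MM);
}
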