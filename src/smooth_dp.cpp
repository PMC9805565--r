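// Smooth Smith-Waterman / Needleman-Wunsch dynamic programming core.
//
// Three-state affine machine over lattice paths:
//   M(i,j): last move matched x_i with y_j
//   D(i,j): last move consumed x_i unmatched (gap in y)
//   I(i,j): last move consumed y_j unmatched (gap in x)
// Cell (i,j) means i residues of x and j residues of y consumed (1-based in
// the DP; the score matrix is 0-based).  Linear gap mode is the special case
// open == extend.  restrict_turns forbids the D -> I transition so that of
// the two orderings of an adjacent deletion/insertion pair only one
// (insertion first) is counted.
//
// The smooth recursion replaces max with logsumexp on scores scaled by 1/T;
// the returned score is T * log(partition).  The posterior match matrix is
// the exact gradient of the smoothed score with respect to the match scores,
// obtained by a reverse sweep.  For training we additionally need
// Hessian-vector products (the vector-Jacobian product of the posterior):
// these are obtained by running the identical forward+reverse computation on
// dual numbers, seeding the tangent of the scores with the incoming
// cotangent of the posterior.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double NEG = -1e9; // disallowed-state sentinel (finite: keeps gradients defined)

struct Dual {
  double v, t;
  Dual() : v(0.0), t(0.0) {}
  Dual(double v_, double t_ = 0.0) : v(v_), t(t_) {}
};

static inline double val(double x) { return x; }
static inline double val(const Dual& x) { return x.v; }

static inline double add(double a, double b) { return a + b; }
static inline Dual add(const Dual& a, double b) { return Dual(a.v + b, a.t); }
static inline Dual add(const Dual& a, const Dual& b) { return Dual(a.v + b.v, a.t + b.t); }

static inline double mul(double a, double b) { return a * b; }
static inline Dual mul(const Dual& a, const Dual& b) {
  return Dual(a.v * b.v, a.v * b.t + a.t * b.v);
}

// logsumexp over k candidates (shifted-max identity)
static inline double lse(const double* xs, int k) {
  double m = NEG;
  for (int i = 0; i < k; ++i) if (xs[i] > m) m = xs[i];
  if (m <= NEG) return NEG;
  double s = 0.0;
  for (int i = 0; i < k; ++i) s += std::exp(xs[i] - m);
  return m + std::log(s);
}
static inline Dual lse(const Dual* xs, int k) {
  double m = NEG;
  for (int i = 0; i < k; ++i) if (xs[i].v > m) m = xs[i].v;
  if (m <= NEG) return Dual(NEG, 0.0);
  double s = 0.0, st = 0.0;
  for (int i = 0; i < k; ++i) {
    double e = std::exp(xs[i].v - m);
    s += e;
    st += e * xs[i].t;
  }
  return Dual(m + std::log(s), st / s);
}

// softmax weight of candidate x inside a logsumexp with value c
static inline double wgt(double x, double c) { return std::exp(x - c); }
static inline Dual wgt(const Dual& x, const Dual& c) {
  double e = std::exp(x.v - c.v);
  return Dual(e, e * (x.t - c.t));
}

// Forward (and optionally reverse) smooth DP.  s is the n x m matrix of
// match scores already divided by temperature (row-major); go/ge are the
// open/extend penalties divided by temperature.  If P is non-null the
// reverse sweep fills it with the posterior match probabilities (for duals,
// the tangent slot carries the Hessian-vector product).
template <class S>
static S sw_core(int n, int m, const std::vector<S>& s, double go, double ge,
                 bool local, bool restrict_turns, std::vector<S>* P) {
  const int W = m + 1;
  std::vector<S> M((n + 1) * W, S(NEG)), D((n + 1) * W, S(NEG)), I((n + 1) * W, S(NEG));
  const S ZERO = S(0.0);
  S cand[5];

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      if (i >= 1 && j >= 1) {
        int k = 0;
        cand[k++] = M[(i - 1) * W + (j - 1)];
        cand[k++] = I[(i - 1) * W + (j - 1)];
        cand[k++] = D[(i - 1) * W + (j - 1)];
        if (local) cand[k++] = ZERO;               // fresh start at any cell
        else if (i == 1 && j == 1) cand[k++] = ZERO; // global start
        M[i * W + j] = add(lse(cand, k), s[(i - 1) * m + (j - 1)]);
      }
      if (i >= 1) {
        int k = 0;
        cand[k++] = add(M[(i - 1) * W + j], go);
        cand[k++] = add(I[(i - 1) * W + j], go);
        cand[k++] = add(D[(i - 1) * W + j], ge);
        if (!local && i - 1 == 0 && j == 0) cand[k++] = add(ZERO, go); // leading gap
        D[i * W + j] = lse(cand, k);
      }
      if (j >= 1) {
        int k = 0;
        cand[k++] = add(M[i * W + (j - 1)], go);
        cand[k++] = add(I[i * W + (j - 1)], ge);
        if (!restrict_turns) cand[k++] = add(D[i * W + (j - 1)], go);
        if (!local && i == 0 && j - 1 == 0) cand[k++] = add(ZERO, go);
        I[i * W + j] = lse(cand, k);
      }
    }
  }

  S Z;
  if (!local) {
    S fin[3] = { M[n * W + m], I[n * W + m], D[n * W + m] };
    Z = lse(fin, 3);
  } else {
    // logsumexp over the empty path (score 0) and every match-ending cell;
    // folded pairwise, which is exact for logsumexp and stable at these sizes
    S acc = ZERO;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j) {
        S pair[2] = { acc, M[i * W + j] };
        acc = lse(pair, 2);
      }
    Z = acc;
  }

  if (P) {
    std::vector<S> Mb((n + 1) * W, S(0.0)), Db((n + 1) * W, S(0.0)), Ib((n + 1) * W, S(0.0));
    if (!local) {
      Mb[n * W + m] = wgt(M[n * W + m], Z);
      Db[n * W + m] = wgt(D[n * W + m], Z);
      Ib[n * W + m] = wgt(I[n * W + m], Z);
    } else {
      for (int i = 1; i <= n; ++i)
        for (int j = 1; j <= m; ++j)
          Mb[i * W + j] = wgt(M[i * W + j], Z);
    }
    for (int i = n; i >= 0; --i) {
      for (int j = m; j >= 0; --j) {
        if (i == 0 && j == 0) continue;
        if (j >= 1) { // I(i,j)
          const S cb = Ib[i * W + j];
          const S pre = I[i * W + j];
          Mb[i * W + (j - 1)] = add(Mb[i * W + (j - 1)], mul(cb, wgt(add(M[i * W + (j - 1)], go), pre)));
          Ib[i * W + (j - 1)] = add(Ib[i * W + (j - 1)], mul(cb, wgt(add(I[i * W + (j - 1)], ge), pre)));
          if (!restrict_turns)
            Db[i * W + (j - 1)] = add(Db[i * W + (j - 1)], mul(cb, wgt(add(D[i * W + (j - 1)], go), pre)));
        }
        if (i >= 1) { // D(i,j)
          const S cb = Db[i * W + j];
          const S pre = D[i * W + j];
          Mb[(i - 1) * W + j] = add(Mb[(i - 1) * W + j], mul(cb, wgt(add(M[(i - 1) * W + j], go), pre)));
          Ib[(i - 1) * W + j] = add(Ib[(i - 1) * W + j], mul(cb, wgt(add(I[(i - 1) * W + j], go), pre)));
          Db[(i - 1) * W + j] = add(Db[(i - 1) * W + j], mul(cb, wgt(add(D[(i - 1) * W + j], ge), pre)));
        }
        if (i >= 1 && j >= 1) { // M(i,j)
          const S cb = Mb[i * W + j];
          // pre-activation: logsumexp of predecessors = M(i,j) - s(i-1,j-1)
          S preM = add(M[i * W + j], mul(S(-1.0), s[(i - 1) * m + (j - 1)]));
          (*P)[(i - 1) * m + (j - 1)] = cb;
          Mb[(i - 1) * W + (j - 1)] = add(Mb[(i - 1) * W + (j - 1)], mul(cb, wgt(M[(i - 1) * W + (j - 1)], preM)));
          Ib[(i - 1) * W + (j - 1)] = add(Ib[(i - 1) * W + (j - 1)], mul(cb, wgt(I[(i - 1) * W + (j - 1)], preM)));
          Db[(i - 1) * W + (j - 1)] = add(Db[(i - 1) * W + (j - 1)], mul(cb, wgt(D[(i - 1) * W + (j - 1)], preM)));
        }
      }
    }
  }
  return Z;
}

static void check_params(double temp) {
  if (!(temp > 0)) stop("temperature must be positive");
}

// [[Rcpp::export]]
double cpp_sw_score(NumericMatrix a, double temp, double open, double extend,
                    bool local, bool restrict_turns) {
  check_params(temp);
  int n = a.nrow(), m = a.ncol();
  std::vector<double> s(n * m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) s[i * m + j] = a(i, j) / temp;
  double Z = sw_core<double>(n, m, s, open / temp, extend / temp, local,
                             restrict_turns, nullptr);
  return temp * Z;
}

// [[Rcpp::export]]
List cpp_sw_posterior(NumericMatrix a, double temp, double open, double extend,
                      bool local, bool restrict_turns) {
  check_params(temp);
  int n = a.nrow(), m = a.ncol();
  std::vector<double> s(n * m), P(n * m, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) s[i * m + j] = a(i, j) / temp;
  double Z = sw_core<double>(n, m, s, open / temp, extend / temp, local,
                             restrict_turns, &P);
  NumericMatrix Pm(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) Pm(i, j) = P[i * m + j];
  return List::create(_["score"] = temp * Z, _["posterior"] = Pm);
}

// Vector-Jacobian product through the posterior: given the cotangent u of
// the posterior matrix, returns abar with abar = (d posterior / d a)^T u,
// computed as the directional (dual-number) derivative of the gradient in
// direction u.  Also returns the primal score and posterior.
// [[Rcpp::export]]
List cpp_sw_vjp(NumericMatrix a, NumericMatrix u, double temp, double open,
                double extend, bool local, bool restrict_turns) {
  check_params(temp);
  int n = a.nrow(), m = a.ncol();
  if (u.nrow() != n || u.ncol() != m) stop("cotangent shape mismatch");
  std::vector<Dual> s(n * m), P(n * m, Dual(0.0));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      s[i * m + j] = Dual(a(i, j) / temp, u(i, j) / temp);
  Dual Z = sw_core<Dual>(n, m, s, open / temp, extend / temp, local,
                         restrict_turns, &P);
  NumericMatrix Pm(n, m), Ab(n, m);
  // P = dZ/ds with s = a/T and score = T*Z, so dscore/da = dZ/ds = P.
  // The Jacobian of P in a is H_s / T; seeding the tangent with u/T makes
  // the dual run return H_s (u/T) = (dP/da) u directly (H_s is symmetric,
  // so this equals the required vector-Jacobian product).
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      Pm(i, j) = P[i * m + j].v;
      Ab(i, j) = P[i * m + j].t;
    }
  return List::create(_["score"] = temp * Z.v, _["posterior"] = Pm,
                      _["abar"] = Ab);
}

// [[Rcpp::export]]
List cpp_sw_posterior_batch(List as, double temp, double open, double extend,
                            bool local, bool restrict_turns) {
  int B = as.size();
  List out(B);
  for (int k = 0; k < B; ++k) {
    NumericMatrix a = as[k];
    out[k] = cpp_sw_posterior(a, temp, open, extend, local, restrict_turns);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_sw_vjp_batch(List as, List us, double temp, double open,
                      double extend, bool local, bool restrict_turns) {
  int B = as.size();
  List out(B);
  for (int k = 0; k < B; ++k) {
    NumericMatrix a = as[k], u = us[k];
    out[k] = cpp_sw_vjp(a, u, temp, open, extend, local, restrict_turns);
  }
  return out;
}

// Classic max/argmax DP with traceback under the same conventions.
// Tie-break priority everywhere: match > gap-in-x (I) > gap-in-y (D);
// in local mode the best end cell is the first maximum in row-major scan.
// [[Rcpp::export]]
List cpp_sw_hard(NumericMatrix a, double open, double extend, bool local,
                 bool restrict_turns) {
  int n = a.nrow(), m = a.ncol();
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), D((n + 1) * W, NEG), I((n + 1) * W, NEG);
  // predecessor codes: 0 = M, 1 = I, 2 = D, 3 = start/fresh
  std::vector<signed char> pM((n + 1) * W, -1), pD((n + 1) * W, -1), pI((n + 1) * W, -1);

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      if (i >= 1 && j >= 1) {
        double cv[4] = { M[(i - 1) * W + (j - 1)], I[(i - 1) * W + (j - 1)],
                         D[(i - 1) * W + (j - 1)], NEG };
        if (local || (i == 1 && j == 1)) cv[3] = 0.0;
        int best = 0;
        for (int k = 1; k < 4; ++k) if (cv[k] > cv[best]) best = k;
        M[i * W + j] = cv[best] + a(i - 1, j - 1);
        pM[i * W + j] = (signed char)best;
      }
      if (i >= 1) {
        double cv[4] = { M[(i - 1) * W + j] + open, I[(i - 1) * W + j] + open,
                         D[(i - 1) * W + j] + extend, NEG };
        if (!local && i - 1 == 0 && j == 0) cv[3] = open;
        int best = 0;
        for (int k = 1; k < 4; ++k) if (cv[k] > cv[best]) best = k;
        D[i * W + j] = cv[best];
        pD[i * W + j] = (signed char)best;
      }
      if (j >= 1) {
        double cv[4] = { M[i * W + (j - 1)] + open, I[i * W + (j - 1)] + extend,
                         restrict_turns ? NEG : D[i * W + (j - 1)] + open, NEG };
        if (!local && i == 0 && j - 1 == 0) cv[3] = open;
        int best = 0;
        for (int k = 1; k < 4; ++k) if (cv[k] > cv[best]) best = k;
        I[i * W + j] = cv[best];
        pI[i * W + j] = (signed char)best;
      }
    }
  }

  double score;
  int ci, cj, cs; // current cell and state (0 = M, 1 = I, 2 = D)
  bool have_path = true;
  if (!local) {
    double fv[3] = { M[n * W + m], I[n * W + m], D[n * W + m] };
    int best = 0;
    for (int k = 1; k < 3; ++k) if (fv[k] > fv[best]) best = k;
    score = fv[best];
    ci = n; cj = m; cs = best;
  } else {
    score = 0.0;
    ci = -1; cj = -1; cs = 0;
    for (int i = 1; i <= n; ++i)
      for (int j = 1; j <= m; ++j)
        if (M[i * W + j] > score) { score = M[i * W + j]; ci = i; cj = j; }
    if (ci < 0) have_path = false; // empty local alignment
  }

  std::vector<int> mi, mj;
  while (have_path) {
    signed char pred;
    if (cs == 0) {
      mi.push_back(ci - 1); mj.push_back(cj - 1);
      pred = pM[ci * W + cj]; ci -= 1; cj -= 1;
    } else if (cs == 1) {
      pred = pI[ci * W + cj]; cj -= 1;
    } else {
      pred = pD[ci * W + cj]; ci -= 1;
    }
    if (pred == 3) break;
    cs = pred;
    if (ci == 0 && cj == 0) break;
  }

  int k = (int)mi.size();
  IntegerMatrix path(k, 2);
  for (int t = 0; t < k; ++t) { // reverse to increasing order
    path(t, 0) = mi[k - 1 - t];
    path(t, 1) = mj[k - 1 - t];
  }
  return List::create(_["score"] = score, _["path"] = path);
}
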