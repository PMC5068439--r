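// Likelihood engine: Felsenstein pruning over compressed site patterns with
// per-pattern rescaling, discrete-gamma + invariant-site rate mixture,
// branch-length optimization by Brent search along an Euler tour, and a
// Metropolis-Hastings sampler over (topology, branch lengths, model).
//
// States are 0-based; nucleotides A,C,G,T; amino acids alphabetical.
// Trees are parent arrays (tips first, then internal nodes); the root has
// parent -1 and 2 or 3 children.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double BL_MIN = 1e-8;
static const double BL_MAX = 10.0;
static const double SCALE_LO = 1e-220;
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// symmetric Jacobi eigendecomposition (small matrices, n <= 20)
static void jacobi_eigen(int n, std::vector<double> a,
                         std::vector<double> &V, std::vector<double> &d) {
  V.assign(n * n, 0.0);
  for (int i = 0; i < n; i++) V[i * n + i] = 1.0;
  for (int sweep = 0; sweep < 100; sweep++) {
    double off = 0.0;
    for (int p = 0; p < n - 1; p++)
      for (int q = p + 1; q < n; q++) off += std::fabs(a[p * n + q]);
    if (off < 1e-13) break;
    for (int p = 0; p < n - 1; p++) {
      for (int q = p + 1; q < n; q++) {
        double apq = a[p * n + q];
        if (std::fabs(apq) < 1e-300) continue;
        double app = a[p * n + p], aqq = a[q * n + q];
        double theta = 0.5 * (aqq - app) / apq;
        double t = (theta >= 0 ? 1.0 : -1.0) /
                   (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < n; k++) {
          double akp = a[k * n + p], akq = a[k * n + q];
          a[k * n + p] = c * akp - s * akq;
          a[k * n + q] = s * akp + c * akq;
        }
        for (int k = 0; k < n; k++) {
          double apk = a[p * n + k], aqk = a[q * n + k];
          a[p * n + k] = c * apk - s * aqk;
          a[q * n + k] = s * apk + c * aqk;
        }
        for (int k = 0; k < n; k++) {
          double vkp = V[k * n + p], vkq = V[k * n + q];
          V[k * n + p] = c * vkp - s * vkq;
          V[k * n + q] = s * vkp + c * vkq;
        }
      }
    }
  }
  d.resize(n);
  for (int i = 0; i < n; i++) d[i] = a[i * n + i];
}

// mean rates of the k equal-probability bins of a gamma(shape, rate=shape)
static void disc_gamma(double alpha, int k, std::vector<double> &r) {
  r.assign(k, 1.0);
  if (k == 1) return;
  std::vector<double> q(k + 1);
  for (int i = 1; i < k; i++)
    q[i] = R::qgamma((double)i / k, alpha, 1.0 / alpha, 1, 0);
  double prev = 0.0;
  for (int i = 0; i < k; i++) {
    double hi = (i == k - 1) ? 1.0
                : R::pgamma(q[i + 1], alpha + 1.0, 1.0 / alpha, 1, 0);
    r[i] = (double)k * (hi - prev);
    prev = hi;
  }
}

// dst[p,s] (*)= sum_j P[s,j] child[p,j]   -- the pruning kernel
template <int NS>
static void kmul_t(double *dst, const double *child, const double *P,
                   int npat, bool first) {
  for (int p = 0; p < npat; p++) {
    const double *x = child + (size_t)p * NS;
    double *d = dst + (size_t)p * NS;
    for (int s = 0; s < NS; s++) {
      const double *Pr = P + s * NS;
      double acc = 0.0;
      for (int j = 0; j < NS; j++) acc += Pr[j] * x[j];
      if (first) d[s] = acc; else d[s] *= acc;
    }
  }
}

// fully unrolled 4-state kernel (dominant cost of nucleotide analyses)
static void kmul4(double *dst, const double *child, const double *P,
                  int npat, bool first) {
  const double p00 = P[0], p01 = P[1], p02 = P[2], p03 = P[3];
  const double p10 = P[4], p11 = P[5], p12 = P[6], p13 = P[7];
  const double p20 = P[8], p21 = P[9], p22 = P[10], p23 = P[11];
  const double p30 = P[12], p31 = P[13], p32 = P[14], p33 = P[15];
  if (first) {
    for (int p = 0; p < npat; p++) {
      const double *x = child + 4 * (size_t)p;
      double *d = dst + 4 * (size_t)p;
      const double x0 = x[0], x1 = x[1], x2 = x[2], x3 = x[3];
      d[0] = p00 * x0 + p01 * x1 + p02 * x2 + p03 * x3;
      d[1] = p10 * x0 + p11 * x1 + p12 * x2 + p13 * x3;
      d[2] = p20 * x0 + p21 * x1 + p22 * x2 + p23 * x3;
      d[3] = p30 * x0 + p31 * x1 + p32 * x2 + p33 * x3;
    }
  } else {
    for (int p = 0; p < npat; p++) {
      const double *x = child + 4 * (size_t)p;
      double *d = dst + 4 * (size_t)p;
      const double x0 = x[0], x1 = x[1], x2 = x[2], x3 = x[3];
      d[0] *= p00 * x0 + p01 * x1 + p02 * x2 + p03 * x3;
      d[1] *= p10 * x0 + p11 * x1 + p12 * x2 + p13 * x3;
      d[2] *= p20 * x0 + p21 * x1 + p22 * x2 + p23 * x3;
      d[3] *= p30 * x0 + p31 * x1 + p32 * x2 + p33 * x3;
    }
  }
}

static void kmul(double *dst, const double *child, const double *P, int ns,
                 int npat, bool first) {
  if (ns == 4) kmul4(dst, child, P, npat, first);
  else if (ns == 20) kmul_t<20>(dst, child, P, npat, first);
  else {
    for (int p = 0; p < npat; p++) {
      const double *x = child + (size_t)p * ns;
      double *d = dst + (size_t)p * ns;
      for (int s = 0; s < ns; s++) {
        const double *Pr = P + s * ns;
        double acc = 0.0;
        for (int j = 0; j < ns; j++) acc += Pr[j] * x[j];
        if (first) d[s] = acc; else d[s] *= acc;
      }
    }
  }
}

// ---------------------------------------------------------------------------
struct Model {
  int ns = 4, ncat = 4;
  double alpha = 1.0, pinv = 0.0;
  std::vector<double> pi, exch;      // exch: ns x ns symmetric
  std::vector<double> U, Uinv, lam;  // Q = U diag(lam) Uinv, rate-normalized
  std::vector<double> catRate, catW;

  void build() {
    int n = ns;
    std::vector<double> Q(n * n, 0.0);
    for (int i = 0; i < n; i++)
      for (int j = 0; j < n; j++)
        if (i != j) Q[i * n + j] = exch[i * n + j] * pi[j];
    double mu = 0.0;
    for (int i = 0; i < n; i++) {
      double rs = 0.0;
      for (int j = 0; j < n; j++)
        if (j != i) rs += Q[i * n + j];
      Q[i * n + i] = -rs;
      mu += pi[i] * rs;
    }
    if (mu <= 0) stop("degenerate rate matrix");
    std::vector<double> S(n * n);
    for (int i = 0; i < n; i++)
      for (int j = 0; j < n; j++)
        S[i * n + j] = Q[i * n + j] / mu * std::sqrt(pi[i] / pi[j]);
    for (int i = 0; i < n; i++)
      for (int j = i + 1; j < n; j++) {
        double m = 0.5 * (S[i * n + j] + S[j * n + i]);
        S[i * n + j] = S[j * n + i] = m;
      }
    std::vector<double> V;
    jacobi_eigen(n, S, V, lam);
    U.assign(n * n, 0.0);
    Uinv.assign(n * n, 0.0);
    for (int i = 0; i < n; i++)
      for (int k = 0; k < n; k++) {
        U[i * n + k] = V[i * n + k] / std::sqrt(pi[i]);
        Uinv[k * n + i] = V[i * n + k] * std::sqrt(pi[i]);
      }
    disc_gamma(alpha, ncat, catRate);
    catW.assign(ncat, 1.0 / ncat);
    double vs = 1.0 - pinv;
    if (vs <= 0) stop("p_inv must be < 1");
    for (int c = 0; c < ncat; c++) catRate[c] /= vs;
  }

  void pmat(double t, double rate, double *P) const {
    int n = ns;
    double ew[20];
    for (int k = 0; k < n; k++) ew[k] = std::exp(lam[k] * rate * t);
    for (int i = 0; i < n; i++)
      for (int j = 0; j < n; j++) {
        double s = 0.0;
        for (int k = 0; k < n; k++)
          s += U[i * n + k] * ew[k] * Uinv[k * n + j];
        P[i * n + j] = s > 0 ? s : 0.0;
      }
  }
};

// ---------------------------------------------------------------------------
struct Engine {
  int ns = 4, npat = 0, ntip = 0, nnode = 0, root = -1;
  std::vector<double> w;
  std::vector<double> tipPart;   // ntip * npat * ns
  std::vector<int> constOK;      // npat * ns
  std::vector<double> constC;    // npat
  Model mod;

  std::vector<int> parent;
  std::vector<std::vector<int> > children;
  std::vector<double> blen;
  std::vector<int> post;         // internal nodes, postorder

  std::vector<std::vector<double> > part;  // per internal node
  std::vector<double> slog;      // nint * npat (per-node log scale)
  std::vector<double> stot;      // npat (sum of slog over nodes)
  std::vector<double> ssum;      // nint * npat (subtree scale sums)
  std::vector<double> scratch;   // npat * ns work area

  // snapshot state for MCMC reject restoration (O(1) buffer swaps)
  std::vector<int> snapNodes;
  std::vector<std::vector<double> > snapPart, pool;
  std::vector<double> snapSlog, snapStot;

  int nint() const { return nnode - ntip; }
  int ii(int v) const { return v - ntip; }
  size_t blk() const { return (size_t)mod.ncat * npat * ns; }
  double *partOf(int v, int cat) {
    return &part[ii(v)][(size_t)cat * npat * ns];
  }
  const double *tipOf(int v) const {
    return &tipPart[(size_t)v * npat * ns];
  }

  void setTree(const IntegerVector &par, const NumericVector &bl) {
    nnode = par.size();
    parent.assign(par.begin(), par.end());
    blen.assign(bl.begin(), bl.end());
    children.assign(nnode, std::vector<int>());
    root = -1;
    for (int v = 0; v < nnode; v++) {
      if (parent[v] < 0) root = v;
      else children[parent[v]].push_back(v);
    }
    if (root < ntip) stop("root must be an internal node");
    computePost();
    part.assign(nint(), std::vector<double>());
    for (int i = 0; i < nint(); i++) part[i].assign(blk(), 0.0);
    pool.clear();
    slog.assign((size_t)nint() * npat, 0.0);
    stot.assign(npat, 0.0);
    ssum.assign((size_t)nint() * npat, 0.0);
    scratch.assign((size_t)npat * ns, 0.0);
  }

  // postorder over internal nodes; must be refreshed after any topology
  // change (NNI moves in the sampler)
  void computePost() {
    post.clear();
    std::vector<int> stack, order;
    stack.push_back(root);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      order.push_back(v);
      for (int c : children[v])
        if (c >= ntip) stack.push_back(c);
    }
    for (int i = (int)order.size() - 1; i >= 0; i--)
      post.push_back(order[i]);
  }

  void setModel(const NumericMatrix &exch, const NumericVector &pi,
                double alpha, double pinv, int ncat) {
    mod.ns = ns;
    mod.ncat = ncat;
    mod.alpha = alpha;
    mod.pinv = pinv;
    mod.exch.assign(exch.begin(), exch.end());
    mod.pi.assign(pi.begin(), pi.end());
    mod.build();
    refreshConst();
    if (nnode > 0) {
      part.assign(nint(), std::vector<double>());
      for (int i = 0; i < nint(); i++) part[i].assign(blk(), 0.0);
      pool.clear();
      slog.assign((size_t)nint() * npat, 0.0);
      stot.assign(npat, 0.0);
    }
  }

  void refreshConst() {
    constC.assign(npat, 0.0);
    for (int p = 0; p < npat; p++) {
      double s = 0.0;
      for (int k = 0; k < ns; k++)
        if (constOK[(size_t)p * ns + k]) s += mod.pi[k];
      constC[p] = s;
    }
  }

  void updateNode(int v) {
    int nc = mod.ncat;
    std::vector<double> P(ns * ns);
    int nch = children[v].size();
    for (int ci = 0; ci < nch; ci++) {
      int ch = children[v][ci];
      double t = std::max(blen[ch], 0.0);
      bool tip = ch < ntip;
      for (int c = 0; c < nc; c++) {
        mod.pmat(t, mod.catRate[c], &P[0]);
        kmul(partOf(v, c), tip ? tipOf(ch) : partOf(ch, c), &P[0], ns,
             npat, ci == 0);
      }
    }
    // conditional per-pattern rescale (needed only for deep trees)
    double *sl = &slog[(size_t)ii(v) * npat];
    for (int p = 0; p < npat; p++) {
      double m = 0.0;
      for (int c = 0; c < nc; c++) {
        const double *d = partOf(v, c) + (size_t)p * ns;
        for (int s = 0; s < ns; s++)
          if (d[s] > m) m = d[s];
      }
      double nsl = 0.0;
      if (m > 0.0 && m < SCALE_LO) {
        double inv = 1.0 / m;
        for (int c = 0; c < nc; c++) {
          double *d = partOf(v, c) + (size_t)p * ns;
          for (int s = 0; s < ns; s++) d[s] *= inv;
        }
        nsl = std::log(m);
      }
      if (nsl != sl[p]) {
        stot[p] += nsl - sl[p];
        sl[p] = nsl;
      }
    }
  }

  void fullUpdate() {
    for (int v : post) updateNode(v);
  }

  void updatePathFrom(int v) {
    while (v >= 0) {
      updateNode(v);
      v = parent[v];
    }
  }

  void computeSsum() {
    for (int v : post) {
      double *dst = &ssum[(size_t)ii(v) * npat];
      const double *sl = &slog[(size_t)ii(v) * npat];
      std::memcpy(dst, sl, sizeof(double) * npat);
      for (int c : children[v])
        if (c >= ntip) {
          const double *cs = &ssum[(size_t)ii(c) * npat];
          for (int p = 0; p < npat; p++) dst[p] += cs[p];
        }
    }
  }

  static double logadd(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    double m = std::max(a, b);
    return m + std::log(std::exp(a - m) + std::exp(b - m));
  }

  double loglikRoot() {
    int nc = mod.ncat;
    double pinv = mod.pinv;
    double ll = 0.0;
    bool scaled = false;
    for (int p = 0; p < npat; p++)
      if (stot[p] != 0.0) { scaled = true; break; }
    for (int p = 0; p < npat; p++) {
      double A = 0.0;
      for (int c = 0; c < nc; c++) {
        const double *d = partOf(root, c) + (size_t)p * ns;
        double lc = 0.0;
        for (int s = 0; s < ns; s++) lc += mod.pi[s] * d[s];
        A += mod.catW[c] * lc;
      }
      A *= (1.0 - pinv);
      double lp;
      if (!scaled || stot[p] == 0.0) {
        double tot = A + (pinv > 0 ? pinv * constC[p] : 0.0);
        lp = tot > 0 ? std::log(tot) : NEG_INF;
      } else {
        double lv = (A > 0) ? std::log(A) + stot[p] : NEG_INF;
        lp = lv;
        if (pinv > 0 && constC[p] > 0)
          lp = logadd(lv, std::log(pinv * constC[p]));
      }
      if (lp == NEG_INF) return NEG_INF;
      ll += w[p] * lp;
    }
    return ll;
  }

  double loglikFull() {
    fullUpdate();
    return loglikRoot();
  }

  // snapshot / restore of partials along a node path (reject handling);
  // node buffers are swapped out in O(1), updateNode rewrites them fully
  void snapshot(const std::vector<int> &nodes) {
    snapNodes = nodes;
    snapPart.resize(nodes.size());
    snapSlog.resize(nodes.size() * (size_t)npat);
    snapStot.assign(stot.begin(), stot.end());
    for (size_t i = 0; i < nodes.size(); i++) {
      int id = ii(nodes[i]);
      snapPart[i] = std::move(part[id]);
      if (pool.empty()) part[id].assign(blk(), 0.0);
      else {
        part[id] = std::move(pool.back());
        pool.pop_back();
      }
      std::memcpy(&snapSlog[i * (size_t)npat],
                  &slog[(size_t)id * npat], sizeof(double) * npat);
    }
  }
  void commit() {
    for (size_t i = 0; i < snapNodes.size(); i++)
      pool.push_back(std::move(snapPart[i]));
    snapNodes.clear();
  }
  void restore() {
    for (size_t i = 0; i < snapNodes.size(); i++) {
      int id = ii(snapNodes[i]);
      pool.push_back(std::move(part[id]));
      part[id] = std::move(snapPart[i]);
      std::memcpy(&slog[(size_t)id * npat], &snapSlog[i * (size_t)npat],
                  sizeof(double) * npat);
    }
    stot.assign(snapStot.begin(), snapStot.end());
    snapNodes.clear();
  }

  // likelihood of the whole tree expressed at the edge above v
  double edgeLoglik(double t, const std::vector<double> &OUT,
                    const std::vector<double> &oslog, int v) {
    int nc = mod.ncat;
    double pinv = mod.pinv;
    std::vector<double> P(ns * ns);
    std::vector<double> A(npat, 0.0);
    for (int c = 0; c < nc; c++) {
      mod.pmat(t, mod.catRate[c], &P[0]);
      const double *d0 = (v < ntip) ? tipOf(v) : partOf(v, c);
      kmul(&scratch[0], d0, &P[0], ns, npat, true);
      const double *o = &OUT[(size_t)c * npat * ns];
      double cw = mod.catW[c];
      for (int p = 0; p < npat; p++) {
        const double *op = o + (size_t)p * ns;
        const double *sp = &scratch[(size_t)p * ns];
        double lc = 0.0;
        for (int s = 0; s < ns; s++) lc += op[s] * sp[s];
        A[p] += cw * lc;
      }
    }
    const double *sub = (v >= ntip) ? &ssum[(size_t)ii(v) * npat] : NULL;
    double ll = 0.0;
    double om = 1.0 - pinv;
    for (int p = 0; p < npat; p++) {
      double a = om * A[p];
      double S = oslog[p] + (sub ? sub[p] : 0.0);
      double lp;
      if (S == 0.0) {
        double tot = a + (pinv > 0 ? pinv * constC[p] : 0.0);
        lp = tot > 0 ? std::log(tot) : NEG_INF;
      } else {
        double lv = (a > 0) ? std::log(a) + S : NEG_INF;
        lp = lv;
        if (pinv > 0 && constC[p] > 0)
          lp = logadd(lv, std::log(pinv * constC[p]));
      }
      if (lp == NEG_INF) return NEG_INF;
      ll += w[p] * lp;
    }
    return ll;
  }

  // Brent maximization of edgeLoglik over log(t)
  double optimizeEdge(int v, const std::vector<double> &OUT,
                      const std::vector<double> &oslog) {
    const double lo = std::log(BL_MIN), hi = std::log(BL_MAX);
    double x0 = std::log(std::min(std::max(blen[v], BL_MIN), BL_MAX));
    double f0 = edgeLoglik(std::exp(x0), OUT, oslog, v);
    double fstart = f0;
    double step = 1.0;
    double a = std::max(lo, x0 - step), b = std::min(hi, x0 + step);
    double fa = edgeLoglik(std::exp(a), OUT, oslog, v);
    double fb = edgeLoglik(std::exp(b), OUT, oslog, v);
    int guard = 0;
    while (fa > f0 && a > lo && guard++ < 20) {
      b = x0; fb = f0; x0 = a; f0 = fa;
      a = std::max(lo, a - step);
      fa = edgeLoglik(std::exp(a), OUT, oslog, v);
    }
    guard = 0;
    while (fb > f0 && b < hi && guard++ < 20) {
      a = x0; fa = f0; x0 = b; f0 = fb;
      b = std::min(hi, b + step);
      fb = edgeLoglik(std::exp(b), OUT, oslog, v);
    }
    const double gold = 0.3819660112501051, xtol = 2e-4;
    double x = x0, ww = x0, vv = x0;
    double fx = f0, fw = f0, fv = f0;
    double d = 0.0, e = 0.0;
    for (int it = 0; it < 30; it++) {
      double xm = 0.5 * (a + b);
      double tol1 = xtol, tol2 = 2.0 * tol1;
      if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
      bool golden = true;
      if (std::fabs(e) > tol1) {
        double r = (x - ww) * (fx - fv);
        double q = (x - vv) * (fx - fw);
        double p = (x - vv) * q - (x - ww) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) p = -p;
        q = std::fabs(q);
        double etmp = e;
        e = d;
        if (std::fabs(p) < std::fabs(0.5 * q * etmp) && p > q * (a - x) &&
            p < q * (b - x)) {
          d = p / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2) d = (xm > x) ? tol1 : -tol1;
          golden = false;
        }
      }
      if (golden) {
        e = (x >= xm) ? a - x : b - x;
        d = gold * e;
      }
      double u = (std::fabs(d) >= tol1) ? x + d
                 : x + ((d > 0) ? tol1 : -tol1);
      double fu = edgeLoglik(std::exp(u), OUT, oslog, v);
      if (fu >= fx) {
        if (u >= x) a = x; else b = x;
        vv = ww; fv = fw; ww = x; fw = fx; x = u; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu >= fw || ww == x) { vv = ww; fv = fw; ww = u; fw = fu; }
        else if (fu >= fv || vv == x || vv == ww) { vv = u; fv = fu; }
      }
    }
    if (fx >= fstart) {
      blen[v] = std::exp(x);
      return fx;
    }
    return fstart;
  }

  // Euler-tour sweep: optimize flagged edges; skip flag-free subtrees
  void sweepRec(int u, std::vector<double> &IN, std::vector<double> &inS,
                const std::vector<bool> &opt,
                const std::vector<bool> &hasFlag) {
    int nc = mod.ncat;
    size_t sz = blk();
    std::vector<double> P(ns * ns);
    for (size_t ci = 0; ci < children[u].size(); ci++) {
      int v = children[u][ci];
      if (!hasFlag[v]) continue;
      std::vector<double> OUT(IN);
      std::vector<double> oslog(inS);
      for (size_t cj = 0; cj < children[u].size(); cj++) {
        if (cj == ci) continue;
        int s2 = children[u][cj];
        double t = std::max(blen[s2], 0.0);
        for (int c = 0; c < nc; c++) {
          mod.pmat(t, mod.catRate[c], &P[0]);
          kmul(&OUT[(size_t)c * npat * ns],
               (s2 < ntip) ? tipOf(s2) : partOf(s2, c), &P[0], ns, npat,
               false);
        }
        if (s2 >= ntip) {
          const double *cs = &ssum[(size_t)ii(s2) * npat];
          for (int p = 0; p < npat; p++) oslog[p] += cs[p];
        }
      }
      // conditional rescale of OUT
      for (int p = 0; p < npat; p++) {
        double m = 0.0;
        for (int c = 0; c < nc; c++) {
          const double *op = &OUT[((size_t)c * npat + p) * ns];
          for (int s = 0; s < ns; s++)
            if (op[s] > m) m = op[s];
        }
        if (m > 0 && m < SCALE_LO) {
          double inv = 1.0 / m;
          for (int c = 0; c < nc; c++) {
            double *op = &OUT[((size_t)c * npat + p) * ns];
            for (int s = 0; s < ns; s++) op[s] *= inv;
          }
          oslog[p] += std::log(m);
        }
      }
      if (opt[v]) optimizeEdge(v, OUT, oslog);
      if (v >= ntip) {
        std::vector<double> INv(sz);
        double t = std::max(blen[v], 0.0);
        for (int c = 0; c < nc; c++) {
          mod.pmat(t, mod.catRate[c], &P[0]);
          const double *Pc = &P[0];
          const double *o = &OUT[(size_t)c * npat * ns];
          double *iv = &INv[(size_t)c * npat * ns];
          for (int p = 0; p < npat; p++) {
            const double *op = o + (size_t)p * ns;
            double *ip = iv + (size_t)p * ns;
            for (int s2 = 0; s2 < ns; s2++) {
              double acc = 0.0;
              for (int s = 0; s < ns; s++) acc += op[s] * Pc[s * ns + s2];
              ip[s2] = acc;
            }
          }
        }
        sweepRec(v, INv, oslog, opt, hasFlag);
        updateNode(v);
        double *dst = &ssum[(size_t)ii(v) * npat];
        const double *sl = &slog[(size_t)ii(v) * npat];
        std::memcpy(dst, sl, sizeof(double) * npat);
        for (int c2 : children[v])
          if (c2 >= ntip) {
            const double *cs = &ssum[(size_t)ii(c2) * npat];
            for (int p = 0; p < npat; p++) dst[p] += cs[p];
          }
      }
    }
  }

  double optimizeEdges(double tol, int maxSweeps,
                       const std::vector<bool> &opt) {
    std::vector<bool> hasFlag(nnode, false);
    for (int v = 0; v < nnode; v++) hasFlag[v] = opt[v];
    for (int v : post)
      for (int c : children[v])
        if (hasFlag[c]) hasFlag[v] = true;
    hasFlag[root] = true;
    double prev = loglikFull();
    for (int it = 0; it < maxSweeps; it++) {
      computeSsum();
      std::vector<double> IN(blk());
      for (int c = 0; c < mod.ncat; c++)
        for (int p = 0; p < npat; p++)
          for (int s = 0; s < ns; s++)
            IN[((size_t)c * npat + p) * ns + s] = mod.pi[s];
      std::vector<double> inS(npat, 0.0);
      sweepRec(root, IN, inS, opt, hasFlag);
      updateNode(root);
      double cur = loglikRoot();
      if (cur < prev - 1e-6) cur = loglikFull();
      if (cur - prev < tol) {
        prev = std::max(cur, prev);
        break;
      }
      prev = cur;
    }
    return prev;
  }
};

// ---------------------------------------------------------------------------
// exported interface

// [[Rcpp::export]]
SEXP cpp_engine_new(List tipPartials, NumericVector weights,
                    IntegerMatrix constOK, int ncat) {
  Engine *e = new Engine();
  e->ntip = tipPartials.size();
  NumericMatrix m0 = tipPartials[0];
  e->ns = m0.nrow();
  e->npat = m0.ncol();
  e->w.assign(weights.begin(), weights.end());
  e->tipPart.assign((size_t)e->ntip * e->npat * e->ns, 0.0);
  for (int i = 0; i < e->ntip; i++) {
    NumericMatrix m = tipPartials[i];
    for (int p = 0; p < e->npat; p++)
      for (int s = 0; s < e->ns; s++)
        e->tipPart[((size_t)i * e->npat + p) * e->ns + s] = m(s, p);
  }
  e->constOK.assign((size_t)e->npat * e->ns, 0);
  for (int p = 0; p < e->npat; p++)
    for (int s = 0; s < e->ns; s++)
      e->constOK[(size_t)p * e->ns + s] = constOK(s, p);
  e->mod.ncat = ncat;
  XPtr<Engine> ptr(e, true);
  return ptr;
}

// [[Rcpp::export]]
void cpp_engine_set_model(SEXP eng, NumericMatrix exch, NumericVector pi,
                          double alpha, double pinv, int ncat) {
  XPtr<Engine> e(eng);
  e->setModel(exch, pi, alpha, pinv, ncat);
}

// [[Rcpp::export]]
void cpp_engine_set_tree(SEXP eng, IntegerVector parent,
                         NumericVector blen) {
  XPtr<Engine> e(eng);
  e->setTree(parent, blen);
}

// [[Rcpp::export]]
double cpp_engine_loglik(SEXP eng) {
  XPtr<Engine> e(eng);
  return e->loglikFull();
}

// [[Rcpp::export]]
List cpp_engine_optimize_edges(SEXP eng, double tol, int maxSweeps,
                               IntegerVector optNodes) {
  XPtr<Engine> e(eng);
  std::vector<bool> opt(e->nnode, optNodes.size() == 0);
  for (int i = 0; i < optNodes.size(); i++) opt[optNodes[i]] = true;
  opt[e->root] = false;
  double ll = e->optimizeEdges(tol, maxSweeps, opt);
  return List::create(_["loglik"] = ll,
                      _["blen"] = NumericVector(e->blen.begin(),
                                                e->blen.end()));
}

// [[Rcpp::export]]
NumericVector cpp_engine_get_blen(SEXP eng) {
  XPtr<Engine> e(eng);
  return NumericVector(e->blen.begin(), e->blen.end());
}

// [[Rcpp::export]]
NumericMatrix cpp_transition_matrix(NumericMatrix exch, NumericVector pi,
                                    double t, double rate) {
  Model m;
  m.ns = pi.size();
  m.ncat = 1;
  m.alpha = 1.0;
  m.pinv = 0.0;
  m.exch.assign(exch.begin(), exch.end());
  m.pi.assign(pi.begin(), pi.end());
  m.build();
  NumericMatrix P(m.ns, m.ns);
  std::vector<double> buf(m.ns * m.ns);
  m.pmat(t, rate, &buf[0]);
  for (int i = 0; i < m.ns; i++)
    for (int j = 0; j < m.ns; j++) P(i, j) = buf[i * m.ns + j];
  return P;
}

// [[Rcpp::export]]
NumericVector cpp_disc_gamma(double alpha, int k) {
  std::vector<double> r;
  disc_gamma(alpha, k, r);
  return NumericVector(r.begin(), r.end());
}

// ML pairwise distances from pair count tables (one Brent search per pair)
// [[Rcpp::export]]
NumericVector cpp_pair_ml_distances(NumericMatrix tabs, NumericMatrix exch,
                                    NumericVector pi, double alpha,
                                    int ncat, double pinv) {
  Model m;
  m.ns = pi.size();
  m.ncat = ncat;
  m.alpha = alpha;
  m.pinv = pinv;
  m.exch.assign(exch.begin(), exch.end());
  m.pi.assign(pi.begin(), pi.end());
  m.build();
  int n = m.ns, npair = tabs.nrow();
  std::vector<double> P(n * n), M(n * n);
  auto pll = [&](const double *tab, double t) {
    std::fill(M.begin(), M.end(), 0.0);
    for (int c = 0; c < m.ncat; c++) {
      m.pmat(t, m.catRate[c], &P[0]);
      double cw = (1.0 - m.pinv) * m.catW[c];
      for (int k = 0; k < n * n; k++) M[k] += cw * P[k];
    }
    double ll = 0.0;
    for (int i = 0; i < n; i++)
      for (int j = 0; j < n; j++) {
        double cnt = tab[i * n + j];
        if (cnt <= 0) continue;
        double L = m.pi[i] * M[i * n + j];
        if (i == j) L += m.pinv * m.pi[i];
        ll += cnt * std::log(std::max(L, 1e-300));
      }
    return ll;
  };
  NumericVector out(npair);
  std::vector<double> trow(n * n);
  for (int pr = 0; pr < npair; pr++) {
    for (int k = 0; k < n * n; k++) trow[k] = tabs(pr, k);
    // golden-section on log t
    double lo = std::log(1e-6), hi = std::log(10.0);
    double a = lo, b = hi;
    const double gr = 0.6180339887498949;
    double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
    double f1 = pll(&trow[0], std::exp(c1)), f2 = pll(&trow[0],
                                                      std::exp(c2));
    for (int it = 0; it < 60 && (b - a) > 1e-6; it++) {
      if (f1 >= f2) {
        b = c2; c2 = c1; f2 = f1;
        c1 = b - gr * (b - a);
        f1 = pll(&trow[0], std::exp(c1));
      } else {
        a = c1; c1 = c2; f1 = f2;
        c2 = a + gr * (b - a);
        f2 = pll(&trow[0], std::exp(c2));
      }
    }
    out[pr] = std::exp(0.5 * (a + b));
  }
  return out;
}

// ---------------------------------------------------------------------------
// Metropolis-Hastings sampler

struct DirProposal {
  static double draw(const std::vector<double> &x, double conc,
                     std::vector<double> &xn) {
    int n = x.size();
    xn.resize(n);
    double s = 0.0;
    for (int i = 0; i < n; i++) {
      xn[i] = R::rgamma(conc * x[i], 1.0);
      if (xn[i] < 1e-12) xn[i] = 1e-12;
      s += xn[i];
    }
    for (int i = 0; i < n; i++) xn[i] /= s;
    return logdens(xn, x, conc);
  }
  static double logdens(const std::vector<double> &to,
                        const std::vector<double> &from, double conc) {
    int n = from.size();
    double ld = R::lgammafn(conc);
    for (int i = 0; i < n; i++) {
      ld -= R::lgammafn(conc * from[i]);
      ld += (conc * from[i] - 1.0) * std::log(to[i]);
    }
    return ld;
  }
};

// [[Rcpp::export]]
List cpp_engine_mcmc(SEXP eng, int nGen, int sampleEvery,
                     NumericVector propWeights, List ctrl) {
  XPtr<Engine> e(eng);
  Engine &E = *e;
  bool priorOnly = as<bool>(ctrl["prior_only"]);
  bool sAlpha = as<bool>(ctrl["sample_alpha"]);
  bool sPinv = as<bool>(ctrl["sample_pinv"]);
  bool sFreq = as<bool>(ctrl["sample_freqs"]);
  bool sExch = as<bool>(ctrl["sample_exch"]);
  double blMean = as<double>(ctrl["branch_prior_mean"]);
  double blRate = 1.0 / blMean;
  double dirConc = as<double>(ctrl["dirichlet_conc"]);

  std::vector<int> modMoves;
  if (sAlpha) modMoves.push_back(0);
  if (sPinv) modMoves.push_back(1);
  if (sFreq) modMoves.push_back(2);
  if (sExch) modMoves.push_back(3);

  double wNNI = propWeights[0], wBL = propWeights[1], wMod = propWeights[2];
  if (modMoves.empty()) { wBL += wMod; wMod = 0.0; }

  std::vector<int> nedges;
  for (int v = E.ntip; v < E.nnode; v++)
    if (v != E.root) nedges.push_back(v);
  if (nedges.empty()) { wBL += wNNI; wNNI = 0.0; }
  std::vector<int> allEdges;
  for (int v = 0; v < E.nnode; v++)
    if (v != E.root) allEdges.push_back(v);
  double wTot = wNNI + wBL + wMod;

  double curLL = priorOnly ? 0.0 : E.loglikFull();
  auto lnPriorBL = [&](double t) { return std::log(blRate) - blRate * t; };
  auto pathNodes = [&](int from) {
    std::vector<int> nodes;
    int v = from;
    while (v >= 0) {
      nodes.push_back(v);
      v = E.parent[v];
    }
    return nodes;
  };

  int nsamp = nGen / sampleEvery;
  IntegerMatrix sampParent(nsamp, E.nnode);
  NumericMatrix sampBlen(nsamp, E.nnode);
  NumericVector sampLL(nsamp), sampAlpha(nsamp), sampPinv(nsamp);
  IntegerVector accCount(3), propCount(3);
  int si = 0;

  int dbg_last_move = -1, dbg_last_acc = 0;
  for (int gen = 1; gen <= nGen; gen++) {
    double u = unif_rand() * wTot;
    if (u < wNNI) {
      propCount[0]++;
      int v = nedges[(int)(unif_rand() * nedges.size()) % nedges.size()];
      int up = E.parent[v];
      int a = E.children[v][unif_rand() < 0.5 ? 0 : 1];
      std::vector<int> others;
      for (int c : E.children[up])
        if (c != v) others.push_back(c);
      int b = others[(int)(unif_rand() * others.size()) % others.size()];
      auto applySwap = [&](int x, int y) {
        for (auto &c : E.children[v]) if (c == x) c = y;
        for (auto &c : E.children[up]) if (c == y) c = x;
        E.parent[y] = v;
        E.parent[x] = up;
        E.computePost();
      };
      double newLL = curLL;
      if (!priorOnly) E.snapshot(pathNodes(v));
      applySwap(a, b);
      if (!priorOnly) {
        E.updatePathFrom(v);
        newLL = E.loglikRoot();
      }
      dbg_last_move = 0;
      if (std::log(unif_rand()) < newLL - curLL) {
        curLL = newLL;
        accCount[0]++;
        dbg_last_acc = 1;
        if (!priorOnly) E.commit();
      } else {
        applySwap(b, a);
        dbg_last_acc = 0;
        if (!priorOnly) E.restore();
      }
    } else if (u < wNNI + wBL) {
      propCount[1]++;
      int v = allEdges[(int)(unif_rand() * allEdges.size()) %
                       allEdges.size()];
      double t = E.blen[v];
      double f = std::exp(2.0 * (unif_rand() - 0.5));
      double tn = t * f;
      if (tn >= BL_MIN && tn <= BL_MAX) {
        double newLL = curLL;
        if (!priorOnly) E.snapshot(pathNodes(E.parent[v]));
        E.blen[v] = tn;
        if (!priorOnly) {
          E.updatePathFrom(E.parent[v]);
          newLL = E.loglikRoot();
        }
        double lr = (newLL - curLL) + (lnPriorBL(tn) - lnPriorBL(t)) +
                    std::log(f);
        dbg_last_move = 1;
        if (std::log(unif_rand()) < lr) {
          curLL = newLL;
          accCount[1]++;
          dbg_last_acc = 1;
          if (!priorOnly) E.commit();
        } else {
          E.blen[v] = t;
          dbg_last_acc = 0;
          if (!priorOnly) E.restore();
        }
      }
    } else if (wMod > 0) {
      propCount[2]++;
      int mv = modMoves[(int)(unif_rand() * modMoves.size()) %
                        modMoves.size()];
      Model old = E.mod;
      double lr = 0.0;
      bool needConst = false;
      if (mv == 0) {
        double f = std::exp(1.0 * (unif_rand() - 0.5));
        double an = E.mod.alpha * f;
        lr += -(an - E.mod.alpha) + std::log(f);
        E.mod.alpha = an;
      } else if (mv == 1) {
        double pn = E.mod.pinv + 0.1 * (unif_rand() - 0.5);
        if (pn < 0) pn = -pn;
        if (pn >= 0.98) pn = 1.96 - pn;
        E.mod.pinv = pn;
      } else if (mv == 2) {
        std::vector<double> xn;
        double lq = DirProposal::draw(E.mod.pi, dirConc, xn);
        double lqr = DirProposal::logdens(E.mod.pi, xn, dirConc);
        lr += lqr - lq;
        E.mod.pi = xn;
        needConst = true;
      } else {
        int n = E.mod.ns;
        std::vector<double> x;
        for (int i = 0; i < n - 1; i++)
          for (int j = i + 1; j < n; j++)
            x.push_back(E.mod.exch[i * n + j]);
        double s = 0.0;
        for (double z : x) s += z;
        for (double &z : x) z /= s;
        std::vector<double> xn;
        double lq = DirProposal::draw(x, dirConc, xn);
        double lqr = DirProposal::logdens(x, xn, dirConc);
        lr += lqr - lq;
        int k = 0;
        for (int i = 0; i < n - 1; i++)
          for (int j = i + 1; j < n; j++) {
            E.mod.exch[i * n + j] = E.mod.exch[j * n + i] = xn[k++] * s;
          }
      }
      E.mod.build();
      if (needConst) E.refreshConst();
      double newLL = curLL;
      if (!priorOnly) {
        std::vector<int> allInt;
        for (int v = E.ntip; v < E.nnode; v++) allInt.push_back(v);
        E.snapshot(allInt);
        newLL = E.loglikFull();
      }
      dbg_last_move = 2 * 10 + mv;
      if (std::log(unif_rand()) < (newLL - curLL) + lr) {
        curLL = newLL;
        accCount[2]++;
        dbg_last_acc = 1;
        if (!priorOnly) E.commit();
      } else {
        E.mod = old;
        if (needConst) E.refreshConst();
        dbg_last_acc = 0;
        if (!priorOnly) E.restore();
      }
    }

    if (as<bool>(ctrl["debug_check"]) && !priorOnly) {
      double fresh = E.loglikFull();
      if (std::fabs(fresh - curLL) > 1e-6) {
        Rprintf("gen %d: move %d acc %d curLL %.6f fresh %.6f\n", gen,
                dbg_last_move, dbg_last_acc, curLL, fresh);
        if (gen > 0) stop("diverged");
      }
      curLL = fresh;
    }
    if (gen % sampleEvery == 0 && si < nsamp) {
      for (int v = 0; v < E.nnode; v++) {
        sampParent(si, v) = E.parent[v];
        sampBlen(si, v) = E.blen[v];
      }
      sampLL[si] = curLL;
      sampAlpha[si] = E.mod.alpha;
      sampPinv[si] = E.mod.pinv;
      si++;
    }
  }

  return List::create(_["parent"] = sampParent, _["blen"] = sampBlen,
                      _["loglik"] = sampLL, _["alpha"] = sampAlpha,
                      _["p_inv"] = sampPinv, _["accepted"] = accCount,
                      _["proposed"] = propCount);
}
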