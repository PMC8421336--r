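// Grid solver for the household bargain, vectorised across households.
// Mirrors the pure-R operations in R/bargaining.R: alternating best
// responses at each fixed transfer, separate-spheres threat point at
// theta = 0, Nash-product selection under participation constraints.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Member {
  double p;                  // private-good preference weight
  double w;                  // wage
  double ca, cg, ct;         // conformity weights (alpha, gamma, theta)
  double mua, mug, mut;      // norm means
};

std::vector<double> make_grid(double step) {
  int n = (int)std::round(1.0 / step) + 1;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) g[i] = i * step;
  g[n - 1] = 1.0;
  return g;
}

int clamp_idx(double a, double step, int n) {
  int i = (int)std::round(a / step);
  if (i < 0) i = 0;
  if (i > n - 1) i = n - 1;
  return i;
}

// Best-response index over the member's own alpha grid. `gives` marks the
// transferor at magnitude th. The exp factor `efb` excludes the theta term
// (a positive scalar, irrelevant for the argmax). Ties break toward the
// previous index, then smaller alpha (ascending scan with strict <).
int best_resp(const Member& m, double w_partner, double a_partner,
              double th, bool gives, bool transfer,
              const std::vector<double>& g, const std::vector<double>& efb,
              int i_prev, std::vector<double>& buf) {
  int n = (int)g.size();
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double a = g[i];
    double priv;
    if (!transfer) priv = m.w * a;
    else if (gives) priv = m.w * a * (1.0 - th);
    else priv = m.w * a + th * w_partner * a_partner;
    double pub = (1.0 - a) + (1.0 - a_partner);
    double u = (m.p * std::sqrt(priv) + (1.0 - m.p) * std::sqrt(pub)) * efb[i];
    buf[i] = u;
    if (u > best) best = u;
  }
  double eps = 1e-12 * (best > 1.0 ? best : 1.0);
  int pick = -1;
  double bestd = 1e300;
  for (int i = 0; i < n; ++i) {
    if (buf[i] >= best - eps) {
      double d = std::fabs(g[i] - g[i_prev]);
      if (d < bestd - 1e-15) { bestd = d; pick = i; }
    }
  }
  return pick;
}

// Full member utility (theta norm term included).
double util_full(const Member& m, double a, double w_partner,
                 double a_partner, double th, bool gives, bool transfer) {
  double priv;
  if (!transfer) priv = m.w * a;
  else if (gives) priv = m.w * a * (1.0 - th);
  else priv = m.w * a + th * w_partner * a_partner;
  double pub = (1.0 - a) + (1.0 - a_partner);
  double da = a - m.mua, dg = (1.0 - a) - m.mug, dt = th - m.mut;
  double pen = m.ca * da * da + m.cg * dg * dg + m.ct * dt * dt;
  return (m.p * std::sqrt(priv) + (1.0 - m.p) * std::sqrt(pub)) * std::exp(-pen);
}

// Alternating best responses (A first) until exact repetition on the grid.
// dir: +1 A transfers to B, -1 B transfers to A, 0 no transfer.
bool equilibrium(const Member& A, const Member& B, double th, int dir,
                 const std::vector<double>& g,
                 const std::vector<double>& efA, const std::vector<double>& efB,
                 int maxit, int& iA, int& iB, std::vector<double>& buf) {
  bool transfer = dir != 0;
  for (int it = 0; it < maxit; ++it) {
    int oldA = iA, oldB = iB;
    iA = best_resp(A, B.w, g[iB], th, dir > 0, transfer, g, efA, oldA, buf);
    iB = best_resp(B, A.w, g[iA], th, dir < 0, transfer, g, efB, oldB, buf);
    if (iA == oldA && iB == oldB) return true;
  }
  return false;
}

} // namespace

//' @name ihm_step_cpp
//' @title Population-level household bargain step (internal)
//' @description For each household, selects the Nash bargain over the
//'   transfer grid in both directions given frozen norm means. Columns of
//'   the returned matrix: alpha_a, alpha_b, theta, dir (+1 = A to B,
//'   -1 = B to A, 0 = none), utility_a, utility_b, converged (selected
//'   equilibrium), n_nonconverged (over all transfer candidates).
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix ihm_step_cpp(NumericVector p_a, NumericMatrix conf_a,
                           NumericVector wage_a, NumericVector mu_a,
                           NumericVector p_b, NumericMatrix conf_b,
                           NumericVector wage_b, NumericVector mu_b,
                           NumericVector alpha_a0, NumericVector alpha_b0,
                           IntegerVector prev_dir,
                           double alpha_step, double theta_step,
                           int max_iter, double constraint_tol) {
  int nh = p_a.size();
  std::vector<double> g = make_grid(alpha_step);
  int n = (int)g.size();
  int K = (int)std::round(1.0 / theta_step);
  std::vector<double> efA(n), efB(n), buf(n);
  NumericMatrix out(nh, 8);

  for (int h = 0; h < nh; ++h) {
    Member A = {p_a[h], wage_a[h], conf_a(h, 0), conf_a(h, 1), conf_a(h, 2),
                mu_a[0], mu_a[1], mu_a[2]};
    Member B = {p_b[h], wage_b[h], conf_b(h, 0), conf_b(h, 1), conf_b(h, 2),
                mu_b[0], mu_b[1], mu_b[2]};
    for (int i = 0; i < n; ++i) {
      double a = g[i], ga = 1.0 - a;
      efA[i] = std::exp(-(A.ca * (a - A.mua) * (a - A.mua) +
                          A.cg * (ga - A.mug) * (ga - A.mug)));
      efB[i] = std::exp(-(B.ca * (a - B.mua) * (a - B.mua) +
                          B.cg * (ga - B.mug) * (ga - B.mug)));
    }
    int i0A = clamp_idx(alpha_a0[h], alpha_step, n);
    int i0B = clamp_idx(alpha_b0[h], alpha_step, n);

    int iA = i0A, iB = i0B;
    bool conv0 = equilibrium(A, B, 0.0, 0, g, efA, efB, max_iter, iA, iB, buf);
    double uAs = util_full(A, g[iA], B.w, g[iB], 0.0, false, false);
    double uBs = util_full(B, g[iB], A.w, g[iA], 0.0, false, false);

    double bA = g[iA], bB = g[iB], bth = 0.0, buA = uAs, buB = uBs;
    int bdir = 0;
    bool bconv = conv0;
    int nonconv = conv0 ? 0 : 1;
    double np_best = 0.0;

    int dirs[2];
    if (prev_dir[h] < 0) { dirs[0] = -1; dirs[1] = 1; }
    else { dirs[0] = 1; dirs[1] = -1; }

    for (int k = 1; k <= K; ++k) {
      double th = (k == K) ? 1.0 : k * theta_step;
      for (int di = 0; di < 2; ++di) {
        int dir = dirs[di];
        int jA = i0A, jB = i0B;
        bool cv = equilibrium(A, B, th, dir, g, efA, efB, max_iter, jA, jB, buf);
        if (!cv) ++nonconv;
        double uA = util_full(A, g[jA], B.w, g[jB], th, dir > 0, true);
        double uB = util_full(B, g[jB], A.w, g[jA], th, dir < 0, true);
        if (uA >= uAs - constraint_tol && uB >= uBs - constraint_tol) {
          double np = (uA - uAs) * (uB - uBs);
          if (np > np_best) {
            np_best = np;
            bA = g[jA]; bB = g[jB]; bth = th; bdir = dir;
            buA = uA; buB = uB; bconv = cv;
          }
        }
      }
    }
    out(h, 0) = bA; out(h, 1) = bB; out(h, 2) = bth; out(h, 3) = bdir;
    out(h, 4) = buA; out(h, 5) = buB; out(h, 6) = bconv ? 1.0 : 0.0;
    out(h, 7) = nonconv;
  }
  return out;
}
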