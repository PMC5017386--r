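#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Orthonormal Daubechies scaling (low-pass analysis) filters, orders 1-10.
// Standard published coefficients; order k has 2k taps and k vanishing moments.
static const double DB1[] = {0.7071067811865476, 0.7071067811865476};
static const double DB2[] = {-0.12940952255126037, 0.2241438680420134,
                             0.8365163037378079, 0.48296291314453416};
static const double DB3[] = {0.03522629188570953, -0.08544127388202666,
                             -0.13501102001025458, 0.45987750211849154,
                             0.8068915093110925, 0.33267055295008263};
static const double DB4[] = {-0.01059740178506903, 0.0328830116668852,
                             0.03084138183556076, -0.18703481171909309,
                             -0.02798376941685985, 0.6308807679298589,
                             0.7148465705529157, 0.2303778133088965};
static const double DB5[] = {0.00333572528547377, -0.012580751999082,
                             -0.00624149021279827, 0.07757149384004572,
                             -0.03224486958463837, -0.24229488706638203,
                             0.13842814590132074, 0.7243085284377729,
                             0.6038292697971896, 0.16010239797419293};
static const double DB6[] = {-1.0773010853084796e-03, 4.7772575109455108e-03,
                             5.5384220116149613e-04, -3.1582039317486030e-02,
                             2.7522865530305727e-02, 9.7501605587323043e-02,
                             -1.2976686756726194e-01, -2.2626469396543983e-01,
                             3.1525035170919763e-01, 7.5113390802109536e-01,
                             4.9462389039845306e-01, 1.1154074335010947e-01};
static const double DB7[] = {3.5371379997452024e-04, -1.8016407040474908e-03,
                             4.2957797292136651e-04, 1.2550998556099840e-02,
                             -1.6574541630666881e-02, -3.8029936935014413e-02,
                             8.0612609151083078e-02, 7.1309219266830259e-02,
                             -2.2403618499387498e-01, -1.4390600392856498e-01,
                             4.6978228740519312e-01, 7.2913209084623509e-01,
                             3.9653931948191729e-01, 7.7852054085009184e-02};
static const double DB8[] = {-1.1747678412476953e-04, 6.7544940645056933e-04,
                             -3.9174037337694705e-04, -4.8703529934515741e-03,
                             8.7460940474057766e-03, 1.3981027917398282e-02,
                             -4.4088253930794755e-02, -1.7369301001807547e-02,
                             1.2874742662047847e-01, 4.7248457391328279e-04,
                             -2.8401554296154691e-01, -1.5829105256349306e-02,
                             5.8535468365420673e-01, 6.7563073629728976e-01,
                             3.1287159091429995e-01, 5.4415842243104008e-02};
static const double DB9[] = {3.9347320316271603e-05, -2.5196318894271012e-04,
                             2.3038576352319597e-04, 1.8476468830562265e-03,
                             -4.2815036824634303e-03, -4.7232047577513972e-03,
                             2.2361662123679096e-02, 2.5094711483145197e-04,
                             -6.7632829061329974e-02, 3.0725681479333380e-02,
                             1.4854074933810638e-01, -9.6840783222976456e-02,
                             -2.9327378327917492e-01, 1.3319738582500756e-01,
                             6.5728807805130052e-01, 6.0482312369011115e-01,
                             2.4383467461259034e-01, 3.8077947363878345e-02};
static const double DB10[] = {-1.3264202894521244e-05, 9.3588670320069592e-05,
                              -1.1646685512928545e-04, -6.8585669495971162e-04,
                              1.9924052951850561e-03, 1.3953517470529011e-03,
                              -1.0733175483330575e-02, 3.6065535669561697e-03,
                              3.3212674059341002e-02, -2.9457536821875813e-02,
                              -7.1394147166397082e-02, 9.3057364603572348e-02,
                              1.2736934033579325e-01, -1.9594627437737705e-01,
                              -2.4984642432731538e-01, 2.8117234366057747e-01,
                              6.8845903945360354e-01, 5.2720118893172563e-01,
                              1.8817680007769150e-01, 2.6670057900555554e-02};

static const double* DB_TABLE[] = {DB1, DB2, DB3, DB4, DB5,
                                   DB6, DB7, DB8, DB9, DB10};

static std::vector<double> scaling_filter(int order) {
  if (order < 1 || order > 10)
    stop("Daubechies order must be between 1 and 10");
  const double* f = DB_TABLE[order - 1];
  return std::vector<double>(f, f + 2 * order);
}

// One periodized analysis step. Convention: with the reversed low-pass
// filter rlo[j] = lo[m-1-j] and quadrature mirror rhi[j] = (-1)^j lo[j],
//   a[k] = sum_j rlo[j] x[(2k + j - (m/2 - 1)) mod n]   (same for d with rhi)
// which is the usual periodized orthonormal DWT. Odd-length inputs are
// padded by repeating the last sample.
static void dwt_step(const std::vector<double>& x,
                     const std::vector<double>& lo,
                     std::vector<double>& approx,
                     std::vector<double>& detail) {
  std::vector<double> xin = x;
  if (xin.size() % 2 == 1) xin.push_back(xin.back());
  const int n = (int)xin.size();
  const int m = (int)lo.size();
  const int n2 = n / 2;
  const int off = m / 2 - 1;
  approx.assign(n2, 0.0);
  detail.assign(n2, 0.0);
  for (int k = 0; k < n2; ++k) {
    double a = 0.0, d = 0.0;
    int base = 2 * k - off;
    for (int j = 0; j < m; ++j) {
      int idx = base + j;
      idx %= n;
      if (idx < 0) idx += n;
      const double xv = xin[idx];
      a += lo[m - 1 - j] * xv;
      d += ((j % 2 == 0) ? lo[j] : -lo[j]) * xv;
    }
    approx[k] = a;
    detail[k] = d;
  }
}

static int max_feasible_level(int n) {
  int lev = 0;
  while (n >= 2) { n = (n + 1) / 2; ++lev; }
  return lev;
}

// Multi-level periodized Daubechies decomposition. Returns detail
// coefficient vectors for levels 1..min(L, feasible) and the final
// approximation.
// [[Rcpp::export]]
List cpp_dwt(NumericVector x, int level, int order) {
  if (x.size() < 2) stop("input must have at least 2 samples");
  if (level < 0) stop("level must be >= 0");
  std::vector<double> lo = scaling_filter(order);
  std::vector<double> cur(x.begin(), x.end());
  int lf = std::min(level, max_feasible_level((int)cur.size()));
  List details(lf);
  std::vector<double> a, d;
  for (int l = 0; l < lf; ++l) {
    dwt_step(cur, lo, a, d);
    details[l] = NumericVector(d.begin(), d.end());
    cur = a;
  }
  return List::create(_["details"] = details,
                      _["approx"] = NumericVector(cur.begin(), cur.end()));
}

// Per-level mean-square coefficient energies (pre-log). Entries 1..L are
// detail levels (NA_real_ where the level is beyond dyadic feasibility);
// entry L+1 is the mean square of the final approximation.
static void level_energies(const std::vector<double>& x, int L,
                           const std::vector<double>& lo, double* out) {
  int lf = std::min(L, max_feasible_level((int)x.size()));
  std::vector<double> cur = x, a, d;
  for (int l = 0; l < L; ++l) {
    if (l < lf) {
      dwt_step(cur, lo, a, d);
      double s = 0.0;
      for (double v : d) s += v * v;
      out[l] = s / (double)d.size();
      cur = a;
    } else {
      out[l] = NA_REAL;
    }
  }
  double s = 0.0;
  for (double v : cur) s += v * v;
  out[L] = s / (double)cur.size();
}

// [[Rcpp::export]]
NumericVector cpp_level_energies(NumericVector x, int level, int order) {
  if (x.size() < 2) stop("input must have at least 2 samples");
  if (level < 0) stop("level must be >= 0");
  std::vector<double> lo = scaling_filter(order);
  std::vector<double> xv(x.begin(), x.end());
  NumericVector out(level + 1);
  level_energies(xv, level, lo, REAL(out));
  return out;
}

static inline int reflect_index(int i, int n) {
  // symmetric (half-point) reflection: ... x1 x0 | x0 x1 ... xn-1 | xn-1 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Windowed wavelet log-energy features for one channel at given 0-based
// frame centers. Row i holds log10(eps + energy) for detail levels 1..L
// then the approximation; infeasible levels give log10(eps).
// [[Rcpp::export]]
NumericMatrix cpp_window_features(NumericVector sig, IntegerVector centers,
                                  int window, int level, int order,
                                  double eps) {
  if (window < 2) stop("window must be >= 2");
  const int n = sig.size();
  if (n < 1) stop("empty signal");
  std::vector<double> lo = scaling_filter(order);
  const int nf = centers.size();
  NumericMatrix out(nf, level + 1);
  std::vector<double> win(window);
  std::vector<double> en(level + 1);
  const int half = window / 2;
  const double logeps = std::log10(eps);
  for (int i = 0; i < nf; ++i) {
    const int c = centers[i];
    for (int j = 0; j < window; ++j)
      win[j] = sig[reflect_index(c - half + j, n)];
    level_energies(win, level, lo, en.data());
    for (int l = 0; l <= level; ++l)
      out(i, l) = ISNA(en[l]) ? logeps : std::log10(eps + en[l]);
  }
  return out;
}

// Raw (instantaneous) center-sample values for one channel.
// [[Rcpp::export]]
NumericVector cpp_center_values(NumericVector sig, IntegerVector centers) {
  const int n = sig.size();
  NumericVector out(centers.size());
  for (int i = 0; i < centers.size(); ++i)
    out[i] = sig[reflect_index(centers[i], n)];
  return out;
}
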