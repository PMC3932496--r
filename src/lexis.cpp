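#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-constant hazard on 1-year-age x 1-calendar-year Lexis cells.
// A subject advances along the 45-degree diagonal: age and calendar time
// increase together at slope 1, so the integral of the cell rates is
// piecewise linear in follow-up time with breaks at (fractional) birthdays
// and at new year.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Forward integral of the rate surface along the diagonal from
// (a0, y0) for t years.  Rows of M are ages age_min..age_min+nrow-1,
// columns are years year_min..year_min+ncol-1.  Out-of-range cells are
// clamped to the nearest edge when the corresponding flag is set,
// otherwise the integral is NA (the R side reports the missing cell).
static double cumhaz_one(const NumericMatrix &M, int age_min, int year_min,
                         double a0, double y0, double t,
                         bool clamp_age, bool clamp_year) {
  const double eps = 1e-9;
  const int na = M.nrow(), ny = M.ncol();
  double u = 0.0, H = 0.0;
  while (u < t - 1e-12) {
    double age = a0 + u, yr = y0 + u;
    int ai = (int)std::floor(age + eps);
    int yi = (int)std::floor(yr + eps);
    double du = t - u;
    double to_age = (double)(ai + 1) - age;
    double to_yr = (double)(yi + 1) - yr;
    if (to_age < du) du = to_age;
    if (to_yr < du) du = to_yr;
    if (du < 1e-12) du = 1e-12;
    int ri = ai - age_min, ci = yi - year_min;
    if (ri < 0 || ri >= na) {
      if (clamp_age) ri = clampi(ri, 0, na - 1); else return NA_REAL;
    }
    if (ci < 0 || ci >= ny) {
      if (clamp_year) ci = clampi(ci, 0, ny - 1); else return NA_REAL;
    }
    H += M(ri, ci) * du;
    u += du;
  }
  return H;
}

// Inverse of the forward integral: smallest t with cumulative hazard z.
// Walks the same segment structure, so the round trip is exact up to
// floating point.  Returns NA when z is not reached before the attained
// age hits age_ceiling (saturation).
static double invert_one(const NumericMatrix &M, int age_min, int year_min,
                         double a0, double y0, double z,
                         bool clamp_year, double age_ceiling) {
  const double eps = 1e-9;
  const int na = M.nrow(), ny = M.ncol();
  if (z <= 0.0) return 0.0;
  double u = 0.0, H = 0.0;
  while (a0 + u < age_ceiling - 1e-12) {
    double age = a0 + u, yr = y0 + u;
    int ai = (int)std::floor(age + eps);
    int yi = (int)std::floor(yr + eps);
    double du = (double)(ai + 1) - age;
    double to_yr = (double)(yi + 1) - yr;
    if (to_yr < du) du = to_yr;
    double rem = age_ceiling - age;
    if (rem < du) du = rem;
    if (du < 1e-12) du = 1e-12;
    int ri = clampi(ai - age_min, 0, na - 1);
    int ci = yi - year_min;
    if (ci < 0 || ci >= ny) {
      if (clamp_year) ci = clampi(ci, 0, ny - 1); else return NA_REAL;
    }
    double r = M(ri, ci);
    if (r > 0.0 && H + r * du >= z) return u + (z - H) / r;
    H += r * du;
    u += du;
  }
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_lexis_cumhaz(NumericMatrix rates, int age_min, int year_min,
                               NumericVector a0, NumericVector y0,
                               NumericVector t, bool clamp_age,
                               bool clamp_year) {
  R_xlen_t n = a0.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = cumhaz_one(rates, age_min, year_min, a0[i], y0[i], t[i],
                        clamp_age, clamp_year);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lexis_invert(NumericMatrix rates, int age_min, int year_min,
                               NumericVector a0, NumericVector y0,
                               NumericVector z, bool clamp_year,
                               double age_ceiling) {
  R_xlen_t n = a0.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = invert_one(rates, age_min, year_min, a0[i], y0[i], z[i],
                        clamp_year, age_ceiling);
  return out;
}
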