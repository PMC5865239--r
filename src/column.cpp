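// Compiled core of the 1D water-column model: the combined
// biological + diffusive + sinking right-hand side and the fixed-step
// classical RK4 loop integrated to equilibrium. Mirrors the R
// reference implementation (column_rhs); a testthat check asserts
// agreement to near machine precision.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// state ordering, matching R's state_vars
enum { NH4, NO2, NO3, DET, BHET, BAOO, BNOO, P, Z, NVAR };

struct ColumnModel {
  int n;
  double dz, w_s, k_w, k_chl, i_max;
  bool diel;
  std::vector<double> kz;      // faces, m^2/d, length n+1
  std::vector<double> gt;      // Arrhenius factor per cell
  std::vector<double> gt_nit;  // factor applied to nitrifiers
  std::vector<double> o2f;     // oxygen Monod factor (1 when disabled)

  // biology (concentration-like parameters in umol/L)
  double y_aoo, vmax_aoo, k_aoo;
  double y_noo, vmax_noo, k_noo;
  double vmax_d, k_d, y_d;
  double mu_max, k_nh4p, k_no2p, k_no3p;
  double gamma_coef;  // Gamma (1/d per theta) per unit irradiance
  double theta_max;
  double chl_coef;    // mg Chl m^-3 per (mol N m^-3 * theta)
  double g_max, k_g, zeta, m_z, m_b;

  // y: column-major n x 9 in mol N/m^3; dydt same units per day
  void rhs(const std::vector<double>& y, double t, std::vector<double>& dydt) const {
    const double um = 1e3;   // mol/m^3 -> umol/L
    double i_face = diel ? 0.5 * i_max * (std::cos(2.0 * M_PI * t) + 1.0)
                         : 0.5 * i_max;

    for (int i = 0; i < n; ++i) {
      double nh4 = std::max(y[NH4 * n + i], 0.0) * um;
      double no2 = std::max(y[NO2 * n + i], 0.0) * um;
      double no3 = std::max(y[NO3 * n + i], 0.0) * um;
      double det = std::max(y[DET * n + i], 0.0) * um;
      double bhet = std::max(y[BHET * n + i], 0.0) * um;
      double baoo = std::max(y[BAOO * n + i], 0.0) * um;
      double bnoo = std::max(y[BNOO * n + i], 0.0) * um;
      double p = std::max(y[P * n + i], 0.0) * um;
      double z = std::max(y[Z * n + i], 0.0) * um;

      // nutrient and temperature limitation
      double t1 = nh4 / (nh4 + k_nh4p);
      double t2 = no2 / (no2 + k_no2p);
      double t3 = no3 / (no3 + k_no3p);
      double gn = t1 + t2 + t3;
      double mu_cap = mu_max * gn * gt[i];

      // light sweep: acclimate theta to mid-cell irradiance, refining
      // once for the cell's own attenuation (matches column_light_field)
      double p_molm3 = p / um;
      double i_mid = i_face * std::exp(-k_w * dz / 2.0);
      double g_l = gamma_coef * i_mid;
      double th = mu_cap > 0.0 ? theta_max / (1.0 + g_l * theta_max / (2.0 * mu_cap))
                               : theta_max;
      double ch = p_molm3 * chl_coef * th;
      i_mid = i_face * std::exp(-(k_w + k_chl * ch) * dz / 2.0);
      g_l = gamma_coef * i_mid;
      th = mu_cap > 0.0 ? theta_max / (1.0 + g_l * theta_max / (2.0 * mu_cap))
                        : theta_max;
      ch = p_molm3 * chl_coef * th;
      i_face *= std::exp(-(k_w + k_chl * ch) * dz);

      double mu_p = (mu_cap > 0.0 && g_l > 0.0)
                        ? mu_cap * (1.0 - std::exp(-g_l * th / mu_cap))
                        : 0.0;
      double s = gn;
      double v_nh4 = s > 0.0 ? mu_p * t1 / s : 0.0;
      double v_no2 = s > 0.0 ? mu_p * t2 / s : 0.0;
      double v_no3 = s > 0.0 ? mu_p * t3 / s : 0.0;

      double mu_aoo = y_aoo * vmax_aoo * nh4 / (nh4 + k_aoo) * gt_nit[i] * o2f[i];
      double mu_noo = y_noo * vmax_noo * no2 / (no2 + k_noo) * gt_nit[i] * o2f[i];
      double mu_het = y_d * vmax_d * det / (det + k_d) * gt[i];

      double prey = p + bhet + baoo + bnoo;
      double g = g_max * gt[i] / (prey + k_g);
      double gz = g * z;
      double m_z_t = m_z * gt[i];

      double d_nh4 = -(mu_aoo / y_aoo) * baoo - mu_noo * bnoo - v_nh4 * p +
                     (1.0 / y_d - 1.0) * mu_het * bhet + (1.0 - zeta) * gz * prey;
      double d_no2 = (1.0 / y_aoo - 1.0) * mu_aoo * baoo -
                     (mu_noo / y_noo) * bnoo - v_no2 * p;
      double d_no3 = (mu_noo / y_noo) * bnoo - v_no3 * p;
      double d_det = -(1.0 / y_d) * mu_het * bhet + m_b * prey + m_z_t * z * z;
      double d_bhet = bhet * (mu_het - m_b) - gz * bhet;
      double d_baoo = baoo * (mu_aoo - m_b) - gz * baoo;
      double d_bnoo = bnoo * (mu_noo - m_b) - gz * bnoo;
      double d_p = p * (mu_p - m_b) - gz * p;
      double d_z = zeta * gz * prey - m_z_t * z * z;

      const double back = 1e-3;  // umol/L -> mol/m^3
      dydt[NH4 * n + i] = d_nh4 * back;
      dydt[NO2 * n + i] = d_no2 * back;
      dydt[NO3 * n + i] = d_no3 * back;
      dydt[DET * n + i] = d_det * back;
      dydt[BHET * n + i] = d_bhet * back;
      dydt[BAOO * n + i] = d_baoo * back;
      dydt[BNOO * n + i] = d_bnoo * back;
      dydt[P * n + i] = d_p * back;
      dydt[Z * n + i] = d_z * back;
    }

    // diffusion of every variable, no-flux boundaries
    for (int v = 0; v < NVAR; ++v) {
      const double* c = &y[v * n];
      double* d = &dydt[v * n];
      double flux_above = 0.0;  // positive downward
      for (int i = 0; i < n; ++i) {
        double flux_below =
            (i < n - 1) ? -kz[i + 1] * (c[i + 1] - c[i]) / dz : 0.0;
        d[i] += -(flux_below - flux_above) / dz;
        flux_above = flux_below;
      }
    }

    // QUICK sinking of detritus; surface closed, bottom accumulates
    {
      const double* c = &y[DET * n];
      double* d = &dydt[DET * n];
      double flux_above = 0.0;
      for (int i = 0; i < n; ++i) {
        double flux_below = 0.0;
        if (i < n - 1) {
          // face below cell i (face index i+1), upstream cell i
          double face;
          if (i == 0) {
            face = c[0];  // upwind fallback: no far-upstream cell
          } else {
            face = (c[i] + c[i + 1]) / 2.0 -
                   (c[i + 1] - 2.0 * c[i] + c[i - 1]) / 8.0;
          }
          flux_below = w_s * face;
        }
        d[i] += -(flux_below - flux_above) / dz;
        flux_above = flux_below;
      }
    }
  }
};

static ColumnModel build_model(int n, List bio, NumericVector kz_faces_m2d,
                               NumericVector gt, NumericVector gt_nit,
                               NumericVector o2f, double dz, double w_s,
                               double k_w, double k_chl, double i_max,
                               bool diel) {
  ColumnModel m;
  m.n = n;
  m.dz = dz;
  m.w_s = w_s;
  m.k_w = k_w;
  m.k_chl = k_chl;
  m.i_max = i_max;
  m.diel = diel;
  m.kz.assign(kz_faces_m2d.begin(), kz_faces_m2d.end());
  m.gt.assign(gt.begin(), gt.end());
  m.gt_nit.assign(gt_nit.begin(), gt_nit.end());
  m.o2f.assign(o2f.begin(), o2f.end());
  m.y_aoo = bio["y_aoo"]; m.vmax_aoo = bio["vmax_aoo"]; m.k_aoo = bio["k_aoo"];
  m.y_noo = bio["y_noo"]; m.vmax_noo = bio["vmax_noo"]; m.k_noo = bio["k_noo"];
  m.vmax_d = bio["vmax_d"]; m.k_d = bio["k_d"]; m.y_d = bio["y_d"];
  m.mu_max = bio["mu_max"]; m.k_nh4p = bio["k_nh4p"];
  m.k_no2p = bio["k_no2p"]; m.k_no3p = bio["k_no3p"];
  m.gamma_coef = bio["gamma_coef"]; m.theta_max = bio["theta_max"];
  m.chl_coef = bio["chl_coef"];
  m.g_max = bio["g_max"]; m.k_g = bio["k_g"]; m.zeta = bio["zeta"];
  m.m_z = bio["m_z"]; m.m_b = bio["m_b"];
  return m;
}

// [[Rcpp::export]]
NumericMatrix col_rhs_cpp(NumericMatrix state, List bio,
                          NumericVector kz_faces_m2d, NumericVector gt,
                          NumericVector gt_nit, NumericVector o2f, double dz,
                          double w_s, double k_w, double k_chl, double i_max,
                          bool diel, double t) {
  int n = state.nrow();
  ColumnModel m = build_model(n, bio, kz_faces_m2d, gt, gt_nit, o2f, dz, w_s,
                              k_w, k_chl, i_max, diel);
  std::vector<double> y(state.begin(), state.end());
  std::vector<double> dydt(y.size());
  m.rhs(y, t, dydt);
  NumericMatrix out(n, NVAR);
  std::copy(dydt.begin(), dydt.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List col_integrate_cpp(NumericMatrix state0, List bio,
                       NumericVector kz_faces_m2d, NumericVector gt,
                       NumericVector gt_nit, NumericVector o2f, double dz,
                       double w_s, double k_w, double k_chl, double i_max,
                       bool diel, double dt, double max_time, double tol,
                       double check_every, double eps_molm3, bool clip) {
  int n = state0.nrow();
  ColumnModel m = build_model(n, bio, kz_faces_m2d, gt, gt_nit, o2f, dz, w_s,
                              k_w, k_chl, i_max, diel);
  size_t len = (size_t)n * NVAR;
  std::vector<double> y(state0.begin(), state0.end());
  std::vector<double> k1(len), k2(len), k3(len), k4(len), tmp(len);
  std::vector<double> day_avg(len, 0.0), day_avg_prev;

  // integer number of steps per day so diel phases align across checks
  long steps_per_day = (long)std::ceil(1.0 / dt);
  double h = 1.0 / (double)steps_per_day;
  long check_days = std::max(1L, (long)std::llround(check_every));
  long max_days = (long)std::ceil(max_time);

  std::vector<double> clipped(NVAR, 0.0);
  std::vector<double> conv_time, conv_metric, inv_time, inv_total;

  bool converged = false;
  double metric = NA_REAL;
  long day = 0;

  for (day = 0; day < max_days && !converged; ++day) {
    bool avg_day = ((day + 1) % check_days) == 0;  // last day before a check
    if (avg_day) std::fill(day_avg.begin(), day_avg.end(), 0.0);

    for (long s = 0; s < steps_per_day; ++s) {
      double t = (double)day + (double)s * h;
      m.rhs(y, t, k1);
      for (size_t i = 0; i < len; ++i) tmp[i] = y[i] + 0.5 * h * k1[i];
      m.rhs(tmp, t + 0.5 * h, k2);
      for (size_t i = 0; i < len; ++i) tmp[i] = y[i] + 0.5 * h * k2[i];
      m.rhs(tmp, t + 0.5 * h, k3);
      for (size_t i = 0; i < len; ++i) tmp[i] = y[i] + h * k3[i];
      m.rhs(tmp, t + h, k4);
      for (size_t i = 0; i < len; ++i) {
        y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      }
      // clip negatives, logging the added mass (mol N per m^2)
      if (clip) {
        for (int v = 0; v < NVAR; ++v) {
          for (int i = 0; i < n; ++i) {
            double& val = y[(size_t)v * n + i];
            if (val < 0.0) {
              clipped[v] += -val * dz;
              val = 0.0;
            }
          }
        }
      }
      if (avg_day) {
        for (size_t i = 0; i < len; ++i) day_avg[i] += y[i];
      }
    }
    if (avg_day) {
      for (size_t i = 0; i < len; ++i) day_avg[i] /= (double)steps_per_day;
    }

    // stability audit
    double ymax = 0.0;
    bool finite = true;
    for (size_t i = 0; i < len; ++i) {
      if (!std::isfinite(y[i])) { finite = false; break; }
      if (y[i] > ymax) ymax = y[i];
    }
    if (!finite || ymax > 1e3) {
      double kzmax = 0.0;
      for (double k : m.kz) kzmax = std::max(kzmax, k);
      stop("column integration unstable at day %ld (dt = %g d; diffusive CFL = %g, advective CFL = %g)",
           day + 1, h, kzmax * h / (dz * dz), w_s * h / dz);
    }

    if ((day + 1) % check_days == 0) {
      double t_now = (double)(day + 1);
      double total = 0.0;
      for (size_t i = 0; i < len; ++i) total += y[i] * dz;
      inv_time.push_back(t_now);
      inv_total.push_back(total);
      if (!day_avg_prev.empty()) {
        double window = (double)check_days;
        metric = 0.0;
        for (size_t i = 0; i < len; ++i) {
          double rate = std::fabs(day_avg[i] - day_avg_prev[i]) / window;
          double rel = rate / (std::max(day_avg[i], 0.0) + eps_molm3);
          if (rel > metric) metric = rel;
        }
        conv_time.push_back(t_now);
        conv_metric.push_back(metric);
        if (metric < tol) converged = true;
      }
      day_avg_prev = day_avg;
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix out(n, NVAR);
  std::copy(y.begin(), y.end(), out.begin());
  return List::create(
      _["state"] = out, _["time"] = (double)day, _["converged"] = converged,
      _["metric"] = metric, _["conv_time"] = wrap(conv_time),
      _["conv_metric"] = wrap(conv_metric), _["clipped"] = wrap(clipped),
      _["inventory_time"] = wrap(inv_time),
      _["inventory_total"] = wrap(inv_total), _["dt"] = h);
}
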