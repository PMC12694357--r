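// 2D Monte Carlo radiative transport in a layered slab phantom with an
// embedded circular vessel. Geometry: x lateral in [-width/2, width/2],
// y = depth (mm), layers horizontal. Weights are tracked so that
// specular + diffuse reflectance + transmittance + side escape + absorbed
// energy sums to the launched weight exactly (photon termination deposits
// residual weight locally; Russian roulette runs without 1/p amplification,
// a bias bounded by the weight threshold).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Medium {
  double mua, mus, g, n; // per-mm coefficients
};

inline double hg_angle(double g) {
  double u = R::unif_rand();
  if (std::fabs(g) < 1e-8) return 2.0 * M_PI * u - M_PI;
  return 2.0 * std::atan(((1.0 - g) / (1.0 + g)) *
                         std::tan(M_PI * (u - 0.5)));
}

} // namespace

// [[Rcpp::export]]
List mc2d_run(NumericVector boundaries,   // cumulative depths, length nl+1
              NumericVector l_mua, NumericVector l_mus,
              NumericVector l_g, NumericVector l_n,  // per layer (1/mm, -)
              double vx, double vy, double vr,       // vessel; vr <= 0: none
              double v_mua, double v_mus, double v_g,
              double width,
              NumericVector src_x, double src_diam,
              double theta_inc_deg, double n_ambient,
              int n_photons, double weight_threshold, double p_survive,
              double grid_dx, double grid_dy,
              double bottom_albedo) {
  const int nl = l_mua.size();
  const double depth = boundaries[nl];
  const double xhalf = width / 2.0;
  const double eps = 1e-9;
  const int max_steps = 1000000;

  // entry refraction + unpolarized Fresnel specular loss (applied once)
  const double ti = theta_inc_deg * M_PI / 180.0;
  const double st = n_ambient * std::sin(ti) / l_n[0];
  if (std::fabs(st) > 1.0) stop("total internal reflection at entry");
  const double tt = std::asin(st);
  double rsp;
  if (ti < 1e-12) {
    double q = (n_ambient - l_n[0]) / (n_ambient + l_n[0]);
    rsp = q * q;
  } else {
    double rs = std::sin(ti - tt) / std::sin(ti + tt);
    double rp = std::tan(ti - tt) / std::tan(ti + tt);
    rsp = 0.5 * (rs * rs + rp * rp);
  }

  const int nx = std::max(1, (int)std::ceil(width / grid_dx));
  const int ny = std::max(1, (int)std::ceil(depth / grid_dy));
  NumericMatrix amap(ny, nx);

  double tal_rspec = 0.0, tal_rdiff = 0.0, tal_t = 0.0, tal_side = 0.0;
  const int nsrc = src_x.size();

  auto deposit = [&](double x, double y, double w) {
    int ix = (int)std::floor((x + xhalf) / grid_dx);
    int iy = (int)std::floor(y / grid_dy);
    if (ix < 0) ix = 0;
    if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0;
    if (iy >= ny) iy = ny - 1;
    amap(iy, ix) += w;
  };

  auto layer_at = [&](double y) {
    for (int l = 0; l < nl; ++l)
      if (y < boundaries[l + 1]) return l;
    return nl - 1;
  };

  for (int ip = 0; ip < n_photons; ++ip) {
    int isrc = ip % nsrc;
    double x = src_x[isrc] + (R::unif_rand() - 0.5) * src_diam;
    double y = eps;
    double ux = std::sin(tt), uy = std::cos(tt);
    double w = 1.0 - rsp;
    tal_rspec += rsp;
    bool in_vessel = false;
    int layer = 0;

    for (int step = 0; step < max_steps; ++step) {
      if (w <= 0.0) break;
      in_vessel = (vr > 0.0) &&
        ((x - vx) * (x - vx) + (y - vy) * (y - vy) <= vr * vr);
      layer = layer_at(y);
      Medium med;
      if (in_vessel) med = {v_mua, v_mus, v_g, l_n[layer]};
      else med = {l_mua[layer], l_mus[layer], l_g[layer], l_n[layer]};
      double mut = med.mua + med.mus;

      // geometric distance to the nearest boundary and its type
      // type: 0 up-interface, 1 down-interface, 2 side, 3 vessel wall
      double dbound = R_PosInf;
      int btype = -1;
      if (!in_vessel) {
        if (uy < 0.0) {
          double d = (boundaries[layer] - y) / uy;
          if (d < dbound) { dbound = d; btype = 0; }
        } else if (uy > 0.0) {
          double d = (boundaries[layer + 1] - y) / uy;
          if (d < dbound) { dbound = d; btype = 1; }
        }
        if (ux > 0.0) {
          double d = (xhalf - x) / ux;
          if (d < dbound) { dbound = d; btype = 2; }
        } else if (ux < 0.0) {
          double d = (-xhalf - x) / ux;
          if (d < dbound) { dbound = d; btype = 2; }
        }
        if (vr > 0.0) { // possible vessel entry
          double mx = x - vx, my = y - vy;
          double b = mx * ux + my * uy;
          double c = mx * mx + my * my - vr * vr;
          double disc = b * b - c;
          if (disc > 0.0 && b < 0.0) {
            double d = -b - std::sqrt(disc);
            if (d > eps && d < dbound) { dbound = d; btype = 3; }
          }
        }
      } else { // inside vessel: wall exit is the only boundary
        double mx = x - vx, my = y - vy;
        double b = mx * ux + my * uy;
        double c = mx * mx + my * my - vr * vr;
        double disc = b * b - c;
        double d = -b + std::sqrt(std::max(disc, 0.0));
        dbound = d; btype = 3;
      }

      double s = (mut > 0.0) ? -std::log(R::unif_rand()) / mut : R_PosInf;

      if (s < dbound) {           // interaction inside the medium
        x += s * ux; y += s * uy;
        double dw = w * med.mua / mut;
        if (dw > 0.0) { deposit(x, y, dw); w -= dw; }
        double ang = std::atan2(uy, ux) + hg_angle(med.g);
        ux = std::cos(ang); uy = std::sin(ang);
        if (w < weight_threshold) {  // roulette (energy-conserving form)
          if (R::unif_rand() >= p_survive) {
            deposit(x, y, w);
            w = 0.0;
            break;
          }
        }
      } else {                     // boundary hit
        x += dbound * ux; y += dbound * uy;
        if (btype == 2) { tal_side += w; w = 0.0; break; }
        if (btype == 0 && layer == 0) { tal_rdiff += w; w = 0.0; break; }
        if (btype == 1 && layer == nl - 1) {
          if (bottom_albedo > 0.0) {
            tal_t += w * (1.0 - bottom_albedo);
            w *= bottom_albedo;
            uy = -uy;
            y -= eps;
            continue;
          }
          tal_t += w; w = 0.0; break;
        }
        if (btype == 3) {          // vessel wall: index-matched, pass through
          x += eps * ux; y += eps * uy;
          continue;
        }
        // internal layer interface: Snell refraction, no partial reflection
        int lnew = (btype == 1) ? layer + 1 : layer - 1;
        double n1 = l_n[layer], n2 = l_n[lnew];
        if (n1 != n2) {
          double sn = ux * n1 / n2;
          if (std::fabs(sn) > 1.0) { // total internal reflection
            uy = -uy;
            y += eps * uy;
            continue;
          }
          ux = sn;
          double uy_sign = (uy >= 0.0) ? 1.0 : -1.0;
          uy = uy_sign * std::sqrt(std::max(0.0, 1.0 - ux * ux));
        }
        x += eps * ux; y += eps * uy;
      }
    }
    if (w > 0.0) deposit(x, y, w); // step-cap residual stays in the ledger
  }

  double nph = (double)n_photons;
  double total_a = 0.0;
  for (int j = 0; j < nx; ++j)
    for (int i = 0; i < ny; ++i) {
      amap(i, j) /= nph;
      total_a += amap(i, j);
    }

  return List::create(
    _["r_specular"] = tal_rspec / nph,
    _["r_diffuse"] = tal_rdiff / nph,
    _["transmittance"] = tal_t / nph,
    _["side_escape"] = tal_side / nph,
    _["absorbed"] = total_a,
    _["absorption_map"] = amap,
    _["grid_dx"] = grid_dx, _["grid_dy"] = grid_dy);
}
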