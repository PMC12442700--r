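// Euler-Maruyama integrators for the two-state run/tumble process.
// The 3D near-surface walk and the planar surface process share the same
// switching logic; both use a counter-based per-trajectory RNG so ensembles
// are reproducible and order-independent.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr int STATE_RUN = 0;
constexpr int STATE_TUMBLE = 1;

struct Rng {
  std::mt19937_64 eng;
  std::normal_distribution<double> norm;
  std::uniform_real_distribution<double> unif;

  Rng(int master_seed, int stream_id) : norm(0.0, 1.0), unif(0.0, 1.0) {
    std::seed_seq seq{master_seed, stream_id, 0x5f3759df};
    eng.seed(seq);
  }
  double normal() { return norm(eng); }
  double uniform() { return unif(eng); }
};

// Diffuse a unit vector in its local tangent plane with per-axis variance
// 2*D*dt, then renormalize (valid for D*dt << 1).
inline void tangent_diffuse(double& ex, double& ey, double& ez,
                            double D, double dt, Rng& rng) {
  if (D <= 0.0) return;
  // orthonormal tangent basis: pick the axis least aligned with e
  double ax = 0.0, ay = 0.0, az = 0.0;
  if (std::fabs(ex) <= std::fabs(ey) && std::fabs(ex) <= std::fabs(ez)) {
    ax = 1.0;
  } else if (std::fabs(ey) <= std::fabs(ez)) {
    ay = 1.0;
  } else {
    az = 1.0;
  }
  // u = normalize(a x e), v = e x u
  double ux = ay * ez - az * ey;
  double uy = az * ex - ax * ez;
  double uz = ax * ey - ay * ex;
  double un = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= un; uy /= un; uz /= un;
  double vx = ey * uz - ez * uy;
  double vy = ez * ux - ex * uz;
  double vz = ex * uy - ey * ux;
  double s = std::sqrt(2.0 * D * dt);
  double g1 = s * rng.normal();
  double g2 = s * rng.normal();
  ex += g1 * ux + g2 * vx;
  ey += g1 * uy + g2 * vy;
  ez += g1 * uz + g2 * vz;
  double n = std::sqrt(ex * ex + ey * ey + ez * ez);
  ex /= n; ey /= n; ez /= n;
}

} // namespace

// 3D near-surface trajectory. Starts on the surface at the origin and
// integrates until z first exceeds z_bulk (escape) or t reaches t_cap
// (censored). Every `record_every`-th step is retained, plus the final one.
//
// Returns a list: matrix `samples` with columns
// t, x, y, z, ex, ey, ez, theta, state, surface_bound; `stop_reason`
// ("escape" | "censored"); `stop_time`.
// [[Rcpp::export(.sim_trajectory_cpp)]]
List sim_trajectory_cpp(double tb, double V, double Dt, double Dr,
                        double Dtheta, double kRT, double kTR,
                        double R, double z_bulk, double dt, double t_cap,
                        int record_every, int seed, int stream_id,
                        double handedness = 1.0) {
  Rng rng(seed, stream_id);

  const double Omega = V / R;          // angular speed of surface circling
  const long n_steps = (long)std::ceil(t_cap / dt);
  const long n_rec_max = n_steps / record_every + 3;

  NumericMatrix out(n_rec_max, 10);
  long n_rec = 0;

  double x = 0.0, y = 0.0, z = 0.0;
  double theta = 2.0 * M_PI * rng.uniform();
  int state = (rng.uniform() < tb) ? STATE_TUMBLE : STATE_RUN;
  bool bound = (state == STATE_RUN);   // tumbles are never surface-bound
  double ex = std::cos(theta), ey = std::sin(theta), ez = 0.0;

  const double p_rt = kRT * dt;
  const double p_tr = kTR * dt;
  const double s_t = std::sqrt(2.0 * Dt * dt);

  auto record = [&](double t) {
    out(n_rec, 0) = t;  out(n_rec, 1) = x;  out(n_rec, 2) = y;
    out(n_rec, 3) = z;  out(n_rec, 4) = ex; out(n_rec, 5) = ey;
    out(n_rec, 6) = ez; out(n_rec, 7) = theta;
    out(n_rec, 8) = state; out(n_rec, 9) = bound ? 1.0 : 0.0;
    ++n_rec;
  };

  auto align_to_surface = [&]() {
    z = 0.0;
    bound = true;
    double lat = std::sqrt(ex * ex + ey * ey);
    if (lat > 1e-12) {
      theta = std::atan2(ey, ex);
    } else {
      theta = 2.0 * M_PI * rng.uniform();
    }
    ex = std::cos(theta); ey = std::sin(theta); ez = 0.0;
  };

  record(0.0);

  std::string stop_reason = "censored";
  double stop_time = t_cap;

  for (long i = 1; i <= n_steps; ++i) {
    // state switching (per-step Bernoulli, prob = rate * dt)
    if (state == STATE_RUN) {
      if (p_rt > 0.0 && rng.uniform() < p_rt) {
        state = STATE_TUMBLE;
        bound = false;              // a tumble releases the cell
      }
    } else {
      if (p_tr > 0.0 && rng.uniform() < p_tr) {
        state = STATE_RUN;
        if (z <= 0.0) align_to_surface();
      }
    }

    if (state == STATE_RUN) {
      if (bound) {
        // clockwise circling on the plane, azimuthal rotational diffusion
        theta += handedness * (-Omega) * dt
               + std::sqrt(2.0 * Dr * dt) * rng.normal();
        ex = std::cos(theta); ey = std::sin(theta); ez = 0.0;
        x += V * ex * dt;
        y += V * ey * dt;
      } else {
        // bulk run: ballistic along e with rotational diffusion
        x += V * ex * dt;
        y += V * ey * dt;
        z += V * ez * dt;
        tangent_diffuse(ex, ey, ez, Dr, dt, rng);
        if (z <= 0.0) align_to_surface();
      }
    } else {
      // tumble: translational Brownian motion, z reflected at the wall,
      // fast orientational diffusion
      x += s_t * rng.normal();
      y += s_t * rng.normal();
      z = std::fabs(z + s_t * rng.normal());
      tangent_diffuse(ex, ey, ez, Dtheta, dt, rng);
      theta = std::atan2(ey, ex);
    }

    double t = i * dt;
    bool last = (i == n_steps);
    if (z > z_bulk) {
      record(t);
      stop_reason = "escape";
      stop_time = t;
      break;
    }
    if (i % record_every == 0 || last) record(t);
  }

  return List::create(
    _["samples"] = out(Range(0, n_rec - 1), Range(0, 9)),
    _["stop_reason"] = stop_reason,
    _["stop_time"] = stop_time);
}

// Strictly planar surface process: perpetual circling runs and planar
// diffusive tumbles, no z coordinate and no escape. Used as the stochastic
// counterpart of the planar Fokker-Planck description.
//
// Returns matrix with columns t, x, y, theta, state.
// [[Rcpp::export(.sim_surface_cpp)]]
NumericMatrix sim_surface_cpp(double tb, double V, double Dt, double Dr,
                              double Dtheta, double kRT, double kTR,
                              double R, double dt, double duration,
                              int record_every, int seed, int stream_id,
                              double handedness = 1.0) {
  Rng rng(seed, stream_id);

  const double Omega = V / R;
  const long n_steps = (long)std::ceil(duration / dt);
  const long n_rec_max = n_steps / record_every + 3;

  NumericMatrix out(n_rec_max, 5);
  long n_rec = 0;

  double x = 0.0, y = 0.0;
  double theta = 2.0 * M_PI * rng.uniform();
  int state = (rng.uniform() < tb) ? STATE_TUMBLE : STATE_RUN;

  const double p_rt = kRT * dt;
  const double p_tr = kTR * dt;
  const double s_t = std::sqrt(2.0 * Dt * dt);
  const double s_r = std::sqrt(2.0 * Dr * dt);
  const double s_th = std::sqrt(2.0 * Dtheta * dt);

  auto record = [&](double t) {
    out(n_rec, 0) = t; out(n_rec, 1) = x; out(n_rec, 2) = y;
    out(n_rec, 3) = theta; out(n_rec, 4) = state;
    ++n_rec;
  };

  record(0.0);
  for (long i = 1; i <= n_steps; ++i) {
    if (state == STATE_RUN) {
      if (p_rt > 0.0 && rng.uniform() < p_rt) state = STATE_TUMBLE;
    } else {
      if (p_tr > 0.0 && rng.uniform() < p_tr) state = STATE_RUN;
    }
    if (state == STATE_RUN) {
      theta += handedness * (-Omega) * dt + s_r * rng.normal();
      x += V * std::cos(theta) * dt;
      y += V * std::sin(theta) * dt;
    } else {
      x += s_t * rng.normal();
      y += s_t * rng.normal();
      theta += s_th * rng.normal();
    }
    if (i % record_every == 0 || i == n_steps) record(i * dt);
  }

  return out(Range(0, n_rec - 1), Range(0, 4));
}
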