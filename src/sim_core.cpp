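// Fixed-step semi-implicit Euler integrator for an articulated ellipsoid
// pedestrian struck by a prescribed-motion zoned vehicle front, with ground
// contact, penalty joints, and regularized Coulomb friction.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
};
inline Vec3 operator+(const Vec3& a, const Vec3& b) { return Vec3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator-(const Vec3& a, const Vec3& b) { return Vec3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator*(double s, const Vec3& a) { return Vec3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Quat {
  double w, x, y, z;
  Quat() : w(1), x(0), y(0), z(0) {}
  Quat(double w_, double x_, double y_, double z_) : w(w_), x(x_), y(y_), z(z_) {}
};
inline Quat qmul(const Quat& a, const Quat& b) {
  return Quat(a.w * b.w - a.x * b.x - a.y * b.y - a.z * b.z,
              a.w * b.x + a.x * b.w + a.y * b.z - a.z * b.y,
              a.w * b.y - a.x * b.z + a.y * b.w + a.z * b.x,
              a.w * b.z + a.x * b.y - a.y * b.x + a.z * b.w);
}
inline Quat qconj(const Quat& q) { return Quat(q.w, -q.x, -q.y, -q.z); }
inline void qnormalize(Quat& q) {
  double n = std::sqrt(q.w * q.w + q.x * q.x + q.y * q.y + q.z * q.z);
  if (n > 0) { q.w /= n; q.x /= n; q.y /= n; q.z /= n; }
}
// rotate body-frame vector into world frame
inline Vec3 qrot(const Quat& q, const Vec3& v) {
  // v' = v + 2*q_vec x (q_vec x v + w*v)
  Vec3 u(q.x, q.y, q.z);
  Vec3 t = cross(u, v);
  t = Vec3(t.x + q.w * v.x, t.y + q.w * v.y, t.z + q.w * v.z);
  Vec3 c = cross(u, t);
  return Vec3(v.x + 2 * c.x, v.y + 2 * c.y, v.z + 2 * c.z);
}
inline Vec3 qrotT(const Quat& q, const Vec3& v) { return qrot(qconj(q), v); }
// rotation vector (axis*angle) of a unit quaternion
inline Vec3 qlog(const Quat& q0) {
  Quat q = q0;
  if (q.w < 0) { q.w = -q.w; q.x = -q.x; q.y = -q.y; q.z = -q.z; }
  double vn = std::sqrt(q.x * q.x + q.y * q.y + q.z * q.z);
  if (vn < 1e-12) return Vec3(0, 0, 0);
  double ang = 2.0 * std::atan2(vn, q.w);
  double s = ang / vn;
  return Vec3(s * q.x, s * q.y, s * q.z);
}

struct Body {
  double m;
  Vec3 I;       // body-frame principal inertia
  Vec3 semi;    // ellipsoid semi-axes
  Vec3 pos, vel;
  Quat q;
  Vec3 wb;      // angular velocity, body frame
  Vec3 force;   // accumulated non-gravity force (world)
  Vec3 torque;  // accumulated torque (world)
};

struct Joint {
  int parent, child;     // 0-based
  Vec3 rp, rc;           // anchors, local frames
  Quat qrel0;            // rest relative rotation parent->child
  double krot, crot, stop, krot_max, ktrans, ctrans;
};

struct Patch {
  double x0, z0, x1, z1;  // vehicle-frame polyline segment (x forward, z up)
  int zone;               // 0-based zone index
  Vec3 n;                 // outward unit normal (vehicle frame = world frame)
};

struct Zone {
  std::vector<double> defl, force;  // piecewise-linear knots, F(0)=0
  double damping;
};

inline double zone_force(const Zone& zn, double pen) {
  if (pen <= 0) return 0.0;
  const std::vector<double>& d = zn.defl;
  const std::vector<double>& f = zn.force;
  size_t k = d.size();
  if (pen >= d[k - 1]) {  // extrapolate with last slope
    double slope = (k >= 2) ? (f[k - 1] - f[k - 2]) / (d[k - 1] - d[k - 2]) : 0.0;
    return f[k - 1] + slope * (pen - d[k - 1]);
  }
  size_t i = 1;
  while (i < k && d[i] < pen) ++i;
  double t = (pen - d[i - 1]) / (d[i] - d[i - 1]);
  return f[i - 1] + t * (f[i] - f[i - 1]);
}

// ellipsoid support distance along unit direction n (world), for orientation q
inline double support_dist(const Vec3& semi, const Quat& q, const Vec3& n) {
  Vec3 nb = qrotT(q, n);
  Vec3 s(semi.x * nb.x, semi.y * nb.y, semi.z * nb.z);
  return norm(s);
}
// world point on the ellipsoid surface extremal against direction -n
inline Vec3 support_point(const Vec3& pos, const Vec3& semi, const Quat& q, const Vec3& n, double h) {
  Vec3 nb = qrotT(q, n);
  Vec3 sb(semi.x * semi.x * nb.x, semi.y * semi.y * nb.y, semi.z * semi.z * nb.z);
  Vec3 pw = qrot(q, sb);
  return pos - (1.0 / h) * pw;
}

struct ContactTracker {
  bool active = false;
  double t_first = NA_REAL, peak = 0.0;
  Vec3 p_first;
};

}  // namespace

// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List bodies_in, List joints_in, List vehicle_in, List env_in,
             double dt, double t_end, int out_stride,
             int head_idx, int femur_idx, bool record_forces) {
  // ---- unpack bodies ----
  NumericVector mass = bodies_in["mass"];
  NumericMatrix inert = bodies_in["inertia"], semi = bodies_in["semi"],
      pos0 = bodies_in["pos"], quat0 = bodies_in["quat"],
      vel0 = bodies_in["vel"], angvel0 = bodies_in["angvel"];
  int nb = mass.size();
  std::vector<Body> B(nb);
  for (int i = 0; i < nb; ++i) {
    B[i].m = mass[i];
    B[i].I = Vec3(inert(i, 0), inert(i, 1), inert(i, 2));
    B[i].semi = Vec3(semi(i, 0), semi(i, 1), semi(i, 2));
    B[i].pos = Vec3(pos0(i, 0), pos0(i, 1), pos0(i, 2));
    B[i].q = Quat(quat0(i, 0), quat0(i, 1), quat0(i, 2), quat0(i, 3));
    B[i].vel = Vec3(vel0(i, 0), vel0(i, 1), vel0(i, 2));
    B[i].wb = Vec3(angvel0(i, 0), angvel0(i, 1), angvel0(i, 2));
  }

  // ---- joints ----
  std::vector<Joint> J;
  if (joints_in.size() > 0 && Rf_length(joints_in["parent"]) > 0) {
    IntegerVector jp = joints_in["parent"], jc = joints_in["child"];
    NumericMatrix ap = joints_in["anchor_parent"], ac = joints_in["anchor_child"],
        qr = joints_in["qrel0"];
    NumericVector krot = joints_in["krot"], crot = joints_in["crot"],
        stop = joints_in["stop"], krotmax = joints_in["krot_max"],
        ktr = joints_in["ktrans"], ctr = joints_in["ctrans"];
    for (int j = 0; j < jp.size(); ++j) {
      Joint jt;
      jt.parent = jp[j] - 1; jt.child = jc[j] - 1;
      jt.rp = Vec3(ap(j, 0), ap(j, 1), ap(j, 2));
      jt.rc = Vec3(ac(j, 0), ac(j, 1), ac(j, 2));
      jt.qrel0 = Quat(qr(j, 0), qr(j, 1), qr(j, 2), qr(j, 3));
      jt.krot = krot[j]; jt.crot = crot[j]; jt.stop = stop[j];
      jt.krot_max = krotmax[j];
      jt.ktrans = ktr[j]; jt.ctrans = ctr[j];
      J.push_back(jt);
    }
  }

  // ---- vehicle ----
  bool has_vehicle = as<bool>(vehicle_in["present"]);
  std::vector<Patch> patches;
  std::vector<Zone> zones;
  double veh_x0 = 0, veh_speed = 0, veh_decel = 0, veh_tbrake = 0, veh_halfw = 0;
  if (has_vehicle) {
    NumericMatrix pp = vehicle_in["patches"];  // cols: x0 z0 x1 z1 zone(1-based)
    for (int i = 0; i < pp.nrow(); ++i) {
      Patch p;
      p.x0 = pp(i, 0); p.z0 = pp(i, 1); p.x1 = pp(i, 2); p.z1 = pp(i, 3);
      p.zone = (int)pp(i, 4) - 1;
      double dx = p.x1 - p.x0, dz = p.z1 - p.z0;
      double L = std::sqrt(dx * dx + dz * dz);
      p.n = Vec3(dz / L, 0.0, -dx / L);
      if (p.n.x < 0) { p.n.x = -p.n.x; p.n.z = -p.n.z; }  // outward = forward
      patches.push_back(p);
    }
    List zl = vehicle_in["zones"];
    for (int i = 0; i < zl.size(); ++i) {
      List z = zl[i];
      NumericMatrix curve = z["curve"];
      Zone zn;
      for (int r = 0; r < curve.nrow(); ++r) {
        zn.defl.push_back(curve(r, 0));
        zn.force.push_back(curve(r, 1));
      }
      zn.damping = as<double>(z["damping"]);
      zones.push_back(zn);
    }
    veh_x0 = as<double>(vehicle_in["x0"]);
    veh_speed = as<double>(vehicle_in["speed"]);
    veh_decel = as<double>(vehicle_in["decel"]);
    veh_tbrake = as<double>(vehicle_in["t_brake"]);
    veh_halfw = as<double>(vehicle_in["half_width"]);
  }

  // ---- environment ----
  double grav = as<double>(env_in["g"]);
  double mu_pg = as<double>(env_in["mu_ped_ground"]);
  double mu_pv = as<double>(env_in["mu_ped_vehicle"]);
  double k_ground = as<double>(env_in["k_ground"]);
  double c_ground = as<double>(env_in["c_ground"]);
  const double v_reg = 0.05;  // tanh slip-velocity regularization, m/s

  int n_steps = (int)std::llround(t_end / dt);
  int n_out = n_steps / out_stride + 1;
  int n_surf = (int)patches.size() + 1;  // last index = ground

  NumericVector out_t(n_out), head_acc(n_out), femur_f(n_out), veh_x_out(n_out);
  NumericMatrix out_pos(n_out, nb * 3), out_quat(n_out, nb * 4);
  NumericMatrix out_vel(n_out, nb * 3), out_angvel(n_out, nb * 3);
  // per (body, surface-kind) trackers; surfaces: zones collapse to zone id for
  // event naming, but track per patch then merge by (body, zone) in R? Simpler:
  // track per (body, zone-or-ground).
  int n_zone = has_vehicle ? (int)zones.size() : 0;
  int n_track = n_zone + 1;
  std::vector<ContactTracker> trk(nb * n_track);
  std::vector<std::vector<double>> events;  // time, body, surf, x,y,z, peak (filled at end)

  std::vector<double> flog;  // time, body, surf, fn, ft  (record_forces)

  int status = 0, blow_step = -1;
  int out_i = 0;

  for (int step = 0; step <= n_steps; ++step) {
    double t = step * dt;
    double veh_x = veh_x0, veh_v = 0;
    if (has_vehicle) {
      if (t <= veh_tbrake || veh_decel <= 0) {
        veh_x = veh_x0 + veh_speed * t;
        veh_v = veh_speed;
      } else {
        double tb = t - veh_tbrake;
        double t_stop = veh_speed / veh_decel;
        if (tb >= t_stop) {
          veh_x = veh_x0 + veh_speed * veh_tbrake + veh_speed * t_stop - 0.5 * veh_decel * t_stop * t_stop;
          veh_v = 0;
        } else {
          veh_x = veh_x0 + veh_speed * veh_tbrake + veh_speed * tb - 0.5 * veh_decel * tb * tb;
          veh_v = veh_speed - veh_decel * tb;
        }
      }
    }

    // zero accumulators
    for (int i = 0; i < nb; ++i) { B[i].force = Vec3(); B[i].torque = Vec3(); }

    // ---- joints ----
    for (size_t j = 0; j < J.size(); ++j) {
      const Joint& jt = J[j];
      Body& P = B[jt.parent];
      Body& C = B[jt.child];
      Vec3 rpw = qrot(P.q, jt.rp), rcw = qrot(C.q, jt.rc);
      Vec3 ap = P.pos + rpw, ac = C.pos + rcw;
      Vec3 wp = qrot(P.q, P.wb), wc = qrot(C.q, C.wb);
      Vec3 vap = P.vel + cross(wp, rpw), vac = C.vel + cross(wc, rcw);
      Vec3 F = jt.ktrans * (ap - ac) + jt.ctrans * (vap - vac);
      C.force = C.force + F;
      C.torque = C.torque + cross(rcw, F);
      P.force = P.force - F;
      P.torque = P.torque - cross(rpw, F);
      // rotational spring toward rest relative orientation
      Quat qrel = qmul(qconj(P.q), C.q);
      Quat qerr = qmul(qconj(jt.qrel0), qrel);
      Vec3 phi = qlog(qerr);  // in parent-at-rest child frame; treat via parent frame
      double ang = norm(phi);
      double kx = jt.krot;
      if (ang > jt.stop && ang > 1e-12)
        kx = std::min(kx + 20.0 * jt.krot * (ang - jt.stop) / ang,
                      std::max(jt.krot, jt.krot_max));
      Vec3 tau_loc = Vec3(-kx * phi.x, -kx * phi.y, -kx * phi.z);
      Vec3 tau = qrot(P.q, tau_loc) - jt.crot * (wc - wp);
      C.torque = C.torque + tau;
      P.torque = P.torque - tau;
    }

    // ---- contacts ----
    std::vector<bool> touched(nb * n_track, false);
    for (int i = 0; i < nb; ++i) {
      Body& b = B[i];
      // ground (z = 0, normal +z)
      {
        Vec3 n(0, 0, 1);
        double h = support_dist(b.semi, b.q, n);
        double pen = h - b.pos.z;
        if (pen > 0) {
          Vec3 cp = support_point(b.pos, b.semi, b.q, n, h);
          Vec3 r = cp - b.pos;
          Vec3 w = qrot(b.q, b.wb);
          Vec3 vcp = b.vel + cross(w, r);
          double vn = dot(vcp, n);
          double fn = k_ground * pen - c_ground * vn;
          if (fn > 0) {
            Vec3 vt = vcp - vn * n;
            double vtn = norm(vt);
            Vec3 Ff(0, 0, 0);
            if (vtn > 1e-12) {
              double fmag = mu_pg * fn * std::tanh(vtn / v_reg);
              Ff = (-fmag / vtn) * vt;
            }
            Vec3 F = fn * n + Ff;
            b.force = b.force + F;
            b.torque = b.torque + cross(r, F);
            int ti = i * n_track + n_zone;  // ground slot
            touched[ti] = true;
            ContactTracker& tr = trk[ti];
            if (!tr.active) { tr.active = true; tr.t_first = t; tr.p_first = cp; tr.peak = fn;
              events.push_back({t, (double)i, (double)n_zone, cp.x, cp.y, cp.z, fn, 1.0});
            }
            if (fn > tr.peak) tr.peak = fn;
            if (!events.empty()) {
              // update peak of the most recent open event for this pair
              for (int e = (int)events.size() - 1; e >= 0; --e)
                if ((int)events[e][1] == i && (int)events[e][2] == n_zone && events[e][7] > 0) {
                  if (fn > events[e][6]) events[e][6] = fn;
                  break;
                }
            }
            if (record_forces && (step % out_stride == 0)) {
              flog.push_back(t); flog.push_back(i); flog.push_back(n_zone);
              flog.push_back(fn); flog.push_back(norm(Ff)); flog.push_back(mu_pg);
            }
          }
        }
      }
      // vehicle patches
      if (has_vehicle) {
        for (size_t pidx = 0; pidx < patches.size(); ++pidx) {
          const Patch& p = patches[pidx];
          Vec3 n = p.n;
          double h = support_dist(b.semi, b.q, n);
          // plane point in world
          Vec3 p0(p.x0 + veh_x, 0.0, p.z0);
          double s = dot(b.pos - p0, n);
          double pen = h - s;
          if (pen <= 0 || pen > 0.6) continue;
          Vec3 cp = support_point(b.pos, b.semi, b.q, n, h);
          // patch bounds check in vehicle frame
          double cx = cp.x - veh_x, cz = cp.z;
          double dx = p.x1 - p.x0, dz = p.z1 - p.z0;
          double L2 = dx * dx + dz * dz;
          double tt = ((cx - p.x0) * dx + (cz - p.z0) * dz) / L2;
          if (tt < -0.08 || tt > 1.08) continue;
          if (std::fabs(cp.y) > veh_halfw) continue;
          const Zone& zn = zones[p.zone];
          Vec3 r = cp - b.pos;
          Vec3 w = qrot(b.q, b.wb);
          Vec3 vcp = b.vel + cross(w, r);
          Vec3 vrel = vcp - Vec3(veh_v, 0, 0);
          double vn = dot(vrel, n);
          double fn = zone_force(zn, pen) - zn.damping * vn;
          if (fn <= 0) continue;
          Vec3 vt = vrel - vn * n;
          double vtn = norm(vt);
          Vec3 Ff(0, 0, 0);
          if (vtn > 1e-12) {
            double fmag = mu_pv * fn * std::tanh(vtn / v_reg);
            Ff = (-fmag / vtn) * vt;
          }
          Vec3 F = fn * n + Ff;
          b.force = b.force + F;
          b.torque = b.torque + cross(r, F);
          int ti = i * n_track + p.zone;
          touched[ti] = true;
          ContactTracker& tr = trk[ti];
          if (!tr.active) { tr.active = true; tr.t_first = t; tr.p_first = cp; tr.peak = fn;
            events.push_back({t, (double)i, (double)p.zone, cp.x, cp.y, cp.z, fn, 1.0});
          }
          if (fn > tr.peak) tr.peak = fn;
          for (int e = (int)events.size() - 1; e >= 0; --e)
            if ((int)events[e][1] == i && (int)events[e][2] == p.zone && events[e][7] > 0) {
              if (fn > events[e][6]) events[e][6] = fn;
              break;
            }
          if (record_forces && (step % out_stride == 0)) {
            flog.push_back(t); flog.push_back(i); flog.push_back(p.zone);
            flog.push_back(fn); flog.push_back(norm(Ff)); flog.push_back(mu_pv);
          }
        }
      }
    }
    // close contact episodes that lost touch this step
    for (int k = 0; k < nb * n_track; ++k) {
      if (trk[k].active && !touched[k]) {
        trk[k].active = false;
        // mark most recent open event closed
        int bi = k / n_track, si = k % n_track;
        for (int e = (int)events.size() - 1; e >= 0; --e)
          if ((int)events[e][1] == bi && (int)events[e][2] == si && events[e][7] > 0) {
            events[e][7] = 0.0;
            break;
          }
      }
    }

    // ---- record output ----
    if (step % out_stride == 0) {
      out_t[out_i] = t;
      veh_x_out[out_i] = veh_x;
      for (int i = 0; i < nb; ++i) {
        out_pos(out_i, i * 3 + 0) = B[i].pos.x;
        out_pos(out_i, i * 3 + 1) = B[i].pos.y;
        out_pos(out_i, i * 3 + 2) = B[i].pos.z;
        out_quat(out_i, i * 4 + 0) = B[i].q.w;
        out_quat(out_i, i * 4 + 1) = B[i].q.x;
        out_quat(out_i, i * 4 + 2) = B[i].q.y;
        out_quat(out_i, i * 4 + 3) = B[i].q.z;
        out_vel(out_i, i * 3 + 0) = B[i].vel.x;
        out_vel(out_i, i * 3 + 1) = B[i].vel.y;
        out_vel(out_i, i * 3 + 2) = B[i].vel.z;
        out_angvel(out_i, i * 3 + 0) = B[i].wb.x;
        out_angvel(out_i, i * 3 + 1) = B[i].wb.y;
        out_angvel(out_i, i * 3 + 2) = B[i].wb.z;
      }
      head_acc[out_i] = norm(B[head_idx - 1].force) / B[head_idx - 1].m / 9.81;
      if (femur_idx >= 1) {
        Vec3 axis = qrot(B[femur_idx - 1].q, Vec3(0, 0, 1));
        femur_f[out_i] = std::fabs(dot(B[femur_idx - 1].force, axis));
      }
      ++out_i;
    }

    if (step == n_steps) break;

    // ---- integrate (semi-implicit Euler) ----
    bool blew = false;
    for (int i = 0; i < nb; ++i) {
      Body& b = B[i];
      Vec3 a = Vec3(b.force.x / b.m, b.force.y / b.m, b.force.z / b.m - grav);
      b.vel = b.vel + dt * a;
      b.pos = b.pos + dt * b.vel;
      Vec3 tb = qrotT(b.q, b.torque);
      Vec3 Iw(b.I.x * b.wb.x, b.I.y * b.wb.y, b.I.z * b.wb.z);
      Vec3 gy = cross(b.wb, Iw);
      Vec3 wd((tb.x - gy.x) / b.I.x, (tb.y - gy.y) / b.I.y, (tb.z - gy.z) / b.I.z);
      b.wb = b.wb + dt * wd;
      // exact rotation over the step: q <- q * exp(dt/2 * omega_body)
      double wn = norm(b.wb);
      if (wn > 1e-14) {
        double half = 0.5 * dt * wn;
        double sc = std::sin(half) / wn;
        Quat dq(std::cos(half), sc * b.wb.x, sc * b.wb.y, sc * b.wb.z);
        b.q = qmul(b.q, dq);
        qnormalize(b.q);
      }
      if (!std::isfinite(b.pos.x) || !std::isfinite(b.pos.y) || !std::isfinite(b.pos.z) ||
          std::fabs(b.pos.x) > 1e3 || std::fabs(b.pos.y) > 1e3 || std::fabs(b.pos.z) > 1e3)
        blew = true;
    }
    if (blew) { status = 1; blow_step = step + 1; break; }
  }

  if (status == 1 && out_i < n_out) {
    // truncate outputs to what was recorded
    out_t = out_t[Range(0, std::max(out_i - 1, 0))];
    head_acc = head_acc[Range(0, std::max(out_i - 1, 0))];
    femur_f = femur_f[Range(0, std::max(out_i - 1, 0))];
    veh_x_out = veh_x_out[Range(0, std::max(out_i - 1, 0))];
    out_pos = out_pos(Range(0, std::max(out_i - 1, 0)), _);
    out_quat = out_quat(Range(0, std::max(out_i - 1, 0)), _);
    out_vel = out_vel(Range(0, std::max(out_i - 1, 0)), _);
    out_angvel = out_angvel(Range(0, std::max(out_i - 1, 0)), _);
  }

  NumericMatrix ev((int)events.size(), 7);
  for (size_t e = 0; e < events.size(); ++e)
    for (int c = 0; c < 7; ++c) ev((int)e, c) = events[e][c];
  colnames(ev) = CharacterVector::create("time", "body", "surface", "x", "y", "z", "peak_force");

  NumericMatrix fl(record_forces ? (int)flog.size() / 6 : 0, 6);
  if (record_forces) {
    for (int r = 0; r < fl.nrow(); ++r)
      for (int c = 0; c < 6; ++c) fl(r, c) = flog[r * 6 + c];
    colnames(fl) = CharacterVector::create("time", "body", "surface", "fn", "ft", "mu");
  }

  return List::create(
      _["time"] = out_t, _["pos"] = out_pos, _["quat"] = out_quat,
      _["vel"] = out_vel, _["angvel"] = out_angvel,
      _["head_accel"] = head_acc, _["femur_force"] = femur_f,
      _["vehicle_x"] = veh_x_out, _["events"] = ev, _["force_log"] = fl,
      _["status"] = status, _["blow_step"] = blow_step,
      _["n_steps"] = n_steps, _["t_final"] = out_t[out_t.size() - 1]);
}
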