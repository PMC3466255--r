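// Event-driven discrete molecular dynamics on stepwise pair potentials.
//
// Atoms move ballistically between events; at a shell crossing the pair's
// velocities change by energy/momentum conservation (reflection when the
// radial kinetic energy cannot pay the step, elastic reflection at infinite
// walls). An Andersen thermostat hits each free atom as a Poisson process,
// resampling its velocity from the Maxwell-Boltzmann distribution. Frozen
// atoms never move. Positions are stored per-atom with a local time stamp
// and extrapolated analytically, so conservation is exact to rounding.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <random>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Event {
  double time;
  int kind;      // 0 = pair, 1 = ghost
  int idx;       // pair index or atom index
  long seq;      // validity stamp
};
struct EventCompare {
  bool operator()(const Event& a, const Event& b) const {
    return a.time > b.time;
  }
};

class DMDEngine {
public:
  int n;
  std::vector<double> px, py, pz, vx, vy, vz, tat, mass;
  std::vector<bool> frozen;

  // pair tables
  int np;
  std::vector<int> pi, pj;
  std::vector<int> roff;          // np+1 offsets into radii
  std::vector<double> radii;      // concatenated shell radii (increasing)
  std::vector<int> eoff;          // np+1 offsets into energies (= roff + pair idx)
  std::vector<double> energies;   // per region, shells+1 per pair
  std::vector<int> region;        // current region per pair
  std::vector<long> pseq;
  std::vector<std::vector<int>> pairs_of_atom;

  // constraints bookkeeping
  std::vector<int> cons_pair;     // indices of constraint pairs
  std::vector<double> cons_target;
  std::vector<double> cons_maxdev;

  double T, rate, t_now, U_total;
  std::vector<long> gseq;
  std::priority_queue<Event, std::vector<Event>, EventCompare> heap;
  std::mt19937_64 rng;
  bool track_energy;
  double E0, max_drift;
  long long n_events;
  bool have_spare;
  double spare;

  double runif01() {
    return (rng() >> 11) * (1.0 / 9007199254740992.0);
  }
  double rnorm01() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = 0.0, u2;
    while (u1 <= 0.0) u1 = runif01();
    u2 = runif01();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
  double rexp1(double lambda) {
    double u = 0.0;
    while (u <= 0.0) u = runif01();
    return -std::log(u) / lambda;
  }

  void advance_atom(int i, double t) {
    if (frozen[i]) { tat[i] = t; return; }
    double dt = t - tat[i];
    px[i] += vx[i] * dt; py[i] += vy[i] * dt; pz[i] += vz[i] * dt;
    tat[i] = t;
  }

  inline void rel_state(int p, double t, double dr[3], double dv[3]) const {
    int i = pi[p], j = pj[p];
    double dti = t - tat[i], dtj = t - tat[j];
    dr[0] = (px[i] + vx[i] * dti) - (px[j] + vx[j] * dtj);
    dr[1] = (py[i] + vy[i] * dti) - (py[j] + vy[j] * dtj);
    dr[2] = (pz[i] + vz[i] * dti) - (pz[j] + vz[j] * dtj);
    dv[0] = vx[i] - vx[j]; dv[1] = vy[i] - vy[j]; dv[2] = vz[i] - vz[j];
  }

  // predict and push the next event for pair p, measured from time t
  void predict_pair(int p, double t) {
    ++pseq[p];
    double dr[3], dv[3];
    rel_state(p, t, dr, dv);
    double v2 = dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2];
    if (v2 <= 0.0) return;
    double b = dr[0]*dv[0] + dr[1]*dv[1] + dr[2]*dv[2];
    double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
    int k = region[p];
    int nsh = roff[p + 1] - roff[p];
    double s_best = INF;
    // outer boundary
    if (k < nsh) {
      double R = radii[roff[p] + k];
      double c = r2 - R * R;
      double disc = b * b - v2 * c;
      if (disc >= 0.0) {
        double s = (-b + std::sqrt(disc)) / v2;
        if (s >= 0.0 && s < s_best) s_best = s;
      }
    }
    // inner boundary (only when approaching)
    if (k > 0 && b < 0.0) {
      double R = radii[roff[p] + k - 1];
      double c = r2 - R * R;
      double disc = b * b - v2 * c;
      if (disc > 0.0) {
        double s = (-b - std::sqrt(disc)) / v2;
        if (s < 0.0) s = 0.0;
        if (s < s_best) s_best = s;
      }
    }
    if (s_best < INF) {
      heap.push({t + s_best, 0, p, pseq[p]});
    }
  }

  void refresh_atom_pairs(int i, double t) {
    for (int p : pairs_of_atom[i]) predict_pair(p, t);
  }

  double kinetic_energy() const {
    double ke = 0.0;
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      ke += 0.5 * mass[i] * (vx[i]*vx[i] + vy[i]*vy[i] + vz[i]*vz[i]);
    }
    return ke;
  }

  void process_pair_event(int p) {
    int i = pi[p], j = pj[p];
    advance_atom(i, t_now);
    advance_atom(j, t_now);
    double dr[3], dv[3];
    rel_state(p, t_now, dr, dv);
    double r2 = dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2];
    double r = std::sqrt(r2);
    if (r <= 0.0) return;  // degenerate; re-predict below
    double nh[3] = {dr[0]/r, dr[1]/r, dr[2]/r};
    double vr = dv[0]*nh[0] + dv[1]*nh[1] + dv[2]*nh[2];
    int k = region[p];
    int nsh = roff[p + 1] - roff[p];

    // which boundary: nearest shell radius to r
    int boundary = -1;  // index into radii
    double best = INF;
    if (k < nsh) {
      double d = std::fabs(r - radii[roff[p] + k]);
      if (d < best) { best = d; boundary = k; }
    }
    if (k > 0) {
      double d = std::fabs(r - radii[roff[p] + k - 1]);
      if (d < best) { best = d; boundary = k - 1; }
    }
    if (boundary < 0) { predict_pair(p, t_now); return; }
    bool outward = (boundary == k);
    int knew = outward ? k + 1 : k - 1;
    // moving direction must match; if not, stale event - just re-predict
    if ((outward && vr <= 0.0) || (!outward && vr >= 0.0)) {
      predict_pair(p, t_now);
      refresh_atom_pairs(i, t_now);
      refresh_atom_pairs(j, t_now);
      return;
    }
    double Uold = energies[eoff[p] + k];
    double Unew = energies[eoff[p] + knew];
    double dU = Unew - Uold;
    double mu;
    if (frozen[i]) mu = mass[j];
    else if (frozen[j]) mu = mass[i];
    else mu = mass[i] * mass[j] / (mass[i] + mass[j]);

    double vr_new;
    bool transmit;
    if (!std::isfinite(dU)) {
      transmit = false;
    } else if (dU <= 0.0) {
      transmit = true;
    } else {
      transmit = (0.5 * mu * vr * vr > dU);
    }
    if (transmit) {
      double s = vr * vr - 2.0 * dU / mu;
      vr_new = (vr > 0 ? 1.0 : -1.0) * std::sqrt(s > 0 ? s : 0);
      region[p] = knew;
      U_total += dU;
    } else {
      vr_new = -vr;
    }
    double lambda = mu * (vr_new - vr);
    if (!frozen[i]) {
      vx[i] += lambda / mass[i] * nh[0];
      vy[i] += lambda / mass[i] * nh[1];
      vz[i] += lambda / mass[i] * nh[2];
    }
    if (!frozen[j]) {
      vx[j] -= lambda / mass[j] * nh[0];
      vy[j] -= lambda / mass[j] * nh[1];
      vz[j] -= lambda / mass[j] * nh[2];
    }
    refresh_atom_pairs(i, t_now);
    refresh_atom_pairs(j, t_now);
  }

  void process_ghost(int i) {
    advance_atom(i, t_now);
    double s = std::sqrt(T / mass[i]);
    vx[i] = s * rnorm01();
    vy[i] = s * rnorm01();
    vz[i] = s * rnorm01();
    refresh_atom_pairs(i, t_now);
    ++gseq[i];
    heap.push({t_now + rexp1(rate), 1, i, gseq[i]});
  }
};

// [[Rcpp::export]]
List run_dmd_cpp(NumericMatrix pos, NumericVector mass, LogicalVector frozen,
                 IntegerVector pair_i, IntegerVector pair_j,
                 IntegerVector radii_off, NumericVector radii,
                 NumericVector energies,
                 IntegerVector cons_idx, NumericVector cons_target,
                 double temperature, double exchange_rate,
                 double duration, double save_interval,
                 int seed, bool track_energy = false,
                 Nullable<NumericMatrix> vel0 = R_NilValue,
                 double max_events_million = 2000.0) {
  DMDEngine E;
  E.n = pos.nrow();
  E.px.resize(E.n); E.py.resize(E.n); E.pz.resize(E.n);
  E.vx.assign(E.n, 0.0); E.vy.assign(E.n, 0.0); E.vz.assign(E.n, 0.0);
  E.tat.assign(E.n, 0.0);
  E.mass.resize(E.n); E.frozen.resize(E.n);
  for (int i = 0; i < E.n; ++i) {
    E.px[i] = pos(i, 0); E.py[i] = pos(i, 1); E.pz[i] = pos(i, 2);
    E.mass[i] = mass[i]; E.frozen[i] = frozen[i];
  }
  E.np = pair_i.size();
  E.pi.assign(pair_i.begin(), pair_i.end());
  E.pj.assign(pair_j.begin(), pair_j.end());
  E.roff.assign(radii_off.begin(), radii_off.end());
  E.radii.assign(radii.begin(), radii.end());
  E.energies.assign(energies.begin(), energies.end());
  E.eoff.resize(E.np + 1);
  for (int p = 0; p <= E.np; ++p) E.eoff[p] = E.roff[p] + p;
  E.region.assign(E.np, 0);
  E.pseq.assign(E.np, 0);
  E.gseq.assign(E.n, 0);
  E.pairs_of_atom.assign(E.n, {});
  for (int p = 0; p < E.np; ++p) {
    E.pairs_of_atom[E.pi[p]].push_back(p);
    E.pairs_of_atom[E.pj[p]].push_back(p);
  }
  E.T = temperature; E.rate = exchange_rate;
  E.rng.seed((uint64_t)seed * 2685821657736338717ULL + 1442695040888963407ULL);
  E.have_spare = false;
  E.track_energy = track_energy;
  E.t_now = 0.0;
  E.n_events = 0;

  // initial regions; reject infinite-energy starting regions
  E.U_total = 0.0;
  for (int p = 0; p < E.np; ++p) {
    double dx = E.px[E.pi[p]] - E.px[E.pj[p]];
    double dy = E.py[E.pi[p]] - E.py[E.pj[p]];
    double dz = E.pz[E.pi[p]] - E.pz[E.pj[p]];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    int nsh = E.roff[p + 1] - E.roff[p];
    int k = 0;
    while (k < nsh && r >= E.radii[E.roff[p] + k]) ++k;
    E.region[p] = k;
    double u = E.energies[E.eoff[p] + k];
    if (!std::isfinite(u)) {
      // tolerate rounding slivers from clash relief: snap to an adjacent
      // finite region whose boundary is within 0.01 A; the first wall event
      // then reflects the pair back inside
      if (k > 0 && std::isfinite(E.energies[E.eoff[p] + k - 1]) &&
          r - E.radii[E.roff[p] + k - 1] < 0.05) {
        E.region[p] = k - 1;
        u = E.energies[E.eoff[p] + k - 1];
      } else if (k < nsh && std::isfinite(E.energies[E.eoff[p] + k + 1]) &&
                 E.radii[E.roff[p] + k] - r < 0.05) {
        E.region[p] = k + 1;
        u = E.energies[E.eoff[p] + k + 1];
      } else {
        stop("pair %d-%d starts in a forbidden region (r = %.4f); relieve clashes first",
             E.pi[p] + 1, E.pj[p] + 1, r);
      }
    }
    E.U_total += u;
  }

  // initial velocities
  if (vel0.isNotNull()) {
    NumericMatrix v(vel0);
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      E.vx[i] = v(i, 0); E.vy[i] = v(i, 1); E.vz[i] = v(i, 2);
    }
  } else {
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      double s = std::sqrt(temperature / E.mass[i]);
      E.vx[i] = s * E.rnorm01();
      E.vy[i] = s * E.rnorm01();
      E.vz[i] = s * E.rnorm01();
    }
  }

  // constraint deviation tracking
  int ncons = cons_idx.size();
  E.cons_pair.assign(cons_idx.begin(), cons_idx.end());
  E.cons_target.assign(cons_target.begin(), cons_target.end());
  E.cons_maxdev.assign(ncons, 0.0);
  std::vector<int> cons_slot(E.np, -1);
  for (int c = 0; c < ncons; ++c) cons_slot[E.cons_pair[c]] = c;

  // seed events
  for (int p = 0; p < E.np; ++p) E.predict_pair(p, 0.0);
  if (exchange_rate > 0.0) {
    for (int i = 0; i < E.n; ++i) {
      if (E.frozen[i]) continue;
      E.heap.push({E.rexp1(exchange_rate), 1, i, E.gseq[i]});
    }
  }

  E.E0 = E.kinetic_energy() + E.U_total;
  E.max_drift = 0.0;

  int nframes = (int)std::floor(duration / save_interval + 1e-9);
  NumericVector snap_times(nframes), snap_pe(nframes), snap_ke(nframes);
  NumericVector snaps((R_xlen_t)nframes * E.n * 3);
  double ke_time_integral = 0.0;
  double last_t = 0.0;
  double cur_ke = E.kinetic_energy();

  long long max_events = (long long)(max_events_million * 1e6);
  int frame = 0;
  double next_save = save_interval;

  auto emit_frame = [&](double tsave) {
    for (int i = 0; i < E.n; ++i) {
      double dt = E.frozen[i] ? 0.0 : (tsave - E.tat[i]);
      snaps[(R_xlen_t)frame * E.n * 3 + i * 3 + 0] = E.px[i] + E.vx[i] * dt;
      snaps[(R_xlen_t)frame * E.n * 3 + i * 3 + 1] = E.py[i] + E.vy[i] * dt;
      snaps[(R_xlen_t)frame * E.n * 3 + i * 3 + 2] = E.pz[i] + E.vz[i] * dt;
    }
    snap_times[frame] = tsave;
    snap_pe[frame] = E.U_total;
    snap_ke[frame] = cur_ke;
    // constraint deviations at the snapshot
    for (int c = 0; c < ncons; ++c) {
      int p = E.cons_pair[c];
      double dr[3], dv[3];
      E.rel_state(p, tsave, dr, dv);
      double r = std::sqrt(dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2]);
      double dev = std::fabs(r - E.cons_target[c]);
      if (dev > E.cons_maxdev[c]) E.cons_maxdev[c] = dev;
    }
    ++frame;
  };

  while (true) {
    if (E.heap.empty()) {
      // free flight to the end
      break;
    }
    Event ev = E.heap.top();
    // emit any snapshots before the next event
    while (frame < nframes && next_save <= ev.time && next_save <= duration + 1e-12) {
      ke_time_integral += cur_ke * (next_save - last_t);
      last_t = next_save;
      emit_frame(next_save);
      next_save += save_interval;
    }
    if (ev.time > duration) break;
    E.heap.pop();
    // validity
    if (ev.kind == 0) {
      if (ev.seq != E.pseq[ev.idx]) continue;
    } else {
      if (ev.seq != E.gseq[ev.idx]) continue;
    }
    ke_time_integral += cur_ke * (ev.time - last_t);
    last_t = ev.time;
    E.t_now = ev.time;
    if (ev.kind == 0) {
      E.process_pair_event(ev.idx);
      int c = cons_slot[ev.idx];
      if (c >= 0) {
        double dr[3], dv[3];
        E.rel_state(ev.idx, E.t_now, dr, dv);
        double r = std::sqrt(dr[0]*dr[0] + dr[1]*dr[1] + dr[2]*dr[2]);
        double dev = std::fabs(r - E.cons_target[c]);
        if (dev > E.cons_maxdev[c]) E.cons_maxdev[c] = dev;
      }
    } else {
      E.process_ghost(ev.idx);
    }
    cur_ke = E.kinetic_energy();
    if (track_energy && ev.kind == 0) {
      double drift = std::fabs(cur_ke + E.U_total - E.E0);
      if (drift > E.max_drift) E.max_drift = drift;
    }
    if (++E.n_events > max_events) {
      stop("event budget exceeded (%lld events)", E.n_events);
    }
    if ((E.n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  // trailing snapshots (free flight)
  while (frame < nframes && next_save <= duration + 1e-12) {
    ke_time_integral += cur_ke * (next_save - last_t);
    last_t = next_save;
    emit_frame(next_save);
    next_save += save_interval;
  }

  // final state at t = duration
  NumericMatrix fpos(E.n, 3), fvel(E.n, 3);
  for (int i = 0; i < E.n; ++i) {
    double dt = E.frozen[i] ? 0.0 : (duration - E.tat[i]);
    fpos(i, 0) = E.px[i] + E.vx[i] * dt;
    fpos(i, 1) = E.py[i] + E.vy[i] * dt;
    fpos(i, 2) = E.pz[i] + E.vz[i] * dt;
    fvel(i, 0) = E.vx[i]; fvel(i, 1) = E.vy[i]; fvel(i, 2) = E.vz[i];
  }
  ke_time_integral += cur_ke * (duration - last_t);

  return List::create(
    _["snapshots"] = snaps,
    _["times"] = snap_times,
    _["potential_energy"] = snap_pe,
    _["kinetic_energy"] = snap_ke,
    _["final_pos"] = fpos,
    _["final_vel"] = fvel,
    _["constraint_maxdev"] = NumericVector(E.cons_maxdev.begin(), E.cons_maxdev.end()),
    _["n_events"] = (double)E.n_events,
    _["max_energy_drift"] = E.max_drift,
    _["mean_kinetic_energy"] = ke_time_integral / duration,
    _["n_frames"] = frame
  );
}
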