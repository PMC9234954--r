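// Lightweight whisker physics: four independent 1-DOF torque-driven rotational
// joints (linear inertia-damper-spring) with a hard angular stop modelling a
// vertical bar in the whisker field. Contact at the stop either bounces
// (restitution) or sticks, producing contact flags, onset/offset events and a
// constant contact distance (the bar's radial placement).
//
// Angles in degrees at the interface, radians internally; torques in N*m.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

// [[Rcpp::export]]
List plant_run_cpp(NumericVector angle_deg, NumericVector vel_deg_s,
                   LogicalVector in_contact0, NumericVector torque,
                   IntegerVector whisker_side, double inertia, double damping,
                   double stiffness, double rest_deg, double restitution,
                   double stick_vel_deg_s, double release_margin_deg,
                   int bar_side, double bar_angle_deg,
                   double bar_radial_cm, double bar_start_ms, double bar_stop_ms,
                   double t0_ms, double dt_ms, int nsteps, int record_every) {
  int nw = angle_deg.size();
  double dt = dt_ms / 1000.0;
  double rest = rest_deg * DEG, barang = bar_angle_deg * DEG;
  double stick = stick_vel_deg_s * DEG, margin = release_margin_deg * DEG;
  std::vector<double> th(nw), om(nw);
  std::vector<char> contact(nw), clamped(nw);
  for (int wi = 0; wi < nw; ++wi) {
    th[wi] = angle_deg[wi] * DEG;
    om[wi] = vel_deg_s[wi] * DEG;
    contact[wi] = in_contact0[wi] ? 1 : 0;
    clamped[wi] = (contact[wi] && th[wi] >= barang - 1e-9) ? 1 : 0;
  }
  int nrec = nsteps / record_every;
  NumericMatrix rec_th(nrec, nw), rec_om(nrec, nw);
  IntegerMatrix rec_ct(nrec, nw);
  NumericVector rec_t(nrec);
  std::vector<double> ev_t;
  std::vector<int> ev_w, ev_type; // 1 = onset, 2 = offset
  int ri = 0;
  for (int s = 1; s <= nsteps; ++s) {
    double t = t0_ms + s * dt_ms;
    bool bar_on = bar_side != 0 && t > bar_start_ms && t <= bar_stop_ms;
    for (int wi = 0; wi < nw; ++wi) {
      // semi-implicit Euler
      double acc = (torque[wi] - damping * om[wi] - stiffness * (th[wi] - rest)) / inertia;
      om[wi] += dt * acc;
      th[wi] += dt * om[wi];
      if (!std::isfinite(th[wi]))
        stop("non-finite whisker state (whisker %d)", wi + 1);
      // The in_contact flag is "engaged" from the first clamp until the
      // whisker retreats below the stop by the release margin (tip
      // compliance): rebounds inside the margin do not toggle it. Every
      // mechanical re-impact at the stop (free -> clamped) is emitted as a
      // type-1 event (these drive the rapidly adapting contact afferents and
      // hence the trigeminal reflex); type-2 events are debounced contact
      // offsets (detach).
      bool ct = contact[wi] != 0, cl = false;
      if (bar_on && whisker_side[wi] == bar_side) {
        if (th[wi] > barang) {
          th[wi] = barang;
          ct = true;
          cl = true;
          if (om[wi] > stick)
            om[wi] = -restitution * om[wi]; // bounce
          else if (om[wi] > 0)
            om[wi] = 0; // stick against the stop
        } else if (th[wi] < barang - margin) {
          ct = false;
        }
      } else {
        ct = false;
      }
      if (cl && !clamped[wi]) {
        ev_t.push_back(t);
        ev_w.push_back(wi + 1);
        ev_type.push_back(1);
      }
      if (!ct && contact[wi]) {
        ev_t.push_back(t);
        ev_w.push_back(wi + 1);
        ev_type.push_back(2);
      }
      contact[wi] = ct ? 1 : 0;
      clamped[wi] = cl ? 1 : 0;
    }
    if (s % record_every == 0 && ri < nrec) {
      rec_t[ri] = t;
      for (int wi = 0; wi < nw; ++wi) {
        rec_th(ri, wi) = th[wi] / DEG;
        rec_om(ri, wi) = om[wi] / DEG;
        rec_ct(ri, wi) = contact[wi];
      }
      ++ri;
    }
  }
  NumericVector fth(nw), fom(nw);
  LogicalVector fct(nw);
  for (int wi = 0; wi < nw; ++wi) {
    fth[wi] = th[wi] / DEG;
    fom[wi] = om[wi] / DEG;
    fct[wi] = contact[wi] == 1;
  }
  return List::create(
      _["time"] = rec_t, _["angle"] = rec_th, _["velocity"] = rec_om,
      _["contact"] = rec_ct,
      _["events"] = DataFrame::create(_["time"] = NumericVector(ev_t.begin(), ev_t.end()),
                                      _["whisker"] = IntegerVector(ev_w.begin(), ev_w.end()),
                                      _["type"] = IntegerVector(ev_type.begin(), ev_type.end())),
      _["final_angle"] = fth, _["final_velocity"] = fom,
      _["final_contact"] = fct, _["contact_distance"] = bar_radial_cm);
}
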