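#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct-method simulation of the two-gene titration circuit CME.
//
// Channels (propensities follow mass-action system-size scaling):
//   0 prod_X      Omega * beta_X(s_X)            N_X += 1
//   1 prod_Y      Omega * beta_Y(s_Y)            N_Y += 1
//   2 deg_X       delta_X * N_X                  N_X -= 1
//   3 deg_Y       delta_Y * N_Y                  N_Y -= 1
//   4 titration   alpha * N_X * N_Y / Omega      N_X -= 1, N_Y -= 1
//   5 bind_X      kappa_X * N_X / Omega          s_X += 1, N_X -= 1
//   6 unbind_X    theta_X                        s_X -= 1, N_X += 1
//   7 bind_Y      kappa_Y * N_X / Omega          s_Y += 1, N_X -= 1
//   8 unbind_Y    theta_Y                        s_Y -= 1, N_X += 1
//
// Boundary channels (s at 0 or nb) have zero propensity. The trajectory is
// thinned to snapshots on a regular grid; every promoter-state change is
// additionally recorded un-thinned. pin_counts freezes N_X, N_Y (used for
// frozen-TF promoter statistics).

// [[Rcpp::export]]
List cme_gillespie_cpp(NumericVector par, NumericVector init, double t_end,
                       double snap_dt, bool pin_counts, double max_events) {
  const double Omega = par["Omega"];
  const int nb_X = (int)par["nb_X"], nb_Y = (int)par["nb_Y"];
  const double bfX = par["beta_f_X"], bbX = par["beta_b_X"];
  const double bfY = par["beta_f_Y"], bbY = par["beta_b_Y"];
  const double dX = par["delta_X"], dY = par["delta_Y"];
  const double kX = par["kappa_X"], kY = par["kappa_Y"];
  const double thX = par["theta_X"], thY = par["theta_Y"];
  const double alpha = par["alpha"];

  double NX = init[0], NY = init[1];
  int sX = (int)init[2], sY = (int)init[3];
  if (NX < 0 || NY < 0 || sX < 0 || sX > nb_X || sY < 0 || sY > nb_Y)
    stop("invalid initial state");

  const int n_snap = (int)std::floor(t_end / snap_dt) + 1;
  NumericMatrix snaps(n_snap, 5);
  int i_snap = 0;
  double t_next_snap = 0.0;

  std::vector<double> ev_t;
  std::vector<int> ev_ch, ev_sX, ev_sY;

  double t = 0.0, a[9];
  double n_events = 0.0;

  while (t < t_end) {
    a[0] = Omega * (sX == 0 ? bfX : bbX);
    a[1] = Omega * (sY == 0 ? bfY : bbY);
    a[2] = dX * NX;
    a[3] = dY * NY;
    a[4] = alpha * NX * NY / Omega;
    a[5] = (sX < nb_X) ? kX * NX / Omega : 0.0;
    a[6] = (sX > 0) ? thX : 0.0;
    a[7] = (sY < nb_Y) ? kY * NX / Omega : 0.0;
    a[8] = (sY > 0) ? thY : 0.0;

    double a0 = 0.0;
    for (int i = 0; i < 9; ++i) a0 += a[i];

    double t_new;
    if (a0 <= 0.0) {
      t_new = t_end; // absorbing: flow snapshots to the end
    } else {
      t_new = t + exp_rand() / a0;
    }

    while (i_snap < n_snap && t_next_snap <= std::min(t_new, t_end)) {
      snaps(i_snap, 0) = t_next_snap;
      snaps(i_snap, 1) = NX;
      snaps(i_snap, 2) = NY;
      snaps(i_snap, 3) = sX;
      snaps(i_snap, 4) = sY;
      ++i_snap;
      t_next_snap += snap_dt;
    }
    if (a0 <= 0.0 || t_new >= t_end) break;
    t = t_new;

    double u = unif_rand() * a0, cum = 0.0;
    int ch = 8;
    for (int i = 0; i < 9; ++i) {
      cum += a[i];
      if (u <= cum) { ch = i; break; }
    }

    switch (ch) {
      case 0: if (!pin_counts) NX += 1; break;
      case 1: if (!pin_counts) NY += 1; break;
      case 2: if (!pin_counts) NX -= 1; break;
      case 3: if (!pin_counts) NY -= 1; break;
      case 4: if (!pin_counts) { NX -= 1; NY -= 1; } break;
      case 5: sX += 1; if (!pin_counts) NX -= 1; break;
      case 6: sX -= 1; if (!pin_counts) NX += 1; break;
      case 7: sY += 1; if (!pin_counts) NX -= 1; break;
      case 8: sY -= 1; if (!pin_counts) NX += 1; break;
    }
    if (NX < 0 || NY < 0 || sX < 0 || sX > nb_X || sY < 0 || sY > nb_Y)
      stop("simulation produced an invalid state (channel %d at t = %g)",
           ch, t);

    if (ch >= 5) { // promoter-state changes kept un-thinned
      ev_t.push_back(t);
      ev_ch.push_back(ch);
      ev_sX.push_back(sX);
      ev_sY.push_back(sY);
    }

    n_events += 1.0;
    if (n_events > max_events)
      stop("event budget exceeded (%g events before t = %g)", max_events, t);
    if (((long long)n_events) % 1048576 == 0) checkUserInterrupt();
  }

  if (i_snap < n_snap) snaps = snaps(Range(0, std::max(i_snap - 1, 0)), _);

  return List::create(
    _["snapshots"] = snaps,
    _["event_time"] = wrap(ev_t),
    _["event_channel"] = wrap(ev_ch),
    _["event_s_X"] = wrap(ev_sX),
    _["event_s_Y"] = wrap(ev_sY),
    _["n_events"] = n_events,
    _["final"] = NumericVector::create(NX, NY, sX, sY));
}
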