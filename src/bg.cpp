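#include <Rcpp.h>
using namespace Rcpp;

// Firing-rate basal ganglia network, two segregated action channels.
//
// Populations (state indices):
//  0,1  C   cortex
//  2,3  G   striatal Go
//  4,5  N   striatal NoGo
//  6,7  E   GPe
//  8,9  I   GPi/SNr
// 10,11 T   thalamus
// 12    STN subthalamic nucleus (shared stop unit)
// 13    H   striatal cholinergic interneuron (shared)
//
// Each population follows first-order low-pass dynamics of a logistic
// static nonlinearity: tau * dz/dt = -z + phi(u). The STN uses the fast
// time constant while its drive exceeds its activity (stop onset) and the
// slow constant tau_L while releasing, so the stop signal decays slowly.

static inline double phi(double u, double a, double u0) {
  return 1.0 / (1.0 + std::exp(-a * (u - u0)));
}

// [[Rcpp::export(name = ".bg_core")]]
List bg_core(double D,
             List params,
             List weights,
             double dt,
             double settle_ms,
             double t_max_ms,
             double threshold,
             double physio_delay_ms,
             int mode,                 // 0 = fixed-S selection, 1 = tapping
             NumericVector S_init,
             bool record_traces,
             int thin,
             bool clamp_H,
             Nullable<NumericVector> init_state) {
  const double tau   = as<double>(params["tau"]);
  const double tau_L = as<double>(params["tau_L"]);
  const double a     = as<double>(params["a"]);
  const double u0    = as<double>(params["u0"]);
  const double thG   = as<double>(params["theta_G"]);
  const double I_E   = as<double>(params["I_E"]);
  const double I_I   = as<double>(params["I_I"]);
  const double I_H   = as<double>(params["I_H"]);
  const double alpha = as<double>(params["alpha"]);
  const double beta  = as<double>(params["beta"]);
  const double gamma = as<double>(params["gamma"]);
  const double sigma = as<double>(params["sigma_noise"]);

  const double L      = as<double>(weights["L"]);
  const double wCSd   = as<double>(weights["W_CS_diag"]);
  const double wCSo   = as<double>(weights["W_CS_off"]);
  const double wCT    = as<double>(weights["W_CT"]);
  const double wGC    = as<double>(weights["W_GC"]);
  const double wGS    = as<double>(weights["W_GS"]);
  const double wNC    = as<double>(weights["W_NC"]);
  const double wNS    = as<double>(weights["W_NS"]);
  const double wEN    = as<double>(weights["W_EN"]);
  const double wIE    = as<double>(weights["W_IE"]);
  const double wIG    = as<double>(weights["W_IG"]);
  const double wTC    = as<double>(weights["W_TC"]);
  const double wTI    = as<double>(weights["W_TI"]);
  const double wESTN  = as<double>(weights["w_ESTN"]);
  const double wISTN  = as<double>(weights["w_ISTN"]);
  const double kE     = as<double>(weights["k_E"]);
  const double wSTNE  = as<double>(weights["W_STNE"]);
  const double wGH    = as<double>(weights["w_GH"]);
  const double wNH    = as<double>(weights["w_NH"]);

  const int nstate = 14;
  std::vector<double> z(nstate, 0.0), u(nstate, 0.0);
  if (init_state.isNotNull()) {
    NumericVector s0(init_state);
    if (s0.size() != nstate) stop("init_state must have length 14");
    for (int i = 0; i < nstate; ++i) z[i] = s0[i];
  }

  double S[2] = {0.0, 0.0};
  const long n_settle = (long)std::lround(settle_ms / dt);
  const long n_run    = (long)std::lround(t_max_ms / dt);

  std::vector<double> ev_t, ev_ch;
  double delay_left = 0.0;
  bool armed = true;
  double prevC0 = z[0], prevC1 = z[1];

  long n_rec = record_traces ? (n_run / thin + 2) : 0;
  NumericMatrix traces(record_traces ? n_rec : 0,
                       record_traces ? nstate + 1 : 0);
  long rec_i = 0;

  const bool noisy = sigma > 0.0;
  RNGScope rngScope;

  bool timed_out = true;

  for (long k = 0; k < n_settle + n_run; ++k) {
    if (k == n_settle) { S[0] = S_init[0]; S[1] = S_init[1]; }

    const double Hval = clamp_H ? 0.0 : z[13];

    // dopaminergic contrast on Go, gated by the sensory-related drive
    double dop0 = (wGS * S[0] > thG) ? alpha * D : -alpha * D;
    double dop1 = (wGS * S[1] > thG) ? alpha * D : -alpha * D;

    // stimulus-cortex mismatch drives the hyperdirect stop
    const double conflict = S[0] * z[1] + S[1] * z[0];

    u[0]  = wCSd * S[0] + wCSo * S[1] + wCT * z[10] + L * z[1];
    u[1]  = wCSd * S[1] + wCSo * S[0] + wCT * z[11] + L * z[0];
    u[2]  = wGC * z[0] + wGS * S[0] + dop0 + wGH * Hval;
    u[3]  = wGC * z[1] + wGS * S[1] + dop1 + wGH * Hval;
    u[4]  = wNC * z[0] + wNS * S[0] + beta * D + wNH * Hval;
    u[5]  = wNC * z[1] + wNS * S[1] + beta * D + wNH * Hval;
    u[6]  = I_E + wEN * z[4] + wESTN * z[12];
    u[7]  = I_E + wEN * z[5] + wESTN * z[12];
    u[8]  = I_I + wIG * z[2] + wIE * z[6] + wISTN * z[12];
    u[9]  = I_I + wIG * z[3] + wIE * z[7] + wISTN * z[12];
    u[10] = wTC * z[0] + wTI * z[8];
    u[11] = wTC * z[1] + wTI * z[9];
    u[12] = kE * conflict + wSTNE * (z[6] + z[7]);
    u[13] = I_H + gamma * D;

    if (noisy) {
      for (int i = 0; i < nstate; ++i) u[i] += sigma * norm_rand();
    }

    for (int i = 0; i < nstate; ++i) {
      double target = phi(u[i], a, u0);
      double tc = tau;
      if (i == 12 && target < z[i]) tc = tau_L;  // slow stop release
      z[i] += dt / tc * (-z[i] + target);
      if (z[i] < 0.0) z[i] = 0.0;
      if (z[i] > 1.0) z[i] = 1.0;
    }

    if (k < n_settle) { prevC0 = z[0]; prevC1 = z[1]; continue; }
    const double t_now = (k - n_settle + 1) * dt;

    if (record_traces && ((k - n_settle) % thin == 0) && rec_i < n_rec) {
      traces(rec_i, 0) = t_now;
      for (int i = 0; i < nstate; ++i) traces(rec_i, i + 1) = z[i];
      ++rec_i;
    }

    if (delay_left > 0.0) {
      delay_left -= dt;
      if (delay_left <= 0.0) {
        if (mode == 1) { std::swap(S[0], S[1]); }
        armed = true;
      }
    } else if (armed) {
      int ch = -1;
      double pc = 0.0, cc = 0.0;
      if (prevC0 < threshold && z[0] >= threshold) { ch = 1; pc = prevC0; cc = z[0]; }
      else if (prevC1 < threshold && z[1] >= threshold) { ch = 2; pc = prevC1; cc = z[1]; }
      if (ch > 0) {
        double frac = (cc > pc) ? (threshold - pc) / (cc - pc) : 1.0;
        ev_t.push_back(t_now - dt + frac * dt);
        ev_ch.push_back(ch);
        if (mode == 0) { timed_out = false; prevC0 = z[0]; prevC1 = z[1]; break; }
        delay_left = physio_delay_ms;
        armed = false;
      }
    }
    prevC0 = z[0]; prevC1 = z[1];
  }
  if (mode == 1) timed_out = false;

  NumericVector final_state(nstate);
  for (int i = 0; i < nstate; ++i) final_state[i] = z[i];

  List out = List::create(
    _["event_time"] = wrap(ev_t),
    _["event_channel"] = wrap(ev_ch),
    _["timed_out"] = timed_out,
    _["final_state"] = final_state);
  if (record_traces) {
    out["traces"] = traces(Range(0, std::max<long>(rec_i - 1, 0)),
                           Range(0, nstate));
  }
  return out;
}
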