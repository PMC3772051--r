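// Core fixed-step (Euler-Maruyama) integrator for the superficial-pyramidal
// (SP) cell model: stochastic LIF with rectified feedforward drive, a
// depolarizing-after-potential (DAP) burst mechanism gated by a dynamic
// dendritic refractory period, and optional phase-segmented parallel-fiber
// feedback with shunting inhibition and online burst-triggered plasticity.
//
// Uses R's RNG (norm_rand) so that set.seed() on the R side makes every
// simulation reproducible.

#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

// periodic reduction into [0, p) without libm fmod (keeps the binary free
// of versioned symbols newer than the host C library)
inline double mod_pos(double x, double p) {
  return x - std::floor(x / p) * p;
}

// difference-of-exponentials DAP waveform: rises with time constant gamma,
// decays with beta (beta > gamma), zero at d = 0, nonnegative for d >= 0
inline double dap_wave(double d, double alpha, double beta, double gamma) {
  if (d <= 0.0) return 0.0;
  double v = alpha * (std::exp(-d / beta) - std::exp(-d / gamma));
  return v > 0.0 ? v : 0.0;
}

struct PlasticityCfg {
  double eta_small, eta_large;   // per-burst depression steps
  double win_small, win_large;   // LTD kernel supports (s)
  double tau_w, w_max;           // homeostatic potentiation
};

// lazy closed-form potentiation: relax w_j toward w_max since last touch
inline void potentiate_to(std::vector<double> &w, std::vector<double> &tpot,
                          int j, double t, double tau_w, double w_max) {
  double el = t - tpot[j];
  if (el > 0.0) {
    w[j] = w_max + (w[j] - w_max) * std::exp(-el / tau_w);
    tpot[j] = t;
  }
}

// depression from one postsynaptic burst at t0 (first-spike time):
// every segment whose most recent onset t_j satisfies 0 <= t0 - t_j <= W_k
// is depressed by eta_k * (1 - dt/W_k), floored at zero
inline void depress(std::vector<double> &w, std::vector<double> &tpot,
                    double t0, int type, double period, double seg_dur,
                    const PlasticityCfg &pc) {
  double eta = (type == 4) ? pc.eta_large : pc.eta_small;
  double win = (type == 4) ? pc.win_large : pc.win_small;
  int nseg = (int)w.size();
  double phase = mod_pos(t0, period);
  for (int j = 0; j < nseg; ++j) {
    double onset = j * seg_dur;
    double dtp = phase - onset;          // most recent onset this cycle
    if (dtp < 0.0) dtp += period;        // onset fell in the previous cycle
    if (dtp <= win) {
      potentiate_to(w, tpot, j, t0, pc.tau_w, pc.w_max);
      double k = 1.0 - dtp / win;
      w[j] -= eta * k;
      if (w[j] < 0.0) w[j] = 0.0;
    }
  }
}

} // namespace

// [[Rcpp::export]]
List sim_core(double duration, double dt,
              double am_f, double drive_amp,
              double v_th, double v_r, double tau_m, double tau_ref,
              double bias, double sigma, double f_cut,
              bool dap_on,
              double alpha, double beta, double gamma,
              double mu1, double mu2, double mu3, double mu4,
              double r_s, double tau_b,
              bool fb_on, double G, double shunt_g, int shunt_mode,
              NumericVector w0, double seg_dur,
              bool plastic,
              double eta_small, double eta_large,
              double t_small, double t_large,
              double win_small, double win_large,
              double tau_w, double w_max,
              bool record_v) {
  if (dt <= 0.0) stop("dt must be positive");
  if (duration <= 0.0) stop("duration must be positive");
  if (f_cut >= 0.5 / dt) stop("noise cutoff above Nyquist for this dt");

  RNGScope rng;

  const int n_steps = (int)std::ceil(duration / dt);
  const double two_pi = 2.0 * M_PI;
  const double period = (am_f > 0.0) ? 1.0 / am_f : R_PosInf;

  // AR(1) low-pass noise, unit stationary variance
  const double a_n = std::exp(-two_pi * f_cut * dt);
  const double b_n = std::sqrt(1.0 - a_n * a_n);
  double xi = norm_rand();

  double V = v_r;
  double ref_until = -1.0;

  // DAP bookkeeping: recent DAP-eligible spike times (waveforms may overlap)
  std::vector<double> dap_spikes;
  double r_dyn = r_s;   // dynamic dendritic refractory period
  double u_tr = 0.0;    // per-spike auxiliary trace
  double t_last = R_NegInf;
  const double dap_horizon = 10.0 * beta;

  std::vector<double> w(w0.begin(), w0.end());
  int nseg = (int)w.size();
  std::vector<double> tpot(nseg, 0.0);

  PlasticityCfg pc{eta_small, eta_large, win_small, win_large, tau_w, w_max};

  std::vector<double> spikes;
  std::vector<double> burst_times;
  std::vector<int> burst_sizes;
  std::deque<double> pending;   // spikes not yet assigned to a burst event

  std::vector<double> vtrace;
  if (record_v) vtrace.reserve(n_steps);

  // resolve pending spikes greedily, largest burst first; a decision at the
  // front spike is final once a 4-spike window is determined or expired
  auto resolve = [&](double t_now, bool flush) {
    while (!pending.empty()) {
      double t0 = pending.front();
      if (pending.size() >= 4) {
        if (pending[3] - t0 <= t_large) {
          burst_times.push_back(t0); burst_sizes.push_back(4);
          if (plastic) depress(w, tpot, t0, 4, period, seg_dur, pc);
          for (int k = 0; k < 4; ++k) pending.pop_front();
          continue;
        }
        // large impossible at t0; fall through to small decision
      } else if (!flush && t_now - t0 <= t_large) {
        break;  // a large burst may still form
      }
      if (pending.size() >= 2 && pending[1] - t0 <= t_small) {
        burst_times.push_back(t0); burst_sizes.push_back(2);
        if (plastic) depress(w, tpot, t0, 2, period, seg_dur, pc);
        pending.pop_front(); pending.pop_front();
      } else if (pending.size() >= 2 || flush || t_now - t0 > t_small) {
        pending.pop_front();  // lone spike, no burst
      } else {
        break;  // wait for a possible small-burst partner
      }
    }
  };

  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;

    // noise update every step so the sample path is independent of gating
    xi = a_n * xi + b_n * norm_rand();

    // dynamic dendritic refractory relaxes toward baseline at all times
    if (dap_on) r_dyn += dt * (r_s - r_dyn) / tau_b;

    if (t < ref_until) {
      V = v_r;
      if (record_v) vtrace.push_back(V);
      continue;
    }

    // DAP current
    double B = 0.0;
    if (dap_on && !dap_spikes.empty()) {
      while (!dap_spikes.empty() && t - dap_spikes.front() > dap_horizon)
        dap_spikes.erase(dap_spikes.begin());
      for (double ts : dap_spikes) B += dap_wave(t - ts, alpha, beta, gamma);
    }

    // rectified feedforward drive
    double ff = bias + drive_amp * std::sin(two_pi * am_f * t);
    if (ff < 0.0) ff = 0.0;

    // feedback: one active phase segment at a time
    double fb = 0.0;
    if (fb_on && nseg > 0) {
      double phase = mod_pos(t, period);
      int j = (int)(phase / seg_dur);
      if (j >= nseg) j = nseg - 1;  // rounding residual at the period edge
      if (plastic) potentiate_to(w, tpot, j, t, tau_w, w_max);
      // excitation G*w_j from the active PF; shunting inhibition from
      // interneurons pooling the whole PF population (mode 0, conductance
      // g*G) or scaled by the active weight as well (mode 1)
      fb = (shunt_mode == 1) ? G * w[j] * (1.0 - shunt_g * V)
                             : G * (w[j] - shunt_g * V);
    }

    V += dt / tau_m * (-V + ff + B + sigma * xi + fb);

    if (V >= v_th) {
      double isi = t - t_last;
      if (dap_on) {
        // DAP delivered only if the preceding ISI cleared the dendritic
        // refractory period; every spike still increments the trace
        if (!(isi < r_dyn)) dap_spikes.push_back(t);
        u_tr = u_tr * std::exp(-isi / mu4) + mu1;
        r_dyn = r_s + mu3 * std::pow(u_tr, mu2);
      }
      t_last = t;
      spikes.push_back(t);
      if (plastic) pending.push_back(t);
      V = v_r;
      ref_until = t + tau_ref;
    }

    if (plastic && (i % 64 == 0)) resolve(t, false);
    if (record_v) vtrace.push_back(V);
  }

  if (plastic) {
    resolve(duration, true);
    for (int j = 0; j < nseg; ++j)
      potentiate_to(w, tpot, j, duration, tau_w, w_max);
  }

  List out = List::create(
    _["spikes"] = wrap(spikes),
    _["weights"] = wrap(w),
    _["burst_times"] = wrap(burst_times),
    _["burst_sizes"] = wrap(burst_sizes));
  if (record_v) out["v"] = wrap(vtrace);
  return out;
}

// Standalone DAP waveform evaluation (for tests / plotting)
// [[Rcpp::export]]
NumericVector dap_waveform(NumericVector d, double alpha, double beta,
                           double gamma) {
  int n = d.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dap_wave(d[i], alpha, beta, gamma);
  return out;
}
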