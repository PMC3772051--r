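#' Low-pass filtered Gaussian noise
#'
#' The membrane noise source: white Gaussian noise passed through a
#' first-order low-pass filter with cutoff \code{f_cut} and rescaled so the
#' stationary variance is one (the scale \code{sigma} and the bias are
#' applied in the membrane equation). Implemented as the exact AR(1)
#' discretization \eqn{\xi_{n+1} = a\xi_n + \sqrt{1-a^2}\,z_n} with
#' \eqn{a = e^{-2\pi f_{cut} dt}}.
#'
#' @param n_steps number of samples.
#' @param dt sample interval (s); \code{f_cut} must be below Nyquist.
#' @param f_cut cutoff frequency (Hz).
#' @param seed optional RNG seed.
#' @return Numeric vector of length \code{n_steps}, zero mean and unit
#'   variance in the stationary state.
#' @export
filtered_noise <- function(n_steps, dt, f_cut = 500, seed = NULL) {
  if (f_cut >= 0.5 / dt)
    stop("f_cut at or above Nyquist for this dt; decrease dt")
  if (!is.null(seed)) set.seed(seed)
  a <- exp(-2 * pi * f_cut * dt)
  innov <- stats::rnorm(n_steps, sd = sqrt(1 - a^2))
  as.numeric(stats::filter(innov, a, method = "recursive",
                           init = stats::rnorm(1)))
}

# low-level wrapper around the compiled integrator; all times in seconds
simulate_sp_raw <- function(duration, dt, am_f, drive_amp,
                            neuron, dap,
                            feedback = NULL, G = 0,
                            shunt_g = 1.44, shunt_mode = "pooled",
                            plastic = FALSE, plasticity = NULL,
                            record_v = FALSE) {
  w0 <- if (is.null(feedback)) numeric(0) else feedback$weights
  seg_dur <- if (is.null(feedback)) 1 else feedback$segment_duration
  pp <- if (is.null(plasticity)) plasticity_params() else plasticity
  res <- sim_core(duration, dt, am_f, drive_amp,
                  neuron$v_th, neuron$v_r, neuron$tau_m, neuron$tau_ref,
                  neuron$bias, neuron$sigma, neuron$f_cut,
                  dap$enabled, dap$alpha, dap$beta, dap$gamma,
                  dap$mu1, dap$mu2, dap$mu3, dap$mu4, dap$r_s, dap$tau_b,
                  !is.null(feedback), G, shunt_g,
                  if (identical(shunt_mode, "weighted")) 1L else 0L,
                  w0, seg_dur,
                  plastic,
                  pp$eta_small, pp$eta_large, pp$t_small, pp$t_large,
                  pp$win_small, pp$win_large, pp$tau_w, pp$w_max,
                  record_v)
  res
}

#' Simulate the SP neuron
#'
#' Integrates the SP membrane equation with forward Euler at step \code{dt}:
#' \deqn{\tau_m \dot V = -V + [I + S(t)]_+ + B(t) + \sigma\xi(t)
#'       + G\,(w_{j(t)} - g V)}
#' where \eqn{[\cdot]_+} is rectification of the strictly excitatory
#' electroreceptor drive, \eqn{B(t)} the DAP current, \eqn{\xi} the
#' filtered noise, and the last term (present only for global stimuli with
#' a supplied \code{feedback} array) combines parallel-fiber excitation
#' with PF-driven shunting inhibition of conductance scale \eqn{g} (see
#' \code{\link{feedback_term}} for the alternative grouping). On
#' reaching threshold a spike is recorded and \eqn{V} is held at the reset
#' for the absolute refractory period.
#'
#' @param spec an \code{\link{am_stimulus}}.
#' @param transfer a \code{\link{punit_transfer}}.
#' @param neuron,dap neuron and DAP parameter objects.
#' @param feedback optional \code{\link{pf_segments}} array; required for
#'   and only permitted with global stimuli.
#' @param gain a \code{\link{feedback_gain_params}} object (used only with
#'   feedback).
#' @param shunt_g shunting conductance scale \eqn{g}.
#' @param shunt_mode shunting grouping, \code{"pooled"} or
#'   \code{"weighted"} (see \code{\link{feedback_term}}).
#' @param dt integration step (s).
#' @param seed optional RNG seed.
#' @param record_v record the membrane trajectory (memory-heavy).
#' @return A list of class \code{"sp_simulation"}: \code{spikes} (strictly
#'   increasing spike times, s), \code{duration}, \code{frequency}, and
#'   \code{v} when recorded.
#' @export
#' @examples
#' tf <- default_transfer()
#' sim <- simulate_sp(am_stimulus(8, 10, 2, "local"), tf, seed = 1)
#' length(sim$spikes) / sim$duration  # mean rate, spikes/s
simulate_sp <- function(spec, transfer, neuron = neuron_params(),
                        dap = dap_params(), feedback = NULL,
                        gain = feedback_gain_params(), shunt_g = 1.44,
                        shunt_mode = c("pooled", "weighted"),
                        dt = 2.5e-5, seed = NULL, record_v = FALSE) {
  shunt_mode <- match.arg(shunt_mode)
  stopifnot(inherits(spec, "am_stimulus"))
  if (spec$type == "local" && !is.null(feedback))
    stop("local stimuli do not activate the feedback pathway")
  if (!is.null(seed)) set.seed(seed)
  G <- if (is.null(feedback)) 0 else
    feedback_gain(spec$contrast, transfer, gain, spec$type,
                  frequency = spec$frequency)
  res <- simulate_sp_raw(spec$duration, dt, spec$frequency,
                         drive_amplitude(spec, transfer),
                         neuron, dap, feedback = feedback, G = G,
                         shunt_g = shunt_g, shunt_mode = shunt_mode,
                         record_v = record_v)
  out <- list(spikes = res$spikes, duration = spec$duration,
              frequency = spec$frequency, contrast = spec$contrast,
              type = spec$type)
  if (record_v) out$v <- res$v
  structure(out, class = "sp_simulation")
}

#' DAP current waveform after an isolated spike
#'
#' Evaluates the depolarizing-after-potential current at lags \code{d}
#' after a DAP-eligible spike.
#'
#' @param d lag(s) after the spike (s).
#' @param dap a \code{\link{dap_params}} object.
#' @return Current values, nonnegative and unimodal, zero at \code{d <= 0}.
#' @export
dap_current <- function(d, dap = dap_params()) {
  dap_waveform(d, dap$alpha, dap$beta, dap$gamma)
}
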