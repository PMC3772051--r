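#' Membrane parameters of the superficial pyramidal (SP) cell
#'
#' Leaky integrate-and-fire parameters for the SP neuron. All times are in
#' seconds; the membrane potential is dimensionless, with the threshold
#' normalized to 1 and the reset to 0. The defaults approximate in vivo SP
#' activity of the electrosensory lateral-line lobe (ELL): the bias \code{I}
#' and the noise scale \code{sigma} fix the spontaneous firing statistics,
#' and the noise is a Gaussian process low-pass filtered at \code{f_cut}
#' with unit stationary variance before scaling.
#'
#' @param v_th spike threshold.
#' @param v_r reset potential.
#' @param tau_m membrane time constant (s).
#' @param tau_ref absolute refractory period (s).
#' @param bias constant input bias \code{I}.
#' @param sigma noise standard deviation.
#' @param f_cut low-pass cutoff of the noise process (Hz).
#' @return An object of class \code{"neuron_params"}.
#' @export
#' @examples
#' neuron_params()
neuron_params <- function(v_th = 1, v_r = 0, tau_m = 7e-3, tau_ref = 0.7e-3,
                          bias = 0.59, sigma = 0.768, f_cut = 500) {
  if (v_th <= v_r) stop("v_th must exceed v_r")
  if (tau_m <= 0 || tau_ref <= 0) stop("time constants must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(v_th = v_th, v_r = v_r, tau_m = tau_m, tau_ref = tau_ref,
                 bias = bias, sigma = sigma, f_cut = f_cut),
            class = "neuron_params")
}

#' Depolarizing-after-potential (DAP) burst parameters
#'
#' Parameters of the burst-generating mechanism of the SP cell. After each
#' spike the soma receives a delayed depolarizing current, modelled as a
#' rectified difference of exponentials
#' \deqn{B(d) = \alpha\,[e^{-d/\beta} - e^{-d/\gamma}]_+}
#' (rise time ~\eqn{\gamma}, decay ~\eqn{\beta}), unless the preceding
#' inter-spike interval falls inside a dynamic dendritic refractory period
#' \eqn{r(t)}. Between spikes \eqn{r} relaxes toward \code{r_s} with time
#' constant \code{tau_b}; at each spike a per-spike trace
#' \eqn{u \leftarrow u\,e^{-\mathrm{ISI}/\mu_4} + \mu_1} is updated and
#' \eqn{r \leftarrow r_s + \mu_3 u^{\mu_2}}, so that rapid firing lengthens
#' the dendritic refractory period and terminates the burst.
#'
#' @param alpha DAP current amplitude scale.
#' @param beta DAP decay time constant (s).
#' @param gamma DAP rise time constant (s).
#' @param mu1 per-spike increment of the refractory trace.
#' @param mu2 exponent mapping the trace to the refractory period.
#' @param mu3 scale (s) mapping the trace to the refractory period.
#' @param mu4 decay time constant (s) of the per-spike trace.
#' @param r_s baseline dendritic refractory period (s).
#' @param tau_b relaxation time constant (s) of the refractory period.
#' @param enabled logical; disable to obtain a plain LIF neuron.
#' @return An object of class \code{"dap_params"}.
#' @export
dap_params <- function(alpha = 20, beta = 2.45e-3, gamma = 1.4e-3,
                       mu1 = 0.6, mu2 = 2, mu3 = 0.7e-3, mu4 = 24.5e-3,
                       r_s = 0.7e-3, tau_b = 7e-3, enabled = TRUE) {
  if (any(c(beta, gamma, mu3, mu4, r_s, tau_b) <= 0))
    stop("all DAP time constants must be positive")
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 mu1 = mu1, mu2 = mu2, mu3 = mu3, mu4 = mu4,
                 r_s = r_s, tau_b = tau_b, enabled = isTRUE(enabled)),
            class = "dap_params")
}

#' Burst-plasticity parameters
#'
#' Parameters of the burst-timing-dependent depression acting on parallel-
#' fiber (PF) weights and of the slow non-associative potentiation that
#' relaxes weights back toward \code{w_max}. A small burst is exactly 2
#' spikes within \code{t_small}; a large burst is exactly 4 spikes within
#' \code{t_large}. A postsynaptic burst at time \eqn{t_b} depresses every
#' segment whose most recent onset \eqn{t_j} satisfies
#' \eqn{0 \le t_b - t_j \le W_k} by \eqn{\eta_k K_k(t_b - t_j)}, with a
#' causal linearly-decaying kernel \eqn{K_k(d) = 1 - d/W_k} by default.
#'
#' @param eta_small depression step for small (2-spike) bursts.
#' @param eta_large depression step for large (4-spike) bursts.
#' @param t_small small-burst detection window (s).
#' @param t_large large-burst detection window (s).
#' @param win_small LTD kernel support for small bursts (s). The defaults
#'   are sized so that, at the burst rates the equilibrated circuit
#'   produces, the depression flux a segment receives can be balanced by
#'   the slow potentiation at mid-range weights.
#' @param win_large LTD kernel support for large bursts (s).
#' @param tau_w potentiation (relaxation) time constant (s).
#' @param w_max upper weight bound and potentiation fixed point.
#' @return An object of class \code{"plasticity_params"}.
#' @export
plasticity_params <- function(eta_small = 0.0018, eta_large = 0.0036,
                              t_small = 10e-3, t_large = 100e-3,
                              win_small = 15e-3, win_large = 30e-3,
                              tau_w = 980, w_max = 1.5) {
  if (eta_small <= 0 || eta_large < eta_small)
    stop("need 0 < eta_small <= eta_large")
  if (any(c(t_small, t_large, win_small, win_large, tau_w) <= 0))
    stop("windows and tau_w must be positive")
  structure(list(eta_small = eta_small, eta_large = eta_large,
                 t_small = t_small, t_large = t_large,
                 win_small = win_small, win_large = win_large,
                 tau_w = tau_w, w_max = w_max),
            class = "plasticity_params")
}

#' Feedback gain configuration
#'
#' Contrast-dependent strength of the parallel-fiber feedback. Under global
#' stimulation the gain is \eqn{G(c) = G_0\, s(c)\, b(c)}, where \eqn{b(c)}
#' is the P-unit input/output amplitude and \eqn{s(c) \le 1} is a saturation
#' factor accounting for the limited growth of feedback-pathway activity at
#' high contrast; under local stimulation the feedback pathway is inactive
#' and the gain is exactly zero. The saturation table is linearly
#' interpolated and linearly extended beyond its last point (saturation
#' keeps deepening with contrast), floored at zero.
#'
#' @param G0 baseline gain, calibrated so the mean SP firing rate under
#'   global stimulation at a reference frequency/contrast matches its
#'   target (see \code{\link{calibrate_gain}}).
#' @param sat_contrasts,sat_factors saturation table \eqn{s(c)}; factors
#'   must be non-increasing in contrast and equal 1 at low contrast.
#' @param saturation logical; when \code{FALSE}, \eqn{s(c) \equiv 1}.
#' @param hf_attenuation multiplicative gain reduction applied only at
#'   frequencies at or above \code{hf_cutoff}, mirroring the decay of
#'   cancellation at the top of the studied frequency band.
#' @param hf_cutoff frequency (Hz) above which \code{hf_attenuation}
#'   applies.
#' @return An object of class \code{"feedback_gain"}.
#' @export
feedback_gain_params <- function(G0 = 2,
                                 sat_contrasts = c(5, 10, 15, 20),
                                 sat_factors = c(1, 1, 0.85, 0.7),
                                 saturation = TRUE,
                                 hf_attenuation = 0.9, hf_cutoff = 16) {
  if (length(sat_contrasts) != length(sat_factors))
    stop("saturation table lengths differ")
  if (is.unsorted(sat_contrasts)) stop("sat_contrasts must be increasing")
  if (any(diff(sat_factors) > 1e-12)) stop("sat_factors must be non-increasing")
  if (any(sat_factors <= 0 | sat_factors > 1)) stop("sat_factors must be in (0, 1]")
  structure(list(G0 = G0, sat_contrasts = sat_contrasts,
                 sat_factors = sat_factors, saturation = isTRUE(saturation),
                 hf_attenuation = hf_attenuation, hf_cutoff = hf_cutoff),
            class = "feedback_gain")
}

#' Saturation factor of the feedback pathway
#'
#' @param gain a \code{\link{feedback_gain_params}} object.
#' @param contrast stimulus contrast (percent).
#' @return \eqn{s(c)} in (0, 1].
#' @export
saturation_factor <- function(gain, contrast) {
  stopifnot(inherits(gain, "feedback_gain"))
  if (!gain$saturation) return(rep(1, length(contrast)))
  cs <- gain$sat_contrasts
  fs <- gain$sat_factors
  n <- length(cs)
  out <- numeric(length(contrast))
  for (i in seq_along(contrast)) {
    c0 <- contrast[i]
    if (c0 <= cs[1]) {
      out[i] <- fs[1]
    } else if (c0 >= cs[n]) {
      # linear extension of the last calibrated slope: saturation deepens
      slope <- if (n > 1) (fs[n] - fs[n - 1]) / (cs[n] - cs[n - 1]) else 0
      out[i] <- max(fs[n] + slope * (c0 - cs[n]), 1e-3)
    } else {
      out[i] <- stats::approx(cs, fs, xout = c0)$y
    }
  }
  out
}
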