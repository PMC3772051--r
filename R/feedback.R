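#' Build the parallel-fiber segment array
#'
#' The feedback cycle locked to one stimulus period is discretized into
#' phase segments of fixed duration; one parallel fiber (one burst per
#' stimulus period) is active per segment, carrying a plastic weight
#' \eqn{w_j \in [0, w_{max}]}. The number of segments is
#' \code{round(period / segment_duration)}; when the period is not an
#' exact multiple the actual segment duration absorbs the residual, which
#' is recorded in the returned object.
#'
#' @param frequency AM frequency (Hz).
#' @param segment_duration nominal segment duration (s); must be shorter
#'   than half the period.
#' @param w_init initial weight for every segment; defaults to
#'   \code{w_max}, the relaxed homeostatic fixed point from which learning
#'   only depresses.
#' @param w_max weight ceiling.
#' @return An object of class \code{"pf_array"} with fields
#'   \code{weights}, \code{onsets} (s), \code{segment_duration} (actual,
#'   s), \code{frequency}, \code{w_max}, \code{rounding_residual} (s).
#' @export
#' @examples
#' pf <- pf_segments(8, 2e-3)
#' length(pf$weights)  # 62 or 63 segments tiling 125 ms
pf_segments <- function(frequency, segment_duration = 2e-3,
                        w_init = w_max, w_max = 1.5) {
  if (frequency <= 0) stop("frequency must be positive")
  period <- 1 / frequency
  if (segment_duration >= period / 2)
    stop("segment_duration must be below half the stimulus period")
  n_seg <- round(period / segment_duration)
  residual <- period - n_seg * segment_duration
  if (abs(residual) > 1e-12)
    message(sprintf(
      "period %.6g s is not a multiple of the segment duration; using %d segments of %.6g s (residual %.3g s absorbed)",
      period, n_seg, period / n_seg, residual))
  actual <- period / n_seg
  w <- rep(w_init, n_seg)
  if (any(w < 0 | w > w_max)) stop("initial weights outside [0, w_max]")
  structure(list(weights = w, onsets = (seq_len(n_seg) - 1) * actual,
                 segment_duration = actual, frequency = frequency,
                 w_max = w_max, rounding_residual = residual),
            class = "pf_array")
}

#' Contrast-dependent feedback gain
#'
#' Overall strength of the parallel-fiber feedback:
#' \eqn{G(c) = G_0\, s(c)\, b(c)} for global stimuli (the feedback pathway
#' is itself driven by P-units, hence inherits their transfer \eqn{b(c)},
#' their low-frequency adaptation, and an extra saturation factor
#' \eqn{s(c)}); exactly zero for local stimuli, which do not recruit the
#' pathway.
#'
#' @param contrast stimulus contrast (percent).
#' @param transfer a \code{\link{punit_transfer}}.
#' @param gain a \code{\link{feedback_gain_params}}.
#' @param type \code{"local"} or \code{"global"}.
#' @param frequency optional AM frequency (Hz) for the adaptation and
#'   high-frequency attenuation factors; omit for the bare contrast map.
#' @return Gain \eqn{G \ge 0}.
#' @export
feedback_gain <- function(contrast, transfer, gain,
                          type = c("global", "local"), frequency = NULL) {
  type <- match.arg(type)
  if (type == "local") return(0)
  G <- gain$G0 * saturation_factor(gain, contrast) *
    transfer_amplitude(transfer, contrast)
  if (!is.null(frequency)) {
    G <- G * adaptation_at(transfer, frequency)
    if (frequency >= gain$hf_cutoff) G <- G * gain$hf_attenuation
  }
  G
}

#' Feedback contribution to the membrane equation
#'
#' Step-wise constant, periodic feedback term: at time \code{t} the active
#' segment is \eqn{j(t) = \lfloor (t \bmod 1/f)/\Delta \rfloor} and the
#' contribution combines parallel-fiber excitation proportional to the
#' weight with PF-driven shunting inhibition proportional to the membrane
#' potential (the inhibitory reversal sits at the resting potential, so
#' the inhibition vanishes at rest). Two algebraic groupings are
#' supported. \code{"pooled"} (default),
#' \eqn{G\,(w_j - g V)}: the interneurons providing the disynaptic
#' inhibition pool many parallel fibers, so the shunting conductance
#' \eqn{g G} follows the overall feedback-pathway activity (and hence the
#' contrast) but not the plastic weight of the single active segment;
#' this preserves the transfer of the weight-profile modulation to the
#' membrane. \code{"weighted"}, \eqn{G\, w_j\, (1 - g V)}: inhibition
#' also scales with the active weight, making excitation and inhibition
#' cancel near \eqn{V = 1/g} and strongly attenuating the modulation
#' transfer.
#'
#' @param t time(s) in seconds.
#' @param v membrane potential (scalar or same length as \code{t}).
#' @param pf a \code{\link{pf_segments}} array.
#' @param G feedback gain (see \code{\link{feedback_gain}}).
#' @param shunt_g shunting conductance scale \eqn{g}.
#' @param shunt_mode \code{"pooled"} or \code{"weighted"} grouping.
#' @return Feedback term value(s).
#' @export
feedback_term <- function(t, v, pf, G, shunt_g = 1.44,
                          shunt_mode = c("pooled", "weighted")) {
  stopifnot(inherits(pf, "pf_array"))
  shunt_mode <- match.arg(shunt_mode)
  period <- 1 / pf$frequency
  j <- pmin(floor((t %% period) / pf$segment_duration),
            length(pf$weights) - 1) + 1
  if (shunt_mode == "weighted")
    G * pf$weights[j] * (1 - shunt_g * v)
  else
    G * (pf$weights[j] - shunt_g * v)
}

#' Calibrate the baseline feedback gain G0
#'
#' Bisection on \eqn{G_0} so that the mean SP firing rate under global
#' stimulation at a reference frequency and contrast, with the PF array at
#' its relaxed state (all weights at \code{w_max}), matches a target mean
#' rate. The rate is monotone in \eqn{G_0} over the operating range (with
#' the default pooled shunting it decreases as the gain grows, because the
#' added conductance quenches the noise-driven firing); the bisection
#' adapts to the direction found at the brackets.
#'
#' @param target_rate target mean firing rate (spikes/s).
#' @param transfer a \code{\link{punit_transfer}}.
#' @param neuron,dap parameter objects.
#' @param gain template \code{\link{feedback_gain_params}}; its saturation
#'   table is kept, \code{G0} is replaced.
#' @param f_ref,c_ref reference frequency (Hz) and contrast (percent).
#' @param segment_duration PF segment duration (s).
#' @param cycles simulated cycles per probe.
#' @param dt integration step (s).
#' @param seed RNG seed (common random numbers across probes).
#' @param G_max upper bracket.
#' @param tol bisection tolerance on \eqn{G_0}.
#' @return The input \code{gain} object with calibrated \code{G0} and an
#'   attribute \code{"achieved_rate"}.
#' @export
calibrate_gain <- function(target_rate, transfer,
                           neuron = neuron_params(), dap = dap_params(),
                           gain = feedback_gain_params(),
                           f_ref = 8, c_ref = 10,
                           segment_duration = 2e-3,
                           cycles = 160, dt = 2.5e-5, seed = 1,
                           G_max = 4, tol = 1e-3) {
  pf <- pf_segments(f_ref, segment_duration)
  spec <- am_stimulus(f_ref, c_ref, cycles / f_ref, "global")
  rate_at <- function(G0) {
    g2 <- gain; g2$G0 <- G0
    sim <- simulate_sp(spec, transfer, neuron, dap, feedback = pf,
                       gain = g2, dt = dt, seed = seed)
    length(sim$spikes) / sim$duration
  }
  r_lo <- rate_at(0)
  r_hi <- rate_at(G_max)
  if (target_rate < min(r_lo, r_hi) || target_rate > max(r_lo, r_hi))
    stop(sprintf("target rate %.1f outside achievable range [%.1f, %.1f]",
                 target_rate, min(r_lo, r_hi), max(r_lo, r_hi)))
  increasing <- r_hi > r_lo
  lo <- 0; hi <- G_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (xor(rate_at(mid) < target_rate, !increasing)) lo <- mid else hi <- mid
  }
  gain$G0 <- (lo + hi) / 2
  attr(gain, "achieved_rate") <- rate_at(gain$G0)
  gain
}
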