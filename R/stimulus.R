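#' Amplitude-modulation stimulus specification
#'
#' Describes a sinusoidal amplitude modulation (AM) of the fish's electric
#' organ discharge: \eqn{s(t) = \sin(2\pi f t)} scaled by the contrast-
#' dependent P-unit output. Local stimuli (prey-like) drive only the
#' feedforward pathway; global stimuli (conspecific-like) additionally
#' recruit the parallel-fiber feedback.
#'
#' @param frequency AM frequency (Hz), positive.
#' @param contrast AM contrast in percent of the carrier amplitude, in
#'   \code{[0, 20]}; the model is validated only over the quasi-linear to
#'   mildly saturating P-unit regime.
#' @param duration stimulus duration (s), positive.
#' @param type \code{"local"} or \code{"global"}.
#' @param phase_origin stimulus phase at t = 0 (radians); phase 0 is the
#'   ascending zero-crossing.
#' @param contrast_max upper validity bound for \code{contrast}; raise it
#'   explicitly (e.g. for learning-contrast scans above 20\%) if needed.
#' @return An object of class \code{"am_stimulus"}.
#' @export
#' @examples
#' am_stimulus(8, 10, duration = 2, type = "global")
am_stimulus <- function(frequency, contrast, duration,
                        type = c("global", "local"), phase_origin = 0,
                        contrast_max = 20) {
  type <- match.arg(type)
  if (frequency <= 0) stop("frequency must be positive")
  if (contrast < 0) stop("contrast must be non-negative")
  if (contrast > contrast_max)
    stop("contrast exceeds the validated range (raise contrast_max to override)")
  if (duration <= 0) stop("duration must be positive")
  structure(list(frequency = frequency, contrast = contrast,
                 duration = duration, type = type,
                 phase_origin = phase_origin),
            class = "am_stimulus")
}

#' P-unit population transfer (contrast to input amplitude)
#'
#' The P-unit electroreceptor population encodes an AM of contrast \eqn{c}
#' as a sinusoidal rate modulation whose amplitude, in model-voltage units,
#' is \eqn{b(c)}: quasi-linear at low contrast and saturating above roughly
#' 10\%. \eqn{b} is stored as a calibration table, linearly interpolated
#' between points and clamped at the last point (saturated regime). At low
#' AM frequencies P-units adapt, which is captured by a constant
#' multiplicative factor \eqn{a(f) < 1} for \eqn{f \le} the cutoff.
#'
#' @param contrasts calibration contrasts (percent), increasing, the first
#'   implicitly anchored by \eqn{b(0) = 0}.
#' @param amplitudes input amplitudes \eqn{b(c)}, non-negative and
#'   non-decreasing with non-increasing increments (saturation).
#' @param adaptation_factor multiplier in (0, 1] applied for
#'   \code{frequency <= adaptation_cutoff}.
#' @param adaptation_cutoff frequency (Hz) at or below which adaptation
#'   applies; default the lowest studied AM band.
#' @return An object of class \code{"punit_transfer"}.
#' @seealso \code{\link{calibrate_transfer}} for fitting the table to
#'   observed maximum firing rates, \code{\link{default_transfer}}.
#' @export
punit_transfer <- function(contrasts, amplitudes,
                           adaptation_factor = 0.9, adaptation_cutoff = 2) {
  if (length(contrasts) < 2) stop("need at least two calibration points")
  if (length(contrasts) != length(amplitudes)) stop("table lengths differ")
  if (is.unsorted(contrasts, strictly = TRUE))
    stop("contrasts must be strictly increasing")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  if (any(diff(amplitudes) < -1e-12)) stop("b(c) must be non-decreasing")
  if (adaptation_factor <= 0 || adaptation_factor > 1)
    stop("adaptation_factor must be in (0, 1]")
  if (contrasts[1] > 0) {  # anchor b(0) = 0
    contrasts <- c(0, contrasts)
    amplitudes <- c(0, amplitudes)
  }
  structure(list(contrasts = contrasts, amplitudes = amplitudes,
                 adaptation_factor = adaptation_factor,
                 adaptation_cutoff = adaptation_cutoff),
            class = "punit_transfer")
}

#' Default P-unit transfer
#'
#' Calibration table obtained by matching the model SP cell's maximum
#' cycle-histogram firing rates to the synthetic reference targets at
#' contrasts 5, 10, 15 and 20\% (see \code{\link{calibrate_transfer}});
#' shipped as a convenience so simulations run without re-calibration.
#'
#' @return A \code{\link{punit_transfer}} object.
#' @export
default_transfer <- function() {
  punit_transfer(contrasts = c(5, 10, 15, 20),
                 amplitudes = .default_b,
                 adaptation_factor = 0.9, adaptation_cutoff = 2)
}

# filled in by calibration against the default synthetic reference
# (quasi-linear to 10%, saturating above)
.default_b <- c(0.23, 0.42, 0.53, 0.60)

#' Interpolate the P-unit transfer at a contrast
#'
#' Linear interpolation between calibration points; clamped beyond the last
#' point, where the P-unit response has saturated.
#'
#' @param transfer a \code{\link{punit_transfer}} object.
#' @param contrast contrast(s) in percent, non-negative.
#' @return Input amplitude(s) \eqn{b(c)}.
#' @export
transfer_amplitude <- function(transfer, contrast) {
  stopifnot(inherits(transfer, "punit_transfer"))
  if (any(contrast < 0)) stop("contrast must be non-negative")
  stats::approx(transfer$contrasts, transfer$amplitudes, xout = contrast,
                rule = 2)$y
}

#' Adaptation factor at an AM frequency
#' @param transfer a \code{\link{punit_transfer}} object.
#' @param frequency AM frequency (Hz).
#' @return \eqn{a(f)}: \code{adaptation_factor} for frequencies at or below
#'   the cutoff, 1 otherwise.
#' @export
adaptation_at <- function(transfer, frequency) {
  ifelse(frequency <= transfer$adaptation_cutoff,
         transfer$adaptation_factor, 1)
}

#' Feedforward drive from the P-unit population
#'
#' The signal entering the SP neuron from the electroreceptors:
#' \deqn{S(t) = a(f)\, b(c)\, \sin(2\pi f t + \phi_0)}
#' deterministic and periodic with period \eqn{1/f}.
#'
#' @param spec an \code{\link{am_stimulus}}.
#' @param transfer a \code{\link{punit_transfer}}.
#' @param t time(s) in seconds within \code{[0, duration]}.
#' @return Drive value(s) \eqn{S(t)}.
#' @export
am_drive <- function(spec, transfer, t) {
  stopifnot(inherits(spec, "am_stimulus"))
  amp <- drive_amplitude(spec, transfer)
  amp * sin(2 * pi * spec$frequency * t + spec$phase_origin)
}

# peak feedforward amplitude a(f) * b(c) for a stimulus
drive_amplitude <- function(spec, transfer) {
  transfer_amplitude(transfer, spec$contrast) *
    adaptation_at(transfer, spec$frequency)
}

#' Calibrate the P-unit transfer against maximum-firing-rate targets
#'
#' Reproduces the input/output calibration: the model SP neuron is
#' simulated without feedback at a reference AM frequency for a range of
#' drive amplitudes; the amplitude at which the maximum of the cycle
#' histogram equals each target rate is found by bracketing and bisection
#' on the monotone amplitude-to-max-rate curve. Common random numbers
#' (the same seed for every amplitude probe) keep the curve smooth so the
#' bisection is well posed.
#'
#' @param targets data frame with columns \code{contrast} (percent) and
#'   \code{max_rate} (spikes/s), the observed maximum cycle-histogram rates.
#' @param neuron,dap \code{\link{neuron_params}} / \code{\link{dap_params}}.
#' @param f_ref reference AM frequency (Hz).
#' @param cycles cycles simulated per probe; more cycles shrink the
#'   Monte-Carlo error of the max-rate estimate (the peak is read from a
#'   circularly smoothed cycle histogram, see
#'   \code{\link{psth_peak_rate}}, so that the bisection acts on a
#'   monotone curve rather than a noisy extreme statistic).
#' @param dt integration step (s).
#' @param seed RNG seed used for every probe.
#' @param amp_max upper bracket for the drive amplitude.
#' @param tol bisection tolerance on the amplitude.
#' @param adaptation_factor,adaptation_cutoff passed to the returned
#'   \code{\link{punit_transfer}}.
#' @return A calibrated \code{\link{punit_transfer}} with an attribute
#'   \code{"report"}: a data frame (contrast, amplitude, achieved rate).
#' @export
calibrate_transfer <- function(targets, neuron = neuron_params(),
                               dap = dap_params(), f_ref = 8,
                               cycles = 400, dt = 2.5e-5, seed = 1,
                               amp_max = 2, tol = 2e-3,
                               adaptation_factor = 0.9,
                               adaptation_cutoff = 2) {
  stopifnot(is.data.frame(targets),
            all(c("contrast", "max_rate") %in% names(targets)))
  targets <- targets[order(targets$contrast), ]
  if (any(diff(targets$max_rate) < 0))
    stop("target max rates must be non-decreasing in contrast")

  max_rate_at <- function(amp) {
    set.seed(seed)
    sp <- simulate_sp_raw(duration = cycles / f_ref, dt = dt,
                          am_f = f_ref, drive_amp = amp,
                          neuron = neuron, dap = dap)
    psth <- compute_psth(sp$spikes, f_ref, n_bins = 32,
                         duration = cycles / f_ref)
    psth_peak_rate(psth)
  }

  r0 <- max_rate_at(0)
  r_hi <- max_rate_at(amp_max)
  amps <- numeric(nrow(targets))
  achieved <- numeric(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    tr <- targets$max_rate[i]
    if (tr <= r0 + 1e-9) {
      amps[i] <- 0; achieved[i] <- r0
      next
    }
    if (tr > r_hi)
      stop(sprintf(
        "target rate %.1f spk/s unreachable: achievable range [%.1f, %.1f]",
        tr, r0, r_hi))
    lo <- 0; hi <- amp_max
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (max_rate_at(mid) < tr) lo <- mid else hi <- mid
    }
    amps[i] <- (lo + hi) / 2
    achieved[i] <- max_rate_at(amps[i])
  }
  if (any(diff(amps) < 0))
    stop("calibration produced a non-monotone b(c); check targets")
  tf <- punit_transfer(targets$contrast, amps,
                       adaptation_factor = adaptation_factor,
                       adaptation_cutoff = adaptation_cutoff)
  attr(tf, "report") <- data.frame(contrast = targets$contrast,
                                   amplitude = amps,
                                   target_rate = targets$max_rate,
                                   achieved_rate = achieved)
  tf
}
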