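#' Cycle histogram (PSTH) of a spike train
#'
#' Folds spike times modulo the stimulus period into uniform phase bins;
#' the rate in a bin is count / (n_cycles * bin_duration), so the total
#' spike count is conserved exactly.
#'
#' @param spikes spike times (s).
#' @param frequency stimulus frequency (Hz).
#' @param n_bins number of phase bins (at least 4).
#' @param duration recording duration (s); must span at least one cycle,
#'   and at least 10 for stable estimates.
#' @return An object of class \code{"psth"}: \code{phase_bins} (bin-center
#'   phases, radians), \code{rates} (spikes/s), \code{n_cycles},
#'   \code{baseline} (mean rate).
#' @export
compute_psth <- function(spikes, frequency, n_bins = 32, duration) {
  if (n_bins < 4) stop("need at least 4 phase bins")
  period <- 1 / frequency
  n_cycles <- duration / period
  if (n_cycles < 1) stop("recording shorter than one stimulus cycle")
  phase <- (spikes %% period) / period                 # in [0, 1)
  counts <- tabulate(pmin(floor(phase * n_bins), n_bins - 1) + 1, n_bins)
  bin_dur <- period / n_bins
  rates <- counts / (n_cycles * bin_dur)
  structure(list(phase_bins = 2 * pi * (seq_len(n_bins) - 0.5) / n_bins,
                 rates = rates, n_cycles = n_cycles,
                 baseline = mean(rates)),
            class = "psth")
}

#' Sine-fit amplitude of a global response
#'
#' Least-squares fit of \eqn{r(\phi) = b_0 + a_1\sin\phi + a_2\cos\phi}
#' to the PSTH at the stimulus frequency; returns the modulation amplitude
#' \eqn{|A| = \sqrt{a_1^2 + a_2^2}}. The attribute \code{"inphase"} holds
#' the signed stimulus-phase component \eqn{a_1}: positive when the
#' residual modulation is in phase with the stimulus (under-cancellation),
#' negative when anti-phase (over-cancellation).
#'
#' @param psth a \code{\link{compute_psth}} object.
#' @return Amplitude (spikes/s) with attributes \code{"inphase"},
#'   \code{"phase"} (radians) and \code{"baseline"}.
#' @export
fit_global_amplitude <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  ph <- psth$phase_bins
  fit <- stats::lm(psth$rates ~ sin(ph) + cos(ph))
  a1 <- unname(stats::coef(fit)[2])
  a2 <- unname(stats::coef(fit)[3])
  structure(sqrt(a1^2 + a2^2), inphase = a1, phase = atan2(a2, a1),
            baseline = unname(stats::coef(fit)[1]))
}

#' Gaussian-fit height of a local response
#'
#' The rectified local response deviates from a sinusoid, so its PSTH is
#' fitted with a circular Gaussian bump plus baseline,
#' \eqn{r(\phi) = b_0 + H \exp(-d(\phi, \phi_c)^2 / 2\varsigma^2)} with
#' wrapped phase distance \eqn{d}; the height \eqn{H} is returned.
#' Fitting is least squares via \code{optim}, initialized at the peak
#' bin, with the width bounded below by roughly one bin so that sampling
#' spikes in a flat histogram cannot masquerade as a narrow response
#' peak; a flat histogram yields \eqn{H = 0} with attribute
#' \code{"flagged" = TRUE}.
#'
#' @param psth a \code{\link{compute_psth}} object.
#' @return Height \eqn{H} (spikes/s) with attributes \code{"center"},
#'   \code{"width"}, \code{"baseline"}, \code{"flagged"}.
#' @export
fit_local_amplitude <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  ph <- psth$phase_bins
  r <- psth$rates
  if (stats::sd(r) < 1e-9)
    return(structure(0, center = NA_real_, width = NA_real_,
                     baseline = mean(r), flagged = TRUE))
  wrap <- function(d) ((d + pi) %% (2 * pi)) - pi
  sd_min <- 0.15                      # ~ 3/4 of a bin at 32 bins
  width_of <- function(p4) sqrt(p4^2 + sd_min^2)
  obj <- function(p) {
    mu <- p[1] + p[2] * exp(-wrap(ph - p[3])^2 / (2 * width_of(p[4])^2))
    sum((r - mu)^2)
  }
  start <- c(b0 = min(r), H = max(r) - min(r),
             phi = ph[which.max(r)], sd = 0.8)
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0) {  # retry from a broader bump
    start2 <- start; start2["sd"] <- 1.5
    opt2 <- stats::optim(start2, obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-10))
    if (opt2$value < opt$value) opt <- opt2
  }
  structure(unname(opt$par["H"]), center = unname(opt$par["phi"]),
            width = width_of(unname(opt$par["sd"])),
            baseline = unname(opt$par["b0"]),
            flagged = opt$convergence != 0)
}

#' Cancellation index
#'
#' \eqn{C = 1 - A_{global}/A_{local}}: 1 is perfect cancellation of the
#' global signal, 0 none. Values below 0 (over-cancellation at the level
#' of raw amplitudes) are reported, not clipped.
#'
#' @param a_local fitted local response height (spikes/s), positive.
#' @param a_global fitted global response amplitude (spikes/s).
#' @return The cancellation fraction.
#' @export
cancellation <- function(a_local, a_global) {
  if (any(a_local <= 0)) stop("A_local must be positive")
  as.numeric(1 - a_global / a_local)
}

#' Degradation of cancellation
#'
#' The complement of the frequency-averaged cancellation at a contrast:
#' \eqn{D = 1 - N_f^{-1} \sum_f C(f)}.
#'
#' @param c_by_frequency cancellation values, one per AM frequency.
#' @return Degradation \eqn{D}.
#' @export
degradation <- function(c_by_frequency) {
  if (length(c_by_frequency) == 0) stop("need at least one frequency")
  1 - mean(as.numeric(c_by_frequency))
}

#' Squared-error between model and reference degradation curves
#'
#' \eqn{E = \sum_c (D_{model}(c) - D_{ref}(c))^2} over a shared contrast
#' grid (capped at 20\% by convention).
#'
#' @param model_d,reference_d named numeric vectors (names = contrasts) or
#'   plain vectors on the same grid.
#' @return Non-negative scalar error.
#' @export
cancellation_error <- function(model_d, reference_d) {
  if (length(model_d) != length(reference_d))
    stop("degradation curves are on different contrast grids")
  if (!is.null(names(model_d)) && !is.null(names(reference_d)) &&
      !identical(names(model_d), names(reference_d)))
    stop("degradation curves are on different contrast grids")
  sum((as.numeric(model_d) - as.numeric(reference_d))^2)
}

#' Peak rate of a cycle histogram
#'
#' Maximum of the rate profile after a circular 3-bin moving average
#' (weights 1/4, 1/2, 1/4). The raw bin maximum is an extreme statistic
#' whose sampling noise makes amplitude calibration ill-conditioned; the
#' light smoothing stabilizes it without shifting a broad response peak.
#'
#' @param psth a \code{\link{compute_psth}} object.
#' @return Peak rate (spikes/s).
#' @export
psth_peak_rate <- function(psth) {
  stopifnot(inherits(psth, "psth"))
  r <- psth$rates
  n <- length(r)
  sm <- 0.5 * r + 0.25 * (r[c(n, seq_len(n - 1))] + r[c(seq_len(n - 1) + 1, 1)])
  max(sm)
}
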