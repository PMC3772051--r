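#' Assemble the full cancellation-circuit model
#'
#' Bundles every component of the ELL cancellation circuit: the P-unit
#' transfer, the SP neuron and its burst mechanism, the feedback gain and
#' the plasticity rule, plus the numerical settings. The object is the
#' single configuration handle passed to \code{\link{ell_train}} and the
#' experiment drivers.
#'
#' @param transfer a \code{\link{punit_transfer}}.
#' @param neuron a \code{\link{neuron_params}}.
#' @param dap a \code{\link{dap_params}}.
#' @param gain a \code{\link{feedback_gain_params}}.
#' @param plasticity a \code{\link{plasticity_params}}.
#' @param segment_duration PF phase-segment duration (s).
#' @param shunt_g shunting conductance scale \eqn{g}.
#' @param shunt_mode shunting grouping, \code{"pooled"} (default) or
#'   \code{"weighted"}; see \code{\link{feedback_term}}.
#' @param dt integration step (s).
#' @return An object of class \code{"ell_model"}.
#' @export
#' @examples
#' m <- ell_model()
#' fit <- ell_train(m, frequency = 8, learning_contrast = 15,
#'                  epochs = 10, seed = 1)
ell_model <- function(transfer = default_transfer(),
                      neuron = neuron_params(),
                      dap = dap_params(),
                      gain = feedback_gain_params(),
                      plasticity = plasticity_params(),
                      segment_duration = 2e-3,
                      shunt_g = 1.44,
                      shunt_mode = c("pooled", "weighted"),
                      dt = 2.5e-5) {
  shunt_mode <- match.arg(shunt_mode)
  stopifnot(inherits(transfer, "punit_transfer"),
            inherits(neuron, "neuron_params"),
            inherits(dap, "dap_params"),
            inherits(gain, "feedback_gain"),
            inherits(plasticity, "plasticity_params"))
  structure(list(transfer = transfer, neuron = neuron, dap = dap,
                 gain = gain, plasticity = plasticity,
                 segment_duration = segment_duration,
                 shunt_g = shunt_g, shunt_mode = shunt_mode, dt = dt),
            class = "ell_model")
}

#' @export
print.ell_model <- function(x, ...) {
  cat("ELL cancellation-circuit model\n")
  cat(sprintf("  P-unit transfer: b(c) at c = {%s}%% -> {%s}\n",
              paste(x$transfer$contrasts[-1], collapse = ", "),
              paste(signif(x$transfer$amplitudes[-1], 3), collapse = ", ")))
  cat(sprintf("  neuron: tau_m %.1f ms, bias %.2f, sigma %.3f; DAP %s\n",
              1e3 * x$neuron$tau_m, x$neuron$bias, x$neuron$sigma,
              if (x$dap$enabled) "on" else "off"))
  cat(sprintf("  feedback: G0 %.3f, saturation %s, segments %.1f ms, g %.2f\n",
              x$gain$G0, if (x$gain$saturation) "on" else "off",
              1e3 * x$segment_duration, x$shunt_g))
  cat(sprintf("  plasticity: eta %.2g/%.2g, tau_w %g s, w_max %.2f\n",
              x$plasticity$eta_small, x$plasticity$eta_large,
              x$plasticity$tau_w, x$plasticity$w_max))
  invisible(x)
}

# plasticity with the desk-run time compression applied: tau_w / scale and
# eta * scale move together so the depression/potentiation balance (and
# hence the equilibrium weight profile) is preserved while convergence is
# reached `scale` times faster
scaled_plasticity <- function(pp, scale) {
  pp$tau_w <- pp$tau_w / scale
  pp$eta_small <- pp$eta_small * scale
  pp$eta_large <- pp$eta_large * scale
  pp
}

#' Train the parallel-fiber weights to equilibrium
#'
#' Runs the full closed loop under a global sinusoidal stimulus at the
#' learning contrast: the SP neuron is simulated with feedback and online
#' plasticity (burst-triggered depression plus continuous homeostatic
#' potentiation) in epochs of several stimulus cycles, until the weight
#' profile stops changing. The equilibrated profile forms a negative image
#' of the stimulus: weights are lowest for segments just preceding the
#' stimulus peak, where SP bursts are concentrated.
#'
#' Training uses a time-compression factor \code{scale}: \eqn{\tau_w} is
#' divided and both \eqn{\eta} multiplied by it, which leaves the
#' depression/potentiation balance -- and therefore the equilibrium
#' profile -- unchanged while reaching it \code{scale} times faster.
#' \code{scale = 1} runs the biological time constants.
#'
#' @param model an \code{\link{ell_model}}.
#' @param frequency AM frequency (Hz); feedback channels are
#'   frequency-specific, so weights are trained per frequency.
#' @param learning_contrast contrast (percent) present during learning.
#' @param epochs maximum number of epochs.
#' @param cycles_per_epoch stimulus cycles per epoch; default gives
#'   epochs of about 4 s (at least 8 cycles).
#' @param tol convergence tolerance: the weight profile is averaged over
#'   blocks of \code{block} epochs (individual epochs fluctuate at the
#'   compressed plasticity step size, so single-epoch changes never
#'   settle); training stops once consecutive block means differ by less
#'   than \code{tol} in the maximum norm. The default accommodates the
#'   stochastic block-to-block fluctuation at \code{scale = 10}.
#' @param block epochs per averaging block.
#' @param scale time-compression factor for the plasticity rates.
#' @param seed RNG seed.
#' @return An object of class \code{"ell_fit"}: the trained \code{pf}
#'   array (weights = mean profile over the final block), the weight
#'   \code{trajectory} (epoch x segment), convergence information, and
#'   the training configuration.
#' @export
ell_train <- function(model, frequency, learning_contrast,
                      epochs = 150, cycles_per_epoch = NULL,
                      tol = 0.10, block = 25, scale = 10, seed = 1) {
  stopifnot(inherits(model, "ell_model"))
  if (is.null(cycles_per_epoch))
    cycles_per_epoch <- max(8, ceiling(4 * frequency))
  pp <- scaled_plasticity(model$plasticity, scale)
  pf <- pf_segments(frequency, model$segment_duration,
                    w_max = model$plasticity$w_max)
  spec <- am_stimulus(frequency, learning_contrast,
                      cycles_per_epoch / frequency, "global",
                      contrast_max = max(20, learning_contrast))
  G <- feedback_gain(learning_contrast, model$transfer, model$gain,
                     "global", frequency = frequency)
  set.seed(seed)
  traj <- matrix(NA_real_, nrow = epochs, ncol = length(pf$weights))
  converged <- FALSE
  n_run <- epochs
  prev_block <- NULL
  delta <- NA_real_
  for (e in seq_len(epochs)) {
    res <- simulate_sp_raw(spec$duration, model$dt, frequency,
                           drive_amplitude(spec, model$transfer),
                           model$neuron, model$dap,
                           feedback = pf, G = G, shunt_g = model$shunt_g,
                           shunt_mode = model$shunt_mode,
                           plastic = TRUE, plasticity = pp)
    pf$weights <- res$weights
    traj[e, ] <- res$weights
    if (e %% block == 0) {
      bm <- colMeans(traj[(e - block + 1):e, , drop = FALSE])
      if (!is.null(prev_block)) {
        delta <- max(abs(bm - prev_block))
        if (delta < tol) { converged <- TRUE; n_run <- e; break }
      }
      prev_block <- bm
    }
  }
  if (!converged)
    warning(sprintf(
      "weights not stationary after %d epochs (last block change %.4f)",
      epochs, delta))
  nb <- min(block, n_run)
  pf$weights <- colMeans(traj[(n_run - nb + 1):n_run, , drop = FALSE])
  structure(list(model = model, pf = pf, frequency = frequency,
                 learning_contrast = learning_contrast,
                 trajectory = traj[seq_len(n_run), , drop = FALSE],
                 converged = converged, epochs = n_run,
                 cycles_per_epoch = cycles_per_epoch,
                 scale = scale, seed = seed),
            class = "ell_fit")
}

#' @export
print.ell_fit <- function(x, ...) {
  cat(sprintf(
    "Equilibrated PF weights: f = %g Hz, learning contrast = %g%%\n",
    x$frequency, x$learning_contrast))
  cat(sprintf("  %d segments, %d epochs (%s), weights in [%.3f, %.3f]\n",
              length(x$pf$weights), x$epochs,
              if (x$converged) "converged" else "NOT converged",
              min(x$pf$weights), max(x$pf$weights)))
  cat(sprintf("  negative-image correlation r = %.3f\n",
              negative_image_correlation(x)))
  invisible(x)
}

#' @export
coef.ell_fit <- function(object, ...) {
  w <- object$pf$weights
  names(w) <- sprintf("phase_%.3f", segment_phases(object$pf))
  w
}

# segment mid-phases in radians
segment_phases <- function(pf) {
  2 * pi * (pf$onsets + pf$segment_duration / 2) * pf$frequency
}

#' Correlation between the weight profile and the stimulus
#'
#' Pearson correlation across segments between the equilibrated weights
#' and the stimulus waveform \eqn{\sin(\phi_j)} at the segment phases.
#' A learned negative image gives a strongly negative value.
#'
#' @param fit an \code{\link{ell_train}} fit.
#' @return Pearson r.
#' @export
negative_image_correlation <- function(fit) {
  stopifnot(inherits(fit, "ell_fit"))
  stats::cor(fit$pf$weights, sin(segment_phases(fit$pf)))
}

#' @export
summary.ell_fit <- function(object, ...) {
  ph <- segment_phases(object$pf)
  w <- object$pf$weights
  out <- list(
    frequency = object$frequency,
    learning_contrast = object$learning_contrast,
    n_segments = length(w),
    converged = object$converged,
    epochs = object$epochs,
    weight_range = range(w),
    negative_image_r = negative_image_correlation(object),
    peak_weight = w[which.min(abs(ph - pi / 2))],
    trough_weight = w[which.min(abs(ph - 3 * pi / 2))])
  class(out) <- "summary.ell_fit"
  out
}

#' @export
print.summary.ell_fit <- function(x, ...) {
  cat(sprintf("PF equilibrium at f = %g Hz, learning contrast %g%%\n",
              x$frequency, x$learning_contrast))
  cat(sprintf("  segments: %d; epochs: %d (%s)\n", x$n_segments, x$epochs,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  weights: [%.3f, %.3f]; at stimulus peak %.3f, trough %.3f\n",
              x$weight_range[1], x$weight_range[2],
              x$peak_weight, x$trough_weight))
  cat(sprintf("  negative-image correlation: r = %.3f\n",
              x$negative_image_r))
  invisible(x)
}

#' @export
plot.ell_fit <- function(x, ...) {
  ph <- segment_phases(x$pf)
  w <- x$pf$weights
  plot(ph, w, type = "s", xlab = "stimulus phase (rad)",
       ylab = "PF weight", ylim = c(0, x$pf$w_max),
       main = sprintf("Negative image (f = %g Hz, learning c = %g%%)",
                      x$frequency, x$learning_contrast), ...)
  sc <- sin(ph)
  lines(ph, mean(w) + diff(range(w)) / 2 * sc, lty = 2, col = "grey50")
  legend("bottomleft", legend = c("PF weights", "stimulus (scaled)"),
         lty = c(1, 2), col = c("black", "grey50"), bty = "n")
  invisible(x)
}

#' Simulate the trained circuit
#'
#' Generates spike trains from the SP neuron driven at a test contrast
#' with the equilibrated PF weights. By default the standing plasticity
#' keeps operating at the biological (uncompressed) rates, whose drift
#' over a test recording is negligible; set \code{freeze = TRUE} to hold
#' the weights fixed.
#'
#' @param object an \code{ell_fit}.
#' @param nsim number of independent trials.
#' @param seed RNG seed.
#' @param contrast test contrast (percent); defaults to the learning
#'   contrast.
#' @param type \code{"global"} (with feedback) or \code{"local"}.
#' @param cycles stimulus cycles per trial.
#' @param freeze hold weights fixed during the simulation.
#' @param ... unused.
#' @return A list of \code{sp_simulation} objects (length \code{nsim}).
#' @export
simulate.ell_fit <- function(object, nsim = 1, seed = NULL,
                             contrast = object$learning_contrast,
                             type = c("global", "local"),
                             cycles = 40, freeze = FALSE, ...) {
  type <- match.arg(type)
  m <- object$model
  f <- object$frequency
  if (!is.null(seed)) set.seed(seed)
  spec <- am_stimulus(f, contrast, cycles / f, type,
                      contrast_max = max(20, contrast))
  lapply(seq_len(nsim), function(i) {
    if (type == "local") {
      res <- simulate_sp_raw(spec$duration, m$dt, f,
                             drive_amplitude(spec, m$transfer),
                             m$neuron, m$dap)
    } else {
      G <- feedback_gain(contrast, m$transfer, m$gain, "global",
                         frequency = f)
      res <- simulate_sp_raw(spec$duration, m$dt, f,
                             drive_amplitude(spec, m$transfer),
                             m$neuron, m$dap,
                             feedback = object$pf, G = G,
                             shunt_g = m$shunt_g,
                             shunt_mode = m$shunt_mode,
                             plastic = !freeze,
                             plasticity = m$plasticity)
    }
    structure(list(spikes = res$spikes, duration = spec$duration,
                   frequency = f, contrast = contrast, type = type),
              class = "sp_simulation")
  })
}

#' Cancellation of the trained circuit at test contrasts
#'
#' For each test contrast, simulates the local response (feedforward only)
#' and the global response (with the trained feedback), fits the response
#' amplitudes (Gaussian height for local, sine amplitude for global) and
#' returns the cancellation index \eqn{C = 1 - A_{global}/A_{local}}.
#'
#' @param object an \code{ell_fit}.
#' @param contrasts test contrasts (percent).
#' @param cycles stimulus cycles per measurement.
#' @param n_bins PSTH bins per cycle.
#' @param seed RNG seed.
#' @param freeze hold weights fixed during the test simulations.
#' @param ... unused.
#' @return Data frame: frequency, contrast, A_local, A_global, C, plus the
#'   signed in-phase residual amplitude \code{inphase} of the global
#'   response (positive = residual in phase with the stimulus, i.e.
#'   under-cancellation; negative = anti-phase, over-cancellation).
#' @export
predict.ell_fit <- function(object, contrasts = c(5, 10, 15, 20),
                            cycles = 60, n_bins = 32, seed = 1,
                            freeze = FALSE, ...) {
  rows <- lapply(contrasts, function(cc) {
    loc <- simulate.ell_fit(object, nsim = 1, seed = seed, contrast = cc,
                            type = "local", cycles = cycles)[[1]]
    glo <- simulate.ell_fit(object, nsim = 1, seed = seed + 1,
                            contrast = cc, type = "global",
                            cycles = cycles, freeze = freeze)[[1]]
    pl <- compute_psth(loc$spikes, object$frequency, n_bins, loc$duration)
    pg <- compute_psth(glo$spikes, object$frequency, n_bins, glo$duration)
    al <- fit_local_amplitude(pl)
    ag <- fit_global_amplitude(pg)
    data.frame(frequency = object$frequency, contrast = cc,
               A_local = al, A_global = ag,
               C = cancellation(al, ag),
               inphase = attr(ag, "inphase"))
  })
  do.call(rbind, rows)
}

#' Residual global-response modulation of a trained fit
#'
#' The phase-binned residual of the global response around its mean rate:
#' what the cancellation failed to remove.
#'
#' @param object an \code{ell_fit}.
#' @param contrast test contrast (percent).
#' @param cycles,n_bins,seed as in \code{\link{predict.ell_fit}}.
#' @param ... unused.
#' @return Numeric vector of per-bin residual rates (spikes/s) with the
#'   bin phases as names.
#' @export
residuals.ell_fit <- function(object, contrast = object$learning_contrast,
                              cycles = 60, n_bins = 32, seed = 1, ...) {
  glo <- simulate.ell_fit(object, nsim = 1, seed = seed,
                          contrast = contrast, cycles = cycles)[[1]]
  p <- compute_psth(glo$spikes, object$frequency, n_bins, glo$duration)
  r <- p$rates - mean(p$rates)
  names(r) <- sprintf("%.3f", p$phase_bins)
  r
}
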