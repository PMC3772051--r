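#' Local-response experiment
#'
#' Simulates the SP cell under local stimulation across a frequency by
#' contrast grid and fits the response heights.
#'
#' @param model an \code{\link{ell_model}}.
#' @param frequencies AM frequencies (Hz).
#' @param contrasts contrasts (percent).
#' @param cycles stimulus cycles per cell.
#' @param n_bins PSTH bins.
#' @param seed RNG seed.
#' @return Data frame: frequency, contrast, A_local, baseline, max_rate.
#' @export
run_local_experiment <- function(model, frequencies = c(2, 4, 8, 16),
                                 contrasts = c(5, 10, 15, 20),
                                 cycles = 60, n_bins = 32, seed = 1) {
  stopifnot(inherits(model, "ell_model"))
  grid <- expand.grid(frequency = frequencies, contrast = contrasts)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    f <- grid$frequency[i]; cc <- grid$contrast[i]
    spec <- am_stimulus(f, cc, cycles / f, "local")
    sim <- simulate_sp(spec, model$transfer, model$neuron, model$dap,
                       dt = model$dt, seed = seed + i)
    p <- compute_psth(sim$spikes, f, n_bins, sim$duration)
    data.frame(frequency = f, contrast = cc,
               A_local = fit_local_amplitude(p),
               baseline = p$baseline, max_rate = max(p$rates))
  })
  do.call(rbind, rows)
}

#' Full cancellation experiment
#'
#' Trains the PF weights at one learning contrast (per frequency, since
#' feedback channels are frequency-specific) and then tests every
#' (frequency, test-contrast) cell with the SAME trained weights: the
#' equilibrium reached at the learning contrast is used to cancel every
#' test contrast, without retraining.
#'
#' @param model an \code{\link{ell_model}}.
#' @param learning_contrast contrast present during learning (percent).
#' @param frequencies AM frequencies (Hz).
#' @param test_contrasts contrasts tested after learning (percent).
#' @param scale,epochs,tol training controls (see \code{\link{ell_train}}).
#' @param cycles test cycles per measurement.
#' @param n_bins PSTH bins.
#' @param seed RNG seed.
#' @return List: \code{table} (frequency, contrast, A_local, A_global, C,
#'   inphase), \code{degradation} (contrast, D), \code{fits} (per
#'   frequency \code{ell_fit}s).
#' @export
run_cancellation_experiment <- function(model, learning_contrast,
                                        frequencies = c(2, 4, 8, 16),
                                        test_contrasts = c(5, 10, 15, 20),
                                        scale = 10, epochs = 150, tol = 0.15,
                                        cycles = 120, n_bins = 32, seed = 1) {
  stopifnot(inherits(model, "ell_model"))
  fits <- lapply(frequencies, function(f)
    ell_train(model, f, learning_contrast, epochs = epochs, tol = tol,
              scale = scale, seed = seed))
  names(fits) <- frequencies
  tab <- do.call(rbind, lapply(fits, function(fit)
    predict(fit, contrasts = test_contrasts, cycles = cycles,
            n_bins = n_bins, seed = seed)))
  rownames(tab) <- NULL
  degr <- do.call(rbind, lapply(test_contrasts, function(cc) {
    data.frame(contrast = cc,
               D = degradation(tab$C[tab$contrast == cc]))
  }))
  list(table = tab, degradation = degr, fits = fits)
}

#' Sampling noise floor of the sine-amplitude fit
#'
#' Simulates the unmodulated (zero-contrast) neuron and fits the sine
#' amplitude at the analysis frequency to repeated recordings; the floor
#' is the maximum fitted amplitude across repeats -- the level below which
#' a fitted residual modulation cannot be distinguished from sampling
#' noise.
#'
#' @param model an \code{\link{ell_model}}.
#' @param frequency analysis frequency (Hz).
#' @param cycles cycles per repeat (match the test measurements).
#' @param n_bins PSTH bins.
#' @param n_rep number of repeats.
#' @param seed RNG seed.
#' @return Noise-floor amplitude (spikes/s).
#' @export
amplitude_noise_floor <- function(model, frequency, cycles = 60,
                                  n_bins = 32, n_rep = 8, seed = 1) {
  amps <- vapply(seq_len(n_rep), function(k) {
    set.seed(seed + 1000 * k)
    res <- simulate_sp_raw(cycles / frequency, model$dt, frequency, 0,
                           model$neuron, model$dap)
    p <- compute_psth(res$spikes, frequency, n_bins, cycles / frequency)
    as.numeric(fit_global_amplitude(p))
  }, numeric(1))
  max(amps)
}

#' Scan the learning contrast
#'
#' Trains the model at each learning contrast on the grid and evaluates
#' how well the resulting equilibrium cancels both a low and a high test
#' contrast. Two complementary criteria are computed:
#' \itemize{
#'   \item \strong{phase criterion}: at the low test contrast an
#'     anti-phase residual above the sampling noise floor flags
#'     over-cancellation; at the high test contrast an in-phase residual
#'     above the floor flags under-cancellation. Candidates flagged for
#'     neither failure are preferred; ranking uses the summed offending
#'     residual (each component normalized by the local response height,
#'     averaged over frequencies), whether or not it clears the floor.
#'   \item \strong{error criterion} (when \code{reference} is given): the
#'     squared error between the model degradation-vs-contrast curve and
#'     the reference curve.
#' }
#'
#' @param model an \code{\link{ell_model}}.
#' @param learning_grid learning contrasts to scan (percent).
#' @param frequencies AM frequencies used for training/testing (Hz).
#' @param test_contrasts low and high test contrasts (percent) for the
#'   phase criterion; the full \code{reference} contrast grid is used for
#'   the error criterion.
#' @param reference optional \code{\link{generate_reference}} dataset.
#' @param scale,epochs,tol training controls.
#' @param cycles test cycles per measurement.
#' @param seed RNG seed.
#' @return List of class \code{"ell_scan"}: \code{results} (one row per
#'   learning contrast with residual components, flags and error),
#'   \code{optimal} (phase criterion), \code{optimal_error} (error
#'   criterion, when computed), \code{noise_floor}.
#' @export
scan_learning_contrast <- function(model, learning_grid = c(5, 10, 15, 20, 25),
                                   frequencies = c(4, 8),
                                   test_contrasts = c(5, 20),
                                   reference = NULL,
                                   scale = 10, epochs = 150, tol = 0.15,
                                   cycles = 1600, seed = 1) {
  stopifnot(inherits(model, "ell_model"))
  lo <- min(test_contrasts); hi <- max(test_contrasts)
  err_grid <- if (!is.null(reference))
    reference$contrasts[reference$contrasts <= 20] else NULL

  floors <- vapply(frequencies, function(f)
    amplitude_noise_floor(model, f, cycles = cycles, seed = seed),
    numeric(1))

  rows <- lapply(learning_grid, function(lc) {
    per_f <- lapply(seq_along(frequencies), function(k) {
      f <- frequencies[k]
      fit <- ell_train(model, f, lc, epochs = epochs, tol = tol,
                       scale = scale, seed = seed)
      cts <- sort(unique(c(test_contrasts, err_grid)))
      pred <- predict(fit, contrasts = cts, cycles = cycles, seed = seed,
                      freeze = TRUE)
      pred$floor <- floors[k]
      pred
    })
    tab <- do.call(rbind, per_f)
    at <- function(cc) tab[tab$contrast == cc, , drop = FALSE]
    # normalized signed in-phase residuals, averaged over frequencies;
    # the floor only decides the over/under flags, not the ranking
    r_lo <- at(lo); r_hi <- at(hi)
    over <- mean(pmax(0, -r_lo$inphase) / r_lo$A_local)
    under <- mean(pmax(0, r_hi$inphase) / r_hi$A_local)
    flag_over <- any(-r_lo$inphase > r_lo$floor)
    flag_under <- any(r_hi$inphase > r_hi$floor)
    err <- NA_real_
    if (!is.null(err_grid)) {
      dmod <- vapply(err_grid, function(cc)
        degradation(at(cc)$C), numeric(1))
      err <- cancellation_error(
        dmod, as.numeric(reference$degradation_curve[
          as.character(err_grid)]))
    }
    data.frame(learning_contrast = lc, over_residual = over,
               under_residual = under, residual_sum = over + under,
               flag_over = flag_over, flag_under = flag_under,
               error = err)
  })
  res <- do.call(rbind, rows)
  clean <- !res$flag_over & !res$flag_under
  pick <- if (any(clean)) {
    res$learning_contrast[clean][which.min(res$residual_sum[clean])]
  } else res$learning_contrast[which.min(res$residual_sum)]
  out <- list(results = res, optimal = pick,
              optimal_error = if (!is.null(err_grid))
                res$learning_contrast[which.min(res$error)] else NA,
              noise_floor = stats::setNames(floors, frequencies))
  class(out) <- "ell_scan"
  out
}

#' @export
print.ell_scan <- function(x, ...) {
  cat("Learning-contrast scan\n")
  print(x$results, row.names = FALSE, digits = 3)
  cat(sprintf("optimal learning contrast (phase criterion): %g%%\n",
              x$optimal))
  if (!is.na(x$optimal_error))
    cat(sprintf("optimal learning contrast (error criterion): %g%%\n",
                x$optimal_error))
  invisible(x)
}

#' Scan the potentiation time constant
#'
#' Repeats the learning-contrast scan for several potentiation time
#' constants \eqn{\tau_w} and reports, for each, the minimal degradation
#' error against the reference curve; the \eqn{\tau_w} attaining the
#' global minimum is the model's estimate of the potentiation time scale.
#'
#' @param model an \code{\link{ell_model}}.
#' @param tau_grid potentiation time constants (s) to scan.
#' @param reference a \code{\link{generate_reference}} dataset (required:
#'   the criterion is the degradation error).
#' @param learning_grid,frequencies,scale,epochs,cycles,seed as in
#'   \code{\link{scan_learning_contrast}}.
#' @return List: \code{results} (tau_w, min_error, optimal learning
#'   contrast per tau), \code{optimal_tau}, \code{scans}.
#' @export
scan_tau_w <- function(model, tau_grid, reference,
                       learning_grid = c(5, 10, 15, 20, 25),
                       frequencies = c(4, 8),
                       scale = 10, epochs = 150, cycles = 200, seed = 1) {
  stopifnot(inherits(reference, "ell_reference"))
  scans <- lapply(tau_grid, function(tw) {
    m <- model
    m$plasticity$tau_w <- tw
    scan_learning_contrast(m, learning_grid = learning_grid,
                           frequencies = frequencies,
                           reference = reference, scale = scale,
                           epochs = epochs, cycles = cycles, seed = seed)
  })
  res <- do.call(rbind, lapply(seq_along(tau_grid), function(i) {
    r <- scans[[i]]$results
    data.frame(tau_w = tau_grid[i], min_error = min(r$error),
               optimal_lc = r$learning_contrast[which.min(r$error)])
  }))
  list(results = res,
       optimal_tau = res$tau_w[which.min(res$min_error)],
       scans = scans)
}
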