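#' Generate a synthetic reference dataset
#'
#' Produces surrogate "experimental" observables with the statistical
#' structure the analysis assumes, standing in for in-vivo recordings:
#' per-(frequency, contrast) maximum local firing rates (saturating, i.e.
#' concave in contrast), near-flat global responses summarized by a mean
#' rate and a small modulation amplitude, and a degradation-vs-contrast
#' curve confined to a gently rising narrow band. Levels are configuration
#' -- this is not a fit to any real recording -- with defaults chosen to
#' respect the structural constraints of the system: quasi-linear P-unit
#' encoding up to about 10\% contrast with saturation above, slightly
#' weaker cancellation at the top AM frequency, and degradation growing
#' mildly with contrast.
#'
#' @param frequencies AM frequencies (Hz).
#' @param contrasts contrasts (percent).
#' @param local_max_rates matrix (frequency x contrast) of maximum
#'   cycle-histogram rates (spikes/s); default built from a saturating
#'   contrast profile with a mild frequency droop.
#' @param global_mean_rate mean SP rate under global stimulation at the
#'   reference condition (spikes/s) with the PF array still relaxed at
#'   \code{w_max} (the acute response, before the negative image has
#'   formed); the G0 calibration target.
#' @param global_amp_frac global modulation amplitude as a fraction of the
#'   local height (small: cancellation is efficient).
#' @param degradation_curve named vector D(c); default a narrow rising
#'   band.
#' @param jitter_sd per-bin Gaussian rate jitter (spikes/s) applied to the
#'   PSTH targets.
#' @param n_bins phase bins for the PSTH targets.
#' @param seed RNG seed; the dataset is deterministic given it.
#' @return An object of class \code{"ell_reference"}.
#' @export
generate_reference <- function(frequencies = c(2, 4, 8, 16),
                               contrasts = c(5, 10, 15, 20),
                               local_max_rates = NULL,
                               global_mean_rate = 121,
                               global_amp_frac = 0.08,
                               degradation_curve = NULL,
                               jitter_sd = 2, n_bins = 32, seed = 1) {
  if (any(diff(contrasts) <= 0)) stop("contrasts must be increasing")
  if (is.null(local_max_rates)) {
    # saturating growth with contrast (quasi-linear only at low contrast),
    # on the operating scale of the SP cell; top frequency slightly weaker
    prof <- stats::approx(c(0, 5, 10, 15, 20), c(18, 150, 285, 333, 365),
                          xout = pmin(contrasts, 20), rule = 2)$y
    fdroop <- ifelse(frequencies >= max(frequencies), 0.93, 1)
    local_max_rates <- outer(fdroop, prof)
  }
  if (!all(dim(local_max_rates) == c(length(frequencies), length(contrasts))))
    stop("local_max_rates dimensions do not match the grids")
  if (any(local_max_rates < 0)) stop("rates must be non-negative")
  d2 <- apply(local_max_rates, 1, function(r) diff(diff(r)))
  if (any(d2 > 1e-9))
    stop("local max rates must be concave (saturating) in contrast")
  if (is.null(degradation_curve)) {
    degradation_curve <- stats::setNames(
      0.05 + 0.003 * (contrasts - contrasts[1]), contrasts)
  }
  if (any(diff(degradation_curve) < 0))
    stop("degradation curve must be non-decreasing in contrast")
  dimnames(local_max_rates) <- list(frequencies, contrasts)

  set.seed(seed)
  psth_phase <- 2 * pi * (seq_len(n_bins) - 0.5) / n_bins
  mk_local <- function(maxr) {
    base <- 0.15 * maxr
    prof <- base + (maxr - base) *
      exp(-(((psth_phase - pi / 2 + pi) %% (2 * pi)) - pi)^2 / (2 * 0.9^2))
    pmax(prof + stats::rnorm(n_bins, sd = jitter_sd), 0)
  }
  mk_global <- function(maxr) {
    amp <- global_amp_frac * maxr
    pmax(global_mean_rate + amp * sin(psth_phase) +
           stats::rnorm(n_bins, sd = jitter_sd), 0)
  }
  local_psth <- array(NA_real_,
                      dim = c(length(frequencies), length(contrasts), n_bins),
                      dimnames = list(frequencies, contrasts, NULL))
  global_psth <- local_psth
  for (i in seq_along(frequencies))
    for (j in seq_along(contrasts)) {
      local_psth[i, j, ] <- mk_local(local_max_rates[i, j])
      global_psth[i, j, ] <- mk_global(local_max_rates[i, j])
    }

  structure(list(frequencies = frequencies, contrasts = contrasts,
                 local_max_rates = local_max_rates,
                 global_mean_rate = global_mean_rate,
                 global_amp_frac = global_amp_frac,
                 degradation_curve = degradation_curve,
                 local_psth = local_psth, global_psth = global_psth,
                 psth_phase = psth_phase,
                 jitter_sd = jitter_sd, seed = seed),
            class = "ell_reference")
}

#' @export
print.ell_reference <- function(x, ...) {
  cat("Synthetic reference dataset\n")
  cat(sprintf("  frequencies: %s Hz; contrasts: %s%%\n",
              paste(x$frequencies, collapse = ", "),
              paste(x$contrasts, collapse = ", ")))
  cat(sprintf("  degradation band: %.3f .. %.3f\n",
              min(x$degradation_curve), max(x$degradation_curve)))
  invisible(x)
}

#' Write a reference dataset to CSV files
#'
#' Serializes the grids and targets as plain CSVs plus a JSON manifest.
#'
#' @param reference an \code{\link{generate_reference}} object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reference <- function(reference, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "local_max_rates.csv")
  utils::write.csv(as.data.frame(reference$local_max_rates), p1)
  p2 <- file.path(dir, "degradation.csv")
  utils::write.csv(data.frame(contrast = reference$contrasts,
                              D = as.numeric(reference$degradation_curve)),
                   p2, row.names = FALSE)
  p3 <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(list(
    frequencies = reference$frequencies, contrasts = reference$contrasts,
    global_mean_rate = reference$global_mean_rate,
    jitter_sd = reference$jitter_sd, seed = reference$seed),
    auto_unbox = TRUE, pretty = TRUE), p3)
  invisible(c(p1, p2, p3))
}

#' End-to-end self-check against a reference dataset
#'
#' Runs the whole pipeline: calibrates the P-unit transfer against the
#' reference maximum-rate targets, calibrates the feedback gain against
#' the reference global mean rate, trains the PF weights at a learning
#' contrast, measures the cancellation table and degradation curve, and
#' scores the squared error against the reference degradation.
#'
#' @param reference an \code{\link{generate_reference}} object.
#' @param learning_contrast learning contrast (percent).
#' @param frequencies frequencies to test (defaults to the reference grid).
#' @param f_ref reference frequency for both calibrations (Hz).
#' @param scale,epochs training controls (see \code{\link{ell_train}}).
#' @param cycles test cycles per measurement.
#' @param seed RNG seed.
#' @return A list report: \code{transfer_table}, \code{G0},
#'   \code{cancellation_table}, \code{degradation}, \code{error},
#'   \code{converged}.
#' @export
end_to_end_selfcheck <- function(reference, learning_contrast = 15,
                                 frequencies = NULL, f_ref = 8,
                                 scale = 10, epochs = 150, cycles = 120,
                                 seed = 1) {
  stopifnot(inherits(reference, "ell_reference"))
  if (is.null(frequencies)) frequencies <- reference$frequencies
  fi <- match(f_ref, reference$frequencies)
  if (is.na(fi)) stop("f_ref not on the reference frequency grid")
  targets <- data.frame(contrast = reference$contrasts,
                        max_rate = reference$local_max_rates[fi, ])
  tf <- calibrate_transfer(targets, f_ref = f_ref, seed = seed)
  gain <- calibrate_gain(reference$global_mean_rate, tf,
                         f_ref = f_ref, seed = seed)
  model <- ell_model(transfer = tf, gain = gain)
  exp_res <- run_cancellation_experiment(
    model, learning_contrast, frequencies = frequencies,
    test_contrasts = reference$contrasts,
    scale = scale, epochs = epochs, cycles = cycles, seed = seed)
  err <- cancellation_error(exp_res$degradation$D,
                            as.numeric(reference$degradation_curve))
  list(transfer_table = attr(tf, "report"),
       G0 = gain$G0,
       cancellation_table = exp_res$table,
       degradation = exp_res$degradation,
       error = err,
       converged = all(vapply(exp_res$fits, function(f) f$converged,
                              logical(1))))
}
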