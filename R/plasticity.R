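#' Detect small and large bursts in a spike train
#'
#' Scans the spike train left to right; at each unconsumed spike the
#' largest valid burst is preferred: a large burst (exactly 4 consecutive
#' spikes spanning at most \code{t_large}) before a small burst (exactly 2
#' consecutive spikes within \code{t_small}). Spikes consumed by an event
#' are unavailable to later events, so a small burst can never sit inside
#' a large one. The time of an event is the time of its first spike.
#'
#' @param spikes strictly increasing spike times (s).
#' @param params a \code{\link{plasticity_params}} object.
#' @return Data frame with columns \code{time} (s), \code{type}
#'   (\code{"small"}/\code{"large"}) and \code{n_spikes}.
#' @export
#' @examples
#' detect_bursts(c(0, 0.005))                 # one small burst at t = 0
#' detect_bursts(c(0, 0.03, 0.06, 0.09))      # one large burst at t = 0
detect_bursts <- function(spikes, params = plasticity_params()) {
  if (length(spikes) && is.unsorted(spikes, strictly = TRUE))
    stop("spike times must be strictly increasing")
  n <- length(spikes)
  times <- numeric(0); sizes <- integer(0)
  i <- 1
  while (i <= n) {
    if (i + 3 <= n && spikes[i + 3] - spikes[i] <= params$t_large) {
      times <- c(times, spikes[i]); sizes <- c(sizes, 4L)
      i <- i + 4
    } else if (i + 1 <= n && spikes[i + 1] - spikes[i] <= params$t_small) {
      times <- c(times, spikes[i]); sizes <- c(sizes, 2L)
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  data.frame(time = times,
             type = c("small", "large")[1L + (sizes == 4L)],
             n_spikes = sizes)
}

#' Apply burst-triggered depression to PF weights
#'
#' For a postsynaptic burst at time \eqn{t_b} (its first spike), every
#' segment whose most recent onset \eqn{t_j} precedes or coincides with the
#' burst within the burst-type-specific kernel support,
#' \eqn{0 \le t_b - t_j \le W_k}, is depressed:
#' \eqn{w_j \leftarrow \max(0,\; w_j - \eta_k K_k(t_b - t_j))} with the
#' causal linear kernel \eqn{K_k(d) = 1 - d/W_k}. Segments outside the
#' window are unchanged. The presynaptic burst type is assumed to match
#' the postsynaptic one, selecting \eqn{(\eta_2, W_2)} for small and
#' \eqn{(\eta_4, W_4)} for large bursts.
#'
#' @param pf a \code{\link{pf_segments}} array.
#' @param burst_time time of the burst's first spike (s).
#' @param burst_type \code{"small"} or \code{"large"}.
#' @param params a \code{\link{plasticity_params}}.
#' @return The updated \code{pf_array}.
#' @export
apply_depression <- function(pf, burst_time, burst_type = c("small", "large"),
                             params = plasticity_params()) {
  stopifnot(inherits(pf, "pf_array"))
  burst_type <- match.arg(burst_type)
  eta <- if (burst_type == "large") params$eta_large else params$eta_small
  win <- if (burst_type == "large") params$win_large else params$win_small
  period <- 1 / pf$frequency
  dtp <- (burst_time %% period) - pf$onsets
  dtp <- ifelse(dtp < 0, dtp + period, dtp)   # most recent onset
  hit <- dtp <= win
  k <- ifelse(hit, 1 - dtp / win, 0)
  pf$weights <- pmax(0, pf$weights - eta * k)
  pf
}

#' Apply homeostatic potentiation to PF weights
#'
#' Closed-form exponential relaxation of all weights toward \code{w_max}
#' over an elapsed time:
#' \eqn{w \leftarrow w_{max} + (w - w_{max})\, e^{-\Delta t/\tau_w}},
#' applied uniformly and independently of activity.
#'
#' @param pf a \code{\link{pf_segments}} array.
#' @param elapsed elapsed time (s), non-negative.
#' @param params a \code{\link{plasticity_params}}.
#' @return The updated \code{pf_array}.
#' @export
apply_potentiation <- function(pf, elapsed, params = plasticity_params()) {
  stopifnot(inherits(pf, "pf_array"))
  if (elapsed < 0) stop("elapsed must be non-negative")
  wm <- params$w_max
  pf$weights <- wm + (pf$weights - wm) * exp(-elapsed / params$tau_w)
  pf
}
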