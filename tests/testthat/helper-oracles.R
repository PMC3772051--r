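# Independent oracles used across the suite.

# Exhaustive burst assignment: enumerate every valid set of disjoint burst
# events (large = 4 consecutive spikes spanning <= t_large, small = 2
# consecutive spikes spanning <= t_small, events consume their spikes), then
# pick the assignment preferred under the ordering "at the earliest
# undecided spike, a large burst beats a small burst beats no burst".
# Structurally different from the package's single left-to-right scan.
enumerate_bursts <- function(spikes, t_small = 10e-3, t_large = 100e-3) {
  n <- length(spikes)
  all_assignments <- function(i) {
    if (i > n) return(list(list()))
    out <- list()
    if (i + 3 <= n && spikes[i + 3] - spikes[i] <= t_large) {
      for (rest in all_assignments(i + 4))
        out <- c(out, list(c(list(list(idx = i, size = 4L)), rest)))
    }
    if (i + 1 <= n && spikes[i + 1] - spikes[i] <= t_small) {
      for (rest in all_assignments(i + 2))
        out <- c(out, list(c(list(list(idx = i, size = 2L)), rest)))
    }
    for (rest in all_assignments(i + 1)) out <- c(out, list(rest))
    out
  }
  # decision sequence over spike indices: 2 = large starts here, 1 = small
  # starts here, 0 = no event starts here; lexicographically larger wins
  decision_key <- function(asg) {
    key <- integer(n)
    for (ev in asg) key[ev$idx] <- ifelse(ev$size == 4L, 2L, 1L)
    key
  }
  asgs <- all_assignments(1)
  keys <- lapply(asgs, decision_key)
  best <- 1
  for (k in seq_along(asgs)[-1]) {
    a <- keys[[k]]; b <- keys[[best]]
    d <- which(a != b)
    if (length(d) && a[d[1]] > b[d[1]]) best <- k
  }
  asg <- asgs[[best]]
  if (!length(asg))
    return(data.frame(time = numeric(0), type = character(0),
                      n_spikes = integer(0)))
  asg <- asg[order(vapply(asg, `[[`, 1, "idx"))]
  data.frame(time = spikes[vapply(asg, `[[`, 1, "idx")],
             type = ifelse(vapply(asg, `[[`, 1L, "size") == 4L,
                           "large", "small"),
             n_spikes = vapply(asg, `[[`, 1L, "size"))
}

# Closed-form LIF firing period under constant suprathreshold drive D:
# tau_m * log(D / (D - v_th)) + tau_ref
lif_period <- function(D, tau_m = 7e-3, v_th = 1, tau_ref = 0.7e-3) {
  tau_m * log(D / (D - v_th)) + tau_ref
}

# small fast model configuration for simulation-heavy tests
quick_model <- function(...) {
  ell_model(dt = 5e-5, ...)
}
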