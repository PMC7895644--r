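# Independent oracles and tiny fixture builders used across the suite.

# Direct sum-formula Pearson r^2, independent of stats::cor.
r2_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  (num / den)^2
}

# Brute-force maximum-cardinality one-to-one matching of detected to truth
# events under a midpoint-distance cap; exponential, for small n only.
brute_force_match_count <- function(detected, truth, max_offset_ms) {
  mid_d <- (detected$start_ms + detected$end_ms) / 2
  mid_t <- (truth$start_ms + truth$end_ms) / 2
  nd <- length(mid_d)
  nt <- length(mid_t)
  best <- 0L
  recurse <- function(i, used_t, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used_t, count) # leave detected i unmatched
    for (j in seq_len(nt)) {
      if (!used_t[j] && abs(mid_d[i] - mid_t[j]) <= max_offset_ms) {
        used_t[j] <- TRUE
        recurse(i + 1L, used_t, count + 1L)
        used_t[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, nt), 0L)
  best
}

# A bare trapezoidal-gesture trace: rest, one ramp/plateau/ramp, rest.
single_puff_trace <- function(plateau_samples = 60, rate = 30,
                              rest = c(9, -1, 5), plateau = c(9, -5, -3),
                              transition_ms = 500, lead_s = 40,
                              noise_sd = 0) {
  lead <- lead_s * 1000
  plateau_ms <- plateau_samples * 1000 / rate
  total_ms <- 2 * lead + 2 * transition_ms + plateau_ms
  n <- round(total_ms / 1000 * rate)
  t <- round((seq_len(n) - 1) * 1000 / rate)
  s <- lead + transition_ms          # plateau start
  e <- s + plateau_ms                # plateau end
  alpha <- rep(0, n)
  in_down <- t >= s - transition_ms & t < s
  in_plat <- t >= s & t < e
  in_up <- t >= e & t < e + transition_ms
  alpha[in_down] <- (t[in_down] - (s - transition_ms)) / transition_ms
  alpha[in_plat] <- 1
  alpha[in_up] <- 1 - (t[in_up] - e) / transition_ms
  mk <- function(i) rest[i] + alpha * (plateau[i] - rest[i]) +
    stats::rnorm(n, 0, noise_sd)
  list(trace = accel_trace(tibble::tibble(t_ms = t, x = mk(1), y = mk(2),
                                          z = mk(3)), sampling_rate = rate),
       start_ms = s, end_ms = e)
}

quick_config <- function(seed = 1, noise_sd = 0, ...) {
  simulation_config(seed = seed, noise_sd = noise_sd, ...)
}
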