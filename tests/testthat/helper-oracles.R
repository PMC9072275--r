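# Independent oracles and small fixture builders shared across tests.

# ICC(2,1) recomputed from stats::aov mean squares (independent of the
# package's direct sums-of-squares implementation).
icc_oracle <- function(x, y) {
  n <- length(x)
  d <- data.frame(score = c(x, y),
                  row = factor(rep(seq_len(n), 2L)),
                  col = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ row + col, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (zeros dropped first); feasible for n <= 12.
wilcox_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1, n <= 12)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(Ws <= W), mean(Ws >= W)))
}

# Artifact-free simulator settings: no noise, no blinks, no overshoots, no
# non-responders.
clean_config <- function(...) {
  args <- list(noise_sd_deg = 0, blink_rate_hz = 0, hypermetric_prob = 0,
               nonresponder_prob_by_foil = c("1" = 0, "2" = 0))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}

# Flat trace with logistic saccades injected at given onsets; returns the
# eye_trace plus the injected waveform attributes.
trace_with_saccades <- function(onsets_s, amplitudes_deg, duration_s = 4,
                                fs = 250, noise_sd = 0, seed = 1) {
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1L) / fs
  delta <- numeric(n)
  peaks <- numeric(length(onsets_s))
  for (j in seq_along(onsets_s)) {
    w <- saccade_waveform(amplitudes_deg[j], fs)
    peaks[j] <- attr(w, "peak_velocity_deg_s")
    i0 <- as.integer(round(onsets_s[j] * fs)) + 1L
    delta[i0:(i0 + length(w) - 1L)] <- delta[i0:(i0 + length(w) - 1L)] + w
  }
  y <- cumsum(delta)
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(n, 0, noise_sd)
  }
  tr <- eye_trace(t, y, fs = fs)
  attr(tr, "analytic_peaks") <- peaks
  tr
}
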