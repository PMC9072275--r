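# Synthetic alternating-cover recordings with known ground truth, plus a
# simulated prism-cover-test examiner. The generator reproduces the study
# protocol: 10 subjects x foil set {1,2,4,6,8,10} PD, 10-s recordings,
# 2-s cover switches, five observable event windows per recording.

#' Simulator configuration
#'
#' Defaults reproduce the replica study protocol: 10 subjects, foils
#' \{1, 2, 4, 6, 8, 10\} PD on one eye, 10-s recordings sampled at 250 Hz
#' with a cover switch every 2 s (first at 0.5 s, so five full event
#' windows fit), corrective saccades with ~200 ms latency whose net
#' amplitude equals the induced deflection, 0.05 deg measurement noise,
#' occasional blinks (masked gaps) and hypermetric overshoots, and
#' non-responders at the small foil values.
#'
#' @param n_subjects Number of subjects (default 10).
#' @param foil_set_pd Foil strengths in prism diopters (default
#'   `c(1, 2, 4, 6, 8, 10)`).
#' @param trial_duration_s Recording duration in seconds (default 10).
#' @param switch_period_s Cover-switch period in seconds (default 2).
#' @param first_switch_s Time of the first switch (default 0.5 s, placing
#'   all five event windows inside the recording).
#' @param fs_hz Sampling rate in Hz (default 250).
#' @param noise_sd_deg Gaussian position noise SD in degrees (default 0.05).
#' @param blink_rate_hz Blink rate in events per second (default 0.05);
#'   blinks become masked gaps of 0.1-0.2 s.
#' @param latency_ms_mean,latency_ms_sd Saccade latency after a switch,
#'   Normal(mean, sd) in ms, truncated below at 80 ms (defaults 200/40).
#' @param hypermetric_prob Probability that a corrective saccade overshoots
#'   by 30-60% and is followed by a fast corrective return whose net
#'   displacement still equals the target (default 0.1).
#' @param nonresponder_prob_by_foil Named numeric vector mapping foil (PD)
#'   to the probability that a recording shows no corrective saccades at
#'   all (default 0.3 at 1 and 2 PD, 0 elsewhere) - central adaptation to
#'   small induced misalignments.
#' @param apct_bias_small_pd Additive examiner bias (PD) applied to true
#'   skews below `apct_bias_below_pd` (default +2.6), modelling the
#'   overestimation of small skews by the cover test.
#' @param apct_bias_below_pd Bias cutoff (default 2 PD).
#' @param apct_noise_sd_pd Examiner noise SD in PD (default 1.5).
#' @param saccade_steepness Logistic steepness of the saccade position
#'   profile (default 8; dimensionless).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10L,
                       foil_set_pd = c(1, 2, 4, 6, 8, 10),
                       trial_duration_s = 10,
                       switch_period_s = 2.0,
                       first_switch_s = 0.5,
                       fs_hz = 250,
                       noise_sd_deg = 0.05,
                       blink_rate_hz = 0.05,
                       latency_ms_mean = 200,
                       latency_ms_sd = 40,
                       hypermetric_prob = 0.1,
                       nonresponder_prob_by_foil = c("1" = 0.3, "2" = 0.3),
                       apct_bias_small_pd = 2.6,
                       apct_bias_below_pd = 2,
                       apct_noise_sd_pd = 1.5,
                       saccade_steepness = 8) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              foil_set_pd = foil_set_pd,
              trial_duration_s = trial_duration_s,
              switch_period_s = switch_period_s,
              first_switch_s = first_switch_s,
              fs_hz = fs_hz,
              noise_sd_deg = noise_sd_deg,
              blink_rate_hz = blink_rate_hz,
              latency_ms_mean = latency_ms_mean,
              latency_ms_sd = latency_ms_sd,
              hypermetric_prob = hypermetric_prob,
              nonresponder_prob_by_foil = nonresponder_prob_by_foil,
              apct_bias_small_pd = apct_bias_small_pd,
              apct_bias_below_pd = apct_bias_below_pd,
              apct_noise_sd_pd = apct_noise_sd_pd,
              saccade_steepness = saccade_steepness)
  probs <- c(cfg$hypermetric_prob, cfg$nonresponder_prob_by_foil)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (cfg$trial_duration_s <= 0 || cfg$switch_period_s <= 0 || cfg$fs_hz <= 0) {
    stop("durations and rates must be > 0", call. = FALSE)
  }
  if (cfg$noise_sd_deg < 0 || cfg$blink_rate_hz < 0) {
    stop("noise SD and blink rate must be >= 0", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic substream seeds: every random draw in a study flows from one
# master seed through (subject, foil, purpose) keys, so adding subjects or
# foils never perturbs earlier recordings. MINSTD-style mixing keeps all
# intermediates below 2^47 (exact in doubles) and the result below 2^31.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Saccade position-increment waveform
#'
#' Smooth sigmoidal (logistic) position profile whose total excursion equals
#' `amplitude_deg` exactly; the duration follows the main-sequence rule
#' `D[ms] = 2.2 * |A|[deg] + 21`, which gives realistic peak velocities for
#' the detector to work against.
#'
#' @param amplitude_deg Signed saccade amplitude in degrees, |A| <= 20.
#' @param fs_hz Sampling rate in Hz.
#' @param steepness Logistic steepness (default 8).
#' @return Numeric vector of per-sample position increments summing to
#'   `amplitude_deg` (to 1e-9), with attributes `duration_s` and
#'   `peak_velocity_deg_s` (analytic peak of the continuous profile).
#' @export
saccade_waveform <- function(amplitude_deg, fs_hz, steepness = 8) {
  stopifnot(is.finite(amplitude_deg), abs(amplitude_deg) <= 20, fs_hz > 0)
  dur_s <- (2.2 * abs(amplitude_deg) + 21) / 1000
  n <- max(2L, as.integer(round(dur_s * fs_hz)))
  if (amplitude_deg == 0) {
    inc <- numeric(n)
    peak <- 0
  } else {
    u <- seq_len(n) / n
    s <- function(x) 1 / (1 + exp(-steepness * (x - 0.5)))
    pos <- amplitude_deg * (s(u) - s(0)) / (s(1) - s(0))
    pos[n] <- amplitude_deg  # pin the endpoint against rounding
    inc <- diff(c(0, pos))
    peak <- abs(amplitude_deg) * steepness / (4 * dur_s * (s(1) - s(0)))
  }
  attr(inc, "duration_s") <- dur_s
  attr(inc, "peak_velocity_deg_s") <- peak
  inc
}

# Expected corrective-saccade sign for a switch: viewing with the left eye
# (prism eye) leaves the tracked right eye deviated upward under cover.
alternation_sign <- function(viewing_eye_after) {
  ifelse(viewing_eye_after == "left", 1, -1)
}

nonresponder_prob <- function(cfg, foil_pd) {
  p <- cfg$nonresponder_prob_by_foil[as.character(foil_pd)]
  if (is.na(p)) 0 else unname(p)
}

#' Simulate one alternating-cover recording
#'
#' Generates a vertical eye-position trace with a cover switch every
#' `switch_period_s`. After each switch (unless the recording is a
#' non-responder) a corrective saccade with Normal latency moves the eye by
#' the signed induced deflection, alternating sign with the viewing eye.
#' Hypermetric events overshoot by 30-60% and return within 150 ms with
#' conserved net displacement. Gaussian noise is added and blinks are
#' inserted as masked gaps.
#'
#' @param foil_pd Induced prism strength (PD).
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this recording's substream.
#' @return A list with elements `trace` ([eye_trace()]), `schedule`
#'   ([cover_schedule()]) and `truth` (a list with `true_skew_deg`,
#'   `true_skew_pd`, `responded` flag, per-switch `events` data.frame and
#'   `blinks` data.frame).
#' @export
simulate_recording <- function(foil_pd, cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), foil_pd >= 0)
  with_seed(seed, {
    fs <- cfg$fs_hz
    n <- as.integer(round(cfg$trial_duration_s * fs))
    t <- (seq_len(n) - 1L) / fs
    sw <- seq(cfg$first_switch_s, cfg$trial_duration_s - 1e-9,
              by = cfg$switch_period_s)
    eyes <- rep(c("left", "right"), length.out = length(sw))
    skew_deg <- pd_to_deg(foil_pd)
    responded <- stats::runif(1) >= nonresponder_prob(cfg, foil_pd)

    delta <- numeric(n)
    ev <- data.frame(switch_s = sw,
                     viewing_eye_after = eyes,
                     responded = rep(responded && skew_deg > 0, length(sw)),
                     onset_s = NA_real_, amplitude_deg = NA_real_,
                     hypermetric = FALSE, truncated = FALSE)
    place <- function(delta, inc, i0) {
      i1 <- i0 + length(inc) - 1L
      kept <- inc[seq_len(max(0L, min(i1, n) - i0 + 1L))]
      if (i0 <= n && length(kept)) {
        delta[i0:(i0 + length(kept) - 1L)] <- delta[i0:(i0 + length(kept) - 1L)] + kept
      }
      list(delta = delta, truncated = i1 > n)
    }
    for (k in seq_along(sw)) {
      if (!ev$responded[k]) next
      amp <- alternation_sign(eyes[k]) * skew_deg
      lat <- max(0.08, stats::rnorm(1, cfg$latency_ms_mean, cfg$latency_ms_sd) / 1000)
      i0 <- as.integer(round((sw[k] + lat) * fs)) + 1L
      hyper <- stats::runif(1) < cfg$hypermetric_prob
      ev$onset_s[k] <- sw[k] + lat
      ev$amplitude_deg[k] <- amp
      ev$hypermetric[k] <- hyper
      if (!hyper) {
        w <- saccade_waveform(amp, fs, cfg$saccade_steepness)
        res <- place(delta, w, i0)
      } else {
        over <- stats::runif(1, 0.3, 0.6)
        w1 <- saccade_waveform(amp * (1 + over), fs, cfg$saccade_steepness)
        gap <- stats::runif(1, 0.05, 0.15)
        res <- place(delta, w1, i0)
        i2 <- i0 + length(w1) + as.integer(round(gap * fs))
        w2 <- saccade_waveform(-amp * over, fs, cfg$saccade_steepness)
        res2 <- place(res$delta, w2, i2)
        res <- list(delta = res2$delta, truncated = res$truncated || res2$truncated)
      }
      delta <- res$delta
      ev$truncated[k] <- res$truncated
    }
    y <- cumsum(delta)
    if (cfg$noise_sd_deg > 0) y <- y + stats::rnorm(n, 0, cfg$noise_sd_deg)

    mask <- rep(FALSE, n)
    nb <- stats::rpois(1, cfg$blink_rate_hz * cfg$trial_duration_s)
    blinks <- data.frame(start_s = numeric(0), end_s = numeric(0))
    if (nb > 0) {
      bs <- stats::runif(nb, 0, cfg$trial_duration_s - 0.2)
      bd <- stats::runif(nb, 0.1, 0.2)
      blinks <- data.frame(start_s = bs, end_s = bs + bd)
      for (b in seq_len(nb)) {
        mask[t >= blinks$start_s[b] & t <= blinks$end_s[b]] <- TRUE
      }
    }
    list(trace = eye_trace(t, y, fs = fs, mask = mask),
         schedule = cover_schedule(sw, eyes, period = cfg$switch_period_s),
         truth = list(true_skew_deg = skew_deg, true_skew_pd = foil_pd,
                      responded = responded, events = ev, blinks = blinks))
  })
}

#' Simulate a prism cover test (APCT) reading
#'
#' Examiner model: the true skew plus an additive overestimation bias for
#' small skews, plus Gaussian examiner noise, quantized to the available
#' prism set \{0, 1, ..., 10\} PD (0 = no prism needed).
#'
#' @param true_skew_pd True induced skew (PD), >= 0.
#' @param cfg A [sim_config()] carrying the examiner parameters.
#' @param seed Integer seed for the examiner substream.
#' @return The simulated reading in PD, an element of `0:10`.
#' @export
simulate_apct <- function(true_skew_pd, cfg = sim_config(), seed = 1L) {
  stopifnot(true_skew_pd >= 0)
  with_seed(seed, {
    bias <- if (true_skew_pd < cfg$apct_bias_below_pd) cfg$apct_bias_small_pd else 0
    raw <- true_skew_pd + bias + stats::rnorm(1, 0, cfg$apct_noise_sd_pd)
    available <- 0:10
    available[which.min(abs(available - raw))]
  })
}

# A random derangement of `prev` (no element keeps its position), by
# rejection sampling; used so no subject sees foils in the previous
# subject's order.
derange <- function(prev) {
  repeat {
    cand <- sample(prev)
    if (all(cand != prev)) return(cand)
  }
}

#' Simulate a full replica study
#'
#' For each subject and each foil (foil order a derangement of the previous
#' subject's order) generates one recording and one simulated APCT reading.
#' Fully reproducible: all randomness flows from `seed` through named
#' substreams keyed by subject and foil.
#'
#' @param cfg A [sim_config()].
#' @param seed Master integer seed.
#' @return A list with `study` (data.frame `subject_id, foil_pd, apct_pd,
#'   vog_pd` with `vog_pd` left `NA` for the estimation engine to fill),
#'   `recordings` (list of [simulate_recording()] results, in study-table
#'   order) and `cfg`.
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  foils <- cfg$foil_set_pd
  orders <- vector("list", cfg$n_subjects)
  orders[[1]] <- with_seed(derive_seed(seed, 0, 1), sample(foils))
  if (cfg$n_subjects > 1) {
    for (s in 2:cfg$n_subjects) {
      orders[[s]] <- with_seed(derive_seed(seed, 0, s), derange(orders[[s - 1]]))
    }
  }
  rows <- list()
  recordings <- list()
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    for (f in orders[[s]]) {
      idx <- idx + 1L
      rec <- simulate_recording(f, cfg, seed = derive_seed(seed, s, f, 1))
      apct <- simulate_apct(f, cfg, seed = derive_seed(seed, s, f, 2))
      rows[[idx]] <- data.frame(subject_id = sprintf("S%02d", s),
                                foil_pd = f, apct_pd = apct, vog_pd = NA_real_)
      rec$subject_id <- sprintf("S%02d", s)
      rec$foil_pd <- f
      recordings[[idx]] <- rec
    }
  }
  list(study = do.call(rbind, rows), recordings = recordings, cfg = cfg)
}
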