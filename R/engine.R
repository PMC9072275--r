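# Skew estimation engine: calibrate, differentiate, detect saccades, window
# around cover switches, integrate velocity per event, aggregate robustly.
#
# Per-event skew is the trapezoidal area under the (signed) velocity curve
# from the first saccade onset to the last saccade offset inside the event
# window (-0.5 s to +1.5 s around the switch). Signed integration makes a
# hypermetric overshoot-plus-return cancel to its net displacement; a 3-MAD
# fence across events guards against residual artifacts.

#' Engine tuning constants
#'
#' @param lambda Saccade threshold multiplier on the robust velocity SD
#'   (default 6).
#' @param threshold_floor_deg_s Lower bound on the velocity threshold
#'   (default 10 deg/s), so near-noiseless traces keep a physical threshold.
#' @param ext_floor_deg_s Floor for the onset/offset extension level
#'   (default 0.5 deg/s): event bounds extend outward until |velocity| drops
#'   below max(robust SD, floor).
#' @param min_duration_s Minimum above-threshold duration for a saccade
#'   (default 0.006 s).
#' @param merge_gap_s Events separated by less than this are merged
#'   (default 0.02 s).
#' @param sg_order,sg_window_samples_250 Savitzky-Golay differentiation
#'   filter: local polynomial order (default 2) and window length in samples
#'   at 250 Hz (default 11; scaled proportionally with the sampling rate and
#'   kept odd).
#' @param window_pre_s,window_post_s Event window around each switch
#'   (defaults 0.5 s before, 1.5 s after).
#' @param outlier_fence Multiplier on the MAD for the across-event outlier
#'   fence (default 3).
#' @param mad_floor_deg Floor on the MAD used by the fence (default 0.1 deg).
#' @return A list of class `vog_control`.
#' @export
vog_control <- function(lambda = 6,
                        threshold_floor_deg_s = 10,
                        ext_floor_deg_s = 0.5,
                        min_duration_s = 0.006,
                        merge_gap_s = 0.02,
                        sg_order = 2L,
                        sg_window_samples_250 = 11L,
                        window_pre_s = 0.5,
                        window_post_s = 1.5,
                        outlier_fence = 3,
                        mad_floor_deg = 0.1) {
  structure(list(lambda = lambda,
                 threshold_floor_deg_s = threshold_floor_deg_s,
                 ext_floor_deg_s = ext_floor_deg_s,
                 min_duration_s = min_duration_s,
                 merge_gap_s = merge_gap_s,
                 sg_order = as.integer(sg_order),
                 sg_window_samples_250 = as.integer(sg_window_samples_250),
                 window_pre_s = window_pre_s,
                 window_post_s = window_post_s,
                 outlier_fence = outlier_fence,
                 mad_floor_deg = mad_floor_deg),
            class = "vog_control")
}

#' Linear calibration from fixation targets
#'
#' Least-squares fit of `raw = gain * deg + offset` over known fixation
#' targets (the recording protocol uses five: center and +/- 8.5 deg
#' vertically and horizontally). The inverse map
#' `deg = (raw - offset) / gain` converts tracker output to degrees.
#'
#' @param raw Raw tracker values at fixation.
#' @param target_deg Known target positions in degrees; >= 2 distinct values.
#' @return A list of class `calibration_fit` with `gain`, `offset`,
#'   `residual_rms`.
#' @export
calibrate <- function(raw, target_deg) {
  raw <- as.numeric(raw)
  target_deg <- as.numeric(target_deg)
  stopifnot(length(raw) == length(target_deg), all(is.finite(raw)),
            all(is.finite(target_deg)))
  if (length(unique(target_deg)) < 2L) {
    stop("calibration needs >= 2 distinct target positions (gain unidentifiable)",
         call. = FALSE)
  }
  fit <- stats::lm(raw ~ target_deg)
  gain <- unname(stats::coef(fit)[2L])
  if (gain == 0) stop("degenerate calibration: zero gain", call. = FALSE)
  structure(list(gain = gain,
                 offset = unname(stats::coef(fit)[1L]),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2))),
            class = "calibration_fit")
}

#' Apply a calibration to a raw-unit trace
#'
#' @param trace An [eye_trace()] whose `y` holds raw tracker units.
#' @param fit A [calibration_fit] from [calibrate()].
#' @return The trace with `y` converted to degrees.
#' @export
apply_calibration <- function(trace, fit) {
  stopifnot(inherits(trace, "eye_trace"), inherits(fit, "calibration_fit"))
  trace$y <- (trace$y - fit$offset) / fit$gain
  trace
}

sg_window <- function(fs, control) {
  nw <- as.integer(round(control$sg_window_samples_250 * fs / 250))
  nw <- max(nw, control$sg_order + 2L)
  if (nw %% 2L == 0L) nw <- nw + 1L
  nw
}

#' Smoothed eye velocity (deg/s)
#'
#' Savitzky-Golay differentiation: a local polynomial (order 2, 11-sample
#' window at 250 Hz, window scaled with the sampling rate) fitted around
#' each sample; exact on linear trends, suppresses differentiated noise.
#' Masked (blink) samples are linearly bridged before filtering and the
#' mask is dilated by the filter half-width, so masked velocity propagates
#' as `NA`.
#'
#' @param trace An [eye_trace()], sampling rate >= 100 Hz.
#' @param control A [vog_control()].
#' @return Numeric velocity vector (deg/s), `NA` where masked, with a
#'   logical attribute `mask`.
#' @export
vog_velocity <- function(trace, control = vog_control()) {
  stopifnot(inherits(trace, "eye_trace"))
  fs <- trace$fs
  if (fs < 100) stop("velocity estimation requires fs >= 100 Hz", call. = FALSE)
  nw <- sg_window(fs, control)
  n <- length(trace$y)
  if (n < nw) stop("trace shorter than the smoothing window", call. = FALSE)
  y <- trace$y
  if (any(trace$mask)) {
    ok <- which(!trace$mask)
    y <- stats::approx(trace$t[ok], y[ok], xout = trace$t, rule = 2)$y
  }
  v <- signal::sgolayfilt(y, p = control$sg_order, n = nw, m = 1) * fs
  half <- (nw - 1L) %/% 2L
  if (any(trace$mask)) {
    cm <- cumsum(as.numeric(trace$mask))
    lo <- pmax(seq_len(n) - half - 1L, 0L)
    hi <- pmin(seq_len(n) + half, n)
    vmask <- (cm[hi] - c(0, cm)[lo + 1L]) > 0
  } else {
    vmask <- rep(FALSE, n)
  }
  v[vmask] <- NA_real_
  attr(v, "mask") <- vmask
  v
}

#' Detect saccades by adaptive velocity threshold
#'
#' Samples where |velocity| exceeds `lambda` times the robust
#' (median-based) velocity SD - with a 10 deg/s physical floor - for at
#' least `min_duration_s` seed an event; onset and offset are extended
#' outward to the nearest crossing of the robust SD level, and events
#' closer than `merge_gap_s` are merged. Amplitude is the net position
#' change `y(offset) - y(onset)`.
#'
#' @param trace An [eye_trace()].
#' @param vel Velocity from [vog_velocity()].
#' @param control A [vog_control()].
#' @return A data.frame with columns `onset_s`, `offset_s`,
#'   `amplitude_deg`, `peak_velocity_deg_s` (possibly zero rows).
#' @export
detect_saccades <- function(trace, vel, control = vog_control()) {
  stopifnot(inherits(trace, "eye_trace"))
  n <- length(vel)
  av <- abs(vel)
  sigma <- 1.4826 * stats::median(abs(vel - stats::median(vel, na.rm = TRUE)),
                                  na.rm = TRUE)
  if (!is.finite(sigma)) sigma <- 0
  thr <- max(control$lambda * sigma, control$threshold_floor_deg_s)
  ext <- max(sigma, control$ext_floor_deg_s)
  above <- !is.na(av) & av > thr
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      amplitude_deg = numeric(0), peak_velocity_deg_s = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_len <- max(1L, as.integer(ceiling(control$min_duration_s * trace$fs)))
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  on <- starts[keep]
  off <- ends[keep]
  for (j in seq_along(on)) {
    while (on[j] > 1L && !is.na(av[on[j] - 1L]) && av[on[j] - 1L] >= ext) {
      on[j] <- on[j] - 1L
    }
    while (off[j] < n && !is.na(av[off[j] + 1L]) && av[off[j] + 1L] >= ext) {
      off[j] <- off[j] + 1L
    }
  }
  # merge events separated by less than merge_gap_s
  gap <- as.integer(round(control$merge_gap_s * trace$fs))
  m_on <- on[1L]; m_off <- off[1L]
  out_on <- integer(0); out_off <- integer(0)
  if (length(on) > 1L) {
    for (j in 2L:length(on)) {
      if (on[j] - m_off < gap) {
        m_off <- max(m_off, off[j])
      } else {
        out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
        m_on <- on[j]; m_off <- off[j]
      }
    }
  }
  out_on <- c(out_on, m_on); out_off <- c(out_off, m_off)
  data.frame(onset_s = trace$t[out_on],
             offset_s = trace$t[out_off],
             amplitude_deg = trace$y[out_off] - trace$y[out_on],
             peak_velocity_deg_s = vapply(seq_along(out_on), function(j) {
               max(av[out_on[j]:out_off[j]], na.rm = TRUE)
             }, numeric(1)))
}

trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) * diff(x)) / 2
}

#' Per-switch event skew
#'
#' Selects the saccades intersecting the event window
#' `[switch - 0.5 s, switch + 1.5 s]` and integrates the signed velocity
#' (trapezoid rule) from the first selected onset to the last selected
#' offset, clipped to the window. No saccade in the window yields skew 0
#' (a valid "no corrective saccade" observation); a masked blink gap
#' overlapping the integration span invalidates the event.
#'
#' @param trace An [eye_trace()].
#' @param vel Velocity from [vog_velocity()].
#' @param saccades Data.frame from [detect_saccades()].
#' @param switch_time Switch time in seconds.
#' @param control A [vog_control()].
#' @return A list of class `event_skew`: `switch_time_s`, `window_lo`,
#'   `window_hi`, `saccades`, `skew_deg_signed`, `valid`,
#'   `exclusion_reason` (`"none"`, `"no_saccade"` or `"blink_gap"`),
#'   `clipped`.
#' @export
event_skew <- function(trace, vel, saccades, switch_time,
                       control = vog_control()) {
  stopifnot(inherits(trace, "eye_trace"))
  w0 <- switch_time - control$window_pre_s
  w1 <- switch_time + control$window_post_s
  t0 <- trace$t[1L]; t1 <- trace$t[length(trace$t)]
  clipped <- w0 < t0 || w1 > t1
  w0 <- max(w0, t0); w1 <- min(w1, t1)
  sel <- saccades[saccades$offset_s >= w0 & saccades$onset_s <= w1, , drop = FALSE]
  out <- list(switch_time_s = switch_time, window_lo = w0, window_hi = w1,
              saccades = sel, skew_deg_signed = 0, valid = TRUE,
              exclusion_reason = "no_saccade", clipped = clipped)
  class(out) <- "event_skew"
  if (nrow(sel) == 0L) {
    # a blink obscuring part of the window means "no saccade seen" cannot
    # be trusted: the corrective movement may be hidden inside the gap
    widx <- which(trace$t >= w0 & trace$t <= w1)
    if (any(trace$mask[widx])) {
      out$valid <- FALSE
      out$exclusion_reason <- "blink_gap"
      out$skew_deg_signed <- NA_real_
    }
    return(out)
  }
  span0 <- max(min(sel$onset_s), w0)
  span1 <- min(max(sel$offset_s), w1)
  i0 <- which.min(abs(trace$t - span0))
  i1 <- which.min(abs(trace$t - span1))
  idx <- i0:i1
  vmask <- attr(vel, "mask")
  if (any(trace$mask[idx]) || (!is.null(vmask) && any(vmask[idx]))) {
    out$valid <- FALSE
    out$exclusion_reason <- "blink_gap"
    out$skew_deg_signed <- NA_real_
    return(out)
  }
  out$skew_deg_signed <- trapz(trace$t[idx], vel[idx])
  out$exclusion_reason <- "none"
  out
}

#' Aggregate event skews into a per-recording estimate
#'
#' Each valid event's signed skew is rectified by its expected alternation
#' sign (from the schedule's viewing-eye sequence). Rectified values more
#' than `outlier_fence` MADs from the event median are excluded as
#' hypermetric/artifact outliers (MAD floored at `mad_floor_deg`); the
#' estimate is the median of the remaining values, reported as a magnitude.
#'
#' @param events List of [event_skew()] results, one per switch.
#' @param schedule The [cover_schedule()] the events were computed against.
#' @param control A [vog_control()].
#' @return A list of class `skew_estimate`: `skew_deg` (magnitude),
#'   `skew_pd`, `n_events_total`, `n_events_used`, `dispersion_deg`
#'   (MAD across used events), `no_valid_events` flag and a per-event
#'   data.frame `events`.
#' @export
estimate_skew <- function(events, schedule, control = vog_control()) {
  stopifnot(inherits(schedule, "cover_schedule"))
  n_total <- length(events)
  tab <- do.call(rbind, lapply(events, function(e) {
    k <- which.min(abs(schedule$switch_times - e$switch_time_s))
    data.frame(switch_s = e$switch_time_s,
               expected_sign = alternation_sign(schedule$viewing_eye_after[k]),
               skew_deg_signed = e$skew_deg_signed,
               valid = e$valid,
               exclusion_reason = e$exclusion_reason,
               n_saccades = nrow(e$saccades))
  }))
  make <- function(deg, used, disp, tab, warn) {
    structure(list(skew_deg = deg, skew_pd = deg_to_pd(deg),
                   n_events_total = n_total, n_events_used = used,
                   dispersion_deg = disp, no_valid_events = warn,
                   events = tab),
              class = "skew_estimate")
  }
  if (is.null(tab) || !any(tab$valid)) {
    if (!is.null(tab)) tab$used <- FALSE
    warning("no valid event windows; skew estimate set to 0", call. = FALSE)
    return(make(0, 0L, NA_real_, tab, TRUE))
  }
  tab$rectified_deg <- tab$skew_deg_signed * tab$expected_sign
  vals <- tab$rectified_deg[tab$valid]
  med <- stats::median(vals)
  fence <- control$outlier_fence *
    max(stats::mad(vals, constant = 1), control$mad_floor_deg)
  keep_val <- abs(vals - med) <= fence
  tab$used <- FALSE
  tab$used[tab$valid] <- keep_val
  tab$exclusion_reason[tab$valid][!keep_val] <- "outlier"
  used <- vals[keep_val]
  est <- stats::median(used)
  make(abs(est), sum(keep_val), stats::mad(used, constant = 1), tab, FALSE)
}

#' @export
print.skew_estimate <- function(x, ...) {
  cat(sprintf("<skew_estimate> %.3f deg (%.2f PD), %d/%d events used\n",
              x$skew_deg, x$skew_pd, x$n_events_used, x$n_events_total))
  invisible(x)
}

#' Full skew estimation pipeline for one recording
#'
#' Optional calibration, Savitzky-Golay velocity, adaptive-threshold
#' saccade detection, per-switch event windows and robust aggregation.
#' Deterministic for fixed inputs.
#'
#' @param trace An [eye_trace()] (degrees, or raw units if `calibration`
#'   is supplied).
#' @param schedule A [cover_schedule()].
#' @param calibration Optional [calibrate()] fit applied before
#'   differentiation.
#' @param control A [vog_control()].
#' @return A [estimate_skew()] result.
#' @export
run_vog <- function(trace, schedule, calibration = NULL,
                    control = vog_control()) {
  stopifnot(inherits(trace, "eye_trace"), inherits(schedule, "cover_schedule"))
  if (!is.null(calibration)) trace <- apply_calibration(trace, calibration)
  vel <- vog_velocity(trace, control)
  sacc <- detect_saccades(trace, vel, control)
  events <- lapply(schedule$switch_times, function(sw) {
    event_skew(trace, vel, sacc, sw, control)
  })
  estimate_skew(events, schedule, control)
}
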