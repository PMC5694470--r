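# Action-potential and calcium-transient biomarker extraction, and detection
# of early afterdepolarizations (EADs) on a simulated beat.

beat_window <- function(trace, beat) {
  bm <- trace$beat_markers
  if (beat < 1 || beat > length(bm)) stop("beat index out of range")
  t0 <- bm[beat]
  t1 <- if (beat < length(bm)) bm[beat + 1] else max(trace$time)
  sel <- trace$time >= t0 & trace$time <= t1
  if (!any(sel)) stop("trace does not cover the indexed beat")
  list(time = trace$time[sel], vm = trace$vm[sel], cai = trace$cai[sel],
       t0 = t0)
}

# time from activation until the signal falls below `level`, crossings
# linearly interpolated; activation = first upstroke crossing of level_act
duration_above <- function(time, x, level, t_act) {
  ip <- which.max(x)
  below <- which(seq_along(x) > ip & x < level)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  # interpolate between i-1 and i
  tc <- time[i - 1] + (time[i] - time[i - 1]) *
    (x[i - 1] - level) / (x[i - 1] - x[i])
  tc - t_act
}

activation_time <- function(time, x, level) {
  ab <- which(x >= level)
  if (!length(ab)) return(NA_real_)
  i <- ab[1]
  if (i == 1) return(time[1])
  time[i - 1] + (time[i] - time[i - 1]) * (level - x[i - 1]) / (x[i] - x[i - 1])
}

#' Extract AP and Ca-transient biomarkers from a simulated beat
#'
#' Computes the standard panel of thirteen derived metrics on one beat of a
#' `sim_trace` (see [pace_to_steady()]): maximal upstroke velocity, peak and resting voltage, APD30/
#' 50/90 (time from activation to 30/50/90% repolarization between the
#' beat's peak and its pre-stimulus diastolic level, crossings linearly
#' interpolated), AP duration above -60 mV, AP triangulation (APD90 -
#' APD30), diastolic and peak intracellular calcium, Ca-transient amplitude,
#' CaTD30/50/90 and CaT triangulation (CaTD90 - CaTD30), plus the EAD flag
#' from [detect_ead()].
#'
#' Baselines are per-beat (pre-stimulus diastolic value), which makes the
#' metrics robust to slow drift across beats.
#'
#' @param trace A `sim_trace` (see [pace_to_steady()]).
#' @param beat Beat index among `trace$beat_markers` (default: last).
#' @param ead_config Optional list passed to [detect_ead()].
#' @return A one-row tibble of class `biomarker_set`. If the beat shows no
#'   capture (peak - rest < 10 mV) all AP/Ca metrics are `NA` and `captured`
#'   is `FALSE`.
#' @export
compute_biomarkers <- function(trace, beat = length(trace$beat_markers),
                               ead_config = list()) {
  w <- beat_window(trace, beat)
  rest <- w$vm[1]
  peak <- max(w$vm)
  captured <- (peak - rest) >= 10
  ead <- detect_ead(trace, beat, config = ead_config)
  if (!captured) {
    out <- tibble::tibble(
      captured = FALSE, upstroke_velocity = NA_real_, peak_voltage = NA_real_,
      resting_voltage = rest, apd30 = NA_real_, apd50 = NA_real_,
      apd90 = NA_real_, apd_at_minus60 = NA_real_,
      ap_triangulation = NA_real_, diastolic_cai = w$cai[1],
      peak_cai = NA_real_, cat_amplitude = NA_real_, catd30 = NA_real_,
      catd50 = NA_real_, catd90 = NA_real_, cat_triangulation = NA_real_,
      ead = ead)
    class(out) <- c("biomarker_set", class(out))
    return(out)
  }
  dv <- diff(w$vm) / diff(w$time)
  t_act <- activation_time(w$time, w$vm, rest + 0.1 * (peak - rest))
  apdx <- function(frac) duration_above(w$time, w$vm,
                                        peak - frac * (peak - rest), t_act)
  apd30 <- apdx(0.30); apd50 <- apdx(0.50); apd90 <- apdx(0.90)
  apd60mv <- duration_above(w$time, w$vm, -60,
                            activation_time(w$time, w$vm, -60))
  ca0 <- w$cai[1]
  capk <- max(w$cai)
  t_act_ca <- activation_time(w$time, w$cai, ca0 + 0.1 * (capk - ca0))
  catdx <- function(frac) duration_above(w$time, w$cai,
                                         capk - frac * (capk - ca0), t_act_ca)
  catd30 <- catdx(0.30); catd50 <- catdx(0.50); catd90 <- catdx(0.90)
  out <- tibble::tibble(
    captured = TRUE,
    upstroke_velocity = max(dv),
    peak_voltage = peak,
    resting_voltage = rest,
    apd30 = apd30, apd50 = apd50, apd90 = apd90,
    apd_at_minus60 = apd60mv,
    ap_triangulation = apd90 - apd30,
    diastolic_cai = ca0,
    peak_cai = capk,
    cat_amplitude = capk - ca0,
    catd30 = catd30, catd50 = catd50, catd90 = catd90,
    cat_triangulation = catd90 - catd30,
    ead = ead)
  class(out) <- c("biomarker_set", class(out))
  out
}

#' Names of the thirteen derived features
#'
#' @return Character vector naming the biomarker columns used as derived
#'   classifier features.
#' @export
biomarker_names <- function() {
  c("upstroke_velocity", "peak_voltage", "apd50", "apd_at_minus60", "apd90",
    "resting_voltage", "ap_triangulation", "diastolic_cai", "cat_amplitude",
    "peak_cai", "catd50", "catd90", "cat_triangulation")
}

#' Detect an early afterdepolarization on a beat
#'
#' An EAD is flagged when, after the primary upstroke has turned into
#' repolarization (dV/dt < 0 past the beat's peak), the membrane voltage
#' while still above `window_mv` depolarizes again: dV/dt exceeding
#' `slope_mv_ms` continuously for at least `sustain_ms`. The numeric
#' criterion values are configurable; the defaults are calibrated so that
#' the detector reproduces the pause-protocol hERG-block thresholds of the
#' underlying myocyte models.
#'
#' @param trace A `sim_trace` (see [pace_to_steady()]).
#' @param beat Beat index (default: last, i.e. the post-pause beat for a
#'   pause protocol).
#' @param config Optional list overriding `slope_mv_ms` (default 0.01
#'   mV/ms), `sustain_ms` (default 1) and `window_mv` (default -60).
#' @return Logical. `FALSE` (with attribute `no_capture = TRUE`) when the
#'   beat shows no depolarization.
#' @export
detect_ead <- function(trace, beat = length(trace$beat_markers),
                       config = list()) {
  cfg <- modifyList(list(slope_mv_ms = 0.01, sustain_ms = 1, window_mv = -60),
                    config)
  w <- beat_window(trace, beat)
  if (max(w$vm) - w$vm[1] < 10) {
    return(structure(FALSE, no_capture = TRUE))
  }
  dv <- diff(w$vm) / diff(w$time)
  ipk <- which.max(w$vm)
  in_window <- seq_along(dv) > ipk & head(w$vm, -1) > cfg$window_mv
  # require the primary repolarization to have started
  started <- cumsum(dv < 0 & in_window) > 0
  rising <- dv > cfg$slope_mv_ms & in_window & started
  if (!any(rising)) return(FALSE)
  r <- rle(rising)
  lens <- r$lengths[r$values]
  # sustained rise, in ms, at the trace's sampling interval
  dt_med <- median(diff(w$time))
  isTRUE(any(lens * dt_med >= cfg$sustain_ms))
}
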