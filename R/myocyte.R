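# Human ventricular myocyte simulation: model construction, steady-state
# pacing and the short-long (pause) stimulation protocol used for EAD work.

#' Specify a ventricular myocyte model configuration
#'
#' Builds the configuration for one of the two supported human ventricular
#' myocyte models: the original O'Hara-Rudy formulation (`"OHR"`) or its
#' conductance-rescaled variant (`"OHRmv"`, with IKr, IKs, IK1, ICaL and INaL
#' maximal conductances rescaled per Dutta and colleagues' optimisation).
#' Drug effects enter exclusively through `scaling`, a per-channel
#' conductance multiplier (see [scale_conductances()]); `gnal_scale` rescales
#' the late-sodium conductance before drug scaling and is used to emulate an
#' LQT3-like gain of function (`gnal_scale = 2`).
#'
#' @param variant `"OHR"` or `"OHRmv"`.
#' @param cell_type `"endo"`, `"mid"` or `"epi"` transmural parameterisation.
#' @param gnal_scale Non-negative scalar applied to the late sodium
#'   conductance (1 = normal).
#' @param scaling A `conductance_scaling` object or named numeric vector of
#'   per-channel multipliers in `[0, 1]`; missing channels default to 1.
#' @return An object of class `cell_spec`.
#' @export
#' @examples
#' cell_spec("OHR", "mid")
#' cell_spec("OHRmv", "mid", gnal_scale = 2,
#'           scaling = c(IKr = 0.7))
cell_spec <- function(variant = c("OHR", "OHRmv"),
                      cell_type = c("endo", "mid", "epi"),
                      gnal_scale = 1,
                      scaling = NULL) {
  variant <- match.arg(variant)
  cell_type <- match.arg(cell_type)
  stopifnot(is.numeric(gnal_scale), length(gnal_scale) == 1, gnal_scale >= 0)
  mult <- rep(1, 7)
  names(mult) <- channel_names()
  if (!is.null(scaling)) {
    if (inherits(scaling, "conductance_scaling")) scaling <- scaling$multiplier
    if (is.null(names(scaling)) || !all(names(scaling) %in% channel_names()))
      stop("scaling must be named with channels from channel_names()")
    if (any(scaling < 0 | scaling > 1))
      stop("conductance multipliers must lie in [0, 1]")
    mult[names(scaling)] <- scaling
  }
  structure(
    list(variant = variant, cell_type = cell_type,
         gnal_scale = gnal_scale, multiplier = mult),
    class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf("<cell_spec> %s %s cell, gNaL x%g\n",
              x$variant, x$cell_type, x$gnal_scale))
  blocked <- x$multiplier[x$multiplier < 1]
  if (length(blocked))
    cat("  block:", paste(sprintf("%s %.0f%%", names(blocked),
                                  100 * (1 - blocked)), collapse = ", "), "\n")
  invisible(x)
}

#' Integrator configuration
#'
#' `forward_euler_fixed` is the reference scheme (default time step 0.001 ms)
#' and is mandatory for protocols whose outcome is an EAD call; the
#' `hybrid_rapid` scheme (forward Euler for concentrations plus Rush-Larsen
#' exponential updates for gating variables at a coarser fixed step) is an
#' order of magnitude faster and adequate for steady-state biomarker runs.
#'
#' @param method `"forward_euler_fixed"` or `"hybrid_rapid"`.
#' @param dt Time step in ms; defaults to 0.001 for the fixed scheme and
#'   0.01 for the rapid scheme.
#' @param record_dt Trace sampling interval in ms (default 0.1).
#' @param stim_amp Stimulus amplitude in uA/uF (default -80).
#' @param stim_dur Stimulus duration in ms (default 0.5).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(method = c("forward_euler_fixed", "hybrid_rapid"),
                              dt = NULL, record_dt = 0.1,
                              stim_amp = -80, stim_dur = 0.5) {
  method <- match.arg(method)
  if (is.null(dt)) dt <- if (method == "hybrid_rapid") 0.01 else 0.001
  stopifnot(dt > 0, record_dt > 0, stim_dur > 0)
  structure(list(method = method, dt = dt, record_dt = record_dt,
                 stim_amp = stim_amp, stim_dur = stim_dur),
            class = "integrator_config")
}

#' Resting initial state of the myocyte model
#'
#' @return Named numeric vector of the 41 state variables at the published
#'   starting point (membrane voltage -87 mV, diastolic ion concentrations).
#' @export
ord_initial_state <- function() ord_initial_state_cpp()

cell_type_code <- function(cell_type) {
  match(cell_type, c("endo", "epi", "mid")) - 1L
}

variant_code <- function(variant) {
  match(variant, c("OHR", "OHRmv")) - 1L
}

# Low-level segment runner. Returns list(state, time, vm, cai).
simulate_segment <- function(spec, state, t0, t_end, stim_times, config,
                             record_start = t_end) {
  res <- ord_run_cpp(
    as.numeric(state),
    cell_type_code(spec$cell_type), variant_code(spec$variant),
    spec$gnal_scale, as.numeric(spec$multiplier),
    t0, t_end, as.numeric(stim_times),
    config$stim_amp, config$stim_dur, config$dt,
    record_start, config$record_dt,
    if (config$method == "hybrid_rapid") 1L else 0L)
  if (isTRUE(res$blowup))
    stop(sprintf("simulation failure (non-finite or |vm| > 500 mV) at t = %.3f ms",
                 res$blowup_time), call. = FALSE)
  res
}

new_sim_trace <- function(time, vm, cai, beat_markers, meta) {
  structure(list(time = time, vm = vm, cai = cai,
                 beat_markers = beat_markers, meta = meta),
            class = "sim_trace")
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace> %d samples, t = [%.1f, %.1f] ms, %d beat marker(s)\n",
              length(x$time), min(x$time), max(x$time), length(x$beat_markers)))
  invisible(x)
}

#' Convert a simulation trace to a data frame
#'
#' @param x A `sim_trace`.
#' @param ... Unused.
#' @return A tibble with columns `time` (ms), `vm` (mV) and `cai` (mM).
#' @export
as.data.frame.sim_trace <- function(x, ...) {
  tibble::tibble(time = x$time, vm = x$vm, cai = x$cai)
}

state_cache_key <- function(spec, cycle_length, n_beats, config, state) {
  rlang::hash(list(spec$variant, spec$cell_type, spec$gnal_scale,
                   round(unname(spec$multiplier), 12),
                   cycle_length, n_beats,
                   config$method, config$dt, config$stim_amp, config$stim_dur,
                   round(as.numeric(state), 12)))
}

#' Pace a myocyte model to (fixed-count) steady state
#'
#' Applies `n_beats` stimuli at a constant cycle length and returns the trace
#' of the final beat together with the end-of-run state. Steady state is
#' defined by beat count, not by a convergence test.
#'
#' @param spec A [cell_spec()].
#' @param cycle_length Pacing cycle length in ms.
#' @param n_beats Number of paced beats (default 1000).
#' @param config An [integrator_config()].
#' @param state Initial state; defaults to [ord_initial_state()].
#' @param cache Reuse a memoised end state for identical inputs (default TRUE).
#' @return A `sim_trace` of the final beat; the end state is available as
#'   `$meta$state`.
#' @export
#' @examples
#' \donttest{
#' tr <- pace_to_steady(cell_spec("OHR", "endo"), 1000, n_beats = 20,
#'                      config = integrator_config("hybrid_rapid"))
#' compute_biomarkers(tr)
#' }
pace_to_steady <- function(spec, cycle_length = 1000, n_beats = 1000,
                           config = integrator_config(),
                           state = ord_initial_state(), cache = TRUE) {
  stopifnot(inherits(spec, "cell_spec"), cycle_length > 0, n_beats >= 1)
  key <- state_cache_key(spec, cycle_length, n_beats, config, state)
  if (cache && !is.null(res <- the$state_cache[[key]])) {
    return(res)
  }
  t_end <- n_beats * cycle_length
  stim_times <- seq(0, by = cycle_length, length.out = n_beats)
  seg <- simulate_segment(spec, state, 0, t_end, stim_times, config,
                          record_start = (n_beats - 1) * cycle_length)
  tr <- new_sim_trace(
    seg$time, seg$vm, seg$cai,
    beat_markers = (n_beats - 1) * cycle_length,
    meta = list(protocol = "pace", cycle_length = cycle_length,
                n_beats = n_beats, config = config, spec = spec,
                state = seg$state))
  if (cache) the$state_cache[[key]] <- tr
  tr
}

#' Short-long (pause) stimulation protocol
#'
#' The classical pause protocol for provoking early afterdepolarizations:
#' the cell is stimulated `n_stimuli` times at `cycle_length` (default 200
#' stimuli at 500 ms, i.e. 2 Hz), then held quiescent and given one
#' additional stimulus after a `pause`. The `pause` is the interval between
#' the final conditioning stimulus and the extra stimulus, so
#' `pause = cycle_length` degenerates to uninterrupted pacing. The returned
#' trace covers the final paced beat, the pause, and the post-pause beat
#' (the beat analysed for EADs); the post-pause stimulus time is in
#' `$meta$post_pause_stim`.
#'
#' Because EAD induction is sensitive to the slow state (intracellular Na,
#' SR load, CaMK activation), the stimulus train is preceded by
#' `pre_beats` conditioning beats at the same cycle length with the drug
#' applied, completing a fixed-count (1000-beat) approach to steady state;
#' the pre-conditioning phase may use the fast integrator (`pre_config`)
#' while the documented protocol segment and the post-pause beat always run
#' under `config` (fixed-step Euler for EAD work). Set `pre_beats = 0` to
#' start the train from the model's initial state.
#'
#' @param spec A [cell_spec()].
#' @param cycle_length Pacing cycle length in ms (default 500, i.e. 2 Hz).
#' @param n_stimuli Number of stimuli in the protocol train (default 200).
#' @param pause Quiescent interval in ms between the final stimulus of the
#'   train and the additional stimulus (default 1000).
#' @param config An [integrator_config()]; EAD calls require the fixed-step
#'   Euler scheme.
#' @param pre_beats Conditioning beats before the train (default 800, for
#'   1000 beats in total).
#' @param pre_config Integrator for the conditioning phase (default the
#'   fast Rush-Larsen scheme); pass `config` to run everything at the gold
#'   standard.
#' @param post_window Time in ms simulated after the post-pause stimulus
#'   (default 1500, enough to cover strongly prolonged EAD beats).
#' @param cache Reuse memoised conditioning states (default TRUE); the
#'   pause and post-pause beat are always re-simulated.
#' @return A `sim_trace`.
#' @export
pause_protocol <- function(spec, cycle_length = 500, n_stimuli = 200,
                           pause = 1000, config = integrator_config(),
                           pre_beats = 800,
                           pre_config = integrator_config("hybrid_rapid"),
                           post_window = 1500, cache = TRUE) {
  stopifnot(inherits(spec, "cell_spec"), pause >= 0, n_stimuli >= 2)
  # stage 1: conditioning beats (fast integrator allowed)
  state <- ord_initial_state()
  t0 <- 0
  if (pre_beats > 0) {
    pre <- pace_to_steady(spec, cycle_length, pre_beats, pre_config,
                          cache = cache)
    state <- pre$meta$state
    t0 <- pre_beats * cycle_length
  }
  # stage 2: the protocol train minus its final stimulus
  t_last <- t0 + (n_stimuli - 1) * cycle_length
  key2 <- rlang::hash(list("pausetrain", state_cache_key(
    spec, cycle_length, n_stimuli, config, state), t0))
  st2 <- if (cache) the$state_cache[[key2]] else NULL
  if (is.null(st2)) {
    seg2 <- simulate_segment(spec, state, t0, t_last,
                             seq(t0, by = cycle_length,
                                 length.out = n_stimuli - 1),
                             config, record_start = t_last + 1)
    st2 <- seg2$state
    if (cache) the$state_cache[[key2]] <- st2
  }
  # stage 3: final paced beat, pause, post-pause beat
  post_stim <- t_last + pause
  seg <- simulate_segment(spec, st2, t_last, post_stim + post_window,
                          c(t_last, post_stim), config,
                          record_start = t_last)
  new_sim_trace(
    seg$time, seg$vm, seg$cai,
    beat_markers = c(t_last, post_stim),
    meta = list(protocol = "pause", cycle_length = cycle_length,
                n_stimuli = n_stimuli, pause = pause, pre_beats = pre_beats,
                config = config, spec = spec, state = seg$state,
                post_pause_stim = post_stim))
}

#' Export a trace and its protocol metadata
#'
#' Writes the sampled trace as delimited text (time, vm, cai) and the
#' protocol metadata as a JSON sidecar next to it.
#'
#' @param trace A `sim_trace`.
#' @param path Output file path for the delimited trace.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(as.data.frame(trace), path)
  meta <- trace$meta
  meta$state <- NULL
  meta$spec <- list(variant = meta$spec$variant, cell_type = meta$spec$cell_type,
                    gnal_scale = meta$spec$gnal_scale,
                    multiplier = as.list(meta$spec$multiplier))
  meta$config <- unclass(meta$config)
  meta$beat_markers <- trace$beat_markers
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
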