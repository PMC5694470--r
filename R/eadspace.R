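# Parametric EAD analysis: pause-protocol EAD tests at combinations of
# ICaV / INaL / IKs block under fixed hERG block, decision-surface
# extraction, hERG-block threshold search, and EAD-based drug
# classification.

#' Test for a pause-induced EAD under a given block combination
#'
#' Runs the short-long pause protocol (conditioning stimuli at 2 Hz followed
#' by one stimulus after a quiescent interval) in the requested model and
#' reports whether the post-pause beat carries an EAD. Results are memoised
#' per session, and conditioning states are shared across pause lengths.
#'
#' @param variant `"OHR"` or `"OHRmv"`.
#' @param block Named percent-block vector (subset of [channel_names()]),
#'   e.g. `c(IKr = 60, ICaV = 30)`.
#' @param pause Quiescent interval in ms between the final conditioning
#'   stimulus and the extra stimulus (default 1000).
#' @param cell_type Cell type (default `"mid"`, the most EAD-prone).
#' @param gnal_scale Late-sodium conductance scale (2 = LQT3-like).
#' @param cycle_length,n_stimuli Conditioning pacing (defaults 500 ms, 200).
#' @param config Integrator; EAD calls use fixed-step Euler at 0.001 ms.
#' @param ead_config Passed to [detect_ead()].
#' @return Logical EAD flag, with the analysed trace in attribute `trace`.
#' @export
pause_ead_test <- function(variant, block = c(IKr = 0), pause = 1000,
                           cell_type = "mid", gnal_scale = 1,
                           cycle_length = 500, n_stimuli = 200,
                           pre_beats = 800,
                           config = integrator_config(),
                           pre_config = integrator_config("hybrid_rapid"),
                           ead_config = list()) {
  spec <- cell_spec(variant, cell_type, gnal_scale,
                    scaling = scale_conductances(block))
  key <- rlang::hash(list("pause_ead", spec$variant, spec$cell_type,
                          spec$gnal_scale, round(unname(spec$multiplier), 12),
                          pause, cycle_length, n_stimuli, pre_beats,
                          config$method, config$dt, pre_config$method,
                          pre_config$dt, ead_config))
  hit <- the$biomarker_cache[[key]]
  if (!is.null(hit)) return(hit)
  tr <- pause_protocol(spec, cycle_length, n_stimuli, pause, config,
                       pre_beats = pre_beats, pre_config = pre_config)
  ead <- detect_ead(tr, beat = length(tr$beat_markers), config = ead_config)
  res <- structure(as.logical(ead), trace = tr,
                   no_capture = isTRUE(attr(ead, "no_capture")))
  # memoise without the trace to keep grid scans light on memory
  the$biomarker_cache[[key]] <- structure(
    as.logical(ead), no_capture = isTRUE(attr(ead, "no_capture")))
  res
}

#' Minimal hERG block triggering a pause-induced EAD
#'
#' Finds the smallest hERG (IKr) block percentage whose post-pause beat
#' shows an EAD; all other channels stay unblocked unless given in
#' `extra_block`. The search scans upward in `coarse_step` increments and
#' then refines to `resolution` below the first positive — a plain
#' bisection is not reliable here because, well above the onset, strong
#' block can push the conditioning train into alternans and the EAD call
#' flickers (the response is not guaranteed monotone over the whole axis).
#'
#' @inheritParams pause_ead_test
#' @param extra_block Additional fixed blocks applied at every candidate.
#' @param lower,upper Search bounds in percent (defaults 0 and 100).
#' @param coarse_step Scan increment in percent (default 5).
#' @param resolution Reporting granularity in percent (default 1).
#' @return Percent block (a multiple of `resolution`), or `NA` if no
#'   candidate up to `upper` produces an EAD.
#' @export
ead_herg_threshold <- function(variant, pause = 1000, cell_type = "mid",
                               gnal_scale = 1, extra_block = NULL,
                               lower = 0, upper = 100, coarse_step = 5,
                               resolution = 1, ...) {
  test <- function(b) {
    blk <- c(IKr = b)
    if (!is.null(extra_block)) blk <- c(blk, extra_block)
    pause_ead_test(variant, blk, pause, cell_type, gnal_scale, ...)
  }
  coarse_step <- max(coarse_step, resolution)
  grid <- unique(c(seq(lower, upper, by = coarse_step), upper))
  first_pos <- NA_real_
  for (b in grid) {
    if (test(b)) { first_pos <- b; break }
  }
  if (is.na(first_pos)) return(NA_integer_)
  if (coarse_step > resolution && first_pos > lower) {
    for (b in seq(max(lower, first_pos - coarse_step) + resolution,
                  first_pos - resolution, by = resolution)) {
      if (test(b)) return(b)
    }
  }
  first_pos
}

#' Largest block of one channel at which EADs persist
#'
#' Sweeps one channel's block over a grid (default 0-100% in 10% steps) at
#' fixed other blocks and reports the largest grid value whose post-pause
#' beat still shows an EAD. EAD status is expected to change at most once
#' along the axis (suppression); non-monotone patterns trigger a warning
#' and the value before the first suppression is returned.
#'
#' @inheritParams pause_ead_test
#' @param channel Channel swept (e.g. `"ICaV"`).
#' @param fixed_block Named percent-block vector held fixed (e.g.
#'   `c(IKr = 60)`).
#' @param grid Block grid in percent (default `seq(0, 100, 10)`).
#' @param assume_monotone Use binary search over the grid instead of a full
#'   sweep (default TRUE; the single-crossing property is asserted by the
#'   grid tests).
#' @return Largest grid value with an EAD (`NA` if none, `max(grid)` if all).
#' @export
ead_persistence_limit <- function(variant, channel, fixed_block,
                                  grid = seq(0, 100, 10), pause = 1000,
                                  cell_type = "mid", gnal_scale = 1,
                                  assume_monotone = TRUE, ...) {
  grid <- sort(grid)
  test <- function(g) {
    blk <- fixed_block
    blk[channel] <- g
    pause_ead_test(variant, blk, pause, cell_type, gnal_scale, ...)
  }
  if (assume_monotone) {
    if (!test(grid[1])) return(NA_real_)
    lo <- 1; hi <- length(grid)
    if (test(grid[hi])) {
      # trust the all-EAD+ conclusion only if the axis looks monotone at
      # the edge; otherwise fall through to the full sweep
      if (test(grid[hi - 1])) return(grid[hi])
      warning("non-monotone EAD pattern along ", channel,
              "; falling back to a full sweep", call. = FALSE)
    } else {
      # invariant: grid[lo] EAD+, grid[hi] EAD-
      while (hi - lo > 1) {
        mid <- (lo + hi) %/% 2
        if (test(grid[mid])) lo <- mid else hi <- mid
      }
      return(grid[lo])
    }
  }
  ead <- vapply(grid, function(g) as.logical(test(g)), logical(1))
  if (!any(ead)) return(NA_real_)
  flips <- sum(diff(ead) != 0)
  if (flips > 1)
    warning("non-monotone EAD pattern along ", channel,
            "; using value before first suppression", call. = FALSE)
  first_off <- which(!ead & seq_along(ead) > which.max(ead))[1]
  if (is.na(first_off)) grid[max(which(ead))] else grid[first_off - 1]
}

#' Scan a grid of (ICaV, INaL, IKs) blocks for pause-induced EADs
#'
#' Evaluates the pause protocol at every combination of the three axes at a
#' fixed hERG block. Per-point simulation failures are recorded as
#' `status = "failed"` rather than aborting the scan. The full published
#' grid (0-100% in 10% steps, 11^3 points) is expensive; a reduced step
#' (25%) or explicit axis subsets are recommended interactively.
#'
#' @inheritParams pause_ead_test
#' @param herg_block hERG block in percent, held fixed.
#' @param step Grid step in percent (used for all axes unless overridden).
#' @param cav,nal,ks Explicit axis values (default `seq(0, 100, step)`).
#' @return An `ead_grid` tibble: `cav`, `nal`, `ks`, `ead`, `status`, with
#'   the scan conditions as attributes.
#' @export
scan_grid <- function(variant, herg_block = 60, step = 25,
                      cav = seq(0, 100, step), nal = seq(0, 100, step),
                      ks = seq(0, 100, step), pause = 1000,
                      cell_type = "mid", gnal_scale = 1, ...) {
  stopifnot(herg_block >= 0, herg_block <= 100)
  pts <- tidyr::expand_grid(cav = sort(cav), nal = sort(nal), ks = sort(ks))
  res <- lapply(seq_len(nrow(pts)), function(i) {
    blk <- c(IKr = herg_block, ICaV = pts$cav[i], INaL = pts$nal[i],
             IKs = pts$ks[i])
    tryCatch(
      list(ead = as.logical(pause_ead_test(variant, blk, pause, cell_type,
                                           gnal_scale, ...)),
           status = "ok"),
      error = function(e) list(ead = NA, status = "failed"))
  })
  out <- dplyr::mutate(pts,
                       ead = vapply(res, function(r) r$ead, logical(1)),
                       status = vapply(res, function(r) r$status, character(1)))
  structure(out, class = c("ead_grid", class(out)),
            variant = variant, herg_block = herg_block, pause = pause,
            cell_type = cell_type, gnal_scale = gnal_scale)
}

#' Extract the EAD+/EAD- decision surface from a grid
#'
#' For each (INaL, IKs) column the boundary is the midpoint between the
#' last EAD+ and the first EAD- ICaV level (EADs are suppressed by
#' sufficient calcium-channel block). Columns that never suppress report
#' the upper grid edge; columns with no EAD at all report `NA`. Columns
#' crossing more than once are flagged and use the first crossing.
#'
#' @param grid An `ead_grid`.
#' @return A tibble `nal`, `ks`, `cav_boundary`, `monotone`.
#' @export
extract_surface <- function(grid) {
  cols <- dplyr::group_split(dplyr::group_by(tibble::as_tibble(grid),
                                             nal, ks))
  rows <- lapply(cols, function(g) {
    g <- g[order(g$cav), ]
    ead <- g$ead
    mono <- sum(diff(ead) != 0) <= 1
    if (!any(ead, na.rm = TRUE)) {
      b <- NA_real_
    } else if (all(ead, na.rm = TRUE)) {
      b <- max(g$cav)
    } else {
      i_off <- which(!ead & seq_along(ead) > which.max(ead))[1]
      b <- if (is.na(i_off)) max(g$cav) else (g$cav[i_off - 1] + g$cav[i_off]) / 2
    }
    tibble::tibble(nal = g$nal[1], ks = g$ks[1], cav_boundary = b,
                   monotone = mono)
  })
  out <- dplyr::bind_rows(rows)
  if (any(!out$monotone))
    warning("non-monotone EAD column(s) in grid; boundary at first crossing",
            call. = FALSE)
  out
}

surface_boundary_at <- function(surface, nal, ks) {
  # nearest IKs level, then linear interpolation of the boundary along INaL
  ks_levels <- sort(unique(surface$ks))
  ks0 <- ks_levels[which.min(abs(ks_levels - ks))]
  s <- surface[surface$ks == ks0, ]
  s <- s[order(s$nal), ]
  if (nrow(s) == 1) return(s$cav_boundary)
  stats::approx(s$nal, s$cav_boundary, xout = nal, rule = 2)$y
}

#' Classify drugs by EAD propensity
#'
#' Step 1: drugs whose hERG ratio is at or above `ratio_threshold` are
#' EAD- (their exposure never reaches the EAD-generating hERG block).
#' Step 2: the drug's multi-channel block profile at `IC60,hERG` (60% hERG
#' block by construction) is tested for pause-induced EADs either by direct
#' simulation (authoritative) or by interpolating a precomputed decision
#' surface.
#'
#' @param panel A `drug_panel`.
#' @param variant Model variant for direct simulation.
#' @param ratio_threshold hERG-ratio gate (e.g. the threshold selected by
#'   [fit_two_step()]).
#' @param mode `"simulation"` or `"surface"`.
#' @param surface A surface from [extract_surface()] (required for
#'   `mode = "surface"`).
#' @param ... Passed to [pause_ead_test()].
#' @return Factor (`EAD-`, `EAD+`) named by drug; `NA` for drugs without an
#'   IKr assay.
#' @export
classify_by_ead <- function(panel, variant = "OHR", ratio_threshold = 100,
                            mode = c("simulation", "surface"),
                            surface = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "surface" && is.null(surface))
    stop("surface mode needs a decision surface")
  out <- rep(NA_character_, nrow(panel))
  for (i in seq_len(nrow(panel))) {
    drug <- panel[i, ]
    ic60 <- ic60_herg(drug)
    if (is.na(ic60)) next
    ratio <- herg_ratio(drug)
    if (!is.na(ratio) && ratio >= ratio_threshold) {
      out[i] <- "EAD-"
      next
    }
    bp <- block_profile(drug, ic60)
    if (mode == "simulation") {
      ead <- pause_ead_test(variant, bp$block, ...)
      out[i] <- if (ead) "EAD+" else "EAD-"
    } else {
      b <- surface_boundary_at(surface, bp$block["INaL"], bp$block["IKs"])
      out[i] <- if (!is.na(b) && bp$block["ICaV"] < b) "EAD+" else "EAD-"
    }
  }
  out <- factor(out, levels = c("EAD-", "EAD+"))
  names(out) <- panel$name
  out
}

#' Export an EAD grid as long-format CSV
#'
#' @param grid An `ead_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ead_grid <- function(grid, path) {
  out <- dplyr::mutate(tibble::as_tibble(grid),
                       herg_block = attr(grid, "herg_block"),
                       variant = attr(grid, "variant"),
                       .before = 1)
  readr::write_csv(out, path)
  invisible(path)
}
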