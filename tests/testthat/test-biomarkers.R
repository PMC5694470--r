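# Biomarker extraction on analytic waveforms, and EAD detection.

test_that("trapezoidal AP biomarkers equal their closed-form crossing times", {
  # rest -85, plateau +20 from t=100 to 300, linear repolarization to t=400
  tr <- make_trapezoid_trace(rest = -85, plateau = 20, t_up = 100,
                             t_repol_start = 300, t_repol_end = 400)
  bm <- compute_biomarkers(tr)
  expect_true(bm$captured)
  expect_equal(bm$peak_voltage, 20)
  expect_equal(bm$resting_voltage, -85)
  # activation: 10% above rest is crossed during the 1-ms upstroke ramp;
  # APDx ends where the linear 100-ms repolarization crosses the level
  amp <- 105
  act <- 100 + 0.1 * 1                       # 10% up the 1-ms ramp
  apdx <- function(frac) (300 + frac * 100) - act
  expect_equal(bm$apd30, apdx(0.30), tolerance = 1e-6)
  expect_equal(bm$apd50, apdx(0.50), tolerance = 1e-6)
  expect_equal(bm$apd90, apdx(0.90), tolerance = 1e-6)
  expect_equal(bm$ap_triangulation, 60, tolerance = 1e-6)
  # duration above -60 mV: crossing at 100 + (25/105) up the ramp until
  # repolarization passes -60 at t = 300 + 100*(80/105)
  t_on <- 100 + (25 / 105) * 1
  t_off <- 300 + 100 * (80 / 105)
  expect_equal(bm$apd_at_minus60, t_off - t_on, tolerance = 1e-3)
  # calcium-transient durations mirror the same geometry
  expect_equal(bm$cat_amplitude, 9e-4, tolerance = 1e-12)
  expect_equal(bm$cat_triangulation, 60, tolerance = 1e-4)
  expect_false(bm$ead)
})

test_that("a square pulse collapses all APDx to the pulse width", {
  tr <- make_square_trace(width = 200)
  bm <- compute_biomarkers(tr)
  expect_equal(bm$apd30, bm$apd90, tolerance = 0.2)
  expect_equal(bm$apd90, 200, tolerance = 0.2)
  expect_equal(bm$ap_triangulation, 0, tolerance = 0.2)
  expect_equal(bm$cat_triangulation, 0, tolerance = 0.2)
})

test_that("biomarkers are invariant to time shifts and resampling", {
  tr <- make_trapezoid_trace(dt = 0.001)
  bm_fine <- compute_biomarkers(tr)
  shifted <- mcbead:::new_sim_trace(tr$time + 5000, tr$vm, tr$cai,
                                    tr$beat_markers + 5000, tr$meta)
  bm_shift <- compute_biomarkers(shifted)
  expect_equal(bm_shift$apd90, bm_fine$apd90, tolerance = 1e-9)
  coarse <- make_trapezoid_trace(dt = 0.1)
  bm_coarse <- compute_biomarkers(coarse)
  for (m in c("apd30", "apd50", "apd90", "catd90")) {
    expect_lt(abs(bm_coarse[[m]] - bm_fine[[m]]),
              max(1, 0.01 * bm_fine[[m]]))
  }
})

test_that("non-captured beats are flagged instead of scored", {
  flat <- mcbead:::new_sim_trace(seq(0, 100, 0.1),
                                 rep(-85, 1001), rep(1e-4, 1001),
                                 beat_markers = 0, meta = list())
  bm <- compute_biomarkers(flat)
  expect_false(bm$captured)
  expect_true(is.na(bm$apd90))
  ead <- detect_ead(flat)
  expect_false(as.logical(ead))
  expect_true(attr(ead, "no_capture"))
})

test_that("EAD detection fires on a secondary depolarization and not on monotone repolarization", {
  tr <- make_trapezoid_trace()
  expect_false(detect_ead(tr))
  # inject a 10 mV bump during repolarization around -20 mV
  t <- tr$time
  bump <- 10 * exp(-((t - 345) / 8)^2)   # at t=345 vm ~ -27 on the ramp
  tr_bump <- mcbead:::new_sim_trace(t, tr$vm + bump, tr$cai,
                                    tr$beat_markers, tr$meta)
  expect_true(detect_ead(tr_bump))
  # the same bump below the -60 mV window must not fire
  bump_low <- 10 * exp(-((t - 398) / 3)^2)  # near the foot, vm < -60
  tr_low <- mcbead:::new_sim_trace(t, tr$vm + bump_low, tr$cai,
                                   tr$beat_markers, tr$meta)
  expect_false(detect_ead(tr_low))
  # criterion parameters are configurable
  expect_false(detect_ead(tr_bump, config = list(slope_mv_ms = 50)))
})

test_that("beat indexing selects the requested beat", {
  tr <- make_trapezoid_trace()
  tr2 <- mcbead:::new_sim_trace(
    c(tr$time, tr$time + 600), c(tr$vm, rep(-85, length(tr$time))),
    c(tr$cai, rep(1e-4, length(tr$time))),
    beat_markers = c(0, 600), meta = list())
  expect_true(compute_biomarkers(tr2, beat = 1)$captured)
  expect_false(compute_biomarkers(tr2, beat = 2)$captured)
  expect_error(compute_biomarkers(tr2, beat = 3), "out of range")
})
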