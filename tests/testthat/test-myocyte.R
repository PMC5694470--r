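# Myocyte simulator: determinism, convergence, baseline physiology.
# Heavier protocol-level behaviour (EAD thresholds) lives in the acceptance
# suite; these tests use short runs.

test_that("simulation is deterministic and pacing advances the state", {
  spec <- cell_spec("OHR", "endo")
  cfg <- integrator_config("hybrid_rapid")
  t1 <- pace_to_steady(spec, 500, n_beats = 3, cfg, cache = FALSE)
  t2 <- pace_to_steady(spec, 500, n_beats = 3, cfg, cache = FALSE)
  expect_identical(t1$vm, t2$vm)
  expect_identical(t1$meta$state, t2$meta$state)
  one <- pace_to_steady(spec, 500, n_beats = 1, cfg, cache = FALSE)
  expect_gt(max(abs(one$meta$state - ord_initial_state())), 1e-6)
})

test_that("the drug-free models reproduce the published resting and AP physiology", {
  # modest beat counts keep this quick; values approach the published
  # steady-state biomarkers (endo APD90 ~268 ms, rest ~-88 mV, epi shorter)
  cfg <- integrator_config("hybrid_rapid")
  tr_endo <- pace_to_steady(cell_spec("OHR", "endo"), 1000, 150, cfg)
  bm_endo <- compute_biomarkers(tr_endo)
  expect_lt(abs(bm_endo$resting_voltage - (-87.8)), 1)
  expect_lt(abs(bm_endo$apd90 - 268), 12)
  expect_gt(bm_endo$upstroke_velocity, 150)
  expect_gt(bm_endo$peak_voltage, 30)
  tr_epi <- pace_to_steady(cell_spec("OHR", "epi"), 1000, 150, cfg)
  bm_epi <- compute_biomarkers(tr_epi)
  expect_lt(bm_epi$apd90, bm_endo$apd90)
  expect_false(bm_endo$ead)
})

test_that("halving the Euler step changes APD90 by less than half a millisecond", {
  spec <- cell_spec("OHR", "endo")
  a <- pace_to_steady(spec, 500, 20, integrator_config(dt = 0.001),
                      cache = FALSE)
  b <- pace_to_steady(spec, 500, 20, integrator_config(dt = 0.0005),
                      cache = FALSE)
  expect_lt(abs(compute_biomarkers(a)$apd90 - compute_biomarkers(b)$apd90),
            0.5)
})

test_that("drug scaling multiplies conductances and prolongs the AP", {
  sc <- cell_spec("OHR", "endo", scaling = c(IKr = 0.4))
  expect_equal(unname(sc$multiplier["IKr"]), 0.4)
  cfg <- integrator_config("hybrid_rapid")
  base <- compute_biomarkers(pace_to_steady(cell_spec("OHR", "endo"),
                                            1000, 60, cfg))
  blocked <- compute_biomarkers(pace_to_steady(sc, 1000, 60, cfg))
  expect_gt(blocked$apd90, base$apd90 + 20)
  # OHRmv at equal block differs from OHR (rescaled conductances)
  mv <- compute_biomarkers(pace_to_steady(cell_spec("OHRmv", "endo"),
                                          1000, 60, cfg))
  expect_gt(abs(mv$apd90 - base$apd90), 0.5)
  # LQT3 configuration: doubled late sodium prolongs the AP
  lqt <- compute_biomarkers(pace_to_steady(
    cell_spec("OHRmv", "endo", gnal_scale = 2), 1000, 60, cfg))
  expect_gt(lqt$apd90, mv$apd90 + 5)
})

test_that("a pause equal to the cycle length degenerates to steady pacing", {
  spec <- cell_spec("OHR", "endo")
  cfg <- integrator_config("hybrid_rapid")
  tr <- pause_protocol(spec, 500, n_stimuli = 30, pause = 500, cfg,
                       pre_beats = 0, post_window = 480)
  steady <- pace_to_steady(spec, 500, 31, cfg, cache = FALSE)
  bm_pp <- compute_biomarkers(tr, beat = 2)
  bm_st <- compute_biomarkers(steady)
  expect_lt(abs(bm_pp$apd90 - bm_st$apd90), 2)
})

test_that("traces export with protocol metadata", {
  spec <- cell_spec("OHR", "endo")
  tr <- pace_to_steady(spec, 500, 2, integrator_config("hybrid_rapid"),
                       cache = FALSE)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  df <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(names(df), c("time", "vm", "cai"))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$protocol, "pace")
  expect_equal(meta$spec$variant, "OHR")
})
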