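# Shared fixtures: tiny hand-built panels and synthetic traces.

make_mini_panel <- function() {
  drug_panel(tibble::tibble(
    name = c("hergonly", "balanced", "safe"),
    ic50_IKr = c(1000, 500, 2000),
    hill_IKr = c(1, 1, 2),
    ic50_ICaV = c(NA, 750, 100),
    hill_ICaV = c(NA, 1, 1),
    eftpc = c(150, 5, 1),
    crediblemeds = c("CM1", "CM2", "CM3"),
    redfern = c("R2", NA, "R5"),
    champeroux = c(NA, "CH1", NA),
    label_warning = c(TRUE, NA, FALSE)))
}

# piecewise-linear AP: rest, instantaneous-ish upstroke, flat plateau,
# linear repolarization; closed-form APDx crossings
make_trapezoid_trace <- function(rest = -85, plateau = 20, t_up = 100,
                                 t_repol_start = 300, t_repol_end = 400,
                                 t_end = 600, dt = 0.1) {
  time <- seq(0, t_end, by = dt)
  vm <- approx(c(0, t_up, t_up + 1, t_repol_start, t_repol_end, t_end),
               c(rest, rest, plateau, plateau, rest, rest),
               xout = time)$y
  cai <- approx(c(0, t_up, t_up + 1, t_repol_start, t_repol_end, t_end),
                c(1e-4, 1e-4, 1e-3, 1e-3, 1e-4, 1e-4), xout = time)$y
  mcbead:::new_sim_trace(time, vm, cai, beat_markers = 0,
                         meta = list(protocol = "synthetic"))
}

make_square_trace <- function(rest = -85, top = 20, width = 200,
                              t_end = 500, dt = 0.1) {
  time <- seq(0, t_end, by = dt)
  vm <- ifelse(time > 50 & time <= 50 + width, top, rest)
  cai <- ifelse(time > 50 & time <= 50 + width, 1e-3, 1e-4)
  mcbead:::new_sim_trace(time, vm, cai, beat_markers = 0,
                         meta = list(protocol = "synthetic"))
}
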