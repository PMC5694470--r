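# Risk-map construction: algebraic identity with the fitted model.

test_that("single-feature maps expose the raw ICaV boundary", {
  p <- generate_synthetic_panel(120, 100, 30, 0, seed = 17)
  labels <- binarize_labels(p, "target3")
  m <- fit_two_step(p, labels, "ICaV")
  spec <- build_risk_map(m)
  expect_equal(spec$x_threshold, m$ratio_threshold)
  expect_equal(spec$y_threshold,
               -m$beta[["(intercept)"]] / m$beta[["block_ICaV"]])
  expect_equal(spec$y_definition$feature, "block_ICaV")
  expect_equal(spec$y_definition$coefficient, 1)
})

test_that("map regions reproduce model predictions for every drug", {
  for (s in c(2, 8)) {
    p <- generate_synthetic_panel(100, 100, 30, 0.1, seed = s)
    labels <- binarize_labels(p, "target3")
    for (feats in list("ICaV", c("ICaV", "INaL"))) {
      m <- fit_two_step(p, labels, feats)
      spec <- build_risk_map(m)
      coords <- risk_map_coords(spec, p, labels)
      expect_equal(coords$region == "high",
                   as.character(predict(m, p)) == "TdP+")
    }
  }
})

test_that("normalized coefficients are invariant to common rescaling", {
  p <- generate_synthetic_panel(80, 100, 30, 0, seed = 23)
  m <- fit_two_step(p, binarize_labels(p, "target3"), c("ICaV", "INaL"))
  spec1 <- build_risk_map(m)
  m2 <- m
  m2$beta <- m$beta * 3.7
  spec2 <- build_risk_map(m2)
  expect_equal(spec2$y_definition$coefficient, spec1$y_definition$coefficient)
  expect_equal(spec2$y_threshold, spec1$y_threshold)
})

test_that("plotting returns a coordinates table usable headlessly", {
  p <- generate_synthetic_panel(40, 100, 30, 0, seed = 19)
  labels <- binarize_labels(p, "target3")
  m <- fit_two_step(p, labels)
  spec <- build_risk_map(m)
  out <- plot_risk_map(spec, p, labels, ead_boundary = 30)
  expect_s3_class(out$plot, "ggplot")
  expect_equal(nrow(out$coords), 40)
  expect_true(all(c("name", "x", "y", "region", "label") %in%
                    names(out$coords)))
  # empty panel: regions only, no points
  empty <- drug_panel(tibble::tibble(name = character()))
  out0 <- plot_risk_map(spec, empty)
  expect_equal(nrow(out0$coords), 0)
  # the worked example: ratio 500 with threshold <= 200 sits in the low zone
  far <- drug_panel(tibble::tibble(name = "safe", ic50_IKr = 1000,
                                   hill_IKr = 1, ic50_ICaV = 1e9,
                                   eftpc = 3))
  cf <- risk_map_coords(spec, far)
  expect_equal(cf$region, "low")
})

test_that("ternary maps partition the plane with two thresholds per axis", {
  set.seed(41)
  n_per <- 6
  ratio <- c(10^runif(n_per, 0, log10(20)),
             10^runif(n_per, 0, log10(140)),
             10^runif(n_per, log10(160), 3),
             10^runif(n_per, 0, log10(140)))
  fs <- c(runif(n_per, 5, 25), runif(n_per, 38, 55),
          runif(n_per, 5, 55), runif(n_per, 75, 99))
  cls <- rep(c("high", "intermediate", "low", "low"), each = n_per)
  p <- drug_panel(tibble::tibble(
    name = sprintf("d%02d", seq_along(ratio)),
    ic50_IKr = 1000, hill_IKr = 1,
    ic50_ICaV = 1500 * (100 - fs) / fs, hill_ICaV = 1,
    eftpc = 1500 / ratio))
  labels <- factor(cls, c("high", "intermediate", "low"))
  m <- fit_ternary(p, labels, features = "ICaV", include_trapping = FALSE)
  spec <- build_risk_map(m)
  expect_equal(spec$kind, "ternary")
  coords <- risk_map_coords(spec, p, labels)
  expect_equal(as.character(coords$region), as.character(predict(m, p)))
  out <- plot_risk_map(spec, p, labels)
  expect_s3_class(out$plot, "ggplot")
})
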