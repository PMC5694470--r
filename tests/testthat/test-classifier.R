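# Two-step classifier, one-step baseline, LOO evaluation, ternary scheme.

test_that("ridge logistic agrees with glm on well-conditioned data", {
  set.seed(11)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.7 + 1.4 * x))
  beta <- mcbead:::ridge_logit(matrix(x, ncol = 1, dimnames =
                                        list(NULL, "x")), y)
  ref <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(beta), unname(ref), tolerance = 1e-3)
  # and stays finite on separable data
  ys <- as.integer(x > 0)
  bs <- mcbead:::ridge_logit(matrix(x, ncol = 1), ys)
  expect_true(all(is.finite(bs)))
  expect_true(bs[2] > 0)
})

test_that("two-step fit recovers the generative rule on a noise-free panel", {
  p <- generate_synthetic_panel(200, ratio_threshold = 100, cav_cutoff = 30,
                                noise_sd = 0, seed = 42)
  labels <- binarize_labels(p, "target3")
  m <- fit_two_step(p, labels, features = "ICaV")
  expect_equal(m$ratio_threshold, 100)
  expect_equal(m$training_accuracy, 100)
  # step-2 boundary (in % ICaV block) recovers the generative cutoff
  boundary <- -m$beta[["(intercept)"]] / m$beta[["block_ICaV"]]
  expect_lt(abs(boundary - 30), 5)
  # predictions match the ground truth drug by drug
  expect_equal(as.character(predict(m, p)), as.character(labels))
})

test_that("high-ratio drugs are always predicted non-torsadogenic", {
  p <- generate_synthetic_panel(60, seed = 3)
  m <- fit_two_step(p, binarize_labels(p, "target3"))
  far <- drug_panel(tibble::tibble(
    name = "farsafe", ic50_IKr = 1000, hill_IKr = 1,
    ic50_ICaV = 1e9, eftpc = 3))  # ratio 500, negligible CaV block
  expect_equal(as.character(predict(m, far)), "TdP-")
})

test_that("a panel separable by the ratio gate alone is perfectly classified at the smallest threshold", {
  p <- drug_panel(tibble::tibble(
    name = sprintf("d%02d", 1:10),
    ic50_IKr = 1000, hill_IKr = 1,
    ic50_ICaV = NA_real_,
    eftpc = c(1500 / seq(10, 45, length.out = 5),    # ratios 10-45 -> TdP+
              1500 / c(300, 400, 500, 800, 1000)),   # ratios 300+  -> TdP-
    crediblemeds = rep(c("CM1", "CM3"), each = 5)))
  m <- fit_two_step(p, binarize_labels(p, "target3"))
  expect_equal(m$training_accuracy, 100)
  expect_equal(m$ratio_threshold, 50)
})

test_that("one-step baseline fits at EFTPC and degrades to majority class", {
  p <- generate_synthetic_panel(80, seed = 9)
  labels <- binarize_labels(p, "target3")
  m1 <- fit_one_step(p, labels, features = c("IKr", "ICaV"))
  expect_true(m1$training_accuracy >= 50)
  # identical features: intercept-only behaviour -> majority class
  pconst <- drug_panel(tibble::tibble(
    name = c("a", "b", "c", "d", "e"),
    ic50_IKr = 1000, hill_IKr = 1, eftpc = 100,
    crediblemeds = c("CM1", "CM3", "CM3", "CM3", "CM3")))
  mc <- fit_one_step(pconst, binarize_labels(pconst, "target3"),
                     features = "IKr")
  expect_equal(as.character(predict(mc, pconst)), rep("TdP-", 5))
})

test_that("two-step beats one-step on the generative family", {
  accs <- vapply(1:10, function(s) {
    p <- generate_synthetic_panel(80, 100, 30, 0, seed = s)
    labels <- binarize_labels(p, "target3")
    two <- fit_two_step(p, labels, "ICaV")$training_accuracy
    one <- fit_one_step(p, labels, c("IKr", "ICaV"))$training_accuracy
    two - one
  }, numeric(1))
  expect_gte(mean(accs), 0)
})

test_that("LOO is exact on separable panels and near chance under permutation", {
  # n large enough that every inter-threshold ratio interval contains
  # multiple drugs, so fold-wise threshold re-selection is stable
  p <- generate_synthetic_panel(200, 100, 30, 0, seed = 5)
  labels <- binarize_labels(p, "target3")
  expect_equal(loo_accuracy(p, labels, "two_step", features = "ICaV"), 100)
  # permuted labels on a balanced panel: accuracy within the binomial
  # null band around the majority-class rate (~50% when balanced)
  pb <- generate_synthetic_panel(60, 200, 70, 0, seed = 6)
  lb <- binarize_labels(pb, "target3")
  set.seed(21)
  perm <- sample(lb)
  names(perm) <- names(lb)
  acc <- loo_accuracy(pb, perm, "two_step", features = "ICaV")
  phat <- max(table(lb)) / length(lb)
  band <- qbinom(c(0.025, 0.975), 60, phat) / 60 * 100
  expect_gte(acc, band[1] - 10)
  expect_lte(acc, band[2] + 10)
})

test_that("LOO on three drugs is quantized to thirds", {
  p <- generate_synthetic_panel(4, seed = 2)[1:3, ]
  p <- drug_panel(tibble::as_tibble(p))
  labels <- factor(c("TdP+", "TdP-", "TdP+"), c("TdP-", "TdP+"))
  acc <- loo_accuracy(p, labels, "two_step")
  expect_true(any(abs(acc - c(0, 100 / 3, 200 / 3, 100)) < 1e-9))
})

test_that("step-2 predictions ignore EFTPC changes that preserve the gate side", {
  p <- generate_synthetic_panel(50, seed = 13)
  labels <- binarize_labels(p, "target3")
  m <- fit_two_step(p, labels, "ICaV")
  ratios <- vapply(seq_len(nrow(p)), function(i) herg_ratio(p[i, ]),
                   numeric(1))
  p2 <- tibble::as_tibble(p)
  # nudge EFTPC by 10% where that cannot cross the selected threshold
  scale <- ifelse(ratios < m$ratio_threshold / 1.5, 1.1,
                  ifelse(ratios > m$ratio_threshold * 1.5, 0.9, 1))
  p2$eftpc <- p2$eftpc * scale
  p2 <- drug_panel(p2)
  expect_equal(predict(m, p2), predict(m, p))
})

test_that("the ternary scheme recovers region-constructed classes", {
  set.seed(31)
  n_per <- 8
  # classes drawn directly from the region definitions, with margins
  # around the feature-sum boundaries (the fitted thresholds must land in
  # the gaps at ~27-43 and ~52-68)
  ratio <- c(10^runif(n_per, 0, log10(20)),        # high
             10^runif(n_per, 0, log10(140)),       # intermediate
             10^runif(n_per, log10(160), 3),       # low via the ratio gate
             10^runif(n_per, 0, log10(140)))       # low via feature sum
  fsum <- c(runif(n_per, 5, 27), runif(n_per, 43, 52),
            runif(n_per, 5, 52), runif(n_per, 68, 99))
  cls <- rep(c("high", "intermediate", "low", "low"), each = n_per)
  ic60 <- 1500
  p <- drug_panel(tibble::tibble(
    name = sprintf("t%03d", seq_along(ratio)),
    ic50_IKr = 1000, hill_IKr = 1,
    ic50_ICaV = ic60 * (100 - fsum) / fsum, hill_ICaV = 1,
    eftpc = ic60 / ratio))
  labels <- factor(cls, c("high", "intermediate", "low"))
  m <- fit_ternary(p, labels, features = "ICaV", include_trapping = FALSE)
  expect_true(m$y_high > 27 & m$y_high < 43)
  expect_true(m$y_low > 52 & m$y_low < 68)
  expect_equal(as.character(predict(m, p)), as.character(labels))
  # a high ratio forces low risk regardless of the feature sum
  hi_ratio <- drug_panel(tibble::tibble(
    name = "safe", ic50_IKr = 1000, hill_IKr = 1, ic50_ICaV = 30,
    eftpc = 1500 / 300))
  expect_equal(as.character(predict(m, hi_ratio)), "low")
  # a low ratio with a feature sum below the high boundary is high risk
  risky <- drug_panel(tibble::tibble(
    name = "risky", ic50_IKr = 1000, hill_IKr = 1, ic50_ICaV = 1e8,
    eftpc = 1500 / 5))
  expect_equal(as.character(predict(m, risky)), "high")
  expect_error(fit_ternary(p, factor(rep("high", nrow(p)),
                                     c("high", "intermediate", "low"))),
               "2 risk classes")
})
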