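# Panel reading, label binarization, merging, synthetic generation.

test_that("panels read from CSV with unit conversion and assumed-zero channels", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("Drug,hERG_IC50_uM,hERG_h,CaV_IC50_uM,EFTPC_uM,CM,warn",
               "quini,0.3,1,10,0.9,CM1,TRUE",
               "vera,0.14,1,0.2,0.08,CM3,FALSE"), csv)
  schema <- list(
    name = "Drug", eftpc = "EFTPC_uM",
    channels = list(IKr = list(ic50 = "hERG_IC50_uM", hill = "hERG_h"),
                    ICaV = list(ic50 = "CaV_IC50_uM")),
    units = list(IKr = "uM", ICaV = "uM", eftpc = "uM"),
    labels = list(crediblemeds = "CM", label_warning = "warn"))
  p <- read_panel(csv, schema)
  expect_s3_class(p, "drug_panel")
  expect_equal(p$ic50_IKr, c(300, 140))     # uM -> nM
  expect_equal(p$eftpc, c(900, 80))
  expect_true(all(is.na(p$ic50_INaL)))
  # a missing channel means 0 block at any concentration
  expect_equal(unname(block_profile(p[1, ], 1e6)$block["INaL"]), 0)
  # missing hill -> 1 assumed at evaluation time
  expect_equal(unname(block_profile(p[1, ], 10000)$block["ICaV"]), 50)
})

test_that("format and validation errors are specific", {
  bad <- tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2"), bad)
  expect_error(read_panel(bad), "drug-name")
  noikr <- tempfile(fileext = ".csv")
  writeLines(c("name,ic50_ICaV", "a,100"), noikr)
  expect_error(read_panel(noikr), "IKr")
  neg <- tempfile(fileext = ".csv")
  writeLines(c("name,ic50_IKr", "a,100", "b,-5"), neg)
  expect_error(read_panel(neg), "row\\(s\\) 2")
  empty <- tempfile(fileext = ".csv")
  file.create(empty)
  expect_equal(nrow(read_panel(empty)), 0)
})

test_that("panels round-trip through write and read unchanged", {
  p <- generate_synthetic_panel(12, seed = 4)
  f <- tempfile(fileext = ".csv")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(tibble::as_tibble(p2), tibble::as_tibble(p), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(file.exists(paste0(f, ".json")))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$concentration_unit, "nM")
})

test_that("binarization follows the label definitions and is idempotent", {
  p <- make_mini_panel()
  t1 <- binarize_labels(p, "target1")
  expect_equal(as.character(t1), c("TdP+", "TdP+", "TdP-"))  # CM1; CH1; R5
  t2 <- binarize_labels(p, "target2")
  expect_equal(as.character(t2), c("TdP+", "TdP+", "TdP-"))  # CM3 not in {CM1,CM2}
  t3 <- binarize_labels(p, "target3")
  expect_equal(as.character(t3), c("TdP+", "TdP-", "TdP-"))
  t4 <- binarize_labels(p, "target4")
  expect_equal(as.character(t4), c("TdP+", "TdP-", "TdP+"))
  # CiPA ternary -> binary: CP1/CP2 positive, CP3 negative
  pc <- drug_panel(tibble::tibble(name = c("a", "b", "c"),
                                  ic50_IKr = 1, cipa = c("CP1", "CP2", "CP3")))
  expect_equal(as.character(binarize_labels(pc, "cipa")),
               c("TdP+", "TdP+", "TdP-"))
  # unlabeled drugs get NA with a warning, and repeat calls are stable
  pu <- drug_panel(tibble::tibble(name = c("a", "b"), ic50_IKr = 1,
                                  crediblemeds = c("CM1", NA)))
  expect_warning(l1 <- binarize_labels(pu, "target2"), "unlabeled")
  expect_true(is.na(l1[2]))
  expect_equal(suppressWarnings(binarize_labels(pu, "target2")), l1)
})

test_that("merging averages on the concentration scale and unions labels", {
  p1 <- drug_panel(tibble::tibble(name = "DrugA", ic50_IKr = 100,
                                  eftpc = 10, crediblemeds = "CM1"))
  p2 <- drug_panel(tibble::tibble(name = "druga", ic50_IKr = 300,
                                  eftpc = 20, redfern = "R2"))
  p3 <- drug_panel(tibble::tibble(name = "Other", ic50_IKr = 50))
  m <- merge_panels(list(p1, p2, p3))
  expect_equal(nrow(m), 2)
  a <- m[m$name == "DrugA", ]
  expect_equal(a$ic50_IKr, 200)
  expect_equal(a$eftpc, 15)
  expect_equal(a$crediblemeds, "CM1")
  expect_equal(a$redfern, "R2")
  # pass-through of singletons
  expect_equal(m$ic50_IKr[m$name == "Other"], 50)
  # order invariance for numeric fields (drug identity is case-insensitive,
  # so the retained name spelling may differ)
  m2 <- merge_panels(list(p3, p2, p1))
  i <- match(tolower(m$name), tolower(m2$name))
  num <- names(m)[vapply(m, is.numeric, logical(1))]
  expect_equal(as.data.frame(m2[i, num]), as.data.frame(m[, num]),
               ignore_attr = TRUE)
  # conflicting categorical labels resolve to the higher risk, with warning
  q1 <- drug_panel(tibble::tibble(name = "x", ic50_IKr = 1,
                                  crediblemeds = "CM3"))
  q2 <- drug_panel(tibble::tibble(name = "x", ic50_IKr = 1,
                                  crediblemeds = "CM1"))
  expect_warning(mq <- merge_panels(list(q1, q2)), "conflicting")
  expect_equal(mq$crediblemeds, "CM1")
})

test_that("label overrides replace labels for matching drugs only", {
  p <- make_mini_panel()
  ov <- tibble::tibble(name = c("HERGONLY", "nosuch"),
                       crediblemeds = c("CM3", "CM1"),
                       label_warning = c(FALSE, NA))
  p2 <- apply_label_overrides(p, ov)
  expect_equal(p2$crediblemeds[1], "CM3")
  expect_false(p2$label_warning[1])
  expect_equal(p2$crediblemeds[-1], p$crediblemeds[-1])
})

test_that("synthetic panels are reproducible and separable at zero noise", {
  a <- generate_synthetic_panel(50, 100, 30, 0, seed = 7)
  b <- generate_synthetic_panel(50, 100, 30, 0, seed = 7)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  tr <- attr(a, "truth")
  # the generative rule itself labels the panel
  expect_equal(tr$tdp_true,
               tr$herg_ratio < 100 & tr$cav_block_at_ic60 < 30)
  expect_equal(as.character(binarize_labels(a, "target3")),
               ifelse(tr$tdp_true, "TdP+", "TdP-"))
  # panel features reproduce the generative coordinates
  ratios <- vapply(seq_len(nrow(a)), function(i) herg_ratio(a[i, ]),
                   numeric(1))
  expect_equal(ratios, tr$herg_ratio, tolerance = 1e-9)
  blocks <- direct_features(a, "ICaV", "ic60")[, 1]
  expect_equal(unname(blocks), tr$cav_block_at_ic60, tolerance = 1e-9)
  expect_error(generate_synthetic_panel(2), ">= 4")
  expect_error(generate_synthetic_panel(10, ratio_threshold = 75), "one of")
  expect_error(generate_synthetic_panel(10, cav_cutoff = 120), "0, 100")
})

test_that("the shipped example assay table loads through its schema", {
  csv <- system.file("extdata", "synthetic_assay_lab_style.csv",
                     package = "mcbead")
  schema <- system.file("extdata", "schema_example.yaml", package = "mcbead")
  p <- read_panel(csv, schema)
  expect_s3_class(p, "drug_panel")
  expect_equal(nrow(p), 12)
  expect_false(anyNA(p$ic50_IKr))
  ref <- read_panel(system.file("extdata", "synthetic_panel_example.csv",
                                package = "mcbead"))
  expect_equal(p$ic50_IKr, ref$ic50_IKr, tolerance = 1e-9)
  expect_equal(p$eftpc, ref$eftpc, tolerance = 1e-9)
})
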