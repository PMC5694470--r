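# The two-step TdP risk classifier: hERG-ratio gate followed by logistic
# regression on channel-block features at EAD-generating (IC60,hERG)
# concentrations; the one-step baseline at EFTPC; leave-one-out evaluation;
# and the equal-weight ternary extension for CiPA-style three-class labels.

#' Direct feature matrix for a panel
#'
#' Per-channel percent block evaluated at a concentration rule: either each
#' drug's `IC60,hERG` (the concentration producing 60% hERG block, derived
#' from its IKr assay) or its EFTPC. Channels without an assay contribute 0
#' (assumed-zero policy). Optionally appends the drug-trapping scalar
#' (missing values set to 0).
#'
#' @param panel A `drug_panel`.
#' @param channels Channels to include (default `"ICaV"`).
#' @param conc_rule `"ic60"` or `"eftpc"`.
#' @param include_trapping Append the `trapping` column (default FALSE).
#' @return Numeric matrix, rows named by drug. Rows where the rule's
#'   concentration is unavailable (no IKr assay for `"ic60"`, no EFTPC for
#'   `"eftpc"`) are `NA`.
#' @export
direct_features <- function(panel, channels = "ICaV",
                            conc_rule = c("ic60", "eftpc"),
                            include_trapping = FALSE) {
  conc_rule <- match.arg(conc_rule)
  stopifnot(all(channels %in% channel_names()))
  n <- nrow(panel)
  cols <- c(paste0("block_", channels), if (include_trapping) "trapping")
  X <- matrix(NA_real_, n, length(cols), dimnames = list(panel$name, cols))
  for (i in seq_len(n)) {
    drug <- panel[i, ]
    conc <- switch(conc_rule, ic60 = ic60_herg(drug), eftpc = drug$eftpc)
    if (is.na(conc)) next
    bp <- block_profile(drug, conc)
    X[i, seq_along(channels)] <- bp$block[channels]
    if (include_trapping)
      X[i, "trapping"] <- if (is.na(drug$trapping)) 0 else drug$trapping
  }
  X
}

# Ridge-stabilised logistic regression via IRLS. A very weak penalty
# (relative strength `lambda`, intercept unpenalised) keeps the fit finite
# on linearly separable feature sets, where the unpenalised MLE diverges.
ridge_logit <- function(X, y, lambda = 1e-6, maxit = 200, tol = 1e-9) {
  X <- as.matrix(X)
  Xa <- cbind("(intercept)" = 1, X)
  p <- ncol(Xa)
  # scale-relative penalty so the fit is invariant to feature rescaling
  sc <- c(1, apply(X, 2, function(col) max(stats::sd(col), 1e-8)))
  pen <- lambda * nrow(Xa) / sc^2
  pen[1] <- 0
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xa %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    H <- crossprod(Xa, Xa * w) + diag(pen, p)
    bnew <- tryCatch(drop(solve(H, crossprod(Xa, w * z))),
                     error = function(e) beta)
    if (max(abs(bnew - beta)) < tol) { beta <- bnew; break }
    beta <- bnew
  }
  names(beta) <- colnames(Xa)
  beta
}

logit_predict <- function(beta, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  stats::plogis(drop(cbind(1, X) %*% beta))
}

#' Fit the two-step TdP classifier
#'
#' Step 1 gates on the hERG safety ratio: drugs whose `IC60,hERG / EFTPC`
#' ratio is at or above a threshold are classified TdP- outright (their
#' therapeutic exposure never approaches the EAD-generating degree of hERG
#' block). Step 2 fits a logistic regression on channel-block features
#' evaluated at `IC60,hERG` — deliberately independent of EFTPC — for the
#' remaining drugs. Four candidate ratio thresholds are tried and the one
#' with the best overall training accuracy is kept (ties go to the smallest
#' threshold); the accuracy denominator includes the gated drugs, counted as
#' TdP- predictions.
#'
#' Drugs lacking an EFTPC cannot be gated and are routed directly to step 2
#' (with a warning); drugs with `NA` labels are ignored for training.
#'
#' @param panel A `drug_panel`.
#' @param labels Factor as returned by [binarize_labels()] (levels `TdP-`,
#'   `TdP+`), or anything coercible.
#' @param features Channels for step 2 (default `"ICaV"`).
#' @param include_trapping Append the trapping scalar as a feature.
#' @param thresholds Candidate hERG-ratio thresholds (default 50, 100, 150,
#'   200).
#' @param lambda Ridge strength for the logistic fit.
#' @param cutoff Probability cutoff (default 0.5).
#' @return An object of class `twostep_model`.
#' @export
fit_two_step <- function(panel, labels, features = "ICaV",
                         include_trapping = FALSE,
                         thresholds = c(50, 100, 150, 200),
                         lambda = 1e-6, cutoff = 0.5) {
  lab <- factor(labels, levels = c("TdP-", "TdP+"))
  keep <- !is.na(lab)
  if (sum(keep) < 4) stop("need at least 4 labeled drugs")
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  if (any(is.na(ratio[keep])))
    warning("drug(s) without hERG ratio routed directly to step 2: ",
            paste(panel$name[keep & is.na(ratio)], collapse = ", "),
            call. = FALSE)
  X <- direct_features(panel, features, "ic60", include_trapping)
  y <- as.integer(lab == "TdP+")
  fits <- lapply(thresholds, function(thr) {
    gated <- !is.na(ratio) & ratio >= thr
    tr <- keep & !gated
    if (!any(tr)) return(NULL)
    ytr <- y[tr]
    if (length(unique(ytr)) < 2) {
      beta <- c("(intercept)" = if (mean(ytr) > 0.5) 50 else -50,
                setNames(numeric(ncol(X)), colnames(X)))
      degenerate <- TRUE
    } else {
      beta <- ridge_logit(X[tr, , drop = FALSE], ytr, lambda)
      degenerate <- FALSE
    }
    pred_pos <- !gated & logit_predict(beta, X) >= cutoff
    acc <- mean(pred_pos[keep] == (y[keep] == 1)) * 100
    list(threshold = thr, beta = beta, accuracy = acc,
         degenerate = degenerate, n_gated = sum(gated & keep))
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("no candidate threshold leaves any drug for step 2")
  fits <- fits[ok]
  accs <- vapply(fits, `[[`, numeric(1), "accuracy")
  best <- fits[[which.max(accs)]]  # which.max takes the first (smallest) tie
  structure(
    list(ratio_threshold = best$threshold, beta = best$beta,
         features = features, include_trapping = include_trapping,
         cutoff = cutoff, lambda = lambda,
         training_accuracy = best$accuracy,
         candidates = tibble::tibble(
           threshold = vapply(fits, `[[`, numeric(1), "threshold"),
           accuracy = accs,
           n_gated = vapply(fits, `[[`, numeric(1), "n_gated"))),
    class = "twostep_model")
}

#' @export
print.twostep_model <- function(x, ...) {
  cat(sprintf("<twostep_model> hERG-ratio threshold %g, step-2 features: %s\n",
              x$ratio_threshold,
              paste(names(x$beta)[-1], collapse = ", ")))
  cat(sprintf("  training accuracy %.1f%%\n", x$training_accuracy))
  invisible(x)
}

#' Predict TdP risk with a fitted two-step model
#'
#' @param object A `twostep_model`.
#' @param panel A `drug_panel`.
#' @param ... Unused.
#' @return Factor of predictions (levels `TdP-`, `TdP+`), named by drug.
#' @export
predict.twostep_model <- function(object, panel, ...) {
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  X <- direct_features(panel, object$features, "ic60",
                       object$include_trapping)
  p <- logit_predict(object$beta, X)
  pos <- p >= object$cutoff
  pos[!is.na(ratio) & ratio >= object$ratio_threshold] <- FALSE
  out <- factor(ifelse(pos, "TdP+", "TdP-"), levels = c("TdP-", "TdP+"))
  names(out) <- panel$name
  out
}

#' Fit the one-step baseline classifier
#'
#' A plain logistic regression on channel-block features evaluated at each
#' drug's EFTPC; no hERG-ratio gate. Drugs without an EFTPC are dropped
#' with a warning.
#'
#' @inheritParams fit_two_step
#' @return An object of class `onestep_model`.
#' @export
fit_one_step <- function(panel, labels, features = c("IKr", "ICaV"),
                         include_trapping = FALSE, lambda = 1e-6,
                         cutoff = 0.5) {
  lab <- factor(labels, levels = c("TdP-", "TdP+"))
  X <- direct_features(panel, features, "eftpc", include_trapping)
  keep <- !is.na(lab) & !apply(X, 1, anyNA)
  if (sum(keep) < 4) stop("need at least 4 labeled drugs with EFTPC")
  if (any(!is.na(lab) & !keep))
    warning("drug(s) without EFTPC dropped from one-step fit: ",
            paste(panel$name[!is.na(lab) & !keep], collapse = ", "),
            call. = FALSE)
  y <- as.integer(lab[keep] == "TdP+")
  beta <- if (length(unique(y)) < 2)
    c("(intercept)" = if (mean(y) > 0.5) 50 else -50,
      setNames(numeric(ncol(X)), colnames(X)))
  else ridge_logit(X[keep, , drop = FALSE], y, lambda)
  pred <- logit_predict(beta, X[keep, , drop = FALSE]) >= cutoff
  structure(
    list(beta = beta, features = features,
         include_trapping = include_trapping, cutoff = cutoff,
         lambda = lambda, training_accuracy = 100 * mean(pred == (y == 1))),
    class = "onestep_model")
}

#' @export
print.onestep_model <- function(x, ...) {
  cat(sprintf("<onestep_model> features at EFTPC: %s; training accuracy %.1f%%\n",
              paste(names(x$beta)[-1], collapse = ", "), x$training_accuracy))
  invisible(x)
}

#' @export
predict.onestep_model <- function(object, panel, ...) {
  X <- direct_features(panel, object$features, "eftpc",
                       object$include_trapping)
  p <- logit_predict(object$beta, X)
  out <- factor(ifelse(!is.na(p) & p >= object$cutoff, "TdP+", "TdP-"),
                levels = c("TdP-", "TdP+"))
  out[apply(X, 1, anyNA)] <- NA
  names(out) <- panel$name
  out
}

#' Leave-one-out accuracy of a classifier
#'
#' Refits the full procedure on n-1 drugs (for the two-step classifier this
#' includes re-selecting the ratio threshold inside each fold) and predicts
#' the held-out drug. Folds where the training set degenerates to one class
#' are scored with the majority-class prediction.
#'
#' @param panel A `drug_panel`.
#' @param labels Labels as for [fit_two_step()]; `NA`-labeled drugs are
#'   excluded.
#' @param method `"two_step"` or `"one_step"`, or a custom list with
#'   elements `fit(panel, labels)` and `predict(model, panel)`.
#' @param ... Passed to the fitting function.
#' @return Percent of held-out drugs predicted correctly.
#' @export
loo_accuracy <- function(panel, labels, method = "two_step", ...) {
  lab <- factor(labels, levels = c("TdP-", "TdP+"))
  idx <- which(!is.na(lab))
  if (length(idx) < 3) stop("need at least 3 labeled drugs for LOO")
  if (is.character(method)) {
    method <- match.arg(method, c("two_step", "one_step"))
    fit_fun <- switch(method,
      two_step = function(p, l) fit_two_step(p, l, ...),
      one_step = function(p, l) fit_one_step(p, l, ...))
    predict_fun <- function(m, p) predict(m, p)
  } else {
    fit_fun <- method$fit
    predict_fun <- method$predict
  }
  correct <- logical(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    tr <- setdiff(idx, i)
    ptr <- panel[tr, ]
    pred <- tryCatch({
      m <- suppressWarnings(fit_fun(ptr, lab[tr]))
      suppressWarnings(predict_fun(m, panel[i, , drop = FALSE]))[1]
    }, error = function(e) {
      # degenerate fold: majority-class prediction
      levels(lab)[which.max(tabulate(lab[tr], 2))]
    })
    correct[k] <- as.character(pred) == as.character(lab[i])
  }
  100 * mean(correct)
}

#' Fit the equal-weight ternary (three-class) risk model
#'
#' For three-class CiPA-style labels (CP1 high, CP2 intermediate, CP3 low)
#' the features are collapsed into an equal-weight sum (percent ICaV block +
#' percent INaL block + drug-trapping scalar, by default); a logistic fit of
#' "high vs rest" and one of "low vs rest" on the feature sum give two
#' boundaries -beta0/beta_f along the feature-sum axis. Together with two
#' fixed hERG-ratio thresholds on the x-axis (25 separating high-risk, 150
#' separating low-risk) they partition the risk plane.
#'
#' Prediction: ratio >= `x_thresholds[2]` or feature sum above the low
#' boundary -> low; otherwise ratio < `x_thresholds[1]` and feature sum
#' below the high boundary -> high; otherwise intermediate.
#'
#' @param panel A `drug_panel` with `cipa` labels (or supply `labels`).
#' @param labels Optional factor with levels `high`, `intermediate`, `low`;
#'   defaults to mapping CP1/CP2/CP3.
#' @param features Channels entering the feature sum (default ICaV + INaL).
#' @param include_trapping Include the trapping scalar (default TRUE;
#'   missing values count 0).
#' @param x_thresholds The two hERG-ratio thresholds (default 25 and 150).
#' @param lambda Ridge strength.
#' @return An object of class `ternary_model`.
#' @export
fit_ternary <- function(panel, labels = NULL,
                        features = c("ICaV", "INaL"),
                        include_trapping = TRUE,
                        x_thresholds = c(25, 150), lambda = 1e-6) {
  if (is.null(labels)) {
    labels <- factor(c(CP1 = "high", CP2 = "intermediate", CP3 = "low")[panel$cipa],
                     levels = c("high", "intermediate", "low"))
  } else {
    labels <- factor(labels, levels = c("high", "intermediate", "low"))
  }
  keep <- !is.na(labels)
  if (length(unique(labels[keep])) < 2)
    stop("need at least 2 risk classes to fit the ternary model")
  X <- direct_features(panel, features, "ic60", include_trapping)
  fsum <- rowSums(X)
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  # the feature-sum boundaries describe drugs below the low-risk ratio
  # gate; drugs already called low by the gate would only blur them
  keep <- keep & !is.na(ratio) & ratio < x_thresholds[2]
  boundary <- function(pos) {
    y <- as.integer(pos[keep])
    if (length(unique(y)) < 2) return(NA_real_)
    b <- ridge_logit(matrix(fsum[keep], ncol = 1,
                            dimnames = list(NULL, "feature_sum")), y, lambda)
    unname(-b[1] / b[2])
  }
  y_high <- boundary(labels == "high")
  y_low <- boundary(labels == "low")
  structure(
    list(features = features, include_trapping = include_trapping,
         x_thresholds = x_thresholds,
         y_high = y_high, y_low = y_low),
    class = "ternary_model")
}

#' @export
print.ternary_model <- function(x, ...) {
  cat(sprintf(
    "<ternary_model> feature sum: %s%s; x thresholds %g/%g; y boundaries high %.1f, low %.1f\n",
    paste(x$features, collapse = " + "),
    if (x$include_trapping) " + trapping" else "",
    x$x_thresholds[1], x$x_thresholds[2], x$y_high, x$y_low))
  invisible(x)
}

#' @export
predict.ternary_model <- function(object, panel, ...) {
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  X <- direct_features(panel, object$features, "ic60",
                       object$include_trapping)
  fsum <- rowSums(X)
  out <- rep("intermediate", nrow(panel))
  is_low <- (!is.na(ratio) & ratio >= object$x_thresholds[2]) |
    (!is.na(object$y_low) & fsum >= object$y_low)
  is_high <- !is_low & !is.na(ratio) & ratio < object$x_thresholds[1] &
    !is.na(object$y_high) & fsum < object$y_high
  out[is_low] <- "low"
  out[is_high] <- "high"
  out <- factor(out, levels = c("high", "intermediate", "low"))
  names(out) <- panel$name
  out
}
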