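# Derived-feature study orchestration: simulate every drug at a stated
# concentration rule across 3 cell types x 3 pacing rates, extract the 13
# AP/Ca biomarkers, and evaluate per-feature LOO classification accuracy.

#' Simulate the biomarker tensor for a panel
#'
#' For each drug, evaluates its multi-channel block profile at the chosen
#' concentration rule (`IC60,hERG` or EFTPC), paces the model to a
#' fixed-count steady state at each of three cycle lengths (2000, 1000, 500
#' ms, i.e. 0.5/1/2 Hz) in each cell type (endo, mid, epi), and extracts
#' the 13 biomarkers from the final beat — 9 simulations per drug. Results
#' are memoised per session keyed on the full simulation inputs, so reruns
#' only simulate what changed. Per-job failures are recorded as `NA`
#' biomarkers with `status = "failed"`.
#'
#' Steady-state biomarker runs default to the fast Rush-Larsen integrator;
#' EAD decisions elsewhere always use fixed-step Euler.
#'
#' @param panel A `drug_panel`.
#' @param conc_rule `"ic60"` or `"eftpc"`.
#' @param variant Model variant (default `"OHR"`).
#' @param channels Channels whose block is applied (default
#'   `c("IKr", "ICaV")`; use [channel_names()] for all).
#' @param cell_types,cycle_lengths Simulation axes.
#' @param n_beats Beats to steady state (default 1000; reduce for quick
#'   exploration).
#' @param config Integrator configuration.
#' @return A `biomarker_tensor`: 4-d array drug x cell_type x rate x metric,
#'   with a `jobs` attribute tibble recording per-job status.
#' @export
run_manifest <- function(panel, conc_rule = c("ic60", "eftpc"),
                         variant = "OHR", channels = c("IKr", "ICaV"),
                         cell_types = c("endo", "mid", "epi"),
                         cycle_lengths = c(2000, 1000, 500),
                         n_beats = 1000,
                         config = integrator_config("hybrid_rapid")) {
  conc_rule <- match.arg(conc_rule)
  metrics <- biomarker_names()
  dims <- list(drug = panel$name, cell_type = cell_types,
               cycle_length = as.character(cycle_lengths), metric = metrics)
  tensor <- array(NA_real_, unname(lengths(dims)), dimnames = dims)
  jobs <- tidyr::expand_grid(drug = panel$name, cell_type = cell_types,
                             cycle_length = cycle_lengths)
  jobs$status <- "ok"
  for (j in seq_len(nrow(jobs))) {
    drug <- panel[panel$name == jobs$drug[j], ]
    conc <- switch(conc_rule, ic60 = ic60_herg(drug), eftpc = drug$eftpc)
    if (is.na(conc)) { jobs$status[j] <- "no_concentration"; next }
    bp <- block_profile(drug, conc)
    blk <- bp$block[channels]
    key <- rlang::hash(list("manifest", variant, jobs$cell_type[j],
                            jobs$cycle_length[j], n_beats, round(blk, 10),
                            config$method, config$dt))
    bm <- the$biomarker_cache[[key]]
    if (is.null(bm)) {
      bm <- tryCatch({
        spec <- cell_spec(variant, jobs$cell_type[j],
                          scaling = scale_conductances(blk))
        tr <- pace_to_steady(spec, jobs$cycle_length[j], n_beats, config,
                             cache = FALSE)
        compute_biomarkers(tr)
      }, error = function(e) NULL)
      the$biomarker_cache[[key]] <- if (is.null(bm)) "failed" else bm
    }
    if (identical(bm, "failed") || is.null(bm)) {
      jobs$status[j] <- "failed"
      next
    }
    tensor[jobs$drug[j], jobs$cell_type[j],
           as.character(jobs$cycle_length[j]), ] <-
      unlist(bm[1, metrics])
  }
  structure(tensor, class = "biomarker_tensor", jobs = jobs,
            conc_rule = conc_rule, variant = variant, channels = channels)
}

#' Per-feature LOO accuracy over cell types and pacing rates
#'
#' For each derived feature and each (cell type, pacing rate) combination,
#' fits a single-feature classifier and reports its leave-one-out accuracy
#' — the heat-map summary of which biomarkers discriminate the target. At
#' the `ic60` concentration rule the classifier is the two-step model
#' (hERG-ratio gate plus logistic step 2 on the feature); at `eftpc` it is
#' the plain one-step logistic fit. The target may be the TdP labels or
#' EAD+/EAD- calls from [classify_by_ead()].
#'
#' Constant feature columns score the majority-class rate and are flagged.
#'
#' @param tensor A `biomarker_tensor` from [run_manifest()].
#' @param panel The `drug_panel` the tensor was built from.
#' @param labels Factor of targets (`TdP-`/`TdP+` or `EAD-`/`EAD+`).
#' @param lambda Ridge strength for the logistic fits.
#' @return A tibble: `metric`, `cell_type`, `cycle_length`, `accuracy`,
#'   `constant`.
#' @export
feature_accuracy_heatmap <- function(tensor, panel, labels, lambda = 1e-6) {
  stopifnot(inherits(tensor, "biomarker_tensor"))
  lab <- factor(labels)
  if (nlevels(lab) != 2) stop("labels must be binary")
  lab <- factor(c("TdP-", "TdP+")[as.integer(lab)], c("TdP-", "TdP+"))
  conc_rule <- attr(tensor, "conc_rule")
  dn <- dimnames(tensor)
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  out <- tidyr::expand_grid(metric = dn$metric, cell_type = dn$cell_type,
                            cycle_length = dn$cycle_length)
  out$accuracy <- NA_real_
  out$constant <- FALSE
  for (r in seq_len(nrow(out))) {
    x <- tensor[panel$name, out$cell_type[r], out$cycle_length[r],
                out$metric[r]]
    keep <- !is.na(lab) & !is.na(x)
    if (sum(keep) < 3) next
    if (stats::sd(x[keep]) < 1e-12) {
      out$constant[r] <- TRUE
      out$accuracy[r] <- 100 * max(table(lab[keep])) / sum(keep)
      next
    }
    method <- list(
      fit = local({
        xx <- x; rr <- ratio
        function(p, l) {
          i <- match(p$name, panel$name)
          Xf <- matrix(xx[i], ncol = 1, dimnames = list(p$name, "feature"))
          y <- as.integer(l == "TdP+")
          if (conc_rule == "ic60") {
            fits <- lapply(c(50, 100, 150, 200), function(thr) {
              gated <- !is.na(rr[i]) & rr[i] >= thr
              if (!any(!gated)) return(NULL)
              ytr <- y[!gated]
              beta <- if (length(unique(ytr)) < 2)
                c(if (mean(ytr) > 0.5) 50 else -50, 0)
              else ridge_logit(Xf[!gated, , drop = FALSE], ytr, lambda)
              pred <- !gated & logit_predict(beta, Xf) >= 0.5
              list(thr = thr, beta = beta, acc = mean(pred == (y == 1)))
            })
            fits <- fits[!vapply(fits, is.null, logical(1))]
            best <- fits[[which.max(vapply(fits, `[[`, numeric(1), "acc"))]]
            list(kind = "two", thr = best$thr, beta = best$beta)
          } else {
            beta <- if (length(unique(y)) < 2)
              c(if (mean(y) > 0.5) 50 else -50, 0)
            else ridge_logit(Xf, y, lambda)
            list(kind = "one", beta = beta)
          }
        }
      }),
      predict = local({
        xx <- x; rr <- ratio
        function(m, p) {
          i <- match(p$name, panel$name)
          Xf <- matrix(xx[i], ncol = 1)
          pos <- logit_predict(m$beta, Xf) >= 0.5
          if (m$kind == "two") pos[!is.na(rr[i]) & rr[i] >= m$thr] <- FALSE
          factor(ifelse(pos, "TdP+", "TdP-"), c("TdP-", "TdP+"))
        }
      }))
    out$accuracy[r] <- tryCatch(
      loo_accuracy(panel[keep, ], lab[keep], method),
      error = function(e) NA_real_)
  }
  out
}
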