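# Two-dimensional TdP risk maps: the fitted two-step classifier rewritten
# as thresholds on a plane with the hERG safety ratio on x and a normalized
# feature combination (ICaV-block-scaled) on y.

#' Build a 2D risk-map specification from a fitted model
#'
#' For a [fit_two_step()] model whose step-2 hyperplane is
#' `b0 + b_ICaV * blockICaV + sum(b_i * f_i) = 0`, the coefficients are
#' normalized to `b_ICaV`, so the y-axis is
#' `blockICaV + sum(b_i / b_ICaV * f_i)` and the y-threshold is
#' `-b0 / b_ICaV`; the x-threshold is the model's selected hERG-ratio
#' threshold. Region classification on the map is algebraically identical
#' to the model's predictions. For a [fit_ternary()] model the y-axis is
#' the equal-weight feature sum with its two fitted boundaries and the two
#' fixed ratio thresholds.
#'
#' @param model A `twostep_model` or `ternary_model`.
#' @return A `risk_map_spec`.
#' @export
build_risk_map <- function(model) {
  if (inherits(model, "ternary_model")) {
    return(structure(
      list(kind = "ternary",
           x_threshold = model$x_thresholds[1],
           x_threshold2 = model$x_thresholds[2],
           y_threshold = model$y_high, y_threshold2 = model$y_low,
           y_definition = tibble::tibble(
             feature = c(paste0("block_", model$features),
                         if (model$include_trapping) "trapping"),
             coefficient = 1),
           model = model),
      class = "risk_map_spec"))
  }
  stopifnot(inherits(model, "twostep_model"))
  beta <- model$beta
  fn <- names(beta)[-1]
  if (!"block_ICaV" %in% fn)
    stop("risk map requires an ICaV-block feature in step 2")
  b_cav <- beta[["block_ICaV"]]
  if (b_cav == 0) {
    warning("ICaV coefficient is zero; map built on raw coefficients",
            call. = FALSE)
    b_cav <- 1
  }
  coefs <- beta[-1] / b_cav
  structure(
    list(kind = "binary",
         x_threshold = model$ratio_threshold,
         y_threshold = -beta[[1]] / b_cav,
         # sign of b_ICaV decides which side of the y-threshold is high-risk
         high_risk_below = b_cav < 0,
         y_definition = tibble::tibble(feature = names(coefs),
                                       coefficient = unname(coefs)),
         model = model),
    class = "risk_map_spec")
}

#' @export
print.risk_map_spec <- function(x, ...) {
  ydef <- paste(sprintf("%+.3g*%s", x$y_definition$coefficient,
                        x$y_definition$feature), collapse = " ")
  if (x$kind == "binary") {
    cat(sprintf("<risk_map_spec> x: hERG ratio (threshold %g); y: %s (threshold %.2f)\n",
                x$x_threshold, ydef, x$y_threshold))
  } else {
    cat(sprintf("<risk_map_spec> ternary; x thresholds %g/%g; y: %s; y boundaries %.2f/%.2f\n",
                x$x_threshold, x$x_threshold2, ydef,
                x$y_threshold, x$y_threshold2))
  }
  invisible(x)
}

#' Map coordinates and region labels for a panel
#'
#' Computes each drug's (x, y) position on the risk map and its region
#' label. For binary maps the region assignment reproduces the generating
#' model's predictions exactly.
#'
#' @param spec A `risk_map_spec`.
#' @param panel A `drug_panel`.
#' @param labels Optional labels to carry along (factor).
#' @return A tibble: `name`, `x` (hERG ratio), `y`, `region`, `label`.
#' @export
risk_map_coords <- function(spec, panel, labels = NULL) {
  ratio <- vapply(seq_len(nrow(panel)), function(i) herg_ratio(panel[i, ]),
                  numeric(1))
  model <- spec$model
  X <- direct_features(panel,
                       model$features, "ic60",
                       model$include_trapping)
  y <- drop(as.matrix(X)[, spec$y_definition$feature, drop = FALSE] %*%
              spec$y_definition$coefficient)
  if (spec$kind == "binary") {
    pred <- as.character(predict(model, panel))
    region <- ifelse(pred == "TdP+", "high", "low")
  } else {
    region <- as.character(predict(model, panel))
  }
  tibble::tibble(
    name = panel$name, x = ratio, y = y, region = region,
    label = if (is.null(labels)) NA_character_ else as.character(labels))
}

#' Plot a 2D TdP risk map
#'
#' hERG ratio (log scale) on x, normalized feature combination on y;
#' high-risk region in red, low-risk in green (intermediate in yellow for
#' ternary maps); drugs drawn as points colored by their observed label.
#' Optionally overlays the EAD suppression boundary (e.g. 30% ICaV block)
#' as a blue rectangle outline. The coordinates table (from
#' [risk_map_coords()]) is returned alongside the plot so the geometry is
#' testable without rendering.
#'
#' @param spec A `risk_map_spec`.
#' @param panel A `drug_panel` (may be empty).
#' @param labels Optional observed labels for coloring.
#' @param ead_boundary Optional ICaV-block percent of the EAD suppression
#'   boundary to outline.
#' @param xlim x-axis range for the ratio (default `c(0.1, 1e4)`).
#' @return A list with elements `plot` (ggplot) and `coords` (tibble).
#' @export
plot_risk_map <- function(spec, panel, labels = NULL, ead_boundary = NULL,
                          xlim = c(0.1, 1e4)) {
  coords <- risk_map_coords(spec, panel, labels)
  if (any(is.na(coords$x) & !is.na(coords$y)))
    warning("drug(s) without hERG ratio plotted at the x-axis edge",
            call. = FALSE)
  ymax <- max(c(coords$y, 100), na.rm = TRUE)
  xt <- spec$x_threshold
  regions <- if (spec$kind == "binary") {
    hb <- spec$high_risk_below
    tibble::tibble(
      xmin = c(xlim[1], xlim[1], xt),
      xmax = c(xt, xt, xlim[2]),
      ymin = c(if (hb) -Inf else spec$y_threshold,
               if (hb) spec$y_threshold else -Inf,
               -Inf),
      ymax = c(if (hb) spec$y_threshold else Inf,
               if (hb) Inf else spec$y_threshold,
               Inf),
      risk = c("high", "low", "low"))
  } else {
    xt2 <- spec$x_threshold2
    tibble::tibble(
      xmin = c(xlim[1], xlim[1], xlim[1], xt, xt2),
      xmax = c(xt, xt, xt2, xt2, xlim[2]),
      ymin = c(-Inf, spec$y_threshold, -Inf, -Inf, -Inf),
      ymax = c(spec$y_threshold, Inf, spec$y_threshold2, Inf, Inf),
      risk = c("high", "intermediate", "intermediate", "intermediate", "low"))
  }
  fill <- c(high = "#f4cccc", intermediate = "#fff2cc", low = "#d9ead3")
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$risk), alpha = 0.8) +
    ggplot2::scale_fill_manual(values = fill, name = "region") +
    ggplot2::scale_x_log10(limits = xlim) +
    ggplot2::labs(x = "hERG ratio (IC60,hERG / EFTPC)",
                  y = paste(sprintf("%+.2g %s", spec$y_definition$coefficient,
                                    sub("block_", "% block ",
                                        spec$y_definition$feature)),
                            collapse = " "))
  if (!is.null(ead_boundary)) {
    p <- p + ggplot2::annotate("rect", xmin = xlim[1], xmax = xt,
                               ymin = -Inf, ymax = ead_boundary,
                               colour = "blue", fill = NA, linewidth = 0.8)
  }
  if (nrow(coords)) {
    pts <- coords[!is.na(coords$x), ]
    p <- p + ggplot2::geom_point(
      data = pts,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label),
      size = 2) +
      ggplot2::scale_colour_manual(
        values = c("TdP+" = "red", "TdP-" = "darkgreen",
                   high = "red", intermediate = "orange", low = "darkgreen"),
        na.value = "grey40", name = "observed")
  }
  list(plot = p, coords = coords)
}
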