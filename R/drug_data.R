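# Drug panel data model: readers/writers for delimited assay tables,
# risk-label binarization, panel merging, label overrides, and a synthetic
# panel generator with a known generative risk rule.

label_levels <- list(
  redfern = paste0("R", 1:5),
  crediblemeds = paste0("CM", 1:3),
  champeroux = paste0("CH", 1:3),
  cipa = paste0("CP", 1:3))

panel_columns <- function() {
  ch <- channel_names()
  c("name",
    paste0("ic50_", ch), paste0("hill_", ch),
    "eftpc", "redfern", "crediblemeds", "champeroux", "cipa",
    "label_warning", "trapping")
}

#' Construct a drug panel
#'
#' A drug panel is a tibble with one row per drug: per-channel IC50 and Hill
#' columns (`ic50_<channel>`, `hill_<channel>`, concentrations in nM),
#' `eftpc` (nM), risk-label columns (`redfern` R1-R5, `crediblemeds`
#' CM1-CM3, `champeroux` CH1-CH3, `cipa` CP1-CP3, logical `label_warning`)
#' and an optional `trapping` scalar (open-bound/closed-bound hERG occupancy
#' ratio). Missing assays are `NA` and are treated as zero block
#' downstream; missing Hill coefficients default to 1 at evaluation time.
#'
#' @param drugs A data frame with at least `name`; unknown columns are
#'   dropped, missing ones filled with `NA`.
#' @param source Character tag describing provenance.
#' @return A `drug_panel` tibble (concentrations in nM).
#' @export
drug_panel <- function(drugs, source = "user") {
  drugs <- tibble::as_tibble(drugs)
  if (!"name" %in% names(drugs)) stop("panel must have a 'name' column")
  for (col in panel_columns()) {
    if (!col %in% names(drugs)) {
      drugs[[col]] <- if (col == "label_warning") NA else NA_real_
    }
  }
  drugs <- drugs[panel_columns()]
  drugs$name <- as.character(drugs$name)
  if (anyDuplicated(tolower(drugs$name)))
    stop("drug names must be unique within a panel (case-insensitive)")
  for (lab in names(label_levels)) {
    drugs[[lab]] <- as.character(drugs[[lab]])
    bad <- !is.na(drugs[[lab]]) & !drugs[[lab]] %in% label_levels[[lab]]
    if (any(bad))
      stop(sprintf("invalid %s label(s): %s", lab,
                   paste(unique(drugs[[lab]][bad]), collapse = ", ")))
  }
  drugs$label_warning <- as.logical(drugs$label_warning)
  for (ch in channel_names()) {
    ic <- drugs[[paste0("ic50_", ch)]]
    bad <- which(!is.na(ic) & ic <= 0)
    if (length(bad))
      stop(sprintf("non-positive IC50 for %s in row(s) %s", ch,
                   paste(bad, collapse = ", ")))
  }
  bad <- which(!is.na(drugs$eftpc) & drugs$eftpc <= 0)
  if (length(bad))
    stop(sprintf("non-positive EFTPC in row(s) %s", paste(bad, collapse = ", ")))
  structure(drugs, class = c("drug_panel", class(drugs)),
            source = source, concentration_unit = "nM")
}

unit_factor <- function(unit) {
  switch(tolower(unit),
         nm = 1, "nM" = 1,
         um = 1e3, "uM" = 1e3, "µm" = 1e3,
         mm = 1e6,
         m = 1e9,
         stop("unknown concentration unit: ", unit))
}

#' Read a drug panel from delimited text
#'
#' Reads a CSV/TSV assay table. Column naming and units are controlled by a
#' schema: a list (or YAML file path) with elements `name`, `eftpc`,
#' `channels` (per-channel list with `ic50` and optional `hill` column
#' names), `labels` (mapping for label columns), `trapping`, and `units`
#' (per-field unit, `"nM"` or `"uM"`; default nM). Without a schema,
#' columns are expected to follow the internal naming
#' (`ic50_IKr`, `hill_IKr`, ..., `eftpc`, `redfern`, ...) in nM.
#'
#' A drug-name column and an IKr IC50 column are mandatory; other channels
#' are optional and, when absent, the channel is treated as unblocked
#' everywhere (recorded in the provenance attribute `assumed_zero`).
#'
#' @param path Delimited text file with a header row.
#' @param schema Optional schema list or path to a YAML schema file.
#' @param source Provenance tag (defaults to the file name).
#' @return A `drug_panel`.
#' @export
read_panel <- function(path, schema = NULL, source = basename(path)) {
  if (is.character(schema)) schema <- yaml::read_yaml(schema)
  delim <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    return(drug_panel(tibble::tibble(name = character()), source = source))
  }
  units <- schema$units %||% list()
  ufac <- function(field) unit_factor(units[[field]] %||% "nM")
  name_col <- schema$name %||% if ("name" %in% names(raw)) "name" else "drug"
  if (!name_col %in% names(raw))
    stop("format error: no drug-name column ('", name_col, "')")
  out <- tibble::tibble(name = as.character(raw[[name_col]]))
  get_col <- function(col) if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  chspec <- schema$channels
  for (ch in channel_names()) {
    ic_col <- if (is.null(chspec)) paste0("ic50_", ch) else chspec[[ch]]$ic50
    hl_col <- if (is.null(chspec)) paste0("hill_", ch) else chspec[[ch]]$hill
    ic <- get_col(ic_col)
    out[[paste0("ic50_", ch)]] <- if (is.null(ic)) NA_real_ else
      as.numeric(ic) * ufac(ch)
    hl <- get_col(hl_col)
    out[[paste0("hill_", ch)]] <- if (is.null(hl)) NA_real_ else as.numeric(hl)
  }
  if (all(is.na(out$ic50_IKr)) && is.null(get_col(
        if (is.null(chspec)) "ic50_IKr" else chspec$IKr$ic50)))
    stop("format error: no IKr IC50 column")
  ef <- get_col(schema$eftpc %||% "eftpc")
  out$eftpc <- if (is.null(ef)) NA_real_ else as.numeric(ef) * ufac("eftpc")
  labmap <- schema$labels %||% list()
  for (lab in names(label_levels)) {
    cl <- get_col(labmap[[lab]] %||% lab)
    out[[lab]] <- if (is.null(cl)) NA_character_ else as.character(cl)
  }
  lw <- get_col(labmap$label_warning %||% "label_warning")
  out$label_warning <- if (is.null(lw)) NA else as.logical(lw)
  tr <- get_col(schema$trapping %||% "trapping")
  out$trapping <- if (is.null(tr)) NA_real_ else as.numeric(tr)
  drug_panel(out, source = source)
}

#' Write a normalized panel, with a JSON provenance sidecar
#'
#' @param panel A `drug_panel`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` listing assumed-zero channels per drug
#'   (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path, sidecar = TRUE) {
  readr::write_csv(tibble::as_tibble(panel), path, na = "")
  if (sidecar) {
    az <- lapply(seq_len(nrow(panel)), function(i) {
      chs <- channel_names()
      chs[vapply(chs, function(ch) is.na(panel[[paste0("ic50_", ch)]][i]),
                 logical(1))]
    })
    names(az) <- panel$name
    jsonlite::write_json(
      list(source = attr(panel, "source"),
           concentration_unit = "nM",
           assumed_zero_channels = az),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Binarize risk labels into TdP+/TdP-
#'
#' Deterministic label definitions:
#' * `target1`: TdP+ if Redfern R1-R3, CredibleMeds CM1, Champeroux CH1, or
#'   a TdP warning on the package label; usable for any drug with at least
#'   one of those fields populated.
#' * `target2`: TdP+ if CM1 or CM2; `target3`: TdP+ if CM1; `target4`: TdP+
#'   if CM1 or CM3 (all three require a CredibleMeds label).
#' * `cipa`: CP1 and CP2 are TdP+, CP3 TdP-.
#'
#' Drugs with no usable label under the chosen definition get `NA` and a
#' warning; they are excluded from training downstream.
#'
#' @param panel A `drug_panel`.
#' @param definition One of `"target1"`..`"target4"`, `"cipa"`.
#' @return A factor vector (levels `TdP-`, `TdP+`), named by drug, `NA`
#'   where unlabeled.
#' @export
binarize_labels <- function(panel,
                            definition = c("target1", "target2", "target3",
                                           "target4", "cipa")) {
  definition <- match.arg(definition)
  rf <- panel$redfern; cm <- panel$crediblemeds; ch <- panel$champeroux
  cp <- panel$cipa; lw <- panel$label_warning
  usable <- switch(definition,
    target1 = !is.na(rf) | !is.na(cm) | !is.na(ch) | !is.na(lw),
    target2 = , target3 = , target4 = !is.na(cm),
    cipa = !is.na(cp))
  pos <- switch(definition,
    target1 = (!is.na(rf) & rf %in% c("R1", "R2", "R3")) |
              (!is.na(cm) & cm == "CM1") |
              (!is.na(ch) & ch == "CH1") |
              (!is.na(lw) & lw),
    target2 = !is.na(cm) & cm %in% c("CM1", "CM2"),
    target3 = !is.na(cm) & cm == "CM1",
    target4 = !is.na(cm) & cm %in% c("CM1", "CM3"),
    cipa = !is.na(cp) & cp %in% c("CP1", "CP2"))
  out <- factor(ifelse(usable, ifelse(pos, "TdP+", "TdP-"), NA),
                levels = c("TdP-", "TdP+"))
  names(out) <- panel$name
  n_un <- sum(!usable)
  if (n_un > 0)
    warning(sprintf("%d drug(s) unlabeled under definition '%s': %s",
                    n_un, definition,
                    paste(panel$name[!usable], collapse = ", ")),
            call. = FALSE)
  out
}

highest_risk <- function(values, scheme) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_character_)
  values <- unique(values)
  if (length(values) > 1)
    warning(sprintf("conflicting %s labels (%s); keeping highest-risk",
                    scheme, paste(values, collapse = " vs ")), call. = FALSE)
  # lower index = higher risk in every scheme used here
  values[which.min(match(values, label_levels[[scheme]]))]
}

#' Merge drug panels
#'
#' Drugs are identified case-insensitively by name. For duplicated drugs the
#' per-channel IC50s, Hill coefficients, EFTPC and trapping are averaged
#' arithmetically on the concentration scale (ignoring missing values);
#' categorical labels are unioned, and conflicting labels within a scheme
#' resolve to the highest-risk category with a warning.
#'
#' @param panels A list of `drug_panel` objects (or a single panel).
#' @return A merged `drug_panel`; numeric results do not depend on the order
#'   of the input panels.
#' @export
merge_panels <- function(panels) {
  if (inherits(panels, "drug_panel")) panels <- list(panels)
  stopifnot(length(panels) >= 1)
  all <- dplyr::bind_rows(lapply(panels, tibble::as_tibble))
  all$.key <- tolower(all$name)
  num_cols <- setdiff(names(all)[vapply(all, is.numeric, logical(1))], ".key")
  merged <- lapply(split(all, all$.key), function(g) {
    out <- g[1, ]
    out$name <- g$name[1]
    for (col in num_cols) {
      v <- g[[col]]
      out[[col]] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    for (lab in names(label_levels)) out[[lab]] <- highest_risk(g[[lab]], lab)
    lw <- g$label_warning
    out$label_warning <- if (all(is.na(lw))) NA else any(lw, na.rm = TRUE)
    out$.key <- NULL
    out
  })
  merged <- dplyr::bind_rows(merged[order(names(merged))])
  drug_panel(merged,
             source = paste(vapply(panels, function(p)
               attr(p, "source") %||% "panel", character(1)), collapse = "+"))
}

#' Apply per-drug label overrides
#'
#' Overrides are supplied explicitly (a data frame or CSV path with a `name`
#' column plus any of the label columns), never hard-coded; non-missing
#' entries replace the panel's labels for matching drugs
#' (case-insensitive).
#'
#' @param panel A `drug_panel`.
#' @param overrides Data frame or CSV path.
#' @return The panel with overridden labels.
#' @export
apply_label_overrides <- function(panel, overrides) {
  if (is.character(overrides))
    overrides <- readr::read_csv(overrides, show_col_types = FALSE,
                                 progress = FALSE)
  overrides <- tibble::as_tibble(overrides)
  idx <- match(tolower(overrides$name), tolower(panel$name))
  for (lab in c(names(label_levels), "label_warning")) {
    if (!lab %in% names(overrides)) next
    v <- overrides[[lab]]
    keep <- !is.na(v) & !is.na(idx)
    panel[[lab]][idx[keep]] <- if (lab == "label_warning")
      as.logical(v[keep]) else as.character(v[keep])
  }
  drug_panel(tibble::as_tibble(panel), source = attr(panel, "source"))
}

#' Generate a synthetic drug panel with a known generative risk rule
#'
#' Draws hERG IC50s log-uniformly over 10 nM-100 uM, hERG ratios
#' (IC60,hERG / EFTPC) log-uniformly over 1-10^4, and the ICaV block at
#' IC60,hERG uniformly over 0-100%; ICaV IC50s are back-computed so the
#' block at IC60 equals the drawn value. The ground-truth label is TdP+ iff
#' `ratio < ratio_threshold` and `ICaV block at IC60 < cav_cutoff`,
#' optionally corrupted by label-flip noise. Labels are written as
#' CredibleMeds CM1 (TdP+) / CM3 (TdP-) plus a package-label warning flag,
#' so every binarization definition applies. The generative truth is
#' attached as attribute `truth`.
#'
#' @param n Number of drugs (>= 4).
#' @param ratio_threshold Generative hERG-ratio threshold, one of 50, 100,
#'   150, 200 (the classifier's candidate grid).
#' @param cav_cutoff Generative ICaV-block cutoff in percent, in (0, 100).
#' @param noise_sd Label-flip probability in `[0, 0.5)` (0 = perfectly
#'   separable in (ratio, ICaV-block) space).
#' @param margin Half-width, in percentage points of ICaV block, of an
#'   exclusion zone around `cav_cutoff` (default 2). Keeping the classes
#'   strictly separated by a margin makes the noise-free panel's perfect
#'   separability robust to leave-one-out refits of the decision boundary.
#' @param seed Integer seed; generation is reproducible.
#' @return A `drug_panel` with attribute `truth` (tibble: name, herg_ratio,
#'   cav_block_at_ic60, tdp_true, flipped).
#' @export
#' @examples
#' p <- generate_synthetic_panel(20, seed = 1)
#' attr(p, "truth")
generate_synthetic_panel <- function(n, ratio_threshold = 100,
                                     cav_cutoff = 30, noise_sd = 0,
                                     margin = 2, seed = 1) {
  if (n < 4) stop("n must be >= 4")
  if (!ratio_threshold %in% c(50, 100, 150, 200))
    stop("ratio_threshold must be one of 50, 100, 150, 200")
  if (cav_cutoff <= 0 || cav_cutoff >= 100)
    stop("cav_cutoff must lie in (0, 100)")
  if (noise_sd < 0 || noise_sd >= 0.5)
    stop("noise_sd must lie in [0, 0.5)")
  old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  ic50_ikr <- 10^runif(n, 1, 5)
  hill_ikr <- round(runif(n, 0.8, 1.6), 2)
  ic60 <- ic50_ikr * (0.6 / 0.4)^(1 / hill_ikr)
  ratio <- 10^runif(n, 0, 4)
  eftpc <- ic60 / ratio
  # uniform over [0, 100] minus the +/- margin zone around the cutoff
  margin <- min(margin, cav_cutoff / 2, (100 - cav_cutoff) / 2)
  u <- runif(n, 0, 100 - 2 * margin)
  cav_block <- ifelse(u < cav_cutoff - margin, u, u + 2 * margin)
  hill_cav <- rep(1, n)
  ic50_cav <- ic60 * (100 - cav_block) / cav_block
  nal_block <- runif(n, 0, 50)
  ic50_nal <- ic60 * (100 - nal_block) / nal_block
  tdp_true <- ratio < ratio_threshold & cav_block < cav_cutoff
  flip <- if (noise_sd > 0) runif(n) < noise_sd else rep(FALSE, n)
  tdp <- xor(tdp_true, flip)
  panel <- drug_panel(tibble::tibble(
    name = sprintf("SYN%03d", seq_len(n)),
    ic50_IKr = ic50_ikr, hill_IKr = hill_ikr,
    ic50_ICaV = ic50_cav, hill_ICaV = hill_cav,
    ic50_INaL = ic50_nal, hill_INaL = 1,
    eftpc = eftpc,
    crediblemeds = ifelse(tdp, "CM1", "CM3"),
    label_warning = tdp,
    trapping = round(runif(n, 0, 1), 3)), source = "synthetic")
  attr(panel, "truth") <- tibble::tibble(
    name = panel$name, herg_ratio = ratio, cav_block_at_ic60 = cav_block,
    tdp_true = tdp_true, flipped = flip)
  panel
}
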