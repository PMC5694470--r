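# Hill-equation dose-response arithmetic: fractional block, inverse
# concentration solving, per-drug block profiles and conductance scaling,
# and the hERG safety ratio used to gate the two-step classifier.

#' Fractional channel block at a drug concentration
#'
#' Hill-type concentration-inhibition curve:
#' block = 100 * c^h / (IC50^h + c^h), in percent. Evaluated in log space so
#' extreme concentration/IC50 ratios do not overflow.
#'
#' @param c Drug concentration(s) in nM (vectorised, `c >= 0`).
#' @param ic50 Half-maximal inhibitory concentration in nM (`> 0`).
#' @param hill Hill coefficient (`> 0`, default 1).
#' @return Percent block in `[0, 100]`.
#' @export
#' @examples
#' fractional_block(1000, ic50 = 1000)        # 50
#' fractional_block(1500, ic50 = 1000)        # 60
fractional_block <- function(c, ic50, hill = 1) {
  if (any(c < 0)) stop("concentration must be non-negative")
  if (ic50 <= 0 || hill <= 0) stop("ic50 and hill must be positive")
  out <- numeric(length(c))
  pos <- c > 0
  # 100 / (1 + (ic50/c)^h) computed via log for numerical range
  z <- hill * (log(ic50) - log(c[pos]))
  z <- pmin(pmax(z, -700), 700)
  out[pos] <- 100 / (1 + exp(z))
  out
}

#' Concentration producing a given fractional block
#'
#' Closed-form inverse of [fractional_block()]:
#' c = IC50 * (f / (1 - f))^(1/h).
#'
#' @param f Target block as a fraction in (0, 1) (e.g. 0.6 for 60%).
#' @param ic50 IC50 in nM.
#' @param hill Hill coefficient (default 1).
#' @return Concentration in nM.
#' @export
#' @examples
#' concentration_at_block(0.6, ic50 = 1000)   # 1500
concentration_at_block <- function(f, ic50, hill = 1) {
  if (any(f <= 0 | f >= 1)) stop("f must lie strictly in (0, 1)")
  if (ic50 <= 0 || hill <= 0) stop("ic50 and hill must be positive")
  ic50 * exp(log(f / (1 - f)) / hill)
}

drug_assay <- function(drug, channel) {
  ic50 <- drug[[paste0("ic50_", channel)]]
  hill <- drug[[paste0("hill_", channel)]]
  if (is.null(ic50) || is.na(ic50)) return(NULL)
  if (is.null(hill) || is.na(hill)) hill <- 1
  list(ic50 = ic50, hill = hill)
}

#' Concentration at 60% hERG block for a drug record
#'
#' @param drug One-row drug record (a row of a [drug_panel] tibble, or any
#'   list with `ic50_IKr` and optional `hill_IKr`).
#' @param f Block fraction (default 0.6).
#' @return Concentration in nM, or `NA` if the drug lacks an IKr assay.
#' @export
ic60_herg <- function(drug, f = 0.6) {
  a <- drug_assay(drug, "IKr")
  if (is.null(a)) return(NA_real_)
  concentration_at_block(f, a$ic50, a$hill)
}

#' hERG safety ratio
#'
#' The ratio IC60,hERG / EFTPC: how far the drug's effective free therapeutic
#' plasma concentration sits below the concentration that blocks 60% of the
#' hERG current. Large ratios indicate that the EAD-generating degree of hERG
#' block is never approached therapeutically.
#'
#' @param drug One-row drug record with `ic50_IKr`, optional `hill_IKr`, and
#'   `eftpc` (nM).
#' @return Dimensionless ratio, or `NA` if the IKr assay or EFTPC is missing.
#' @export
#' @examples
#' herg_ratio(list(ic50_IKr = 1000, hill_IKr = 1, eftpc = 10))  # 150
herg_ratio <- function(drug) {
  ic60 <- ic60_herg(drug)
  eftpc <- drug[["eftpc"]]
  if (is.na(ic60) || is.null(eftpc) || is.na(eftpc)) return(NA_real_)
  ic60 / eftpc
}

#' Per-channel block profile of a drug at a concentration
#'
#' Applies the Hill equation per channel assay. Channels without an assay are
#' reported as 0% block (assumed-zero policy) and listed in the
#' `assumed_zero` attribute.
#'
#' @param drug One-row drug record.
#' @param c Concentration in nM (`>= 0`).
#' @return An object of class `block_profile`: list with `concentration` and
#'   named `block` (percent per channel).
#' @export
block_profile <- function(drug, c) {
  stopifnot(length(c) == 1, c >= 0)
  block <- setNames(numeric(7), channel_names())
  assumed <- character()
  for (ch in channel_names()) {
    a <- drug_assay(drug, ch)
    if (is.null(a)) {
      assumed <- c(assumed, ch)
    } else {
      block[ch] <- fractional_block(c, a$ic50, a$hill)
    }
  }
  structure(list(concentration = c, block = block),
            class = "block_profile", assumed_zero = assumed)
}

#' @export
print.block_profile <- function(x, ...) {
  cat(sprintf("<block_profile> at %.4g nM\n", x$concentration))
  print(round(x$block, 2))
  invisible(x)
}

#' Conductance scaling from a block profile
#'
#' Converts percent block to the multiplicative conductance factor
#' g_drug = (1 - block/100) * g applied in the myocyte model. Channels
#' without an assay keep multiplier 1.
#'
#' @param profile A [block_profile()] (or a named numeric vector of percent
#'   block).
#' @return An object of class `conductance_scaling` with named `multiplier`.
#' @export
#' @examples
#' scale_conductances(c(IKr = 60))   # IKr multiplier 0.4
scale_conductances <- function(profile) {
  if (inherits(profile, "block_profile")) profile <- profile$block
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  if (!all(names(profile) %in% channel_names()))
    stop("unknown channel in block profile")
  if (any(profile < 0 | profile > 100)) stop("block must lie in [0, 100]")
  mult <- setNames(rep(1, 7), channel_names())
  mult[names(profile)] <- 1 - profile / 100
  structure(list(multiplier = mult), class = "conductance_scaling")
}
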