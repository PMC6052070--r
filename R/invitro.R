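# Wet-lab arithmetic: calcein-leakage normalization, ITC blank
# subtraction, binding-isotherm fitting, and the thermodynamic identities.

# gas constant, kJ/(mol K)
.RGAS <- 8.314462618e-3

#' Percentage of released calcein
#'
#' 100 * (F_t - F_contr) / (F_tot - F_contr), where F_contr is the
#' minimal (methanol) control and F_tot the maximal (Triton X-100)
#' control. The result is affine-invariant in the fluorescence scale and
#' may fall outside [0, 100] for noisy inputs; such values are reported
#' as-is and flagged in the \code{"outOfRange"} attribute.
#'
#' @param Ft fluorescence at the measurement (vectorized).
#' @param Fcontr minimal-control fluorescence.
#' @param Ftot maximal-control fluorescence (must differ from Fcontr).
#' @return leakage percentage(s)
#' @export
leakagePercent <- function(Ft, Fcontr, Ftot) {
  if (Ftot == Fcontr)
    stop("Ftot equals Fcontr: leakage normalization undefined")
  out <- 100 * (Ft - Fcontr) / (Ftot - Fcontr)
  attr(out, "outOfRange") <- out < 0 | out > 100
  out
}

#' Construct an ITC titration series
#'
#' @param volumes injection volumes, microliter (scalar recycled).
#' @param heats per-injection heats, microjoule.
#' @param cellConc saponin concentration in the cell, micromolar.
#' @param syringeConc lipid concentration in the syringe, millimolar.
#' @param cellVolume working cell volume, milliliter.
#' @param temperature Kelvin (default 299.15 K = 26 C).
#' @param meta metadata list.
#' @return a [TitrationSeries-class]
#' @export
titrationSeries <- function(heats, volumes = 10, cellConc = 20,
                            syringeConc = 5, cellVolume = 1.4565,
                            temperature = 299.15, meta = list()) {
  if (length(volumes) == 1) volumes <- rep(volumes, length(heats))
  new("TitrationSeries", volumes = as.numeric(volumes),
      heats = as.numeric(heats), cellConc = cellConc,
      syringeConc = syringeConc, cellVolume = cellVolume,
      temperature = temperature, meta = meta)
}

#' Subtract the two ITC blank titrations
#'
#' Corrected heats are raw minus (lipid-into-buffer blank) minus
#' (buffer-into-saponin blank), element-wise; all three series must share
#' the injection count and volumes.
#'
#' @param raw,blankLipidIntoBuffer,blankBufferIntoSaponin
#'   [TitrationSeries-class] objects.
#' @return the corrected [TitrationSeries-class]
#' @export
subtractBlanks <- function(raw, blankLipidIntoBuffer,
                           blankBufferIntoSaponin) {
  ns <- c(length(heats(raw)), length(heats(blankLipidIntoBuffer)),
          length(heats(blankBufferIntoSaponin)))
  if (length(unique(ns)) != 1)
    stop("series have mismatched injection counts: ",
         paste(ns, collapse = ", "))
  if (max(abs(injectionVolumes(raw) -
                injectionVolumes(blankLipidIntoBuffer))) > 1e-9 ||
      max(abs(injectionVolumes(raw) -
                injectionVolumes(blankBufferIntoSaponin))) > 1e-9)
    stop("series have mismatched injection volumes")
  out <- raw
  out@heats <- heats(raw) - heats(blankLipidIntoBuffer) -
    heats(blankBufferIntoSaponin)
  out@meta <- c(raw@meta, list(blanksSubtracted = TRUE))
  out
}

# Lipid concentration in the cell after each injection (mM), simple
# mixing dilution, and the diluted saponin amount (mol).
.itcGeometry <- function(series) {
  v <- cumsum(injectionVolumes(series))        # uL
  V0 <- series@cellVolume * 1000               # uL
  list(L = series@syringeConc * v / (V0 + v),  # mM lipid in cell
       nS = series@cellConc * 1e-6 * series@cellVolume * 1e-3)  # mol saponin
}

# Model heats (uJ) for binding constant K (1/mM) and enthalpy dH (kJ/mol).
.itcModelHeats <- function(series, K, dH,
                           model = c("partition", "one_site")) {
  model <- match.arg(model)
  g <- .itcGeometry(series)
  if (model == "partition") {
    # bound saponin fraction follows the lipid partition isotherm
    f <- K * g$L / (1 + K * g$L)
  } else {
    # stoichiometric 1:1 association in the (diluted) cell
    v <- cumsum(injectionVolumes(series))
    V0 <- series@cellVolume * 1000
    S <- series@cellConc / 1000 * V0 / (V0 + v)  # mM
    L <- g$L
    b <- K * (S + L) + 1
    C <- (b - sqrt(b^2 - 4 * K^2 * S * L)) / (2 * K)  # mM complex
    f <- C / S
  }
  dH * 1e9 * g$nS * diff(c(0, f))
}

#' Fit a binding isotherm to a corrected titration series
#'
#' Least-squares fit of the binding constant K and enthalpy dH to the
#' per-injection heats under the selected model, with per-injection
#' dilution bookkeeping. The default \code{"partition"} model treats the
#' incremental heat as proportional to the increment of the bound saponin
#' fraction K L / (1 + K L); \code{"one_site"} is a stoichiometric 1:1
#' association. K is fitted on a log scale (positivity); dG and TdS are
#' derived through [deriveThermodynamics()]. The fit diagnostics (residual
#' norm, parameter standard errors, convergence) live in the result's
#' \code{fit} slot.
#'
#' @param series a corrected [TitrationSeries-class] with >= 6 informative
#'   injections.
#' @param model \code{"partition"} or \code{"one_site"}.
#' @param start optional list with starting \code{K} (1/mM) and \code{dH}
#'   (kJ/mol).
#' @return a [ThermoResult-class]
#' @export
fitBindingIsotherm <- function(series, model = c("partition", "one_site"),
                               start = NULL) {
  model <- match.arg(model)
  q <- heats(series)
  if (length(q) < 6) stop("need at least 6 injections to fit")
  if (max(abs(q)) < .Machine$double.eps * 100)
    stop("all heats are ~0; isotherm unidentifiable")
  g <- .itcGeometry(series)
  if (is.null(start)) {
    K0 <- 1 / g$L[ceiling(length(q) / 2)]
    dH0 <- sum(q) / (1e9 * g$nS)
    if (!is.finite(dH0) || dH0 == 0) dH0 <- sign(sum(q) + 1e-12)
    start <- list(K = K0, dH = dH0)
  }
  df <- data.frame(q = q)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      q ~ .itcModelHeats(series, exp(logK), dH, model),
      data = df, start = list(logK = log(start$K), dH = start$dH),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("isotherm fit did not converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  K <- exp(est[["logK"]])
  dH <- est[["dH"]]
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  fhat <- .itcModelHeats(series, K, dH, model) /
    (dH * 1e9 * g$nS)
  fhat <- cumsum(fhat)
  diag <- list(model = model,
               residualNorm = sqrt(sum(stats::resid(fit)^2)),
               se = list(K = if (!is.null(se)) K * se[["logK"]] else NA,
                         dH = if (!is.null(se)) se[["dH"]] else NA),
               converged = fit$convInfo$isConv %||% TRUE)
  if (fhat[1] > 0.99)
    warning("first injection already saturates the isotherm; K is poorly identified")
  out <- deriveThermodynamics(K, dH, series@temperature)
  out@fit <- diag
  out
}

#' Thermodynamic state functions from K and dH
#'
#' dG = -R T ln(K c0) with standard state c0 = 1 M (K given in 1/mM is
#' converted to 1/M inside the log), and TdS = dH - dG. Both identities
#' are exact by construction.
#'
#' @param K binding constant, 1/mM (> 0).
#' @param dH enthalpy, kJ/mol.
#' @param temperature Kelvin (> 0); default 299.15 K (26 C).
#' @return a [ThermoResult-class]
#' @export
deriveThermodynamics <- function(K, dH, temperature = 299.15) {
  if (K <= 0) stop("K must be > 0")
  if (temperature <= 0) stop("temperature must be > 0")
  dG <- -.RGAS * temperature * log(K * 1000)
  new("ThermoResult", K = K, dH = dH, TdS = dH - dG, dG = dG,
      temperature = temperature, fit = list())
}

#' Read ITC injections or fluorescence traces from CSV
#'
#' Injections CSV: columns \code{index}, \code{volume_uL}, \code{heat_uJ}.
#' Fluorescence CSV: columns \code{time_s}, \code{F}.
#'
#' @param path CSV file path
#' @param ... further arguments to [titrationSeries()] (concentrations,
#'   cell volume, temperature).
#' @return \code{readInjectionsCSV}: a [TitrationSeries-class];
#'   \code{readFluorescenceCSV}: a data.frame.
#' @export
readInjectionsCSV <- function(path, ...) {
  tab <- read.csv(path)
  need <- c("volume_uL", "heat_uJ")
  if (!all(need %in% names(tab)))
    stop("injection CSV must have columns: ", paste(need, collapse = ", "))
  titrationSeries(heats = tab$heat_uJ, volumes = tab$volume_uL, ...)
}

#' @rdname readInjectionsCSV
#' @export
readFluorescenceCSV <- function(path) {
  tab <- read.csv(path)
  if (!all(c("time_s", "F") %in% names(tab)))
    stop("fluorescence CSV must have columns time_s, F")
  tab
}
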