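# Seeded synthetic generators for every input the pipeline consumes:
# idealized fixture molecules, interaction-matrix scenarios, ITC titration
# series from a known model, and calcein-leakage fluorescence traces.
# Every generator is a pure function of its arguments and seed.

#' Idealized fixture molecules
#'
#' Hand-built coarse-grained molecules reproducing the qualitative shapes
#' that drive the biology, not chemical detail:
#' \describe{
#'   \item{cholesterol_like}{an elongated apolar rod with one polar
#'     hydroxyl-like head atom}
#'   \item{delta7_like}{the same atoms and parameter multiset with the
#'     tail bent ~90 degrees (the "L" shape of the bent sterol), hence a
#'     wider interfacial footprint}
#'   \item{frondoside_like}{an amphiphilic cone: a wide polar
#'     (sugar-like) base above the interface and an apolar tail below}
#'   \item{dmpc_like}{a zwitterionic head (paired +/- charges) over two
#'     apolar acyl tails}
#' }
#' Geometries and parameters are shipped as versioned CSV atom tables
#' under \code{inst/extdata} and parameterized through [readStructure()]
#' with bond auto-detection.
#'
#' @param name fixture name.
#' @return a [ParameterizedMolecule-class]
#' @export
fixtureMolecule <- function(name = c("dmpc_like", "cholesterol_like",
                                     "delta7_like", "frondoside_like")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("fixture_", name, ".csv"),
                      package = "frondosim")
  if (path == "") stop("unknown fixture: ", name)
  readStructure(path, bonds = "auto", name = name)
}

.scenarioMatrices <- list(
  cholesterol_system = list(
    types = c("DMPC", "CHOL", "SAP"),
    # upper triangle row-wise incl. diagonal:
    # DD, DC, DS, CC, CS, SS
    values = c(-0.60, -0.55, -1.40, -1.20, -1.00, -0.90)),
  delta7_system = list(
    types = c("DMPC", "D7", "SAP"),
    values = c(-0.60, -0.62, -1.40, -0.75, -0.70, -0.90)),
  null_system = list(
    types = c("DMPC", "STEROL", "SAP"),
    values = c(0, 0, 0, 0, 0, 0))
)

#' Synthetic interaction-matrix scenarios
#'
#' Symmetric per-heavy-atom interaction matrices (kJ/mol) encoding, by
#' construction, the orderings observed for this system:
#' saponin/phospholipid coupling more negative than saponin/sterol, and
#' saponin/cholesterol more negative than saponin/bent-sterol;
#' \code{cholesterol_system} additionally carries strong sterol-sterol
#' cohesion (demixing into large domains) while \code{delta7_system}
#' couples the sterol only weakly (scattered small clusters).
#' \code{null_system} is the all-zero matrix.
#'
#' @param scenario scenario name.
#' @param jitter standard deviation of optional seeded Gaussian noise
#'   added to each unordered entry (kJ/mol); 0 disables.
#' @param seed integer seed for the jitter.
#' @return an [InteractionMatrix-class]
#' @export
syntheticInteractionMatrix <- function(scenario = c("cholesterol_system",
                                                    "delta7_system",
                                                    "null_system"),
                                       jitter = 0, seed = 1L) {
  scenario <- match.arg(scenario)
  s <- .scenarioMatrices[[scenario]]
  v <- s$values
  if (jitter < 0) stop("jitter must be >= 0")
  if (jitter > 0)
    v <- v + .withSeed(seed, rnorm(length(v), sd = jitter))
  nt <- length(s$types)
  E <- matrix(0, nt, nt)
  E[lower.tri(E, diag = TRUE)] <- NA # fill via upper triangle row-wise
  k <- 0
  for (i in seq_len(nt)) for (j in i:nt) {
    k <- k + 1
    E[i, j] <- E[j, i] <- v[k]
  }
  interactionMatrix(s$types, E)
}

#' Simulate an ITC titration series from known parameters
#'
#' Per-injection heats from the partition (or one-site) model with
#' dilution bookkeeping, plus seeded Gaussian noise. The generating
#' parameters are recorded in the series metadata for recovery tests.
#'
#' @param K binding constant, 1/mM.
#' @param dH enthalpy, kJ/mol.
#' @param nInj number of injections (>= 1).
#' @param noiseSd Gaussian noise standard deviation, microjoule (>= 0).
#' @param seed integer seed.
#' @param injectionVolume microliter per injection.
#' @param model heat model, as in [fitBindingIsotherm()].
#' @param ... further geometry arguments passed to [titrationSeries()]
#'   (cellConc, syringeConc, cellVolume, temperature).
#' @return a [TitrationSeries-class]
#' @export
simulateItcTrace <- function(K, dH, nInj = 30, noiseSd = 0, seed = 1L,
                             injectionVolume = 10,
                             model = c("partition", "one_site"), ...) {
  model <- match.arg(model)
  stopifnot(nInj >= 1)
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  series <- titrationSeries(heats = numeric(nInj),
                            volumes = rep(injectionVolume, nInj), ...)
  q <- .itcModelHeats(series, K, dH, model)
  if (noiseSd > 0)
    q <- q + .withSeed(seed, rnorm(nInj, sd = noiseSd))
  series@heats <- q
  series@meta <- list(generator = list(K = K, dH = dH, model = model,
                                       noiseSd = noiseSd, seed = seed))
  series
}

#' Simulate a calcein-leakage fluorescence trace
#'
#' Saturating fluorescence time course over 900 s plateauing at
#' F_contr + level/100 (F_tot - F_contr), with seeded Gaussian noise.
#' At the plateau, [leakagePercent()] recovers \code{level}.
#'
#' @param level target leakage percentage; sanity band [-10, 120].
#' @param Fcontr,Ftot minimal/maximal control fluorescence
#'   (Ftot > Fcontr).
#' @param noiseSd Gaussian noise standard deviation (fluorescence units).
#' @param seed integer seed.
#' @param duration trace length, seconds.
#' @param by sampling interval, seconds.
#' @param tau rise time constant, seconds.
#' @return data.frame with columns \code{time_s}, \code{F}
#' @export
simulateLeakageTrace <- function(level, Fcontr = 10, Ftot = 100,
                                 noiseSd = 0, seed = 1L, duration = 900,
                                 by = 1, tau = 120) {
  if (Ftot <= Fcontr) stop("Ftot must exceed Fcontr")
  if (level < -10 || level > 120)
    stop("level outside the sanity band [-10, 120]")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  t <- seq(0, duration, by = by)
  plateau <- Fcontr + level / 100 * (Ftot - Fcontr)
  F <- Fcontr + (plateau - Fcontr) * (1 - exp(-t / tau))
  if (noiseSd > 0)
    F <- F + .withSeed(seed, rnorm(length(t), sd = noiseSd))
  data.frame(time_s = t, F = F)
}

#' Run one replicate of a monolayer scenario end-to-end
#'
#' Convenience wrapper for the headline simulation: build the scenario's
#' interaction matrix, initialize a lattice at the given composition,
#' anneal it with [mcMinimize()] and return the final state together with
#' the sterol [domainStats()].
#'
#' @param scenario scenario name, see [syntheticInteractionMatrix()].
#' @param side lattice side.
#' @param seed integer seed (drives the initial shuffle and the MC chain).
#' @param nSteps proposed exchanges.
#' @param tHot,tCold annealing temperatures (coupling units).
#' @param preset composition preset, see [compositionPreset()].
#' @param connectivity,boundary domain-labeling parameters.
#' @return list with \code{state} (final [LatticeState-class]),
#'   \code{stats} ([domainStats()]), \code{trajectory}.
#' @export
runScenarioReplicate <- function(scenario = c("cholesterol_system",
                                              "delta7_system"),
                                 side = 100, seed = 1L, nSteps = 2e6,
                                 tHot = 1.2, tCold = 0.05,
                                 preset = "67-23-10",
                                 connectivity = 8, boundary = "clipped") {
  scenario <- match.arg(scenario)
  M <- syntheticInteractionMatrix(scenario)
  sterol <- setdiff(moleculeTypes(M), c("DMPC", "SAP"))
  comp <- compositionPreset(preset, sterol = sterol)
  state <- initLattice(comp, side = side, seed = seed, M = M)
  sched <- mcSchedule(nSteps, tHot = tHot, tCold = tCold, seed = seed,
                      nSnapshots = 2)
  traj <- mcMinimize(state, M, sched)
  lab <- labelDomains(traj$finalState, targetTypes = sterol,
                      connectivity = connectivity, boundary = boundary)
  list(state = traj$finalState, stats = domainStats(lab),
       trajectory = traj)
}
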