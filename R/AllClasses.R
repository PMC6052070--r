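#' @import methods
#' @importFrom stats setNames rnorm runif sd var pt qt coef
#' @importFrom grDevices col2rgb palette.colors
#' @importFrom utils read.csv write.csv head
#' @useDynLib frondosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Parameterized small molecule
#'
#' A molecule as used throughout the package: an ordered atom table carrying
#' per-atom physicochemical parameters, plus (optional) connectivity and
#' rotatable torsions. Coordinates are in Angstrom in a right-handed frame
#' where the membrane normal is +z and the interface plane of an oriented
#' molecule is z = 0.
#'
#' The atom table has one row per atom with columns
#' \describe{
#'   \item{name}{atom name (free text)}
#'   \item{element}{chemical element symbol}
#'   \item{x, y, z}{coordinates, Angstrom}
#'   \item{charge}{partial charge, elementary charge units}
#'   \item{etr}{atomic transfer energy per unit accessible surface,
#'     kJ/(mol A^2); negative for apolar atoms, positive for polar ones}
#'   \item{radius}{van der Waals radius, Angstrom (> 0)}
#'   \item{surface}{solvent-accessible surface, A^2 (>= 0)}
#'   \item{heavy}{logical, FALSE iff the element is hydrogen}
#' }
#'
#' @slot molName single character identifier.
#' @slot atoms data.frame as described above.
#' @slot bonds two-column integer matrix of 1-based atom indices.
#' @slot torsions four-column integer matrix of bonded atom paths defining
#'   the rotatable torsions.
#'
#' @seealso [readStructure()], [fixtureMolecule()], [orientAtInterface()]
#' @export
setClass("ParameterizedMolecule",
  representation(
    molName  = "character",
    atoms    = "data.frame",
    bonds    = "matrix",
    torsions = "matrix"
  ),
  prototype(
    molName  = "molecule",
    bonds    = matrix(integer(0), ncol = 2),
    torsions = matrix(integer(0), ncol = 4)
  )
)

.atom_cols <- c("name", "element", "x", "y", "z", "charge", "etr",
                "radius", "surface", "heavy")

setValidity("ParameterizedMolecule", function(object) {
  a <- object@atoms
  msgs <- character(0)
  if (!all(.atom_cols %in% names(a)))
    msgs <- c(msgs, paste("atom table must have columns:",
                          paste(.atom_cols, collapse = ", ")))
  else {
    if (nrow(a) < 1L) msgs <- c(msgs, "molecule must have at least one atom")
    num <- a[, c("x", "y", "z", "charge", "etr", "radius", "surface")]
    if (!all(vapply(num, is.numeric, logical(1))) ||
        !all(is.finite(as.matrix(num))))
      msgs <- c(msgs, "all numeric atom parameters must be finite")
    if (any(a$radius <= 0)) msgs <- c(msgs, "atom radii must be > 0")
    if (any(a$surface < 0)) msgs <- c(msgs, "accessible surfaces must be >= 0")
    if (!identical(as.logical(a$heavy), !(toupper(a$element) == "H")))
      msgs <- c(msgs, "heavy must be FALSE iff element is hydrogen")
    if (sum(a$heavy) < 1L) msgs <- c(msgs, "at least one heavy atom required")
    b <- object@bonds
    if (ncol(b) != 2L) msgs <- c(msgs, "bonds must have two columns")
    else if (nrow(b) && (any(b < 1L) || any(b > nrow(a))))
      msgs <- c(msgs, "bond indices out of range")
    tq <- object@torsions
    if (ncol(tq) != 4L) msgs <- c(msgs, "torsions must have four columns")
    else if (nrow(tq)) {
      if (any(tq < 1L) || any(tq > nrow(a)))
        msgs <- c(msgs, "torsion indices out of range")
      else if (nrow(b)) {
        key <- function(i, j) paste(pmin(i, j), pmax(i, j))
        bk <- key(b[, 1], b[, 2])
        for (r in seq_len(nrow(tq))) {
          q <- tq[r, ]
          if (!all(key(q[-4], q[-1]) %in% bk)) {
            msgs <- c(msgs, sprintf("torsion %d is not a bonded path", r))
            break
          }
        }
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Pairwise interaction matrix
#'
#' Symmetric table of per-heavy-atom interaction energies (kJ/mol) for every
#' unordered pair of molecule types, including self pairs. These are the
#' coupling constants of the lattice monolayer simulation.
#'
#' @slot types ordered character vector of molecule-type names.
#' @slot energies symmetric numeric matrix with \code{types} as dimnames.
#'
#' @seealso [buildInteractionMatrix()], [syntheticInteractionMatrix()],
#'   [latticeEnergy()]
#' @export
setClass("InteractionMatrix",
  representation(types = "character", energies = "matrix"))

setValidity("InteractionMatrix", function(object) {
  e <- object@energies
  t <- object@types
  if (length(t) < 1L) return("at least one molecule type required")
  if (anyDuplicated(t)) return("type names must be unique")
  if (!is.numeric(e) || nrow(e) != length(t) || ncol(e) != length(t))
    return("energies must be a numeric types x types matrix")
  if (!identical(rownames(e), t) || !identical(colnames(e), t))
    return("dimnames of energies must equal types")
  if (!all(is.finite(e))) return("energies must be finite")
  if (max(abs(e - t(e))) > 1e-9) return("energies must be symmetric")
  TRUE
})

#' Monolayer lattice state
#'
#' A (by default 200 x 200) grid of molecule-type codes representing one
#' molecule per cell, together with its display palette and current total
#' lattice energy under the interaction matrix it was last scored with.
#'
#' @slot grid integer matrix of codes indexing into \code{types}.
#' @slot types character vector of molecule-type names (code i = types[i]).
#' @slot palette named character vector of display colors, one per type.
#' @slot seed integer seed the grid was generated/evolved with.
#' @slot energy numeric scalar, total lattice energy in kJ/mol.
#'
#' @seealso [initLattice()], [mcMinimize()], [renderLattice()]
#' @export
setClass("LatticeState",
  representation(grid = "matrix", types = "character",
                 palette = "character", seed = "integer",
                 energy = "numeric"))

setValidity("LatticeState", function(object) {
  g <- object@grid
  nt <- length(object@types)
  if (nt < 1L) return("at least one type required")
  if (!is.integer(g)) return("grid must be integer")
  if (any(g < 1L) || any(g > nt)) return("grid codes out of range")
  if (length(object@palette) &&
      !all(object@types %in% names(object@palette)))
    return("palette must cover all types")
  if (length(object@energy) != 1L) return("energy must be scalar")
  TRUE
})

#' Implicit-membrane insertion profile
#'
#' Result of an exhaustive z-translation / rotation scan of a molecule
#' through an implicit bilayer: for each position of the molecular center
#' along the membrane normal, the minimum over the rotation grid of the
#' restraint energy, with its decomposition and the minimizing orientation.
#'
#' @slot z numeric grid of center-of-mass positions, Angstrom.
#' @slot energy minimum total restraint energy per z, kJ/mol.
#' @slot pho hydrophobic restraint component at the minimizing pose, kJ/mol.
#' @slot lip lipid-perturbation component at the minimizing pose, kJ/mol.
#' @slot poses data.frame of the minimizing tilt angles (degrees) per z.
#' @slot membrane the [ImplicitMembrane-class] scanned against.
#'
#' @seealso [insertionScan()]
#' @export
setClass("InsertionProfile",
  representation(z = "numeric", energy = "numeric", pho = "numeric",
                 lip = "numeric", poses = "data.frame", membrane = "ANY"))

setValidity("InsertionProfile", function(object) {
  if (length(object@energy) != length(object@z))
    return("one energy per z required")
  if (length(object@pho) != length(object@z) ||
      length(object@lip) != length(object@z))
    return("component vectors must match z grid")
  TRUE
})

#' Implicit bilayer model
#'
#' The empirical hydration description of a flat bilayer: properties are
#' constant in the membrane plane and vary only along the normal z, which
#' originates at the bilayer center. The hydration function
#' C(z) = 1 - 1/(1 + exp(alpha (|z| - z0))) runs from ~0 at the hydrophobic
#' core to ~1 in bulk water.
#'
#' @slot alpha dimensionless steepness of the hydration transition.
#' @slot z0 position of the hydrophilic/hydrophobic interface, Angstrom.
#' @slot halfThickness half the bilayer thickness, Angstrom.
#' @slot aLip lipid-perturbation coefficient, kJ/(mol A^2).
#'
#' @seealso [implicitMembrane()], [hydration()], [restraintEnergy()]
#' @export
setClass("ImplicitMembrane",
  representation(alpha = "numeric", z0 = "numeric",
                 halfThickness = "numeric", aLip = "numeric"))

setValidity("ImplicitMembrane", function(object) {
  if (object@alpha <= 0) return("alpha must be > 0")
  if (object@z0 <= 0 || object@z0 >= object@halfThickness)
    return("need 0 < z0 < halfThickness")
  TRUE
})

#' ITC titration series
#'
#' Per-injection heats of an isothermal titration calorimetry experiment in
#' which a lipid (liposome) suspension in the syringe is titrated into a
#' saponin solution in the cell.
#'
#' @slot volumes injection volumes, microliter.
#' @slot heats per-injection heats, microjoule.
#' @slot cellConc saponin concentration in the cell, micromolar.
#' @slot syringeConc lipid concentration in the syringe, millimolar.
#' @slot cellVolume working cell volume, milliliter.
#' @slot temperature temperature, Kelvin.
#' @slot meta list of free-form metadata (e.g. generator parameters).
#'
#' @seealso [titrationSeries()], [simulateItcTrace()], [subtractBlanks()],
#'   [fitBindingIsotherm()]
#' @export
setClass("TitrationSeries",
  representation(volumes = "numeric", heats = "numeric",
                 cellConc = "numeric", syringeConc = "numeric",
                 cellVolume = "numeric", temperature = "numeric",
                 meta = "list"))

setValidity("TitrationSeries", function(object) {
  if (length(object@heats) != length(object@volumes))
    return("one heat per injection required")
  if (any(object@volumes <= 0)) return("injection volumes must be > 0")
  if (object@cellConc <= 0 || object@syringeConc <= 0 ||
      object@cellVolume <= 0 || object@temperature <= 0)
    return("concentrations, cell volume and temperature must be > 0")
  TRUE
})

#' Thermodynamic description of a binding interaction
#'
#' Binding constant and the thermodynamic state functions connected by the
#' exact identities dG = dH - TdS and dG = -R T ln(K c0) with standard state
#' c0 = 1 M (K is stored in 1/mM and converted to 1/M inside the log).
#'
#' @slot K binding constant, 1/mM.
#' @slot dH enthalpy, kJ/mol.
#' @slot TdS entropy term T*dS, kJ/mol.
#' @slot dG Gibbs free energy, kJ/mol.
#' @slot temperature Kelvin.
#' @slot fit list of fit diagnostics (possibly empty).
#'
#' @seealso [deriveThermodynamics()], [fitBindingIsotherm()]
#' @export
setClass("ThermoResult",
  representation(K = "numeric", dH = "numeric", TdS = "numeric",
                 dG = "numeric", temperature = "numeric", fit = "list"),
  prototype(fit = list()))

setValidity("ThermoResult", function(object) {
  if (object@K <= 0) return("K must be > 0")
  if (object@temperature <= 0) return("temperature must be > 0")
  if (abs(object@dG - (object@dH - object@TdS)) > 1e-8 * max(1, abs(object@dG)))
    return("identity dG = dH - TdS violated")
  TRUE
})
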