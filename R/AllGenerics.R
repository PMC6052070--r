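# Accessor generics for the core containers. Slot access from user code is
# discouraged; these are the supported surface.

#' @rdname ParameterizedMolecule-class
#' @param object,x a \code{ParameterizedMolecule}
#' @export
setGeneric("molName", function(object) standardGeneric("molName"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("coords", function(object) standardGeneric("coords"))

#' @rdname ParameterizedMolecule-class
#' @param value replacement value
#' @export
setGeneric("coords<-", function(object, value) standardGeneric("coords<-"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("bonds", function(object) standardGeneric("bonds"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("rotatableTorsions",
           function(object) standardGeneric("rotatableTorsions"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("atomCount", function(object) standardGeneric("atomCount"))

#' @rdname ParameterizedMolecule-class
#' @export
setGeneric("heavyAtomCount",
           function(object) standardGeneric("heavyAtomCount"))

#' @rdname InteractionMatrix-class
#' @param object an object with molecule types
#' @export
setGeneric("moleculeTypes", function(object) standardGeneric("moleculeTypes"))

#' @rdname InteractionMatrix-class
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))

#' @rdname LatticeState-class
#' @export
setGeneric("latticeGrid", function(object) standardGeneric("latticeGrid"))

#' @rdname LatticeState-class
#' @export
setGeneric("typePalette", function(object) standardGeneric("typePalette"))

#' @rdname LatticeState-class
#' @export
setGeneric("typeCounts", function(object) standardGeneric("typeCounts"))

#' @rdname LatticeState-class
#' @export
setGeneric("latticeEnergyValue",
           function(object) standardGeneric("latticeEnergyValue"))

#' @rdname TitrationSeries-class
#' @export
setGeneric("heats", function(object) standardGeneric("heats"))

#' @rdname TitrationSeries-class
#' @export
setGeneric("injectionVolumes",
           function(object) standardGeneric("injectionVolumes"))

setMethod("molName", "ParameterizedMolecule", function(object) object@molName)
setMethod("atoms", "ParameterizedMolecule", function(object) object@atoms)
setMethod("coords", "ParameterizedMolecule", function(object)
  as.matrix(object@atoms[, c("x", "y", "z")]))
setMethod("coords<-", "ParameterizedMolecule", function(object, value) {
  stopifnot(is.matrix(value), ncol(value) == 3,
            nrow(value) == nrow(object@atoms))
  object@atoms$x <- value[, 1]
  object@atoms$y <- value[, 2]
  object@atoms$z <- value[, 3]
  validObject(object)
  object
})
setMethod("bonds", "ParameterizedMolecule", function(object) object@bonds)
setMethod("rotatableTorsions", "ParameterizedMolecule",
          function(object) object@torsions)
setMethod("atomCount", "ParameterizedMolecule",
          function(object) nrow(object@atoms))
setMethod("heavyAtomCount", "ParameterizedMolecule",
          function(object) sum(object@atoms$heavy))

setMethod("moleculeTypes", "InteractionMatrix", function(object) object@types)
setMethod("energies", "InteractionMatrix", function(object) object@energies)
setMethod("moleculeTypes", "LatticeState", function(object) object@types)

setMethod("latticeGrid", "LatticeState", function(object) object@grid)
setMethod("typePalette", "LatticeState", function(object) object@palette)
setMethod("typeCounts", "LatticeState", function(object) {
  n <- tabulate(object@grid, nbins = length(object@types))
  setNames(n, object@types)
})
setMethod("latticeEnergyValue", "LatticeState", function(object) object@energy)

setMethod("heats", "TitrationSeries", function(object) object@heats)
setMethod("injectionVolumes", "TitrationSeries",
          function(object) object@volumes)

setMethod("show", "ParameterizedMolecule", function(object) {
  cat(sprintf("ParameterizedMolecule \"%s\": %d atoms (%d heavy), %d bonds, %d rotatable torsions\n",
              object@molName, nrow(object@atoms), sum(object@atoms$heavy),
              nrow(object@bonds), nrow(object@torsions)))
  etr <- object@atoms$etr * object@atoms$surface
  cat(sprintf("  amphiphilic weight: apolar %.1f / polar %.1f kJ/mol\n",
              -sum(pmin(etr, 0)), sum(pmax(etr, 0))))
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix over %d types (kJ/mol per heavy atom)\n",
              length(object@types)))
  print(round(object@energies, 3))
})

setMethod("show", "LatticeState", function(object) {
  d <- dim(object@grid)
  cat(sprintf("LatticeState %d x %d (seed %d), energy %.2f kJ/mol\n",
              d[1], d[2], object@seed, object@energy))
  print(typeCounts(object))
})

setMethod("show", "InsertionProfile", function(object) {
  i <- which.min(object@energy)
  cat(sprintf("InsertionProfile: %d z positions in [%.1f, %.1f] A\n",
              length(object@z), min(object@z), max(object@z)))
  cat(sprintf("  global best: z = %.1f A, E = %.2f kJ/mol (pho %.2f, lip %.2f)\n",
              object@z[i], object@energy[i], object@pho[i], object@lip[i]))
})

setMethod("show", "TitrationSeries", function(object) {
  cat(sprintf("TitrationSeries: %d injections of %.1f uL at %.2f K\n",
              length(object@heats), object@volumes[1], object@temperature))
  cat(sprintf("  cell %.1f uM saponin (%.4g mL), syringe %.1f mM lipid\n",
              object@cellConc, object@cellVolume, object@syringeConc))
})

setMethod("show", "ThermoResult", function(object) {
  cat(sprintf("ThermoResult at %.2f K\n", object@temperature))
  cat(sprintf("  K = %.4g mM^-1, dG = %.3f, dH = %.3f, TdS = %.3f kJ/mol\n",
              object@K, object@dG, object@dH, object@TdS))
})
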