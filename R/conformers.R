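# Simplified systematic conformer enumeration over the main torsional
# angles, scored with the empirical intramolecular field.

#' Set of enumerated conformers
#'
#' @slot molName parent molecule name.
#' @slot torsions matrix of torsion-angle offsets (degrees) relative to the
#'   input geometry, one row per conformer, sorted by energy.
#' @slot energies intramolecular energies, kJ/mol, ascending.
#' @slot coords list of n x 3 coordinate matrices, parallel to rows.
#' @slot rejected number of grid points discarded as steric clashes.
#' @slot gridSize total cardinality of the enumerated torsion grid.
#' @export
setClass("ConformerSet",
  representation(molName = "character", torsions = "matrix",
                 energies = "numeric", coords = "list",
                 rejected = "integer", gridSize = "integer"))

setValidity("ConformerSet", function(object) {
  n <- length(object@energies)
  if (nrow(object@torsions) != n || length(object@coords) != n)
    return("torsions/coords must parallel energies")
  if (is.unsorted(object@energies)) return("energies must be ascending")
  if (n + object@rejected != object@gridSize)
    return("returned + rejected conformers must equal the grid cardinality")
  TRUE
})

setMethod("show", "ConformerSet", function(object) {
  cat(sprintf("ConformerSet for \"%s\": %d conformers (grid %d, %d clash-rejected)\n",
              object@molName, length(object@energies), object@gridSize,
              object@rejected))
  if (length(object@energies))
    cat(sprintf("  best energy %.3f kJ/mol\n", object@energies[1]))
})

#' @export
#' @method as.data.frame ConformerSet
#' @param x a \code{ConformerSet}
#' @param ... unused
#' @rdname ConformerSet-class
as.data.frame.ConformerSet <- function(x, ...) {
  tq <- x@torsions
  colnames(tq) <- paste0("torsion", seq_len(ncol(tq)))
  data.frame(tq, energy = x@energies)
}

#' Number of conformers in a set
#' @rdname ConformerSet-class
#' @export
setMethod("length", "ConformerSet", function(x) length(x@energies))

#' Coordinates of conformer i
#' @param cs a \code{ConformerSet}
#' @param i conformer index (energy rank)
#' @return n x 3 coordinate matrix
#' @export
conformerCoords <- function(cs, i = 1L) cs@coords[[i]]

# Rotate the atoms on the k/l side of torsion (i,j,k,l) by `deg` about the
# j->k axis. The moving set is the connected component containing k after
# deleting bond j-k.
.rotateTorsion <- function(xyz, bonds, quad, deg) {
  j <- quad[2]; k <- quad[3]
  keep <- !((bonds[, 1] == j & bonds[, 2] == k) |
              (bonds[, 1] == k & bonds[, 2] == j))
  b <- bonds[keep, , drop = FALSE]
  n <- nrow(xyz)
  adj <- vector("list", n)
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
      adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
    }
  }
  seen <- logical(n)
  seen[k] <- TRUE
  frontier <- k
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  if (seen[j]) stop("torsion bond ", j, "-", k, " lies on a ring; cannot rotate")
  ax <- xyz[k, ] - xyz[j, ]
  ax <- ax / sqrt(sum(ax^2))
  a <- .deg2rad(deg)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
  mov <- which(seen)
  xyz[mov, ] <- sweep(sweep(xyz[mov, , drop = FALSE], 2, xyz[j, ]) %*% t(R),
                      2, xyz[j, ], "+")
  xyz
}

#' Enumerate conformers on a systematic torsion grid
#'
#' Scans every combination of offsets (0, step, 2*step, ...) of the
#' molecule's rotatable torsions relative to the input geometry, discards
#' grid points with steric clashes (non-bonded interatomic distance below
#' \code{clashFactor} times the radius sum), scores the rest with
#' [intramolecularEnergy()] and returns them sorted ascending by energy.
#' A molecule without rotatable torsions yields exactly one conformer with
#' the input coordinates.
#'
#' @param mol a [ParameterizedMolecule-class] with bonds and torsions.
#' @param step torsion grid step in degrees; must divide 360.
#' @param cap refuse enumerations larger than this many grid points.
#' @param ff force-field constants, see [forceFieldParams()].
#' @return a [ConformerSet-class]
#' @export
enumerateConformations <- function(mol, step = 120, cap = 1e5,
                                   ff = forceFieldParams()) {
  stopifnot(step > 0)
  if (360 %% step != 0) stop("step must divide 360")
  a <- atoms(mol)
  tq <- rotatableTorsions(mol)
  nt <- nrow(tq)
  nlev <- as.integer(360 / step)
  gridSize <- nlev^nt
  if (gridSize > cap)
    stop(sprintf("torsion grid has %d points, exceeding the cap of %d; raise `cap` or coarsen `step`",
                 gridSize, as.integer(cap)))
  levs <- seq(0, 360 - step, by = step)
  if (nt == 0L) {
    e <- intramolecularEnergy(mol, ff = ff)
    return(new("ConformerSet", molName = molName(mol),
               torsions = matrix(numeric(0), nrow = 1, ncol = 0),
               energies = e$total, coords = list(coords(mol)),
               rejected = 0L, gridSize = 1L))
  }
  combos <- as.matrix(expand.grid(rep(list(levs), nt)))
  colnames(combos) <- NULL
  D <- .bondDistances(nrow(a), bonds(mol))
  base <- coords(mol)
  keep <- logical(nrow(combos))
  energies <- numeric(nrow(combos))
  clist <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    xyz <- base
    for (t in seq_len(nt)) {
      if (combos[r, t] != 0)
        xyz <- .rotateTorsion(xyz, bonds(mol), tq[t, ], combos[r, t])
    }
    if (.hasClash(xyz, a$radius, D, ff$clashFactor)) next
    keep[r] <- TRUE
    energies[r] <- intramolecularEnergy(mol, xyz, ff)$total
    clist[[r]] <- xyz
  }
  ord <- order(energies[keep])
  kept <- which(keep)[ord]
  new("ConformerSet", molName = molName(mol),
      torsions = combos[kept, , drop = FALSE],
      energies = energies[kept], coords = clist[kept],
      rejected = as.integer(sum(!keep)), gridSize = as.integer(gridSize))
}
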