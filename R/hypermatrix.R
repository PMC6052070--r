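# Pairwise docking of interface-oriented molecules.
#
# Both partners stay oriented at the hydrophobic/hydrophilic interface
# (z = 0 plane); the pose space is therefore restricted to
# interface-preserving moves: azimuthal placement of the ligand around the
# central molecule, radial distance, ligand self-rotation about z, and a
# small z offset. Energies decompose into van der Waals, electrostatic and
# hydrophobic terms, reported both raw and per heavy atom of the pair.

# Precompute pose-independent pair quantities for molecules a (fixed) and
# b (posed).
.pairField <- function(a, b, ff) {
  aa <- atoms(a); ab <- atoms(b)
  list(
    xyzA = coords(a),
    qq = outer(aa$charge, ab$charge),
    rsum = outer(aa$radius, ab$radius, "+"),
    heavy = outer(aa$heavy, ab$heavy, "&"),
    apolar = outer(aa$heavy & aa$etr < 0, ab$heavy & ab$etr < 0, "&"),
    hterm = outer(aa$surface * abs(aa$etr), ab$surface * abs(ab$etr), "+"),
    nHeavyPair = sum(aa$heavy) + sum(ab$heavy),
    ff = ff
  )
}

# Energy components given posed coordinates of b.
.pairEnergyFromCoords <- function(fld, xyzB) {
  d2 <- outer(rowSums(fld$xyzA^2), rowSums(xyzB^2), "+") -
    2 * tcrossprod(fld$xyzA, xyzB)
  d2[d2 < 1e-12] <- 1e-12
  if (any(d2 < (fld$ff$clashFactor * fld$rsum)^2))
    return(list(vdw = NA_real_, electrostatic = NA_real_,
                hydrophobic = NA_real_, total = Inf,
                perHeavyAtom = Inf, clash = TRUE))
  d <- sqrt(d2)
  s6 <- (fld$rsum / d)^6
  vdw <- fld$ff$epsVdw * sum((s6 * s6 - 2 * s6)[fld$heavy])
  ele <- .KE / fld$ff$dielectricFactor * sum((fld$qq / d2))
  contact <- fld$apolar & (d < fld$rsum + fld$ff$contactProbe)
  pho <- -fld$ff$hydrophobicWeight * sum(fld$hterm[contact])
  tot <- vdw + ele + pho
  list(vdw = vdw, electrostatic = ele, hydrophobic = pho, total = tot,
       perHeavyAtom = tot / fld$nHeavyPair, clash = FALSE)
}

#' Interaction energy of two posed molecules
#'
#' Components: 6-12 van der Waals over heavy-atom pairs, Coulomb with
#' distance-dependent dielectric eps(r) = 3r over all charged pairs, and a
#' hydrophobic contact term -w (S_i |Etr_i| + S_j |Etr_j|) for apolar
#' heavy-atom pairs within contact distance (r < r_i + r_j + probe).
#' The total is reported raw and per heavy atom of the pair (divisor = sum
#' of heavy atoms of both partners). A pose with atoms overlapping beyond
#' the clash cutoff is rejected with sentinel energy \code{Inf}.
#'
#' @param a,b [ParameterizedMolecule-class] objects, interface-oriented.
#' @param pose a [rigidTransform()] applied to \code{b}'s coordinates.
#' @param ff force-field constants, see [forceFieldParams()].
#' @return list with \code{vdw}, \code{electrostatic}, \code{hydrophobic},
#'   \code{total}, \code{perHeavyAtom} (kJ/mol) and flag \code{clash}.
#' @export
pairEnergy <- function(a, b, pose = rigidTransform(),
                       ff = forceFieldParams()) {
  fld <- .pairField(a, b, ff)
  .pairEnergyFromCoords(fld, applyTransform(coords(b), pose))
}

#' Interface-preserving docking grid
#'
#' The pose grid enumerated by [dockPair()]: radial distances of the
#' ligand center from the central molecule (Angstrom), azimuthal placement
#' angles and ligand self-rotations about z (degrees), and small vertical
#' offsets (Angstrom). The default is a coarse desk-scale grid (~10^4
#' poses); \code{dockGrid("production")} enumerates the fine grid whose
#' cardinality exceeds 10^7 when combined over molecule pairs and
#' conformer choices.
#'
#' @param preset \code{"coarse"} or \code{"production"}.
#' @param dist,azimuth,rotation,dzOffset numeric vectors overriding the
#'   preset.
#' @return a \code{dockGrid} list with a \code{cardinality} field.
#' @export
dockGrid <- function(preset = c("coarse", "production"), dist = NULL,
                     azimuth = NULL, rotation = NULL, dzOffset = NULL) {
  preset <- match.arg(preset)
  g <- if (preset == "coarse")
    list(dist = seq(2, 12, by = 1), azimuth = seq(0, 330, by = 30),
         rotation = seq(0, 330, by = 30), dzOffset = c(-1.5, 0, 1.5))
  else
    list(dist = seq(1.5, 14, by = 0.25), azimuth = seq(0, 359, by = 2.5),
         rotation = seq(0, 359, by = 2.5), dzOffset = seq(-3, 3, by = 0.5))
  if (!is.null(dist)) g$dist <- dist
  if (!is.null(azimuth)) g$azimuth <- azimuth
  if (!is.null(rotation)) g$rotation <- rotation
  if (!is.null(dzOffset)) g$dzOffset <- dzOffset
  g$cardinality <- length(g$dist) * length(g$azimuth) *
    length(g$rotation) * length(g$dzOffset)
  structure(g, class = "dockGrid")
}

# Transform for one grid pose: self-rotate ligand about z, then translate
# to (d cos(az), d sin(az), dz).
.poseTransform <- function(dist, azimuth, rotation, dz) {
  rigidTransform(rotZ(rotation),
                 c(dist * cos(.deg2rad(azimuth)),
                   dist * sin(.deg2rad(azimuth)), dz))
}

#' Exhaustive pairwise docking at the interface
#'
#' Enumerates every pose of the docking grid, scores it with
#' [pairEnergy()] and returns the non-clashing poses sorted ascending by
#' total energy.
#'
#' @param central,ligand interface-oriented
#'   [ParameterizedMolecule-class] objects.
#' @param search a [dockGrid()].
#' @param ff force-field constants.
#' @return a \code{dockResult}: list with \code{poses} (data.frame of pose
#'   parameters and energy components, sorted), \code{gridCardinality},
#'   \code{nClash}, and the molecule names.
#' @export
dockPair <- function(central, ligand, search = dockGrid(),
                     ff = forceFieldParams()) {
  fld <- .pairField(central, ligand, ff)
  xyzB0 <- coords(ligand)
  combos <- expand.grid(dist = search$dist, azimuth = search$azimuth,
                        rotation = search$rotation, dz = search$dzOffset,
                        KEEP.OUT.ATTRS = FALSE)
  n <- nrow(combos)
  res <- matrix(NA_real_, n, 5,
                dimnames = list(NULL, c("vdw", "electrostatic",
                                        "hydrophobic", "total",
                                        "perHeavyAtom")))
  # group by rotation: self-rotation of the ligand is shared across poses
  for (rot in unique(combos$rotation)) {
    rows <- which(combos$rotation == rot)
    xyzR <- xyzB0 %*% t(rotZ(rot))
    for (i in rows) {
      xyz <- xyzR
      az <- .deg2rad(combos$azimuth[i])
      xyz[, 1] <- xyz[, 1] + combos$dist[i] * cos(az)
      xyz[, 2] <- xyz[, 2] + combos$dist[i] * sin(az)
      xyz[, 3] <- xyz[, 3] + combos$dz[i]
      e <- .pairEnergyFromCoords(fld, xyz)
      res[i, ] <- c(e$vdw, e$electrostatic, e$hydrophobic, e$total,
                    e$perHeavyAtom)
    }
  }
  ok <- is.finite(res[, "total"])
  if (!any(ok))
    warning("all ", n, " poses clash; empty docking result")
  poses <- cbind(combos[ok, , drop = FALSE],
                 as.data.frame(res[ok, , drop = FALSE]))
  poses <- poses[order(poses$total), , drop = FALSE]
  rownames(poses) <- NULL
  structure(list(poses = poses, gridCardinality = n,
                 nClash = sum(!ok), central = molName(central),
                 ligand = molName(ligand)),
            class = "dockResult")
}

#' @export
print.dockResult <- function(x, ...) {
  cat(sprintf("dockResult %s / %s: %d poses scored (%d clash-rejected)\n",
              x$central, x$ligand, x$gridCardinality, x$nClash))
  if (nrow(x$poses)) {
    b <- x$poses[1, ]
    cat(sprintf("  best: d = %.1f A, az = %g, rot = %g, dz = %.1f -> %.3f kJ/mol (%.4f per heavy atom)\n",
                b$dist, b$azimuth, b$rotation, b$dz, b$total,
                b$perHeavyAtom))
  }
  invisible(x)
}

#' Best pose of a docking result
#'
#' @param dock a \code{dockResult} from [dockPair()]
#' @return list with the pose parameters, its [rigidTransform()], and the
#'   energy breakdown
#' @export
bestPose <- function(dock) {
  if (!nrow(dock$poses)) stop("docking result is empty (all poses clashed)")
  b <- dock$poses[1, ]
  list(dist = b$dist, azimuth = b$azimuth, rotation = b$rotation,
       dz = b$dz,
       transform = .poseTransform(b$dist, b$azimuth, b$rotation, b$dz),
       vdw = b$vdw, electrostatic = b$electrostatic,
       hydrophobic = b$hydrophobic, total = b$total,
       perHeavyAtom = b$perHeavyAtom)
}

#' Greedy sequential assembly of ligands around a central molecule
#'
#' Places \code{n} copies of the ligand one at a time: each takes the best
#' non-clashing grid pose given the central molecule and the previously
#' placed copies, provided the energy increment is favorable (<= 0);
#' otherwise the assembly is truncated with a warning. The total assembly
#' energy is therefore monotone non-increasing while placements succeed.
#'
#' @param central,ligand interface-oriented
#'   [ParameterizedMolecule-class] objects.
#' @param n number of ligands to place (>= 1).
#' @param search a [dockGrid()].
#' @param ff force-field constants.
#' @return list with \code{placements} (list of pose transforms),
#'   \code{energies} (per-ligand increments, kJ/mol), \code{total},
#'   \code{meanEnergy}, and \code{nPlaced}.
#' @export
buildAssembly <- function(central, ligand, n, search = dockGrid(),
                          ff = forceFieldParams()) {
  stopifnot(n >= 1)
  fldC <- .pairField(central, ligand, ff)
  xyzB0 <- coords(ligand)
  combos <- expand.grid(dist = search$dist, azimuth = search$azimuth,
                        rotation = search$rotation, dz = search$dzOffset,
                        KEEP.OUT.ATTRS = FALSE)
  placedXyz <- list()
  placements <- list()
  energies <- numeric(0)
  fldL <- .pairField(ligand, ligand, ff)
  for (k in seq_len(n)) {
    best <- Inf; bestPose <- NULL; bestXyz <- NULL
    for (i in seq_len(nrow(combos))) {
      tf <- .poseTransform(combos$dist[i], combos$azimuth[i],
                           combos$rotation[i], combos$dz[i])
      xyz <- applyTransform(xyzB0, tf)
      e <- .pairEnergyFromCoords(fldC, xyz)
      if (e$clash) next
      tot <- e$total
      bad <- FALSE
      for (p in placedXyz) {
        ep <- .pairEnergyFromCoords(list(xyzA = p, qq = fldL$qq,
                                         rsum = fldL$rsum,
                                         heavy = fldL$heavy,
                                         apolar = fldL$apolar,
                                         hterm = fldL$hterm,
                                         nHeavyPair = fldL$nHeavyPair,
                                         ff = ff), xyz)
        if (ep$clash) { bad <- TRUE; break }
        tot <- tot + ep$total
      }
      if (bad) next
      if (tot < best) {
        best <- tot
        bestPose <- combos[i, ]
        bestXyz <- xyz
      }
    }
    if (is.null(bestXyz) || best > 0) {
      warning(sprintf("no favorable non-clashing pose for ligand %d; assembly truncated at %d",
                      k, k - 1L))
      break
    }
    placedXyz[[k]] <- bestXyz
    placements[[k]] <- .poseTransform(bestPose$dist, bestPose$azimuth,
                                      bestPose$rotation, bestPose$dz)
    energies[k] <- best
  }
  list(placements = placements, energies = energies,
       total = sum(energies), meanEnergy = mean(energies),
       nPlaced = length(energies))
}

#' Build the pairwise interaction matrix for a set of molecule types
#'
#' For every unordered pair of types (including self pairs) the
#' per-heavy-atom best-pose total from [dockPair()] is computed for both
#' role assignments (a central / b ligand and vice versa) and averaged;
#' the symmetric matrix of these values is the coupling table of the
#' lattice monolayer simulation.
#'
#' @param mols named list of interface-oriented
#'   [ParameterizedMolecule-class] objects (>= 2 types).
#' @param search a [dockGrid()].
#' @param ff force-field constants.
#' @return an [InteractionMatrix-class]
#' @export
buildInteractionMatrix <- function(mols, search = dockGrid(),
                                   ff = forceFieldParams()) {
  if (length(mols) < 2) stop("need at least 2 molecule types")
  types <- names(mols)
  if (is.null(types) || any(types == ""))
    stop("`mols` must be a named list")
  nt <- length(types)
  E <- matrix(NA_real_, nt, nt, dimnames = list(types, types))
  for (i in seq_len(nt)) {
    for (j in i:nt) {
      d1 <- dockPair(mols[[i]], mols[[j]], search, ff)
      if (!nrow(d1$poses))
        stop("docking failed for pair ", types[i], "/", types[j],
             ": all poses clash; matrix incomplete")
      e1 <- d1$poses$perHeavyAtom[1]
      if (i == j) e2 <- e1
      else {
        d2 <- dockPair(mols[[j]], mols[[i]], search, ff)
        if (!nrow(d2$poses))
          stop("docking failed for pair ", types[j], "/", types[i],
               ": all poses clash; matrix incomplete")
        e2 <- d2$poses$perHeavyAtom[1]
      }
      E[i, j] <- E[j, i] <- (e1 + e2) / 2
    }
  }
  new("InteractionMatrix", types = types, energies = E)
}

#' Construct an interaction matrix from explicit entries
#'
#' @param types character vector of type names.
#' @param energies symmetric numeric matrix (kJ/mol per heavy atom); a
#'   vector of upper-triangle values (row-wise, including the diagonal) is
#'   also accepted.
#' @return an [InteractionMatrix-class]
#' @export
interactionMatrix <- function(types, energies) {
  nt <- length(types)
  if (!is.matrix(energies)) {
    E <- matrix(0, nt, nt)
    E[upper.tri(E, diag = TRUE)] <- energies
    E <- E + t(E) - diag(diag(E))
    energies <- E
  }
  dimnames(energies) <- list(types, types)
  new("InteractionMatrix", types = types, energies = energies)
}

#' Read/write an interaction matrix as CSV
#'
#' The CSV carries a units comment line, a header of type names and the
#' symmetric numeric body.
#'
#' @param M an [InteractionMatrix-class]
#' @param path file path
#' @return \code{writeInteractionMatrix}: invisibly, the path;
#'   \code{readInteractionMatrix}: an [InteractionMatrix-class].
#' @export
writeInteractionMatrix <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# pairwise interaction energies, kJ/mol per heavy atom", con)
  writeLines(paste(c("type", M@types), collapse = ","), con)
  for (i in seq_along(M@types))
    writeLines(paste(c(M@types[i], format(M@energies[i, ], digits = 15)),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname writeInteractionMatrix
#' @export
readInteractionMatrix <- function(path) {
  tab <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  types <- as.character(tab[[1]])
  E <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(E) <- list(types, types)
  # symmetrize away CSV round-trip noise
  E <- (E + t(E)) / 2
  new("InteractionMatrix", types = types, energies = E)
}
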