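# Implicit-bilayer insertion profiling.
#
# The bilayer is described only by the logistic hydration function C(z)
# along the membrane normal; a molecule's position is scored by two
# empirical restraints (hydrophobic + lipid perturbation) summed over its
# atoms, and an exhaustive translation/rotation scan locates the most
# stable position.

#' Construct an implicit bilayer
#'
#' Defaults describe a 36 Angstrom bilayer: hydration steepness
#' \code{alpha} = 1.99, hydrophilic/hydrophobic interface at
#' \code{z0} = 13.5 A (the polar-head / alkyl-chain boundary), half
#' thickness 18 A, and lipid-perturbation coefficient
#' \code{aLip} = 0.0753 kJ/(mol A^2).
#'
#' @param alpha steepness constant (dimensionless).
#' @param z0 interface position, Angstrom; 0 < z0 < halfThickness.
#' @param halfThickness half bilayer thickness, Angstrom.
#' @param aLip lipid perturbation coefficient, kJ/(mol A^2).
#' @return an [ImplicitMembrane-class]
#' @export
implicitMembrane <- function(alpha = 1.99, z0 = 13.5, halfThickness = 18,
                             aLip = 0.0753) {
  new("ImplicitMembrane", alpha = alpha, z0 = z0,
      halfThickness = halfThickness, aLip = aLip)
}

setMethod("show", "ImplicitMembrane", function(object) {
  cat(sprintf("ImplicitMembrane: thickness %.1f A, interface at +/-%.1f A, alpha = %.2f, aLip = %.4f kJ/(mol A^2)\n",
              2 * object@halfThickness, object@z0, object@alpha, object@aLip))
})

#' Hydration function C(z)
#'
#' C(z) = 1 - 1/(1 + exp(alpha (|z| - z0))): ~0 in the hydrophobic core,
#' 0.5 exactly at the interface |z| = z0, approaching 1 in bulk water.
#' Strictly increasing in |z| and symmetric about the bilayer center.
#'
#' @param z depth(s) along the membrane normal, Angstrom (z = 0 is the
#'   bilayer center).
#' @param mem an [ImplicitMembrane-class]
#' @return hydration value(s) in (0, 1)
#' @export
hydration <- function(z, mem = implicitMembrane()) {
  1 - 1 / (1 + exp(mem@alpha * (abs(z) - mem@z0)))
}

#' Membrane restraint energy of a posed molecule
#'
#' Sum over atoms of the two implicit-membrane restraints:
#' hydrophobic restraint -sum S(i) Etr(i) C(z_i) (apolar atoms, Etr < 0,
#' are penalized in water and relieved in the core; polar atoms the
#' reverse) and lipid-perturbation restraint
#' aLip sum S(i) (1 - C(z_i)) (any atom inside the bilayer perturbs the
#' lipid packing). Both depend only on the atomic z coordinates, so the
#' energy is exactly invariant under rotation about the normal and
#' translation in the membrane plane.
#'
#' @param mol a [ParameterizedMolecule-class]
#' @param pose list with \code{z} (center position along the normal,
#'   Angstrom) and optional \code{rx}, \code{ry}, \code{rz} rotations
#'   (degrees, applied about x, then y, then z, around the molecular
#'   center) — or NULL to score the coordinates as they are.
#' @param mem an [ImplicitMembrane-class]
#' @return list with \code{pho}, \code{lip}, \code{total} (kJ/mol)
#' @export
restraintEnergy <- function(mol, pose = NULL, mem = implicitMembrane()) {
  a <- atoms(mol)
  xyz <- coords(mol)
  if (!is.null(pose)) {
    ctr <- colMeans(xyz)
    xyz <- sweep(xyz, 2, ctr)
    R <- rotZ(pose$rz %||% 0) %*% rotY(pose$ry %||% 0) %*% rotX(pose$rx %||% 0)
    xyz <- xyz %*% t(R)
    xyz[, 3] <- xyz[, 3] + (pose$z %||% 0)
  }
  C <- hydration(xyz[, 3], mem)
  pho <- -sum(a$surface * a$etr * C)
  lip <- mem@aLip * sum(a$surface * (1 - C))
  list(pho = pho, lip = lip, total = pho + lip)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Exhaustive insertion scan through an implicit bilayer
#'
#' Translates the molecular center along the membrane normal in steps of
#' \code{dz} from \code{-(halfThickness + margin)} to
#' \code{+(halfThickness + margin)} and, at each depth, minimizes the
#' restraint sum over a full rotation grid (both in-plane tilt angles
#' scanned 0..360 degrees in steps of \code{angularStep}; the rotation
#' about the normal is an exact invariance of the restraints and is not
#' enumerated). With this exhaustive grid the profile is symmetric,
#' E(z) = E(-z), to machine precision, because the grid is closed under
#' the reflection (rx, ry) -> (rx + 180, -ry).
#'
#' @param mol a [ParameterizedMolecule-class]
#' @param mem an [ImplicitMembrane-class]
#' @param dz translation step, Angstrom.
#' @param angularStep rotation grid step in degrees; must divide 360.
#' @param margin bulk-water margin beyond the bilayer on each side,
#'   Angstrom.
#' @return an [InsertionProfile-class]
#' @export
insertionScan <- function(mol, mem = implicitMembrane(), dz = 1,
                          angularStep = 30, margin = 18) {
  stopifnot(dz > 0)
  if (360 %% angularStep != 0) stop("angularStep must divide 360")
  angles <- seq(0, 360 - angularStep, by = angularStep)
  if (!length(angles)) stop("empty rotation grid")
  a <- atoms(mol)
  xyz0 <- sweep(coords(mol), 2, colMeans(coords(mol)))
  # precompute centered z-coordinates for every grid rotation
  zrots <- vector("list", length(angles)^2)
  k <- 0
  for (rx in angles) for (ry in angles) {
    k <- k + 1
    R <- rotY(ry) %*% rotX(rx)
    zrots[[k]] <- list(rx = rx, ry = ry, zc = as.numeric(xyz0 %*% R[3, ]))
  }
  zmax <- mem@halfThickness + margin
  zg <- seq(-zmax, zmax, by = dz)
  n <- length(zg)
  etot <- epho <- elip <- numeric(n)
  brx <- bry <- numeric(n)
  Se <- a$surface * a$etr
  S <- a$surface
  for (i in seq_len(n)) {
    best <- Inf; bp <- bl <- 0; bx <- by <- 0
    for (rot in zrots) {
      C <- hydration(rot$zc + zg[i], mem)
      pho <- -sum(Se * C)
      lip <- mem@aLip * sum(S * (1 - C))
      tot <- pho + lip
      if (tot < best) {
        best <- tot; bp <- pho; bl <- lip; bx <- rot$rx; by <- rot$ry
      }
    }
    etot[i] <- best; epho[i] <- bp; elip[i] <- bl
    brx[i] <- bx; bry[i] <- by
  }
  new("InsertionProfile", z = zg, energy = etot, pho = epho, lip = elip,
      poses = data.frame(z = zg, rx = brx, ry = bry), membrane = mem)
}

#' Global best pose of an insertion profile
#'
#' @param profile an [InsertionProfile-class]
#' @return list with \code{z}, \code{rx}, \code{ry}, \code{energy},
#'   \code{pho}, \code{lip}
#' @export
globalBest <- function(profile) {
  i <- which.min(profile@energy)
  list(z = profile@z[i], rx = profile@poses$rx[i], ry = profile@poses$ry[i],
       energy = profile@energy[i], pho = profile@pho[i],
       lip = profile@lip[i])
}

#' Insertion profile as a data.frame
#'
#' Columns z, e_total, e_pho, e_lip (plus the minimizing tilt angles).
#'
#' @param x an [InsertionProfile-class]
#' @param ... unused
#' @export
#' @method as.data.frame InsertionProfile
as.data.frame.InsertionProfile <- function(x, ...) {
  data.frame(z = x@z, e_total = x@energy, e_pho = x@pho, e_lip = x@lip,
             rx = x@poses$rx, ry = x@poses$ry)
}
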