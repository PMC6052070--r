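# Interface orientation and interfacial-area projection.
#
# Convention: the hydrophobic/hydrophilic interface is the plane z = 0 of
# an oriented molecule; +z points toward water, -z toward the membrane
# interior. Amphiphilic weights are S(i) * Etr(i): negative = apolar.

#' Orient a molecule at the hydrophobic/hydrophilic interface
#'
#' Computes the rigid transform that aligns the axis joining the
#' hydrophobic-weighted and hydrophilic-weighted atomic centroids with the
#' membrane normal (+z, hydrophilic side up), and translates the molecule
#' so that its amphiphilic balance point (the |S*Etr|-weighted centroid,
#' i.e. the point where polar and apolar torques about the interface plane
#' cancel) lies at z = 0 and its lateral centroid at the origin.
#'
#' A molecule with no amphiphilic contrast (all weights of one sign, or a
#' degenerate axis) yields the identity transform with a warning.
#'
#' @param mol a [ParameterizedMolecule-class]
#' @return a [rigidTransform()]; apply with [transformMolecule()].
#' @export
orientAtInterface <- function(mol) {
  a <- atoms(mol)
  xyz <- coords(mol)
  w <- a$surface * a$etr
  wpol <- pmax(w, 0)
  wapo <- pmax(-w, 0)
  if (sum(wpol) < 1e-9 || sum(wapo) < 1e-9) {
    warning("molecule has no amphiphilic contrast; orientation undefined, returning identity")
    return(rigidTransform())
  }
  cpol <- colSums(xyz * wpol) / sum(wpol)
  capo <- colSums(xyz * wapo) / sum(wapo)
  ax <- cpol - capo
  if (sqrt(sum(ax^2)) < 1e-9) {
    warning("polar and apolar centroids coincide; orientation undefined, returning identity")
    return(rigidTransform())
  }
  R <- .rotationBetween(ax, c(0, 0, 1))
  rot <- xyz %*% t(R)
  wabs <- abs(w)
  bal <- colSums(rot * wabs) / sum(wabs)
  rigidTransform(R, -bal)
}

#' Projected interfacial area of an oriented molecule
#'
#' Area (A^2) of the union of atomic disks obtained by projecting every
#' atom lying within a slab around the interface plane onto that plane,
#' each with its van der Waals radius, evaluated on a fine raster grid.
#' The area is invariant under rotation about z and translation within the
#' plane, and monotone non-decreasing when atoms are added.
#'
#' @param mol a [ParameterizedMolecule-class]
#' @param transform rigid transform placing the molecule at the interface;
#'   defaults to [orientAtInterface()]. Pass [rigidTransform()] to use the
#'   molecule's coordinates as-is.
#' @param slabHalfWidth half-width of the slab around z = 0, Angstrom.
#' @param res raster resolution, Angstrom.
#' @return area in A^2 (0, with a warning, if no atom falls in the slab).
#' @export
interfacialArea <- function(mol, transform = orientAtInterface(mol),
                            slabHalfWidth = 6, res = 0.05) {
  xyz <- applyTransform(coords(mol), transform)
  a <- atoms(mol)
  sel <- abs(xyz[, 3]) <= slabHalfWidth
  if (!any(sel)) {
    warning("no atom within the interfacial slab; area is 0")
    return(0)
  }
  x <- xyz[sel, 1]; y <- xyz[sel, 2]; r <- a$radius[sel]
  gx <- seq(min(x - r) - res, max(x + r) + res, by = res)
  gy <- seq(min(y - r) - res, max(y + r) + res, by = res)
  covered <- matrix(FALSE, length(gx), length(gy))
  for (i in seq_along(x)) {
    dx2 <- (gx - x[i])^2
    dy2 <- (gy - y[i])^2
    covered <- covered | outer(dx2, dy2, "+") <= r[i]^2
  }
  sum(covered) * res^2
}
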