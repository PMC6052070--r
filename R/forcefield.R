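# Empirical intra- and intermolecular energy terms.
#
# The scoring field is deliberately simple and fully parameterized from an
# editable table: a 6-12 van der Waals term on heavy atoms, a Coulomb term
# with distance-dependent dielectric eps(r) = 3r, a 3-fold torsional
# potential, and a hydrophobic term built from atomic transfer energies and
# accessible surfaces. It is designed to reproduce robust qualitative
# contracts (signs, orderings, shape preferences), not calorimetric
# accuracy.

# Coulomb constant, kJ A / (mol e^2)
.KE <- 1389.35458

#' Force-field configuration
#'
#' @param epsVdw well depth of the 6-12 term, kJ/mol.
#' @param dielectricFactor d in eps(r) = d * r (distance-dependent
#'   dielectric, dimensionless per Angstrom).
#' @param torsionBarrier V3 barrier of the 3-fold torsional term, kJ/mol.
#' @param hydrophobicWeight weight w of the pairwise hydrophobic contact
#'   term, dimensionless.
#' @param contactProbe added to the radius sum to define the hydrophobic
#'   contact distance, Angstrom.
#' @param clashFactor pairs closer than \code{clashFactor * (r_i + r_j)}
#'   are steric clashes.
#' @return list of force-field constants
#' @export
forceFieldParams <- function(epsVdw = 0.4, dielectricFactor = 3,
                             torsionBarrier = 2.0, hydrophobicWeight = 0.1,
                             contactProbe = 1.4, clashFactor = 0.7) {
  list(epsVdw = epsVdw, dielectricFactor = dielectricFactor,
       torsionBarrier = torsionBarrier,
       hydrophobicWeight = hydrophobicWeight,
       contactProbe = contactProbe, clashFactor = clashFactor)
}

# 6-12 van der Waals with minimum at r_i + r_j:
# eps * ((rm/r)^12 - 2 (rm/r)^6)
.vdw612 <- function(d, rm, eps) {
  s6 <- (rm / d)^6
  eps * (s6 * s6 - 2 * s6)
}

# Coulomb with eps(r) = d*r: KE qi qj / (d r^2)
.coulomb <- function(d, qi, qj, dfac) .KE * qi * qj / (dfac * d^2)

# Shortest bond-path distances between all atom pairs (BFS per atom).
.bondDistances <- function(n, bonds) {
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    dd <- 0
    while (length(frontier)) {
      dd <- dd + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      if (!length(nxt)) break
      D[s, nxt] <- dd
      frontier <- nxt
    }
  }
  D
}

#' Intramolecular energy of a conformation
#'
#' Sum of (a) 6-12 van der Waals over heavy-atom pairs at bond-path
#' distance >= 3, (b) Coulomb with eps(r) = 3r over the same pairs, (c) a
#' 3-fold torsional potential V3/2 (1 + cos 3 phi) over the rotatable
#' torsions, and (d) a hydrophobic exposure penalty
#' -sum S(i) Etr(i) recomputed from the conformation's accessible
#' surfaces (exposed apolar surface raises the energy, favoring compact
#' shapes that bury apolar atoms).
#'
#' @param mol a [ParameterizedMolecule-class] (provides parameters, bonds,
#'   torsions)
#' @param xyz optional n x 3 coordinates overriding the molecule's own.
#' @param ff force-field constants from [forceFieldParams()].
#' @return list with components \code{vdw}, \code{electrostatic},
#'   \code{torsional}, \code{hydrophobic}, \code{total} (kJ/mol).
#' @export
intramolecularEnergy <- function(mol, xyz = NULL, ff = forceFieldParams()) {
  a <- atoms(mol)
  if (is.null(xyz)) xyz <- coords(mol)
  n <- nrow(a)
  D <- .bondDistances(n, bonds(mol))
  evdw <- eel <- 0
  hv <- which(a$heavy)
  if (length(hv) > 1) {
    for (ii in seq_along(hv)[-length(hv)]) {
      i <- hv[ii]
      for (j in hv[(ii + 1):length(hv)]) {
        if (D[i, j] < 3) next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        evdw <- evdw + .vdw612(d, a$radius[i] + a$radius[j], ff$epsVdw)
        eel <- eel + .coulomb(d, a$charge[i], a$charge[j],
                              ff$dielectricFactor)
      }
    }
  }
  etor <- 0
  tq <- rotatableTorsions(mol)
  if (nrow(tq)) {
    for (r in seq_len(nrow(tq))) {
      phi <- .dihedral(xyz[tq[r, 1], ], xyz[tq[r, 2], ],
                       xyz[tq[r, 3], ], xyz[tq[r, 4], ])
      etor <- etor + ff$torsionBarrier / 2 * (1 + cos(3 * .deg2rad(phi)))
    }
  }
  S <- accessibleSurface(xyz, a$radius)
  ehyd <- -sum(S * a$etr)
  list(vdw = evdw, electrostatic = eel, torsional = etor,
       hydrophobic = ehyd, total = evdw + eel + etor + ehyd)
}

# TRUE if any non-bonded pair (bond-path distance >= 3, or disconnected)
# is closer than clashFactor * (r_i + r_j).
.hasClash <- function(xyz, radii, D, clashFactor) {
  n <- nrow(xyz)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (D[i, j] < 3) next
      if (sum((xyz[i, ] - xyz[j, ])^2) <
          (clashFactor * (radii[i] + radii[j]))^2)
        return(TRUE)
    }
  }
  FALSE
}
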