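# Geometry helpers and seeded-RNG plumbing shared across modules.

.deg2rad <- function(d) d * pi / 180

#' Rotation matrices about the coordinate axes
#'
#' @param deg angle in degrees
#' @return 3x3 rotation matrix
#' @keywords internal
rotX <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' @rdname rotX
#' @keywords internal
rotY <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' @rdname rotX
#' @keywords internal
rotZ <- function(deg) {
  a <- .deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rigid transforms
#'
#' A rigid transform is a list with a 3x3 proper rotation \code{rotation}
#' and a length-3 \code{translation}; points transform as
#' \code{x' = rotation \%*\% x + translation}.
#'
#' @param rotation 3x3 rotation matrix
#' @param translation length-3 numeric
#' @return a \code{rigidTransform} list
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)),
            length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-6 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be a proper rotation matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigidTransform")
}

#' Apply a rigid transform to an n x 3 coordinate matrix
#'
#' @param xyz n x 3 matrix of coordinates
#' @param tf a [rigidTransform()]
#' @return transformed n x 3 matrix
#' @export
applyTransform <- function(xyz, tf) {
  stopifnot(inherits(tf, "rigidTransform"))
  sweep(xyz %*% t(tf$rotation), 2, -tf$translation)
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(a, b)} applies \code{b} first, then \code{a}.
#'
#' @param a,b,tf rigid transforms
#' @return a rigid transform
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a$rotation %*% b$rotation,
                 as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(tf) {
  rigidTransform(t(tf$rotation),
                 as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' Apply a rigid transform to a molecule
#'
#' @param mol a [ParameterizedMolecule-class]
#' @param tf a [rigidTransform()]
#' @return the molecule with transformed coordinates
#' @export
transformMolecule <- function(mol, tf) {
  coords(mol) <- applyTransform(coords(mol), tf)
  mol
}

# Rotation taking unit vector u onto unit vector v (Rodrigues).
.rotationBetween <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees: rotate about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(2 * tcrossprod(ax) - diag(3))
  }
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- matrix(c(0, w[3], -w[2], -w[3], 0, w[1], w[2], -w[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# Dihedral angle (degrees, in (-180, 180]) of points p1-p2-p3-p4.
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Run expr with a locally seeded RNG, restoring global .Random.seed after.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
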