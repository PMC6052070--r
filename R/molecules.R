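# Structure input and per-atom physicochemical parameterization.
#
# Atoms carry four parameters used by every downstream module: partial
# charge, an atomic transfer energy per unit surface (the hydrophobicity
# scale; negative = apolar), a van der Waals radius and the solvent
# accessible surface computed from the input conformation.

#' Built-in per-element parameter table
#'
#' Reads the editable CSV parameter table shipped with the package
#' (columns \code{element}, \code{etr} in kJ/(mol A^2), \code{radius} in
#' Angstrom, \code{charge} default). The transfer-energy scale follows the
#' convention that apolar atoms (C, S) are negative and polar atoms (O, N)
#' positive; it can be replaced wholesale by passing your own table to
#' [readStructure()].
#'
#' @param path optional path to an alternative parameter CSV.
#' @return data.frame with one row per element.
#' @export
defaultAtomParams <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_params.csv", package = "frondosim")
  # na.strings = "" so the sodium row ("NA") survives parsing
  p <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("element", "etr", "radius")
  if (!all(need %in% names(p)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  if (is.null(p$charge)) p$charge <- 0
  p$element <- toupper(p$element)
  p
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
.spherePoints <- function(n = 242L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface per atom
#'
#' Deterministic Shrake-Rupley style estimate: each atom's sphere is
#' inflated by the probe radius and covered with a fixed Fibonacci point
#' set; the accessible fraction is the fraction of points not buried inside
#' any other inflated sphere.
#'
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param radii length-n van der Waals radii, Angstrom.
#' @param probe probe radius, Angstrom (water, 1.4).
#' @param nPoints sphere points per atom.
#' @return numeric vector of accessible surfaces, A^2.
#' @export
accessibleSurface <- function(xyz, radii, probe = 1.4, nPoints = 242L) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3, length(radii) == nrow(xyz))
  n <- nrow(xyz)
  sp <- .spherePoints(nPoints)
  r_ext <- radii + probe
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sp * r_ext[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      if (sum((xyz[i, ] - xyz[j, ])^2) >= (r_ext[i] + r_ext[j])^2) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      free <- free & (d2 > r_ext[j]^2)
      if (!any(free)) break
    }
    out[i] <- 4 * pi * r_ext[i]^2 * mean(free)
  }
  out
}

# Bond auto-detection: pairs closer than 0.6 x sum of vdW radii.
.autoBonds <- function(xyz, radii) {
  n <- nrow(xyz)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2) return(out)
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(radii, radii, "+") * 0.6
  idx <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2)
}

.buildMolecule <- function(name, at, bonds, torsions, probe = 1.4) {
  xyz <- as.matrix(at[, c("x", "y", "z")])
  at$surface <- accessibleSurface(xyz, at$radius, probe = probe)
  at$heavy <- toupper(at$element) != "H"
  if (identical(bonds, "auto")) bonds <- .autoBonds(xyz, at$radius)
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (is.null(torsions)) torsions <- matrix(integer(0), ncol = 4)
  torsions <- matrix(as.integer(torsions), ncol = 4)
  new("ParameterizedMolecule", molName = name,
      atoms = at[, .atom_cols], bonds = bonds, torsions = torsions)
}

#' Read a molecular structure and assign per-atom parameters
#'
#' Accepts PDB-format coordinates (ATOM/HETATM records, read through
#' \pkg{bio3d}) or an atom-table CSV with columns \code{name},
#' \code{element}, \code{x}, \code{y}, \code{z} and optional per-atom
#' \code{charge}, \code{etr}, \code{radius} overriding the per-element
#' defaults of the parameter table. Every atom must resolve to a parameter
#' row; unknown elements raise an error naming the offending atom.
#' The accessible surface of every atom is computed once from the input
#' conformation.
#'
#' @param source path to a .pdb or .csv file, or a data.frame in the
#'   atom-table layout.
#' @param params parameter table (data.frame or CSV path); defaults to
#'   [defaultAtomParams()].
#' @param bonds two-column index matrix, \code{"auto"} for distance-based
#'   detection, or NULL for none.
#' @param torsions four-column index matrix of rotatable torsions, or NULL.
#' @param name molecule name; defaults to the file base name.
#' @param probe solvent probe radius for the surface computation, Angstrom.
#' @return a [ParameterizedMolecule-class]
#' @export
readStructure <- function(source, params = defaultAtomParams(), bonds = NULL,
                          torsions = NULL, name = NULL, probe = 1.4) {
  if (is.character(params)) params <- defaultAtomParams(params)
  params <- as.data.frame(params)
  if (!all(c("element", "etr", "radius") %in% names(params)))
    stop("parameter table must have columns element, etr, radius")
  if (is.null(params$charge)) params$charge <- 0
  params$element <- toupper(params$element)
  if (is.data.frame(source)) {
    tab <- source
    if (is.null(name)) name <- "molecule"
  } else {
    stopifnot(is.character(source), length(source) == 1)
    if (!file.exists(source)) stop("file not found: ", source)
    if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(source))
    if (grepl("\\.pdb$", source, ignore.case = TRUE)) {
      pdb <- tryCatch(bio3d::read.pdb(source),
                      error = function(e) stop("PDB parse error in '", source,
                                               "': ", conditionMessage(e)))
      a <- pdb$atom
      ele <- a$elesy
      if (is.null(ele) || all(is.na(ele)) || all(ele == ""))
        ele <- substr(trimws(a$elety), 1, 1)
      ele[is.na(ele) | ele == ""] <- substr(trimws(a$elety), 1, 1)[is.na(ele) | ele == ""]
      tab <- data.frame(name = trimws(a$elety), element = trimws(ele),
                        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    } else {
      tab <- tryCatch(read.csv(source, stringsAsFactors = FALSE,
                               na.strings = ""),
                      error = function(e) stop("CSV parse error in '", source,
                                               "': ", conditionMessage(e)))
    }
  }
  need <- c("name", "element", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("atom table lacks column(s): ", paste(miss, collapse = ", "))
  tab$element <- toupper(trimws(tab$element))
  m <- match(tab$element, params$element)
  fill <- function(col) {
    v <- if (col %in% names(tab)) tab[[col]] else rep(NA_real_, nrow(tab))
    v <- as.numeric(v)
    take <- is.na(v)
    v[take] <- params[[col]][m[take]]
    v
  }
  at <- data.frame(name = as.character(tab$name), element = tab$element,
                   x = as.numeric(tab$x), y = as.numeric(tab$y),
                   z = as.numeric(tab$z),
                   charge = fill("charge"), etr = fill("etr"),
                   radius = fill("radius"), stringsAsFactors = FALSE)
  bad <- which(!is.finite(at$etr) | !is.finite(at$radius) |
                 !is.finite(at$charge))
  if (length(bad))
    stop("cannot parameterize atom ", bad[1], " ('", at$name[bad[1]],
         "', element '", at$element[bad[1]], "'): no parameter row")
  .buildMolecule(name, at, bonds, torsions, probe = probe)
}

#' Write a molecule as PDB-format coordinates
#'
#' Emits HETATM records (coordinates and element symbols only), suitable
#' for visualizing oriented structures or best insertion poses.
#'
#' @param mol a [ParameterizedMolecule-class]
#' @param path output file path
#' @return invisibly, the path
#' @export
writeStructurePDB <- function(mol, path) {
  a <- atoms(mol)
  lines <- sprintf(
    "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), substr(a$name, 1, 4), "LIG", 1L,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write a conformer list as CSV
#'
#' One row per conformer: torsion offsets (degrees) and the intramolecular
#' energy score, sorted as returned by [enumerateConformations()].
#'
#' @param conformers a \code{ConformerSet}
#' @param path output file path
#' @return invisibly, the path
#' @export
writeConformersCSV <- function(conformers, path) {
  df <- as.data.frame(conformers)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
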