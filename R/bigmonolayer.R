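# The lattice monolayer ("big monolayer") simulation: a grid of molecules,
# one per cell, minimized by Kawasaki-exchange Monte Carlo under the
# pairwise interaction matrix.

#' Monolayer composition
#'
#' Named molar fractions of the molecule types occupying the lattice.
#' Fractions must be non-negative and sum to 1 (within 1e-9).
#'
#' @param ... named fractions, e.g. \code{DMPC = 0.67, CHOL = 0.23,
#'   SAP = 0.10}, or a single named numeric vector.
#' @return a named numeric vector of class \code{monolayerComposition}
#' @export
monolayerComposition <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all fractions must be named")
  if (any(x < 0)) stop("fractions must be >= 0")
  if (abs(sum(x) - 1) > 1e-9) stop("fractions must sum to 1")
  structure(as.numeric(x), names = names(x),
            class = "monolayerComposition")
}

#' Named composition presets
#'
#' Two ternary DMPC/sterol/saponin compositions are in common use for this
#' system: 67/23/10 (the default here) and 63/27/10. Both are shipped;
#' pick with \code{preset}.
#'
#' @param preset \code{"67-23-10"} or \code{"63-27-10"}.
#' @param sterol name to give the sterol type (e.g. \code{"CHOL"} or
#'   \code{"D7"}).
#' @param saponin name of the saponin type.
#' @return a [monolayerComposition()]
#' @export
compositionPreset <- function(preset = c("67-23-10", "63-27-10"),
                              sterol = "CHOL", saponin = "SAP") {
  preset <- match.arg(preset)
  f <- if (preset == "67-23-10") c(0.67, 0.23, 0.10) else c(0.63, 0.27, 0.10)
  monolayerComposition(setNames(f, c("DMPC", sterol, saponin)))
}

#' Default display palette for known molecule types
#'
#' Cholesterol yellow, DMPC teal, saponin red, the bent sterol green;
#' unknown types get colors from the R palette.
#'
#' @param types character vector of type names.
#' @return named character vector of colors.
#' @export
defaultPalette <- function(types) {
  known <- c(DMPC = "#008080", CHOL = "#FFD700", SAP = "#FF0000",
             D7 = "#00A000", STEROL = "#FFD700", FRO = "#FF0000")
  out <- known[types]
  miss <- is.na(out)
  if (any(miss))
    out[miss] <- grDevices::palette.colors(sum(miss) + 1)[-1]
  names(out) <- types
  out
}

#' Initialize a monolayer lattice at a given composition
#'
#' Type counts are \code{round(fraction * side^2)} with largest-remainder
#' correction so they sum exactly to \code{side^2}; placement is a seeded
#' uniform shuffle. A declared type whose count rounds to zero triggers a
#' warning.
#'
#' @param comp a [monolayerComposition()].
#' @param side lattice side length (>= 2); the classic monolayer grid is
#'   200.
#' @param seed integer seed for the shuffle.
#' @param M optional [InteractionMatrix-class]; if supplied the initial
#'   energy is computed (periodic boundary), otherwise it is NA until the
#'   state is scored.
#' @param palette display colors; defaults to [defaultPalette()].
#' @return a [LatticeState-class]
#' @export
initLattice <- function(comp, side = 200L, seed = 1L, M = NULL,
                        palette = defaultPalette(names(comp))) {
  stopifnot(side >= 2)
  side <- as.integer(side)
  types <- names(comp)
  ncell <- side * side
  exact <- as.numeric(comp) * ncell
  counts <- floor(exact)
  rem <- ncell - sum(counts)
  if (rem > 0) {
    ord <- order(exact - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  if (any(counts == 0 & as.numeric(comp) > 0))
    warning("type(s) ", paste(types[counts == 0 & comp > 0], collapse = ", "),
            " round to zero cells at side ", side)
  codes <- rep(seq_along(types), counts)
  grid <- matrix(.withSeed(seed, sample(codes)), side, side)
  storage.mode(grid) <- "integer"
  energy <- NA_real_
  state <- new("LatticeState", grid = grid, types = types,
               palette = palette, seed = as.integer(seed), energy = energy)
  if (!is.null(M)) state@energy <- latticeEnergy(state, M)
  state
}

# Interaction matrix reindexed to the state's type order.
.matrixForState <- function(state, M) {
  idx <- match(moleculeTypes(state), moleculeTypes(M))
  if (anyNA(idx))
    stop("type(s) missing from interaction matrix: ",
         paste(moleculeTypes(state)[is.na(idx)], collapse = ", "))
  energies(M)[idx, idx, drop = FALSE]
}

#' Total lattice energy under an interaction matrix
#'
#' Sum over unordered nearest-neighbor pairs (4-neighborhood) of the
#' coupling between the occupying types, with periodic (default) or
#' clipped boundary.
#'
#' @param state a [LatticeState-class].
#' @param M an [InteractionMatrix-class] covering every type on the grid.
#' @param boundary \code{"periodic"} or \code{"clipped"}.
#' @return energy in kJ/mol
#' @export
latticeEnergy <- function(state, M, boundary = c("periodic", "clipped")) {
  boundary <- match.arg(boundary)
  E <- .matrixForState(state, M)
  .lattice_energy_cpp(latticeGrid(state) - 1L, E, boundary == "periodic")
}

#' Monte Carlo schedule
#'
#' Defines the exchange count, the (annealing) temperature protocol and
#' the move set of [mcMinimize()]. Temperatures are expressed through a
#' dimensionless inverse temperature beta = 1/(scale * T): the interaction
#' matrix carries coarse per-heavy-atom energies, so only the ratio of
#' couplings to scale*T matters; with \code{scale = 1} temperatures are in
#' the same (kJ/mol) units as the couplings. \code{tHot > tCold} gives a
#' geometric annealing schedule ("minimization"); \code{tCold = tHot}
#' samples at fixed temperature.
#'
#' @param nSteps number of proposed exchanges (>= 0).
#' @param tHot starting temperature (>= 0; 0 means downhill-only).
#' @param tCold final temperature; defaults to \code{tHot}.
#' @param scale energy-per-temperature conversion factor.
#' @param seed integer RNG seed.
#' @param nSnapshots number of trajectory snapshots to record.
#' @param moveMode \code{"global"} (any two sites exchange; fast
#'   equilibration) or \code{"neighbor"} (adjacent exchanges; kinetic
#'   realism).
#' @param boundary \code{"periodic"} or \code{"clipped"}.
#' @param sampleEvery if > 0, record an encoded copy of the grid every
#'   this many steps (tiny lattices only; used for distribution tests).
#' @return an \code{mcSchedule} list
#' @export
mcSchedule <- function(nSteps, tHot = 1, tCold = tHot, scale = 1, seed = 1L,
                       nSnapshots = 10L, moveMode = c("global", "neighbor"),
                       boundary = c("periodic", "clipped"),
                       sampleEvery = 0L) {
  moveMode <- match.arg(moveMode)
  boundary <- match.arg(boundary)
  if (nSteps < 0) stop("nSteps must be >= 0")
  if (tHot < 0 || tCold < 0) stop("temperature must be >= 0")
  beta <- function(T) if (T == 0) Inf else 1 / (scale * T)
  structure(list(nSteps = nSteps, tHot = tHot, tCold = tCold,
                 scale = scale, beta0 = beta(tHot), beta1 = beta(tCold),
                 seed = as.integer(seed), nSnapshots = as.integer(nSnapshots),
                 moveMode = moveMode, boundary = boundary,
                 sampleEvery = as.integer(sampleEvery)),
            class = "mcSchedule")
}

#' Minimize / sample a lattice by Kawasaki-exchange Monte Carlo
#'
#' Repeatedly proposes the exchange of two sites of different type and
#' accepts with the Metropolis rule at the schedule's (annealed) inverse
#' temperature. Composition is conserved exactly by construction; the
#' energy is tracked incrementally and matches a full recomputation to
#' rounding error. Fully seeded: identical state + schedule give
#' bit-identical trajectories.
#'
#' @param state a [LatticeState-class].
#' @param M an [InteractionMatrix-class].
#' @param sched an [mcSchedule()].
#' @return an \code{mcTrajectory}: list with \code{trajectory} (list of
#'   [LatticeState-class] snapshots, final state last), \code{finalState},
#'   \code{energyTrace} (data.frame step/energy), \code{acceptanceRate},
#'   and \code{samples} (encoded tiny-grid states, if requested).
#' @export
mcMinimize <- function(state, M, sched) {
  stopifnot(inherits(sched, "mcSchedule"))
  E <- .matrixForState(state, M)
  grid0 <- latticeGrid(state)
  nt <- length(moleculeTypes(state))
  if (sched$sampleEvery > 0 &&
      length(grid0) * log2(max(nt, 2)) > 30)
    stop("sampleEvery is only supported for tiny lattices")
  if (sched$nSteps == 0 || nt == 1L || length(unique(as.vector(grid0))) == 1L) {
    state@energy <- latticeEnergy(state, M, sched$boundary)
    return(structure(list(trajectory = list(state), finalState = state,
                          energyTrace = data.frame(step = 0,
                                                   energy = state@energy),
                          acceptanceRate = NA_real_,
                          samples = integer(0)),
                     class = "mcTrajectory"))
  }
  res <- .mc_lattice_cpp(grid0 - 1L, E, as.double(sched$nSteps),
                         sched$beta0, sched$beta1, sched$seed,
                         sched$nSnapshots,
                         sched$boundary == "periodic",
                         sched$moveMode == "global",
                         sched$sampleEvery)
  mkState <- function(g, e) {
    s <- state
    s@grid <- g + 1L
    s@energy <- e
    s@seed <- sched$seed
    s
  }
  traj <- mapply(mkState, res$snapshots, res$snapshotEnergies,
                 SIMPLIFY = FALSE)
  final <- mkState(res$grid, res$energy)
  if (!length(traj) ||
      !identical(traj[[length(traj)]]@grid, final@grid))
    traj <- c(traj, list(final))
  structure(list(trajectory = traj, finalState = final,
                 energyTrace = data.frame(step = c(res$snapshotSteps),
                                          energy = c(res$snapshotEnergies)),
                 acceptanceRate = res$accepted / sched$nSteps,
                 samples = res$samples),
            class = "mcTrajectory")
}

#' @export
print.mcTrajectory <- function(x, ...) {
  cat(sprintf("mcTrajectory: %d snapshots, acceptance %.3f, final energy %.2f kJ/mol\n",
              length(x$trajectory), x$acceptanceRate,
              latticeEnergyValue(x$finalState)))
  invisible(x)
}

#' Render a lattice as a raster image
#'
#' One pixel per molecule with a deterministic color per type. Optionally
#' writes a PNG and/or a plain-text grid (which round-trips through
#' [readLatticeGrid()] to an identical grid).
#'
#' @param state a [LatticeState-class].
#' @param palette named colors covering all types; defaults to the
#'   state's palette.
#' @param pngFile optional PNG output path.
#' @param gridFile optional text-grid output path.
#' @return invisibly, the side x side x 3 RGB array in [0, 1].
#' @export
renderLattice <- function(state, palette = typePalette(state),
                          pngFile = NULL, gridFile = NULL) {
  types <- moleculeTypes(state)
  if (!all(types %in% names(palette)))
    stop("palette lacks entries for: ",
         paste(setdiff(types, names(palette)), collapse = ", "))
  g <- latticeGrid(state)
  rgb <- grDevices::col2rgb(palette[types]) / 255
  img <- array(0, c(nrow(g), ncol(g), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[ch, g], nrow(g), ncol(g))
  if (!is.null(pngFile)) png::writePNG(img, pngFile)
  if (!is.null(gridFile)) writeLatticeGrid(state, gridFile)
  invisible(img)
}

#' Write/read a lattice grid as plain text
#'
#' Two header lines (type names, seed) followed by one line of 1-based
#' type codes per grid row. The round trip preserves the grid exactly.
#'
#' @param state a [LatticeState-class]
#' @param path file path
#' @return \code{writeLatticeGrid}: invisibly, the path;
#'   \code{readLatticeGrid}: a [LatticeState-class] (energy NA).
#' @export
writeLatticeGrid <- function(state, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("types:", paste(moleculeTypes(state), collapse = " ")),
             con)
  writeLines(paste("seed:", state@seed), con)
  g <- latticeGrid(state)
  writeLines(apply(g, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname writeLatticeGrid
#' @export
readLatticeGrid <- function(path) {
  lines <- readLines(path)
  types <- strsplit(sub("^types: *", "", lines[1]), " +")[[1]]
  seed <- as.integer(sub("^seed: *", "", lines[2]))
  rows <- lapply(strsplit(lines[-(1:2)], " +"), as.integer)
  g <- do.call(rbind, rows)
  storage.mode(g) <- "integer"
  new("LatticeState", grid = g, types = types,
      palette = defaultPalette(types), seed = seed, energy = NA_real_)
}
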