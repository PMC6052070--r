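zeroMatrix <- function(types = c("A", "B"))
  interactionMatrix(types, matrix(0, length(types), length(types)))

test_that("initLattice realizes exact counts and a homogeneous energy", {
  M <- interactionMatrix("A", matrix(-2, 1, 1))
  st <- initLattice(monolayerComposition(A = 1), side = 10, seed = 1, M = M)
  expect_equal(unname(typeCounts(st)), 100L)
  # periodic 10x10: 2 * side^2 neighbor pairs
  expect_equal(latticeEnergyValue(st), 200 * -2)
  st2 <- initLattice(monolayerComposition(A = 0.5, B = 0.5), side = 10,
                     seed = 3)
  expect_equal(unname(typeCounts(st2)), c(50L, 50L))
})

test_that("largest-remainder rounding conserves the cell count", {
  comp <- monolayerComposition(A = 1 / 3, B = 1 / 3, C = 1 / 3)
  st <- initLattice(comp, side = 10, seed = 1)
  expect_equal(sum(typeCounts(st)), 100L)
  expect_true(all(abs(typeCounts(st) - 100 / 3) < 1))
  expect_warning(initLattice(monolayerComposition(A = 0.999, B = 0.001),
                             side = 3, seed = 1), "zero cells")
})

test_that("lattice initialization is seeded and deterministic", {
  comp <- monolayerComposition(A = 0.5, B = 0.5)
  s1 <- initLattice(comp, side = 10, seed = 7)
  s2 <- initLattice(comp, side = 10, seed = 7)
  s3 <- initLattice(comp, side = 10, seed = 8)
  expect_identical(latticeGrid(s1), latticeGrid(s2))
  expect_false(identical(latticeGrid(s1), latticeGrid(s3)))
  expect_equal(typeCounts(s1), typeCounts(s3))
})

test_that("lattice energy matches hand-counted neighbor pairs", {
  M <- interactionMatrix("A", matrix(-1.5, 1, 1))
  g <- matrix(1L, 2, 2)
  st <- new("LatticeState", grid = g, types = "A", palette = c(A = "red"),
            seed = 1L, energy = NA_real_)
  # 2x2 periodic: each cell has a right and down bond (wrapped) -> 8 pairs
  expect_equal(latticeEnergy(st, M), 8 * -1.5)
  expect_equal(latticeEnergy(st, zeroMatrix("A")), 0)
  # clipped 2x2: only 4 physical bonds
  expect_equal(latticeEnergy(st, M, boundary = "clipped"), 4 * -1.5)
})

test_that("lattice energy is invariant under transpose for symmetric M", {
  M <- interactionMatrix(c("A", "B"),
                         matrix(c(-1, 0.4, 0.4, -0.2), 2, 2))
  st <- initLattice(monolayerComposition(A = 0.4, B = 0.6), side = 8,
                    seed = 5)
  tr <- st
  tr@grid <- t(latticeGrid(st))
  expect_equal(latticeEnergy(st, M), latticeEnergy(tr, M))
  expect_error(latticeEnergy(st, zeroMatrix(c("A", "X"))), "missing")
})

test_that("null couplings give free dynamics that conserve composition", {
  st <- initLattice(monolayerComposition(A = 0.5, B = 0.5), side = 10,
                    seed = 2)
  tr <- mcMinimize(st, zeroMatrix(), mcSchedule(2e4, tHot = 5, seed = 3))
  expect_gt(tr$acceptanceRate, 0.999)
  expect_equal(typeCounts(tr$finalState), typeCounts(st))
})

test_that("composition is conserved and energy bookkeeping is exact over 1e6 moves", {
  M <- interactionMatrix(c("A", "B"),
                         matrix(c(-1, 0.2, 0.2, -0.6), 2, 2))
  st <- initLattice(monolayerComposition(A = 0.3, B = 0.7), side = 50,
                    seed = 11, M = M)
  tr <- mcMinimize(st, M, mcSchedule(1e6, tHot = 1.5, tCold = 0.2,
                                     seed = 4, nSnapshots = 5))
  for (s in tr$trajectory)
    expect_equal(typeCounts(s), typeCounts(st))
  efinal <- latticeEnergyValue(tr$finalState)
  erecomp <- latticeEnergy(tr$finalState, M)
  expect_lt(abs(efinal - erecomp) / abs(erecomp), 1e-6)
})

test_that("identical seeds give bit-identical trajectories", {
  M <- interactionMatrix(c("A", "B"),
                         matrix(c(-1, 0, 0, -1), 2, 2))
  st <- initLattice(monolayerComposition(A = 0.5, B = 0.5), side = 20,
                    seed = 9)
  t1 <- mcMinimize(st, M, mcSchedule(5e4, tHot = 1, tCold = 0.1, seed = 21))
  t2 <- mcMinimize(st, M, mcSchedule(5e4, tHot = 1, tCold = 0.1, seed = 21))
  t3 <- mcMinimize(st, M, mcSchedule(5e4, tHot = 1, tCold = 0.1, seed = 22))
  expect_identical(latticeGrid(t1$finalState), latticeGrid(t2$finalState))
  expect_false(identical(latticeGrid(t1$finalState),
                         latticeGrid(t3$finalState)))
})

test_that("cohesive couplings coarsen domains from a random start", {
  M <- interactionMatrix(c("A", "B"),
                         matrix(c(-2, 0, 0, 0), 2, 2))
  st <- initLattice(monolayerComposition(A = 0.3, B = 0.7), side = 50,
                    seed = 13)
  meanA <- function(s) domainStats(labelDomains(s, "A",
                                                connectivity = 4))$meanSize
  tr <- mcMinimize(st, M, mcSchedule(8e5, tHot = 0.8, tCold = 0.05,
                                     seed = 5))
  expect_gt(meanA(tr$finalState), meanA(st))
})

test_that("fixed-temperature sampling matches the exact Boltzmann law on 3x3", {
  M <- interactionMatrix(c("A", "B"),
                         matrix(c(-1, 0.3, 0.3, -0.5), 2, 2))
  st <- initLattice(monolayerComposition(A = 4 / 9, B = 5 / 9), side = 3,
                    seed = 2)
  tr <- mcMinimize(st, M, mcSchedule(2e6, tHot = 1, tCold = 1, seed = 7,
                                     sampleEvery = 20, nSnapshots = 2))
  # exact enumeration over all C(9,4) arrangements, periodic boundary
  combs <- utils::combn(9, 4)
  codes <- numeric(ncol(combs))
  energ <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    g <- matrix(2L, 3, 3)
    g[combs[, i]] <- 1L
    s <- new("LatticeState", grid = g, types = c("A", "B"),
             palette = c(A = "x", B = "y"), seed = 1L, energy = 0)
    energ[i] <- latticeEnergy(s, M)
    code <- 0
    for (cc in 1:3) for (rr in 1:3) code <- code * 2 + (g[rr, cc] - 1L)
    codes[i] <- code
  }
  p <- exp(-energ / 1) # beta = 1/(scale*T) = 1
  p <- p / sum(p)
  counts <- table(factor(tr$samples, levels = codes))
  expect_equal(sum(counts), length(tr$samples)) # all states reachable
  chi <- suppressWarnings(stats::chisq.test(as.vector(counts), p = p))
  expect_gt(chi$p.value, 0.01)
})

test_that("schedule validation and degenerate lattices", {
  expect_error(mcSchedule(1000, tHot = -1), "temperature")
  expect_error(mcSchedule(-5), "nSteps")
  M <- interactionMatrix("A", matrix(-1, 1, 1))
  st <- initLattice(monolayerComposition(A = 1), side = 5, seed = 1)
  tr <- mcMinimize(st, M, mcSchedule(1000, tHot = 1, seed = 1))
  expect_identical(latticeGrid(tr$finalState), latticeGrid(st))
  expect_equal(length(tr$trajectory), 1L)
})

test_that("rendering is deterministic and the text grid round-trips", {
  st <- initLattice(monolayerComposition(A = 0.25, B = 0.25, C = 0.25,
                                         D = 0.25), side = 2, seed = 1)
  img <- renderLattice(st)
  pix <- apply(img, c(1, 2), paste, collapse = "/")
  expect_equal(length(unique(as.vector(pix))), 4L)
  hom <- initLattice(monolayerComposition(A = 1), side = 4, seed = 1)
  imgh <- renderLattice(hom)
  expect_equal(length(unique(as.vector(
    apply(imgh, c(1, 2), paste, collapse = "/")))), 1L)
  tmp <- withr::local_tempfile(fileext = ".txt")
  writeLatticeGrid(st, tmp)
  back <- readLatticeGrid(tmp)
  expect_identical(latticeGrid(back), latticeGrid(st))
  expect_identical(moleculeTypes(back), moleculeTypes(st))
  expect_error(renderLattice(st, palette = c(A = "red")), "palette")
  png <- withr::local_tempfile(fileext = ".png")
  renderLattice(st, pngFile = png)
  expect_true(file.exists(png))
})
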