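test_that("pair energy decays to zero at large separation", {
  a <- singleAtom("C")
  b <- singleAtom("C")
  e <- pairEnergy(a, b, rigidTransform(diag(3), c(100, 0, 0)))
  expect_lt(abs(e$vdw), 1e-6)
  expect_equal(e$electrostatic, 0)
  expect_equal(e$hydrophobic, 0)
  expect_equal(e$total, e$vdw + e$electrostatic + e$hydrophobic)
})

test_that("electrostatics match the closed-form Coulomb with eps(r) = 3r", {
  plus <- singleAtom("O", charge = 1)
  minus <- singleAtom("O", charge = -1)
  e <- pairEnergy(plus, minus, rigidTransform(diag(3), c(5, 0, 0)))
  # KE q1 q2 / (3 r * r) at r = 5
  expect_equal(e$electrostatic, 1389.35458 * (1) * (-1) / (3 * 5^2),
               tolerance = 1e-12)
  expect_lt(e$electrostatic, 0)
})

test_that("pair energy is symmetric under role exchange", {
  a <- orientedFixture("cholesterol_like")
  b <- orientedFixture("frondoside_like")
  tf <- rigidTransform(rotZ(40), c(5, 1, -0.5))
  e1 <- pairEnergy(a, b, tf)
  e2 <- pairEnergy(b, a, invertTransform(tf))
  expect_equal(e1$total, e2$total, tolerance = 1e-9)
  expect_equal(e1$vdw, e2$vdw, tolerance = 1e-9)
  expect_equal(e1$hydrophobic, e2$hydrophobic, tolerance = 1e-9)
})

test_that("overlapping poses are rejected with sentinel energy", {
  a <- singleAtom("C")
  e <- pairEnergy(a, a, rigidTransform(diag(3), c(0.5, 0, 0)))
  expect_true(e$clash)
  expect_identical(e$total, Inf)
})

test_that("dockPair equals an independent brute-force enumeration", {
  a <- singleAtom("C")
  b <- singleAtom("C")
  grid <- dockGrid()
  res <- dockPair(a, b, grid)
  expect_equal(res$gridCardinality, grid$cardinality)
  # independent oracle: explicit loops, energies written from the formulas
  ff <- forceFieldParams()
  ra <- atoms(a)$radius; rb <- atoms(b)$radius
  Sa <- atoms(a)$surface; Sb <- atoms(b)$surface
  ea <- atoms(a)$etr; eb <- atoms(b)$etr
  oracle <- expand.grid(dist = grid$dist, azimuth = grid$azimuth,
                        rotation = grid$rotation, dz = grid$dzOffset)
  oracle$total <- NA_real_
  for (i in seq_len(nrow(oracle))) {
    d <- sqrt(oracle$dist[i]^2 + oracle$dz[i]^2) # both atoms at origin
    if (d < ff$clashFactor * (ra + rb)) next
    rm6 <- ((ra + rb) / d)^6
    vdw <- ff$epsVdw * (rm6^2 - 2 * rm6)
    pho <- if (d < ra + rb + ff$contactProbe)
      -ff$hydrophobicWeight * (Sa * abs(ea) + Sb * abs(eb)) else 0
    oracle$total[i] <- vdw + pho
  }
  keep <- !is.na(oracle$total)
  expect_equal(res$nClash, sum(!keep))
  ord <- order(oracle$total[keep])
  expect_equal(res$poses$total, oracle$total[keep][ord], tolerance = 1e-12)
  # best pose found by the package equals the oracle's best
  expect_equal(res$poses$dist[1], oracle$dist[keep][ord][1])
  expect_equal(res$poses$dz[1], oracle$dz[keep][ord][1])
})

test_that("self-docking of a symmetric diatomic is role-invariant", {
  m <- quickMol("C", x = c(-0.9, 0.9))
  r1 <- dockPair(m, m)
  r2 <- dockPair(m, m)
  expect_equal(r1$poses$total[1], r2$poses$total[1])
})

test_that("refining the docking grid never worsens the best energy", {
  fro <- orientedFixture("frondoside_like")
  chol <- orientedFixture("cholesterol_like")
  coarse <- dockGrid(dist = seq(3, 10, 2), azimuth = seq(0, 270, 90),
                     rotation = 0, dzOffset = 0)
  fine <- dockGrid(dist = seq(3, 10, 1), azimuth = seq(0, 315, 45),
                   rotation = c(0, 180), dzOffset = c(-1, 0))
  eC <- dockPair(fro, chol, coarse)$poses$total[1]
  eF <- dockPair(fro, chol, fine)$poses$total[1]
  expect_lte(eF, eC)
})

test_that("saponin docking reproduces the lipid-affinity ordering", {
  fro <- orientedFixture("frondoside_like")
  e <- vapply(c("dmpc_like", "cholesterol_like", "delta7_like"),
              function(nm) dockPair(fro, orientedFixture(nm))$
                poses$perHeavyAtom[1], numeric(1))
  expect_lt(e[["dmpc_like"]], e[["cholesterol_like"]])
  expect_lt(e[["cholesterol_like"]], e[["delta7_like"]])
  expect_lt(e[["delta7_like"]], 0)
})

test_that("fixture docking energies are hydrophobically dominated", {
  fro <- orientedFixture("frondoside_like")
  for (nm in c("dmpc_like", "cholesterol_like", "delta7_like")) {
    b <- dockPair(fro, orientedFixture(nm))$poses[1, ]
    expect_gt(abs(b$hydrophobic), abs(b$electrostatic), label = nm)
  }
})

test_that("assembly with one ligand reduces to the best docked pose", {
  a <- singleAtom("C")
  grid <- dockGrid(dist = c(3, 4, 5), azimuth = c(0, 90, 180, 270),
                   rotation = 0, dzOffset = 0)
  asm <- buildAssembly(a, a, n = 1, grid)
  expect_equal(asm$nPlaced, 1L)
  expect_equal(asm$energies[1], dockPair(a, a, grid)$poses$total[1])
})

test_that("a second ligand takes the mirror site and energy is monotone", {
  a <- singleAtom("C")
  grid <- dockGrid(dist = 4, azimuth = c(0, 180), rotation = 0,
                   dzOffset = 0)
  asm <- buildAssembly(a, a, n = 2, grid)
  expect_equal(asm$nPlaced, 2L)
  az <- vapply(asm$placements, function(tf) atan2(tf$translation[2],
                                                  tf$translation[1]),
               numeric(1))
  expect_equal(sort(round(az / pi * 180)) %% 360, c(0, 180))
  expect_true(all(diff(cumsum(asm$energies)) <= 0))
  expect_true(all(asm$energies <= 0))
})

test_that("interaction matrices are symmetric with equal-type degeneracy", {
  m <- quickMol("C", x = c(-0.9, 0.9))
  grid <- dockGrid(dist = c(3.5, 4, 5), azimuth = seq(0, 270, 90),
                   rotation = c(0, 90), dzOffset = 0)
  M <- buildInteractionMatrix(list(A = m, B = m), grid)
  E <- energies(M)
  expect_equal(E, t(E))
  expect_equal(length(unique(round(as.vector(E), 9))), 1L)
})

test_that("docked interaction matrix reproduces the saponin orderings", {
  mols <- list(DMPC = orientedFixture("dmpc_like"),
               CHOL = orientedFixture("cholesterol_like"),
               D7 = orientedFixture("delta7_like"),
               SAP = orientedFixture("frondoside_like"))
  M <- buildInteractionMatrix(mols)
  E <- energies(M)
  expect_equal(E, t(E))
  expect_lt(E["SAP", "DMPC"], E["SAP", "CHOL"])
  expect_lt(E["SAP", "CHOL"], E["SAP", "D7"])
  expect_lt(E["SAP", "D7"], 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeInteractionMatrix(M, tmp)
  back <- readInteractionMatrix(tmp)
  expect_equal(energies(back), E, tolerance = 1e-10)
  expect_equal(moleculeTypes(back), moleculeTypes(M))
})
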