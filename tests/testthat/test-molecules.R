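test_that("readStructure parameterizes a single carbon and preserves order", {
  params <- data.frame(element = "C", etr = -0.105, radius = 1.8,
                       charge = 0)
  mol <- readStructure(data.frame(name = "C1", element = "C",
                                  x = 0, y = 0, z = 0), params = params)
  expect_s4_class(mol, "ParameterizedMolecule")
  expect_equal(heavyAtomCount(mol), 1L)
  a <- atoms(mol)
  expect_equal(a$etr, -0.105)
  expect_equal(a$radius, 1.8)
  # isolated sphere: accessible surface is the full probe-extended sphere
  expect_equal(a$surface, 4 * pi * (1.8 + 1.4)^2, tolerance = 1e-12)
})

test_that("unknown atom types raise a parameterization error naming the atom", {
  params <- data.frame(element = "C", etr = -0.105, radius = 1.8)
  expect_error(
    readStructure(data.frame(name = c("C1", "XX2"),
                             element = c("C", "XX"),
                             x = c(0, 2), y = 0, z = 0), params = params),
    "XX2")
  expect_error(readStructure("/no/such/file.csv"), "not found")
})

test_that("parameter assignment is total for every shipped fixture", {
  for (nm in c("dmpc_like", "cholesterol_like", "delta7_like",
               "frondoside_like")) {
    a <- atoms(fixtureMolecule(nm))
    expect_true(all(is.finite(a$charge)), info = nm)
    expect_true(all(is.finite(a$etr)), info = nm)
    expect_true(all(a$radius > 0), info = nm)
    expect_true(all(a$surface >= 0), info = nm)
  }
})

test_that("heavy atom count matches the non-hydrogen rows of an atom table", {
  path <- test_path("fixtures", "cholesterol_atoms.csv")
  expected <- sum(read.csv(path)$element != "H")
  mol <- readStructure(path)
  expect_equal(heavyAtomCount(mol), expected)
  expect_equal(expected, 27L)
  expect_equal(atomCount(mol), nrow(read.csv(path)))
})

test_that("PDB output round-trips coordinates and atom order", {
  mol <- fixtureMolecule("cholesterol_like")
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePDB(mol, tmp)
  back <- readStructure(tmp)
  expect_equal(unname(coords(back)), unname(coords(mol)), tolerance = 1e-3)
  expect_equal(atoms(back)$element, atoms(mol)$element)
})

test_that("a rigid molecule yields exactly one conformer with input geometry", {
  mol <- quickMol("C", x = c(0, 1.8))
  cs <- enumerateConformations(mol, step = 60)
  expect_equal(length(cs), 1L)
  expect_equal(conformerCoords(cs, 1), coords(mol))
})

test_that("butane-like torsion scan ranks the anti conformer first via vdW", {
  but <- readStructure(
    data.frame(name = paste0("C", 1:4), element = "C",
               x = c(0, 1.54, 2.31, 3.85), y = c(0, 0, 1.33, 1.33),
               z = 0),
    bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
    torsions = rbind(c(1, 2, 3, 4)))
  cs <- enumerateConformations(but, step = 120)
  expect_equal(length(cs), 3L)
  # independent oracle: only the 1-4 pair varies between grid points, so
  # the vdW term (identical torsional/hydrophobic base up to surface
  # changes) must rank the largest 1-4 separation first. The input is the
  # anti geometry (dihedral 180), i.e. offset 0.
  d14 <- vapply(seq_len(3), function(i) {
    xyz <- conformerCoords(cs, i)
    sqrt(sum((xyz[1, ] - xyz[4, ])^2))
  }, numeric(1))
  expect_equal(cs@torsions[which.max(d14), 1], cs@torsions[1, 1])
  expect_equal(cs@torsions[1, 1], 0)
  expect_false(is.unsorted(cs@energies))
})

test_that("torsion grids are exhaustive: kept + clash-rejected = grid size", {
  pent <- readStructure(
    data.frame(name = paste0("C", 1:5), element = "C",
               x = c(0, 1.54, 2.31, 3.85, 4.62),
               y = c(0, 0, 1.33, 1.33, 2.66), z = 0),
    bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)),
    torsions = rbind(c(1, 2, 3, 4), c(2, 3, 4, 5)))
  cs <- enumerateConformations(pent, step = 90)
  expect_equal(cs@gridSize, 16L)
  expect_lte(length(cs), 16L)
  expect_equal(length(cs) + cs@rejected, cs@gridSize)
  expect_gt(cs@rejected, 0) # eclipsed/backfolded grid points clash
  expect_error(enumerateConformations(pent, step = 1, cap = 1e4), "cap")
  expect_error(enumerateConformations(pent, step = 70), "divide")
})

test_that("orientAtInterface aligns a diatomic with the interface normal", {
  mol <- quickMol(c("C", "O"), x = c(0, 1))
  tf <- orientAtInterface(mol)
  xyz <- applyTransform(coords(mol), tf)
  # bond mapped onto the z axis, apolar atom below the polar one
  expect_equal(xyz[, 1], c(0, 0) + xyz[1, 1], tolerance = 1e-9)
  expect_lt(xyz[1, 3], xyz[2, 3])
  expect_equal(abs(xyz[1, 3] - xyz[2, 3]), 1, tolerance = 1e-9)
  # amphiphilic balance point sits on the interface plane
  a <- atoms(mol)
  w <- abs(a$surface * a$etr)
  expect_equal(sum(w * xyz[, 3]) / sum(w), 0, tolerance = 1e-9)
})

test_that("orientAtInterface is idempotent and degenerate inputs warn", {
  mol <- fixtureMolecule("delta7_like")
  once <- transformMolecule(mol, orientAtInterface(mol))
  tf2 <- orientAtInterface(once)
  expect_equal(tf2$rotation, diag(3), tolerance = 1e-8)
  expect_equal(tf2$translation, c(0, 0, 0), tolerance = 1e-8)
  apolar <- quickMol("C", x = c(0, 1.8))
  expect_warning(tf <- orientAtInterface(apolar), "contrast")
  expect_equal(tf$rotation, diag(3))
  expect_equal(tf$translation, c(0, 0, 0))
})

test_that("interfacial area reproduces analytic disks and union semantics", {
  one <- quickMol("C", x = 0)
  r <- atoms(one)$radius[1]
  expect_equal(interfacialArea(one, rigidTransform()), pi * r^2,
               tolerance = 0.02)
  two <- quickMol("C", x = c(0, 50))
  expect_equal(interfacialArea(two, rigidTransform()), 2 * pi * r^2,
               tolerance = 0.02)
  coincident <- quickMol("C", x = c(0, 0))
  expect_equal(interfacialArea(coincident, rigidTransform()), pi * r^2,
               tolerance = 0.02)
  # monotone when atoms are added
  expect_gte(interfacialArea(two, rigidTransform()),
             interfacialArea(one, rigidTransform()))
  empty <- quickMol("C", x = 0, z = 50)
  expect_warning(a0 <- interfacialArea(empty, rigidTransform()), "slab")
  expect_equal(a0, 0)
})

test_that("interfacial area is invariant under in-plane rotation/translation", {
  mol <- orientedFixture("delta7_like")
  base <- interfacialArea(mol, rigidTransform())
  for (ang in c(30, 117)) {
    rot <- interfacialArea(mol, rigidTransform(rotZ(ang)))
    expect_equal(rot, base, tolerance = 0.01)
  }
  shifted <- interfacialArea(mol, rigidTransform(diag(3), c(5, -3, 0)))
  expect_equal(shifted, base, tolerance = 0.01)
})

test_that("the bent sterol projects a larger interfacial area than the rod", {
  expect_gt(interfacialArea(orientedFixture("delta7_like"),
                            rigidTransform()),
            interfacialArea(orientedFixture("cholesterol_like"),
                            rigidTransform()))
})
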