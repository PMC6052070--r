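test_that("leakage percentage reproduces the normalization identities", {
  expect_equal(as.numeric(leakagePercent(100, 10, 100)), 100)
  expect_equal(as.numeric(leakagePercent(10, 10, 100)), 0)
  expect_equal(as.numeric(leakagePercent(55, 10, 100)), 50)
  expect_error(leakagePercent(5, 10, 10), "undefined")
})

test_that("leakage percentage is affine-invariant and flags excursions", {
  withr::local_seed(1)
  for (i in 1:50) {
    Ft <- runif(1, 0, 120); Fc <- runif(1, 0, 50)
    Fm <- Fc + runif(1, 10, 100)
    a <- runif(1, 0.1, 10); b <- runif(1, -20, 20)
    expect_equal(as.numeric(leakagePercent(a * Ft + b, a * Fc + b,
                                           a * Fm + b)),
                 as.numeric(leakagePercent(Ft, Fc, Fm)),
                 tolerance = 1e-9)
  }
  noisy <- leakagePercent(c(120, 50, 5), 10, 100)
  expect_identical(attr(noisy, "outOfRange"), c(TRUE, FALSE, TRUE))
})

test_that("blank subtraction is element-wise with volume checks", {
  raw <- titrationSeries(heats = c(-5, -3))
  b1 <- titrationSeries(heats = c(-1, -1))
  b2 <- titrationSeries(heats = c(0.5, 0.5))
  corr <- subtractBlanks(raw, b1, b2)
  expect_equal(heats(corr), c(-4.5, -2.5))
  zero <- titrationSeries(heats = c(0, 0))
  expect_equal(heats(subtractBlanks(raw, zero, zero)), heats(raw))
  expect_equal(heats(subtractBlanks(raw, titrationSeries(heats = c(-3, -1)),
                                    titrationSeries(heats = c(-2, -2)))),
               c(0, 0))
  expect_error(subtractBlanks(raw, titrationSeries(heats = c(-1, -1, -1)),
                              b2), "injection counts")
  b3 <- titrationSeries(heats = c(-1, -1), volumes = c(5, 5))
  expect_error(subtractBlanks(raw, b3, b2), "volumes")
})

test_that("noiseless isotherm fits recover the generator across a K grid", {
  for (K in c(0.5, 5, 50)) {
    for (dH in c(-30, 20)) {
      ser <- simulateItcTrace(K = K, dH = dH, nInj = 30, noiseSd = 0)
      fit <- fitBindingIsotherm(ser)
      expect_lt(abs(fit@K - K) / K, 0.01)
      expect_lt(abs(fit@dH - dH) / abs(dH), 0.01)
    }
  }
})

test_that("the one-site model also round-trips its generator", {
  ser <- simulateItcTrace(K = 2, dH = -25, nInj = 30, noiseSd = 0,
                          model = "one_site")
  fit <- fitBindingIsotherm(ser, model = "one_site")
  expect_lt(abs(fit@K - 2) / 2, 0.01)
  expect_lt(abs(fit@dH + 25) / 25, 0.01)
})

test_that("doubling the heats doubles dH and leaves K unchanged", {
  ser <- simulateItcTrace(K = 5, dH = -30, nInj = 25, noiseSd = 0)
  doubled <- ser
  doubled@heats <- heats(ser) * 2
  f1 <- fitBindingIsotherm(ser)
  f2 <- fitBindingIsotherm(doubled)
  expect_equal(f2@dH, 2 * f1@dH, tolerance = 1e-6)
  expect_equal(f2@K, f1@K, tolerance = 1e-6)
})

test_that("5% noise still recovers the generator within 15%", {
  ser <- simulateItcTrace(K = 5, dH = -30, nInj = 30, noiseSd = 0)
  sd5 <- 0.05 * max(abs(heats(ser)))
  noisy <- simulateItcTrace(K = 5, dH = -30, nInj = 30, noiseSd = sd5,
                            seed = 42)
  fit <- fitBindingIsotherm(noisy)
  expect_lt(abs(fit@K - 5) / 5, 0.15)
  expect_lt(abs(fit@dH + 30) / 30, 0.15)
})

test_that("fit diagnostics and degenerate series behave as documented", {
  ser <- simulateItcTrace(K = 5, dH = -30, nInj = 30, noiseSd = 0)
  fit <- fitBindingIsotherm(ser)
  expect_true(fit@fit$converged)
  expect_lt(fit@fit$residualNorm, 1e-4 * max(abs(heats(ser))))
  expect_error(fitBindingIsotherm(simulateItcTrace(5, -30, nInj = 4)),
               "at least 6")
  flat <- simulateItcTrace(K = 5, dH = 0, nInj = 10)
  expect_error(fitBindingIsotherm(flat), "unidentifiable")
  # near-instant saturation leaves K unidentified
  expect_warning(try(fitBindingIsotherm(
    simulateItcTrace(K = 5000, dH = -30, nInj = 10)), silent = TRUE),
    "saturat")
})

test_that("thermodynamic identities are exact", {
  # K c0 = 1 (K = 0.001 /mM = 1 /M): dG = 0, TdS = dH
  t0 <- deriveThermodynamics(K = 0.001, dH = -12, temperature = 299.15)
  expect_equal(t0@dG, 0, tolerance = 1e-12)
  expect_equal(t0@TdS, -12, tolerance = 1e-12)
  tr <- deriveThermodynamics(K = 469.6, dH = -10)
  R <- 8.314462618e-3
  expect_equal(tr@dG, -R * 299.15 * log(4.696e5), tolerance = 1e-12)
  expect_lt(tr@dG, 0)
  expect_equal(tr@dG, tr@dH - tr@TdS, tolerance = 1e-12)
  t2 <- deriveThermodynamics(K = 2 * 469.6, dH = -10)
  expect_equal(t2@dG - tr@dG, -R * 299.15 * log(2), tolerance = 1e-12)
  expect_error(deriveThermodynamics(K = -1, dH = 0), "K must be")
  expect_error(deriveThermodynamics(K = 1, dH = 0, temperature = 0),
               "temperature")
})

test_that("injection CSV input round-trips through the reader", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(index = 1:8, volume_uL = 10,
                       heat_uJ = c(-40, -20, -10, -5, -3, -2, -1, -1)),
            tmp, row.names = FALSE)
  ser <- readInjectionsCSV(tmp, cellConc = 20, syringeConc = 5)
  expect_s4_class(ser, "TitrationSeries")
  expect_equal(length(heats(ser)), 8L)
  expect_equal(injectionVolumes(ser), rep(10, 8))
  ftmp <- withr::local_tempfile(fileext = ".csv")
  tr <- simulateLeakageTrace(40, noiseSd = 0)
  write.csv(tr, ftmp, row.names = FALSE)
  back <- readFluorescenceCSV(ftmp)
  expect_equal(back$F, tr$F)
  expect_error(readFluorescenceCSV(tmp), "time_s")
})
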