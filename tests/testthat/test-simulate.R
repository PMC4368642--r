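test_that("mixture benchmark has the stated composition", {
  sim <- simMixtureData(seed = 1, perCombo = 12)
  expect_equal(nrow(datasetValues(sim)), 15840)
  expect_equal(sum(datasetTruth(sim)$rhythmic), 1584)
  expect_equal(mean(datasetTruth(sim)$rhythmic), 0.10)
  expect_equal(ncol(datasetValues(sim)), 24)        # 2 periods x 12 points
  # cosine-like variant: single asymmetry, still exactly 10% rhythmic
  simc <- simMixtureData(seed = 1, perCombo = 2, asymmetries = 12)
  expect_equal(mean(datasetTruth(simc)$rhythmic), 0.10)
  expect_true(all(datasetTruth(simc)$asymmetry[
    datasetTruth(simc)$rhythmic] == 12))
  # minimal scale: 132 rhythmic + 1188 noise
  simm <- simMixtureData(seed = 2, perCombo = 1)
  expect_equal(nrow(datasetValues(simm)), 1320)
  expect_equal(sum(datasetTruth(simm)$rhythmic), 132)
})

test_that("noiseless shapes span peak-to-trough amplitude 2 with the peak at the phase", {
  t <- seq(0, 24, by = 0.01)
  for (shape in c("sine", "ramp", "step", "impulse", "triangle")) {
    v <- rhythmscan:::.shapeValue(shape, t, phi = 7)
    # the ramp's minimum is an instantaneous drop, only approached on a grid
    expect_equal(max(v) - min(v), 2, info = shape,
                 tolerance = if (shape == "ramp") 1e-3 else 1e-12)
    expect_equal(max(v), 1, info = shape)
    expect_equal(v[t == 7], 1, info = shape)          # peak at the phase
  }
  # ramp: instantaneous drop right after the peak, linear rise back
  v <- rhythmscan:::.shapeValue("ramp", c(7, 7.01, 19, 30.99), phi = 7)
  expect_equal(v[1], 1)
  expect_lt(v[2], -0.99)
  expect_equal(v[3], 0)
  expect_gt(v[4], 0.99)
})

test_that("impulse width at half max is 2 h", {
  # on a 12-point grid with the pulse on-grid, only the peak sample exceeds
  # the half-maximum
  t <- seq(0, 22, by = 2)
  v <- rhythmscan:::.shapeValue("impulse", t, phi = 8)
  expect_equal(sum(v > 0), 1)
  expect_equal(which(v > 0), 5L)                      # the t = 8 sample
  # half-maximum (0) is reached exactly 1 h either side of the peak
  expect_equal(rhythmscan:::.shapeValue("impulse", c(7, 9), phi = 8),
               c(0, 0))
})

test_that("simulated datasets are pure functions of parameters and seed", {
  a <- simWaveformData("sine", 50, 12, 2, 0.5, seed = 10)
  b <- simWaveformData("sine", 50, 12, 2, 0.5, seed = 10)
  expect_identical(datasetValues(a), datasetValues(b))
  expect_identical(datasetTruth(a), datasetTruth(b))
  c <- simWaveformData("sine", 50, 12, 2, 0.5, seed = 11)
  expect_false(identical(datasetValues(a), datasetValues(c)))
  expect_error(simWaveformData("sawtooth", 5, 12, 2, 0.5, seed = 1),
               "unknown shape")
})

test_that("zero noise gives identical replicates; noise sd follows the amplitude convention", {
  d0 <- simWaveformData("step", 20, 6, 3, 0, seed = 4)
  v <- datasetValues(d0)
  for (tp in unique(foldedTimes(datasetGrid(d0)))) {
    cols <- foldedTimes(datasetGrid(d0)) == tp
    expect_true(all(apply(v[, cols, drop = FALSE], 1,
                          function(r) diff(range(r))) == 0))
  }
  # at noiseFraction f the pointwise sd is 2f
  dn <- simWaveformData("sine", 2000, 12, 2, 0.5, seed = 6)
  resid <- datasetValues(dn) -
    t(apply(cbind(datasetTruth(dn)$phase), 1, function(phi)
      cos(2 * pi * (gridTimes(datasetGrid(dn)) - phi) / 24)))
  expect_equal(sd(resid), 1, tolerance = 0.02)
})

test_that("noise datasets are labelled negative and centred", {
  g <- regularGrid(12, 2)
  neg <- simNoiseData(10000, g, seed = 3)
  expect_equal(nrow(datasetValues(neg)), 10000)
  expect_true(all(!datasetTruth(neg)$rhythmic))
  total <- length(datasetValues(neg))
  expect_lt(abs(mean(datasetValues(neg))), 3 / sqrt(total))
  expect_identical(datasetValues(neg),
                   datasetValues(simNoiseData(10000, g, seed = 3)))
})

test_that("replicates-as-periods and repeated labels are equivalent designs", {
  rep2 <- simWaveformData("triangle", 10, 12, 2, 0.25, seed = 9,
                          asymmetry = 16)
  per2 <- simWaveformData("triangle", 10, 12, 2, 0.25, seed = 9,
                          asymmetry = 16, asPeriods = TRUE)
  expect_equal(sort(foldedTimes(datasetGrid(rep2))),
               sort(foldedTimes(datasetGrid(per2))))
  fam <- referenceFamily(24, 2, seq(2, 22, 2))
  b1 <- bestCorrelation(datasetValues(rep2), fam, datasetGrid(rep2))
  # same folded design: identical tie structure, so same tau distribution
  expect_true(all(abs(b1$tau) <= 1))
})
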