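test_that("Gamma moment fit recovers shape and scale from sample moments", {
  # sample with mean 2 and variance 2: shape = 4/2 = 2, scale = 2/2 = 1
  x <- c(1, 3)
  fit <- gammaMomentFit(x)
  expect_equal(fit$shape, 2)
  expect_equal(fit$scale, 1)
  expect_error(gammaMomentFit(rep(2, 5)), "degenerate")
})

test_that("F24 recovers the phase of a noiseless cosine and calls it significant", {
  g <- regularGrid(12, 2)
  for (phi in c(0, 8, 15)) {
    x <- cos(2 * pi * (gridTimes(g) - phi) / 24)
    res <- f24Test(x, g, seed = 1)
    expect_equal(res$phase, phi, tolerance = 1e-8)
    expect_lt(res$p, 0.01)
  }
})

test_that("F24 statistic vanishes for constant series and is phase-shift invariant", {
  g <- regularGrid(12, 2)
  res <- f24Test(rep(4, nSamples(g)), g, seed = 1)
  expect_equal(res$statistic, 0, tolerance = 1e-10)
  expect_equal(res$p, 1)
  # shifting a periodic signal by whole sampling intervals permutes the
  # sampled values cyclically and leaves |projection| fixed
  stat <- vapply(c(0, 4, 10, 16), function(phi)
    f24Test(evaluateWaveform(g, phi, 8), g, seed = 1)$statistic, numeric(1))
  expect_equal(max(stat) - min(stat), 0, tolerance = 1e-9)
})

test_that("Gamma-fit p tracks the raw permutation distribution in the mid-range", {
  # the moment-fit Gamma approximates the permutation null of |projection|
  # to within ~0.04 in CDF even with exact moments (see the methods
  # vignette); assert the 0.05 envelope over the central quantiles, plus
  # agreement of the two p flavours on the same modest permutation sample
  g <- regularGrid(12, 2)
  set.seed(30)
  for (i in 1:3) {
    x <- rnorm(nSamples(g))
    pg <- f24Test(x, g, nPerm = 5000, seed = i, pMethod = "gamma")$p
    pr <- f24Test(x, g, nPerm = 5000, seed = i, pMethod = "rank")$p
    expect_lt(abs(pg - pr), 0.05)
  }
  # systematic fit quality, decoupled from moment-estimation noise
  t <- gridTimes(g)
  x <- cos(2 * pi * t / 24) + rnorm(nSamples(g), sd = 0.5)
  big <- replicate(20000, {
    xx <- sample(x)
    sqrt(sum(xx * cos(2 * pi * t / 24))^2 + sum(xx * sin(2 * pi * t / 24))^2)
  })
  fit <- gammaMomentFit(big)
  qs <- quantile(big, seq(0.05, 0.95, by = 0.05))
  pGam <- pgamma(qs, shape = fit$shape, scale = fit$scale,
                 lower.tail = FALSE)
  pRank <- vapply(qs, function(q) mean(big >= q), numeric(1))
  expect_lt(max(abs(pGam - pRank)), 0.05)
})

test_that("one-way ANOVA matches the closed form and the lm oracle", {
  # groups (0,1) and (2,3): SSB = 4, SSW = 1, F = 8 on (1, 2) df
  res <- anovaTest(c(0, 1, 2, 3), c(0, 0, 12, 12))
  expect_equal(res$F, 8)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
  # textbook oracle on random instances
  set.seed(13)
  for (rep in 1:10) {
    g <- regularGrid(6, sample(2:4, 1))
    x <- rnorm(nSamples(g))
    mine <- anovaTest(x, g)
    or <- anova(lm(x ~ factor(foldedTimes(g))))
    expect_equal(mine$F, or[["F value"]][1], tolerance = 1e-10)
    expect_equal(mine$p, or[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("ANOVA handles degenerate inputs as defined", {
  res <- anovaTest(rep(2, 12), regularGrid(6, 2))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_error(anovaTest(rnorm(6), regularGrid(6, 1)), "undefined")
  err <- tryCatch(anovaTest(rnorm(6), regularGrid(6, 1)), error = identity)
  expect_s3_class(err, "rhythmscan_anova_undefined")
})

test_that("pseudo-replicates interpolate cyclic neighbours", {
  pr <- makePseudoReplicates(c(0, 1, 0, -1), timeGrid(c(0, 6, 12, 18)))
  expect_equal(unname(pr$values[1, 5:8]), c(0, 0, 0, 0))
  expect_equal(nSamples(pr$grid), 8)
  # constant series stay constant
  pc <- makePseudoReplicates(rep(5, 4), timeGrid(c(0, 6, 12, 18)))
  expect_true(all(pc$values == 5))
  # endpoints wrap: pseudo at the first time uses the last time as neighbour
  pw <- makePseudoReplicates(c(10, 0, 0, 2), timeGrid(c(0, 6, 12, 18)))
  expect_equal(unname(pw$values[1, 6]), (10 + 0) / 2)   # pseudo at t = 6
  expect_equal(unname(pw$values[1, 5]), (2 + 0) / 2)    # pseudo at t = 0 wraps
  # interpolation is exact on a linear-in-time segment (interior points)
  t <- c(0, 6, 12, 18)
  lin <- 2 * t + 1
  pl <- makePseudoReplicates(lin, timeGrid(t))
  expect_equal(unname(pl$values[1, 6:7]), lin[2:3])
})

test_that("pseudo-replication needs a Monte-Carlo null to keep p-values honest", {
  g <- regularGrid(8, 1)
  set.seed(21)
  M <- matrix(rnorm(1e4 * nSamples(g)), 1e4)
  aug <- makePseudoReplicates(M, g)
  nominal <- anovaTest(aug$values, aug$grid)$p
  ksNominal <- suppressWarnings(ks.test(nominal, "punif"))$statistic
  expect_gt(ksNominal, 0.05)        # anti-conservative if uncorrected
  nullF <- anovaMCNull(g, 2e4, seed = 5)
  corrected <- anovaEmpiricalP(anovaTest(aug$values, aug$grid)$F, nullF)
  ksCorr <- suppressWarnings(ks.test(corrected, "punif"))$statistic
  expect_lt(ksCorr, 0.02)
  expect_identical(nullF, anovaMCNull(g, 2e4, seed = 5))  # seed-stable
})
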