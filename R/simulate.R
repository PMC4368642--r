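## Simulated benchmark generators. Every noiseless shape spans [-1, 1]
## (peak-to-trough amplitude 2), so Gaussian noise at `noiseFraction` of the
## amplitude has sd = 2 * noiseFraction. Phases follow the peak-at-phase
## convention throughout.

## noiseless shape value at times t (hours), peak at phi
.shapeValue <- function(shape, t, phi, period = 24, asymmetry = 12,
                        fwhm = 2, rampFalling = FALSE) {
    u <- (t - phi) %% period
    switch(shape,
        sine = cos(2 * pi * u / period),
        triangle = evaluateWaveform(t, phi, asymmetry, period, "triangle"),
        ramp = if (rampFalling) 1 - 2 * u / period
               else ifelse(u == 0, 1, -1 + 2 * u / period),
        step = ifelse(u < period / 2, 1, -1),
        impulse = {
            d <- pmin(u, period - u)       # distance from the peak
            # half-maximum (0) at d = fwhm/2, baseline -1 from d = fwhm on
            ifelse(d < fwhm, 1 - 2 * d / fwhm, -1)
        },
        stop("unknown shape: ", shape))
}

.truthFrame <- function(n, rhythmic, shape, phase, asymmetry, noiseFraction) {
    data.frame(rhythmic = rep_len(rhythmic, n),
               shape = rep_len(shape, n),
               phase = rep_len(phase, n),
               asymmetry = rep_len(asymmetry, n),
               noiseFraction = rep_len(noiseFraction, n))
}

#' Simulate rhythmic series of a given waveform
#'
#' Generates `nSeries` series of the chosen shape with phases drawn
#' uniformly on `[0, period)`, sampled on a regular grid, with pointwise
#' Gaussian noise of standard deviation `noiseFraction` times the
#' peak-to-trough amplitude (2). Replicates are drawn independently.
#'
#' Shapes: `sine` is `cos(2*pi*(t - phase)/period)`; `ramp` rises linearly
#' over the full period to a peak at the phase with an instantaneous drop
#' just after it (the maximal-asymmetry limit of the triangle;
#' `rampFalling = TRUE` flips the orientation); `step` is high for half the
#' period from the phase, low for the other half; `impulse` is a triangular
#' pulse of full width at half maximum `fwhm` (default 2 h) on a flat
#' baseline; `triangle` takes the `asymmetry` argument.
#'
#' @param shape one of `"sine"`, `"ramp"`, `"step"`, `"impulse"`,
#'   `"triangle"`.
#' @param nSeries number of series.
#' @param pointsPerPeriod evenly spaced points per period (4, 6, 8 or 12 in
#'   the benchmark presets).
#' @param replicates replicates per time point (1-4 in the presets).
#' @param noiseFraction noise sd as a fraction of peak-to-trough amplitude
#'   (0.25 or 0.50 in the presets).
#' @param seed integer seed.
#' @param period period in hours.
#' @param asymmetry triangle asymmetry (hours), used by `shape="triangle"`.
#' @param fwhm impulse full width at half maximum (hours).
#' @param rampFalling flip the ramp orientation.
#' @param asPeriods lay replicates out as consecutive periods instead of
#'   repeated time labels (equivalent designs for detection).
#' @return A [SimulatedDataset-class].
#' @export
simWaveformData <- function(shape, nSeries, pointsPerPeriod = 12,
                            replicates = 2, noiseFraction = 0.5, seed,
                            period = 24, asymmetry = 12, fwhm = 2,
                            rampFalling = FALSE, asPeriods = FALSE) {
    grid <- regularGrid(pointsPerPeriod, replicates, period, asPeriods)
    t <- gridTimes(grid)
    .withSeed(seed, function() {
        phi <- runif(nSeries, 0, period)
        V <- matrix(NA_real_, nSeries, length(t))
        for (i in seq_len(nSeries))
            V[i, ] <- .shapeValue(shape, t, phi[i], period, asymmetry,
                                  fwhm, rampFalling)
        V <- V + matrix(rnorm(length(V), sd = 2 * noiseFraction),
                        nrow(V), ncol(V))
        new("SimulatedDataset", values = V, grid = grid,
            truth = .truthFrame(nSeries, TRUE, shape, phi,
                                if (shape == "triangle") asymmetry
                                else NA_real_, noiseFraction))
    })
}

#' Simulate arrhythmic (pure noise) series
#'
#' i.i.d. standard Gaussian values on the grid; the true negatives of the
#' benchmarks.
#'
#' @param nSeries number of series.
#' @param grid a [TimeGrid-class].
#' @param seed integer seed.
#' @return A [SimulatedDataset-class] with `rhythmic = FALSE` throughout.
#' @export
simNoiseData <- function(nSeries, grid, seed) {
    n <- nSamples(grid)
    V <- .withSeed(seed, function() matrix(rnorm(nSeries * n), nSeries, n))
    new("SimulatedDataset", values = V, grid = grid,
        truth = .truthFrame(nSeries, FALSE, "noise", NA_real_, NA_real_,
                            NA_real_))
}

#' Simulate the mixed triangle/noise benchmark
#'
#' `perCombo` noisy triangle series for every (phase, asymmetry) pair plus
#' nine times as many pure-noise series, i.e. exactly 10% rhythmic —
#' reflective of a genome-wide dataset. The rhythmic series are sampled over
#' `periods` consecutive periods of `pointsPerPeriod` points (default: 24
#' points as 2 periods of 12). The full grids (12 phases by 2 h, 11
#' asymmetries 2-22 by 2 h) with `perCombo = 12` give the 15,840-series
#' benchmark; `asymmetries = 12` gives the cosine-like variant.
#'
#' @param seed integer seed.
#' @param perCombo rhythmic series per (phase, asymmetry) combination.
#' @param phases,asymmetries grids in hours.
#' @param noiseFraction Gaussian noise sd as a fraction of the amplitude
#'   (0.25 or 0.50 in the presets).
#' @param pointsPerPeriod,periods sampling design for all series.
#' @param period period in hours.
#' @return A [SimulatedDataset-class]; rhythmic rows come first.
#' @examples
#' sim <- simMixtureData(seed = 1, perCombo = 1, noiseFraction = 0.25)
#' mean(datasetTruth(sim)$rhythmic)  # exactly 0.1
#' @export
simMixtureData <- function(seed, perCombo = 12, phases = seq(0, 22, by = 2),
                           asymmetries = seq(2, 22, by = 2),
                           noiseFraction = 0.25, pointsPerPeriod = 12,
                           periods = 2, period = 24) {
    stopifnot(perCombo >= 1)
    grid <- regularGrid(pointsPerPeriod, periods, period, asPeriods = TRUE)
    t <- gridTimes(grid)
    combos <- expand.grid(phase = phases, asymmetry = asymmetries,
                          KEEP.OUT.ATTRS = FALSE)
    nPos <- nrow(combos) * perCombo
    nNeg <- 9L * nPos
    .withSeed(seed, function() {
        phi <- rep(combos$phase, each = perCombo)
        asy <- rep(combos$asymmetry, each = perCombo)
        P <- matrix(NA_real_, nPos, length(t))
        for (i in seq_len(nPos))
            P[i, ] <- evaluateWaveform(t, phi[i], asy[i], period, "triangle")
        P <- P + matrix(rnorm(length(P), sd = 2 * noiseFraction),
                        nrow(P), ncol(P))
        Ng <- matrix(rnorm(nNeg * length(t)), nNeg, length(t))
        truth <- rbind(
            .truthFrame(nPos, TRUE, "triangle", phi, asy, noiseFraction),
            .truthFrame(nNeg, FALSE, "noise", NA_real_, NA_real_, NA_real_))
        new("SimulatedDataset", values = rbind(P, Ng), grid = grid,
            truth = truth)
    })
}
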