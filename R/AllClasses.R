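#' @import methods
#' @importFrom stats rnorm pnorm pgamma pf sd var p.adjust runif model.matrix setNames
#' @importFrom utils read.delim write.table
NULL

## ---------------------------------------------------------------------------
## TimeGrid
## ---------------------------------------------------------------------------

#' Sampling time grid
#'
#' An ordered set of sample times in hours, together with the period of the
#' rhythm being tested. Repeated times encode replicates; times beyond one
#' period are equivalent, for genome-wide designs, to replicates at
#' `time mod period` (samples from successive periods at the same zeitgeber
#' time are treated as replicates).
#'
#' @slot times numeric vector of sample times (hours, non-negative, finite).
#' @slot period numeric scalar, period in hours (default 24).
#' @export
setClass("TimeGrid",
         representation(times = "numeric", period = "numeric"))

setValidity("TimeGrid", function(object) {
    msg <- character()
    if (length(object@period) != 1L || !is.finite(object@period) ||
        object@period <= 0)
        msg <- c(msg, "'period' must be a single positive finite number")
    if (length(object@times) < 3L || !all(is.finite(object@times)))
        msg <- c(msg, "'times' must be >= 3 finite values")
    if (any(object@times < 0))
        msg <- c(msg, "'times' must be non-negative")
    if (length(msg) == 0L &&
        length(unique(object@times %% object@period)) < 3L)
        msg <- c(msg, "need >= 3 distinct times modulo the period")
    if (length(msg)) msg else TRUE
})

#' Construct a TimeGrid
#'
#' @param times numeric vector of sample times in hours. Repeated values are
#'   replicates; values beyond one period fold onto `times %% period`.
#' @param period rhythm period in hours, default 24.
#' @return A [TimeGrid-class] object.
#' @examples
#' timeGrid(rep(seq(0, 22, by = 2), each = 2))
#' @export
timeGrid <- function(times, period = 24) {
    new("TimeGrid", times = as.numeric(times), period = as.numeric(period))
}

#' Regular sampling design
#'
#' Convenience constructor for the benchmark designs: `pointsPerPeriod`
#' evenly spaced time points with `replicates` samples each. With
#' `asPeriods = TRUE` the replicates are laid out as consecutive periods
#' (times run past the period) instead of repeated labels; the two designs
#' are equivalent for detection.
#'
#' @param pointsPerPeriod number of evenly spaced time points per period.
#' @param replicates samples per time point (or number of periods).
#' @param period period in hours.
#' @param asPeriods lay replicates out as consecutive periods.
#' @return A [TimeGrid-class].
#' @examples
#' regularGrid(12, 2)
#' @export
regularGrid <- function(pointsPerPeriod, replicates = 1L, period = 24,
                        asPeriods = FALSE) {
    base <- seq(0, period - period / pointsPerPeriod,
                by = period / pointsPerPeriod)
    times <- if (asPeriods)
        as.vector(outer(base, (seq_len(replicates) - 1L) * period, `+`))
    else rep(base, each = replicates)
    timeGrid(times, period)
}

#' @describeIn TimeGrid-class sample times (hours)
#' @param x,object a `TimeGrid`
#' @export
gridTimes <- function(x) x@times

#' @describeIn TimeGrid-class period (hours)
#' @export
gridPeriod <- function(x) x@period

#' @describeIn TimeGrid-class number of samples
#' @export
nSamples <- function(x) length(x@times)

#' @describeIn TimeGrid-class times reduced modulo the period
#' @export
foldedTimes <- function(x) x@times %% x@period

setMethod("show", "TimeGrid", function(object) {
    ft <- sort(unique(foldedTimes(object)))
    cat("TimeGrid:", length(object@times), "samples,",
        length(ft), "distinct times (period", object@period, "h)\n")
    cat("  times mod period:", paste(ft, collapse = " "), "\n")
})

.gridSignature <- function(grid) {
    paste0("T", format(grid@period, digits = 12), ";t",
           paste(format(grid@times, digits = 12), collapse = ","))
}

## ---------------------------------------------------------------------------
## ReferenceFamily
## ---------------------------------------------------------------------------

#' Reference waveform family
#'
#' The set of reference waveforms JTK_CYCLE tests a series against: every
#' phase on `phases` crossed with every asymmetry on `asymmetries`. The
#' asymmetry is the length in hours of the falling interval from the
#' waveform's maximum to its minimum; `period/2` is the symmetric
#' (cosine-like) waveform. The family size is the number of hypotheses
#' tested per series.
#'
#' @slot shape `"triangle"` or `"cosine"`.
#' @slot period period in hours.
#' @slot phases numeric vector of peak times (hours, in `[0, period)`).
#' @slot asymmetries numeric vector of asymmetries (hours, in `(0, period)`).
#' @export
setClass("ReferenceFamily",
         representation(shape = "character", period = "numeric",
                        phases = "numeric", asymmetries = "numeric"))

setValidity("ReferenceFamily", function(object) {
    msg <- character()
    if (!object@shape %in% c("triangle", "cosine"))
        msg <- c(msg, "shape must be 'triangle' or 'cosine'")
    if (length(object@period) != 1L || object@period <= 0)
        msg <- c(msg, "period must be a single positive number")
    if (length(object@phases) == 0L || length(object@asymmetries) == 0L)
        msg <- c(msg, "phase and asymmetry grids must be non-empty")
    if (any(object@phases < 0 | object@phases >= object@period))
        msg <- c(msg, "phases must lie in [0, period)")
    if (any(object@asymmetries <= 0 | object@asymmetries >= object@period))
        msg <- c(msg, "asymmetries must lie strictly inside (0, period)")
    if (anyDuplicated(object@phases) || anyDuplicated(object@asymmetries))
        msg <- c(msg, "duplicate phases or asymmetries")
    if (length(msg)) msg else TRUE
})

#' Construct a reference family
#'
#' Phases enumerate `0, phaseStep, ..., period - phaseStep`. Asymmetries are
#' given explicitly in hours, or as `"symmetric"` for the single symmetric
#' waveform (`period/2`, cosine-like). The conventional searches are
#' `asymmetries = seq(2, 22, by = 2)` ("by 2 h") and
#' `c(4, 8, 12, 16, 20)` ("by 4 h").
#'
#' @param period period in hours.
#' @param phaseStep spacing of the phase grid in hours; must divide `period`.
#' @param asymmetries numeric vector of asymmetries in hours, or
#'   `"symmetric"`.
#' @param shape reference shape; only ranks matter to the test, and the
#'   triangle at asymmetry `period/2` is rank-equivalent to the cosine.
#' @return A [ReferenceFamily-class].
#' @examples
#' familySize(referenceFamily(24, 4, c(4, 8, 12, 16, 20)))   # 30 hypotheses
#' familySize(referenceFamily(24, 4, "symmetric"))           # 6
#' @export
referenceFamily <- function(period = 24, phaseStep = 2,
                            asymmetries = seq(2, 22, by = 2),
                            shape = c("triangle", "cosine")) {
    shape <- match.arg(shape)
    if (length(phaseStep) != 1L || phaseStep <= 0 ||
        abs(period / phaseStep - round(period / phaseStep)) > 1e-9)
        stop("'phaseStep' must be a positive divisor of the period")
    if (identical(asymmetries, "symmetric"))
        asymmetries <- period / 2
    new("ReferenceFamily", shape = shape, period = period,
        phases = seq(0, period - phaseStep, by = phaseStep),
        asymmetries = as.numeric(asymmetries))
}

#' @describeIn ReferenceFamily-class number of waveforms (hypotheses per
#'   series)
#' @param x,object a `ReferenceFamily`
#' @export
familySize <- function(x) length(x@phases) * length(x@asymmetries)

#' @describeIn ReferenceFamily-class the (phase, asymmetry) grid as a
#'   data.frame, in the deterministic selection order used to break arg-max
#'   ties (smallest distance of asymmetry from period/2 first, then smaller
#'   asymmetry, then smaller phase)
#' @export
familyGrid <- function(x) {
    g <- expand.grid(phase = x@phases, asymmetry = x@asymmetries,
                     KEEP.OUT.ATTRS = FALSE)
    g[order(abs(g$asymmetry - x@period / 2), g$asymmetry, g$phase), ,
      drop = FALSE]
}

setMethod("show", "ReferenceFamily", function(object) {
    cat("ReferenceFamily:", object@shape, "waves, period",
        object@period, "h\n")
    cat(" ", length(object@phases), "phases x",
        length(object@asymmetries), "asymmetries =",
        familySize(object), "hypotheses per series\n")
})

.familySignature <- function(fam) {
    paste0(fam@shape, ";T", format(fam@period, digits = 12), ";p",
           paste(format(fam@phases, digits = 12), collapse = ","), ";a",
           paste(format(fam@asymmetries, digits = 12), collapse = ","))
}

## ---------------------------------------------------------------------------
## NullDistribution
## ---------------------------------------------------------------------------

#' Monte-Carlo null distribution of the max-tau statistic
#'
#' Sorted max-over-family Kendall tau values from applying the full
#' best-correlation procedure to random-rank time series on the same grid
#' and family. A lookup is legal only when the grid and family signatures
#' match the query's; the sample count sets the smallest attainable
#' empirical p-value, `1/(N + 1)`.
#'
#' @slot samples sorted ascending max-tau draws.
#' @slot gridSignature,familySignature identity strings of the grid/family
#'   the null was sampled under.
#' @slot seed integer seed used.
#' @export
setClass("NullDistribution",
         representation(samples = "numeric", gridSignature = "character",
                        familySignature = "character", seed = "integer"))

setValidity("NullDistribution", function(object) {
    if (length(object@samples) < 1L)
        return("empty null sample")
    if (is.unsorted(object@samples))
        return("samples must be sorted ascending")
    TRUE
})

#' @describeIn NullDistribution-class number of Monte-Carlo samples
#' @param x,object a `NullDistribution`
#' @export
nullSize <- function(x) length(x@samples)

setMethod("show", "NullDistribution", function(object) {
    cat("NullDistribution:", length(object@samples),
        "max-tau samples (seed", object@seed, ")\n")
    cat("  p floor:", format(1 / (length(object@samples) + 1)), "\n")
})

## ---------------------------------------------------------------------------
## SimulatedDataset
## ---------------------------------------------------------------------------

#' Simulated benchmark dataset
#'
#' A value matrix (series in rows, samples in columns) on a [TimeGrid-class],
#' with per-series ground truth: rhythmic flag, generating waveform shape,
#' phase, asymmetry (NA where not applicable), and noise fraction.
#'
#' @slot values numeric matrix, series x samples.
#' @slot grid the sampling [TimeGrid-class].
#' @slot truth data.frame with columns `rhythmic`, `shape`, `phase`,
#'   `asymmetry`, `noiseFraction`.
#' @export
setClass("SimulatedDataset",
         representation(values = "matrix", grid = "TimeGrid",
                        truth = "data.frame"))

setValidity("SimulatedDataset", function(object) {
    msg <- character()
    if (nrow(object@values) != nrow(object@truth))
        msg <- c(msg, "truth must have one row per series")
    if (ncol(object@values) != length(object@grid@times))
        msg <- c(msg, "value columns must match the grid")
    need <- c("rhythmic", "shape", "phase", "asymmetry", "noiseFraction")
    if (!all(need %in% names(object@truth)))
        msg <- c(msg, paste("truth needs columns:",
                            paste(need, collapse = ", ")))
    if (length(msg) == 0L &&
        any(object@truth$rhythmic & !is.finite(object@truth$phase)))
        msg <- c(msg, "every rhythmic series must carry a phase")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimulatedDataset-class value matrix (series x samples)
#' @param x,object a `SimulatedDataset`
#' @export
datasetValues <- function(x) x@values

#' @describeIn SimulatedDataset-class sampling grid
#' @export
datasetGrid <- function(x) x@grid

#' @describeIn SimulatedDataset-class ground-truth labels
#' @export
datasetTruth <- function(x) x@truth

setMethod("show", "SimulatedDataset", function(object) {
    cat("SimulatedDataset:", nrow(object@values), "series x",
        ncol(object@values), "samples;",
        sum(object@truth$rhythmic), "rhythmic (",
        format(100 * mean(object@truth$rhythmic)), "% )\n")
})
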