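## Reference waveforms: parametric triangle / cosine curves with the peak at
## the phase. Amplitude is fixed to [-1, 1]; only rank order matters to the
## rank-correlation test downstream.

#' Evaluate a reference waveform on sample times
#'
#' The triangle takes value 1 at `t = phase (mod period)`, falls linearly to
#' -1 over the `asymmetry` interval, and rises linearly back to 1 over the
#' remaining `period - asymmetry` hours. The cosine is
#' `cos(2*pi*(t - phase)/period)` (its asymmetry is intrinsically
#' `period/2`). Replicate times receive identical values.
#'
#' @param times numeric sample times in hours (or a [TimeGrid-class]).
#' @param phase peak time in hours.
#' @param asymmetry falling-interval length in hours, strictly inside
#'   `(0, period)`; ignored for the cosine.
#' @param period period in hours.
#' @param shape `"triangle"` or `"cosine"`.
#' @return numeric vector of reference values in `[-1, 1]`.
#' @examples
#' evaluateWaveform(8, phase = 0, asymmetry = 8)    # minimum 8 h after peak
#' evaluateWaveform(6, phase = 0, asymmetry = 12)   # midpoint of descent
#' @export
evaluateWaveform <- function(times, phase, asymmetry = period / 2,
                             period = 24, shape = c("triangle", "cosine")) {
    shape <- match.arg(shape)
    if (is(times, "TimeGrid")) {
        period <- gridPeriod(times)
        times <- gridTimes(times)
    }
    if (!is.finite(phase) || length(phase) != 1L)
        stop("'phase' must be a single finite number")
    if (shape == "cosine")
        return(cos(2 * pi * (times - phase) / period))
    if (!is.finite(asymmetry) || asymmetry <= 0 || asymmetry >= period)
        stop("'asymmetry' must lie strictly inside (0, period)")
    u <- (times - phase) %% period
    ifelse(u < asymmetry,
           1 - 2 * u / asymmetry,
           -1 + 2 * (u - asymmetry) / (period - asymmetry))
}

#' Evaluate a whole family on a grid
#'
#' Returns the reference matrix used by [bestCorrelation()]: one row per
#' waveform (in the family's deterministic selection order, see
#' [familyGrid()]), one column per sample.
#'
#' @param family a [ReferenceFamily-class].
#' @param grid a [TimeGrid-class].
#' @return numeric matrix, `familySize(family)` x `nSamples(grid)`, with the
#'   corresponding `familyGrid(family)` rows as an attribute `"grid"`.
#' @export
referenceMatrix <- function(family, grid) {
    stopifnot(is(family, "ReferenceFamily"), is(grid, "TimeGrid"))
    if (abs(family@period - gridPeriod(grid)) > 1e-9)
        stop("family and grid periods differ")
    g <- familyGrid(family)
    t <- gridTimes(grid)
    R <- matrix(NA_real_, nrow(g), length(t))
    for (k in seq_len(nrow(g)))
        R[k, ] <- evaluateWaveform(t, g$phase[k], g$asymmetry[k],
                                   family@period, family@shape)
    rownames(R) <- paste0("phi", g$phase, "_a", g$asymmetry)
    attr(R, "grid") <- g
    R
}

## Warn when the search grid is denser than the data support: searching
## phases/asymmetries below the resolution of the data needlessly multiplies
## hypotheses without adding rank information.
.checkFamilyResolution <- function(family, grid, override = FALSE) {
    ft <- sort(unique(foldedTimes(grid)))
    res <- min(diff(c(ft, ft[1] + gridPeriod(grid))))
    step <- if (length(family@phases) > 1L) min(diff(sort(family@phases)))
            else gridPeriod(grid)
    if (step < res - 1e-9) {
        msg <- sprintf(
            "phase grid (%g h) is denser than the data resolution (%g h)",
            step, res)
        if (override) warning(msg, call. = FALSE) else stop(
            msg, "; pass denseSearch = TRUE to override", call. = FALSE)
    }
    invisible(TRUE)
}
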