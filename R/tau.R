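## Kendall tau of the rank test and the max-over-family selection step.
##
## tau(x, y) = sum_{i<j} sgn(x_j - x_i) * sgn(y_j - y_i) / (n(n-1)/2)
##
## The denominator is the total number of pairs (tau-a) even in the presence
## of ties, so |tau| < 1 is the attainable ceiling for tied data; sgn(0) = 0,
## ties contribute nothing. Every pair is included, not only neighbours.

## indices of all i < j pairs for a series of length n
.pairIndices <- function(n) {
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- sequence((n - 1L):1L) + i
    list(i = i, j = j)
}

#' Kendall rank correlation (tau-a)
#'
#' Concordant minus discordant pairs over the total number of pairs
#' `n(n-1)/2`. Tied pairs (in either vector) contribute zero to the
#' numerator but stay in the denominator.
#'
#' With `tieNorm = "a"` (the default) the denominator stays `n(n-1)/2` even
#' in the presence of ties, so `|tau| < 1` is the attainable ceiling for
#' tied data — e.g. a noiseless series matched against itself on a
#' replicated grid scores slightly below 1. `tieNorm = "b"` divides by
#' `sqrt((P - Tx)(P - Ty))` (pairs untied in each vector), restoring
#' `tau = 1` for a perfect self-match.
#'
#' @param x,y numeric vectors of equal length `n >= 3`, no missing values.
#' @param tieNorm `"a"` (total-pair denominator) or `"b"` (tie-corrected).
#' @return tau in `[-1, 1]`.
#' @examples
#' kendallTau(1:5, 1:5)          #  1
#' kendallTau(1:5, 5:1)          # -1
#' kendallTau(1:4, c(1, 3, 2, 4)) # 2/3
#' @export
kendallTau <- function(x, y, tieNorm = c("a", "b")) {
    tieNorm <- match.arg(tieNorm)
    n <- length(x)
    if (length(y) != n) stop("'x' and 'y' must have equal length")
    if (n < 3L) stop("need at least 3 observations")
    if (!all(is.finite(x)) || !all(is.finite(y)))
        stop("missing or non-finite values; handle them upstream")
    p <- .pairIndices(n)
    sx <- sign(x[p$j] - x[p$i]); sy <- sign(y[p$j] - y[p$i])
    den <- if (tieNorm == "a") n * (n - 1) / 2
           else sqrt(sum(abs(sx)) * sum(abs(sy)))
    if (den == 0) return(0)
    sum(sx * sy) / den
}

## Pairwise sign matrix for a block of series (rows). M: nseries x n.
.signPairs <- function(M, p) {
    sign(M[, p$j, drop = FALSE] - M[, p$i, drop = FALSE])
}

#' Best correlation over a reference family
#'
#' Computes the Kendall tau of each series against every waveform in the
#' family and selects the maximum (one-sided: only positive correlation is
#' sought; anti-phase signals are captured by the phase grid). Arg-max ties
#' are broken deterministically: smallest distance of asymmetry from
#' `period/2` first, then smaller asymmetry, then smaller phase.
#'
#' A constant series has every pair tied, so tau is identically 0 against
#' every reference; such series are flagged `degenerate`.
#'
#' @param x numeric vector (one series) or matrix (series in rows) aligned
#'   to `grid`.
#' @param family a [ReferenceFamily-class].
#' @param grid a [TimeGrid-class].
#' @param denseSearch allow (with a warning) a phase grid denser than the
#'   data resolution.
#' @param tieNorm tie normalization, as in [kendallTau()]; `"a"` by
#'   default.
#' @param returnAll also return the full per-reference tau matrix as
#'   attribute `"taus"` (columns in [familyGrid()] order).
#' @param chunkSize series per block in the vectorized sweep.
#' @return data.frame with one row per series: `tau` (the max), `phase`,
#'   `asymmetry` (arg-max), `degenerate`.
#' @examples
#' g <- regularGrid(12, 2)
#' x <- evaluateWaveform(g, phase = 8, asymmetry = 16)
#' bestCorrelation(x, referenceFamily(24, 4, c(4, 8, 12, 16, 20)), g)
#' @export
bestCorrelation <- function(x, family, grid, denseSearch = FALSE,
                            tieNorm = c("a", "b"), returnAll = FALSE,
                            chunkSize = 20000L) {
    tieNorm <- match.arg(tieNorm)
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (ncol(x) != nSamples(grid))
        stop("series length does not match the grid")
    .checkFamilyResolution(family, grid, override = denseSearch)
    R <- referenceMatrix(family, grid)
    g <- attr(R, "grid")
    n <- nSamples(grid)
    p <- .pairIndices(n)
    SY <- .signPairs(R, p)
    denom <- n * (n - 1) / 2
    untiedY <- rowSums(abs(SY))            # P - Ty per reference

    nser <- nrow(x)
    tauStar <- numeric(nser)
    pick <- integer(nser)
    degenerate <- logical(nser)
    allTaus <- if (returnAll) matrix(NA_real_, nser, nrow(g)) else NULL
    for (s in seq(1L, nser, by = chunkSize)) {
        idx <- s:min(s + chunkSize - 1L, nser)
        SX <- .signPairs(x[idx, , drop = FALSE], p)
        num <- tcrossprod(SX, SY)
        untiedX <- rowSums(abs(SX))
        TT <- if (tieNorm == "a") num / denom
              else num / outer(sqrt(untiedX), sqrt(untiedY))
        TT[untiedX == 0, ] <- 0            # constant series: tau identically 0
        pick[idx] <- max.col(TT, ties.method = "first")
        tauStar[idx] <- TT[cbind(seq_along(idx), pick[idx])]
        degenerate[idx] <- untiedX == 0
        if (returnAll) allTaus[idx, ] <- TT
    }
    out <- data.frame(tau = tauStar,
                      phase = g$phase[pick],
                      asymmetry = g$asymmetry[pick],
                      degenerate = degenerate)
    if (!is.null(rownames(x))) rownames(out) <- rownames(x)
    if (returnAll) {
        colnames(allTaus) <- rownames(R)
        attr(out, "taus") <- allTaus
    }
    out
}
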