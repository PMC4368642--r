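## Significance of the max-over-waveforms statistic: empirical Monte-Carlo
## p-values (the method's contribution) alongside the classical corrections
## (initial normal-approximation p, Bonferroni, Benjamini-Hochberg) used by
## the comparator variants.

## Run fn with a temporarily seeded RNG, restoring the caller's state.
.withSeed <- function(seed, fn) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
                else suppressWarnings(rm(".Random.seed", envir = globalenv())))
        set.seed(seed)
    }
    fn()
}

#' Sample the Monte-Carlo null of the max-tau statistic
#'
#' Applies the full best-correlation procedure (same grid, same family) to
#' i.i.d. standard Gaussian series. Under the null only the rank order of
#' the values matters, and i.i.d. continuous draws induce uniformly random
#' rank orders, so this is equivalent to explicit permutation. Samples are
#' stored sorted; the smallest attainable empirical p is `1/(nNull + 1)`.
#'
#' @param grid a [TimeGrid-class].
#' @param family a [ReferenceFamily-class].
#' @param nNull number of null series (default `2e5`; `2e6` gives a p-value
#'   floor of 5e-7). Values below `1e5` draw a warning.
#' @param seed integer seed (required for a cacheable, reproducible null).
#' @param cacheDir optional directory: the null is stored/reused keyed by
#'   (grid signature, family signature, nNull, seed); a cache file whose
#'   signatures do not match the query is refused.
#' @param denseSearch passed to [bestCorrelation()].
#' @param chunkSize series per vectorized block.
#' @return A [NullDistribution-class].
#' @export
sampleNull <- function(grid, family, nNull = 2e5, seed, cacheDir = NULL,
                       denseSearch = FALSE, chunkSize = 20000L) {
    nNull <- as.integer(nNull)
    if (nNull < 1000L) stop("'nNull' must be at least 1000")
    if (nNull < 1e5) warning("nNull below 1e5: empirical p floor is ",
                             format(1 / (nNull + 1)), call. = FALSE)
    gs <- .gridSignature(grid); fs <- .familySignature(family)
    cacheFile <- NULL
    if (!is.null(cacheDir)) {
        key <- sprintf("null_%08x_N%d_s%d.rds",
                       .stringHash(paste(gs, fs)), nNull, as.integer(seed))
        cacheFile <- file.path(cacheDir, key)
        if (file.exists(cacheFile)) {
            nd <- readRDS(cacheFile)
            if (!identical(nd@gridSignature, gs) ||
                !identical(nd@familySignature, fs) ||
                nullSize(nd) != nNull || nd@seed != as.integer(seed))
                stop("null cache collision: parameters do not match; ",
                     "refusing to reuse ", cacheFile)
            return(nd)
        }
    }
    n <- nSamples(grid)
    samples <- .withSeed(seed, function() {
        out <- numeric(nNull)
        for (s in seq(1L, nNull, by = chunkSize)) {
            idx <- s:min(s + chunkSize - 1L, nNull)
            M <- matrix(rnorm(length(idx) * n), length(idx), n)
            out[idx] <- bestCorrelation(M, family, grid,
                                        denseSearch = denseSearch,
                                        chunkSize = chunkSize)$tau
        }
        out
    })
    nd <- new("NullDistribution", samples = sort(samples),
              gridSignature = gs, familySignature = fs,
              seed = as.integer(seed))
    if (!is.null(cacheFile)) {
        dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(nd, cacheFile)
    }
    nd
}

## small stable string hash (djb2), for cache file names only
.stringHash <- function(s) {
    v <- utf8ToInt(s)
    h <- 5381
    for (c in v) h <- (h * 33 + c) %% 2^28
    as.integer(h)
}

#' Empirical p-value of an observed max-tau
#'
#' Add-one permutation estimator `p = (1 + #{null >= tau}) / (N + 1)`: never
#' zero, monotone non-increasing in tau, and ties with null samples count as
#' exceedances (the conservative direction).
#'
#' @param tauStar numeric vector of observed max-tau statistics.
#' @param null a [NullDistribution-class] (grid/family must match the run
#'   that produced `tauStar`; [detectRhythms()] enforces this).
#' @return numeric vector of p-values in `(0, 1]`.
#' @export
empiricalPvalue <- function(tauStar, null) {
    stopifnot(is(null, "NullDistribution"))
    N <- nullSize(null)
    nGreaterEq <- N - findInterval(tauStar, null@samples, left.open = TRUE)
    (1 + nGreaterEq) / (N + 1)
}

#' Initial p-value from the normal approximation
#'
#' One-sided upper-tail p-value for a single Kendall tau from the normal
#' approximation to the null of Kendall's S statistic (mean 0, variance
#' `n(n-1)(2n+5)/18`), with a continuity correction of 1 on the S scale.
#' This is the per-waveform p-value of the classical procedure; after the
#' max-over-family selection it underestimates the true significance, which
#' is what the Bonferroni/Benjamini-Hochberg comparator variants correct
#' and the empirical null replaces.
#'
#' @param tau numeric vector of tau values.
#' @param n series length (`>= 3`).
#' @return one-sided p-values.
#' @export
initialPvalue <- function(tau, n) {
    if (n < 3L) stop("need n >= 3")
    S <- tau * n * (n - 1) / 2
    sdS <- sqrt(n * (n - 1) * (2 * n + 5) / 18)
    pnorm((S - 1) / sdS, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' Multiplies a p-value by the number of hypotheses tested (the family
#' size), capped at 1. Controls the family-wise error rate.
#'
#' @param p numeric vector of p-values.
#' @param m number of hypotheses (`>= 1`).
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m) {
    if (m < 1) stop("'m' must be >= 1")
    pmin(1, m * p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted values (`stats::p.adjust(method = "BH")`): p-values are
#' multiplied by the number of tests, divided by their rank from lowest to
#' highest, then forced monotone so the ordering is not violated, and
#' capped at 1. Controls the false discovery rate. Used both within a
#' series (across waveforms) and across series.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return adjusted values, same length.
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    p.adjust(p, method = "BH")
}

## Per-series minimum BH-adjusted p over the family, from a series x m
## matrix of per-waveform initial p-values (the JTK_BH comparator).
.minBHWithin <- function(pmat) {
    m <- ncol(pmat)
    sorted <- t(apply(pmat, 1L, sort))
    adj <- sweep(sorted, 2L, m / seq_len(m), `*`)
    pmin(1, apply(adj, 1L, min))
}
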