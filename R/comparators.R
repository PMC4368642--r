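## Comparator rhythm-detection tests: the F24 Fourier projection with a
## Gamma-fit permutation null, and one-way ANOVA across time points with an
## optional interpolated pseudo-replicate augmentation.

#' F24: projection onto the 24 h Fourier basis
#'
#' The statistic is the modulus of the (un-normalized) discrete projection
#' of the series onto the Fourier basis function at the test period,
#' `|sum_t x_t exp(-2*pi*i*t/T)|`; only its rank against its own permutation
#' null matters, so the normalization is immaterial. The phase estimate is
#' the continuous arg-max of the projection onto `cos(2*pi*(t - phi)/T)`
#' (closed form from the real and imaginary parts). The null is obtained by
#' recomputing the statistic over random permutations of the data and is
#' modelled by a Gamma distribution parameterized by the method of moments
#' (`shape = mean^2/var`, `scale = var/mean`); `pMethod = "rank"` uses the
#' raw add-one permutation rank instead. Other periods are tested simply by
#' changing `period`.
#'
#' @param x numeric series aligned to `grid`.
#' @param grid a [TimeGrid-class].
#' @param period test period in hours (default 24).
#' @param nPerm number of permutations for the null (default 100, minimum
#'   30).
#' @param seed optional integer seed for the permutations.
#' @param pMethod `"gamma"` (default) or `"rank"`.
#' @return list with `statistic`, `phase` (hours in `[0, period)`), `p`,
#'   and the Gamma fit `shape`/`scale` (NA for `pMethod = "rank"`).
#' @examples
#' g <- regularGrid(12, 2)
#' f24Test(cos(2 * pi * gridTimes(g) / 24), g, seed = 1)
#' @export
f24Test <- function(x, grid, period = 24, nPerm = 100L, seed = NULL,
                    pMethod = c("gamma", "rank")) {
    pMethod <- match.arg(pMethod)
    if (nPerm < 30L) stop("'nPerm' must be at least 30")
    t <- gridTimes(grid)
    if (length(x) != length(t)) stop("series length does not match the grid")
    w <- 2 * pi * t / period
    cv <- cos(w); sv <- sin(w)
    stat <- function(v) {
        C <- sum(v * cv); S <- sum(v * sv)
        sqrt(C^2 + S^2)
    }
    C <- sum(x * cv); S <- sum(x * sv)
    obs <- sqrt(C^2 + S^2)
    phase <- (period * atan2(S, C) / (2 * pi)) %% period
    if (sd(x) == 0)
        return(list(statistic = obs, phase = phase, p = 1,
                    shape = NA_real_, scale = NA_real_))
    perm <- .withSeed(seed, function()
        vapply(seq_len(nPerm), function(i) stat(sample(x)), numeric(1)))
    if (pMethod == "rank") {
        p <- (1 + sum(perm >= obs)) / (nPerm + 1)
        return(list(statistic = obs, phase = phase, p = p,
                    shape = NA_real_, scale = NA_real_))
    }
    fit <- gammaMomentFit(perm)
    p <- pgamma(obs, shape = fit$shape, scale = fit$scale,
                lower.tail = FALSE)
    list(statistic = obs, phase = phase, p = p,
         shape = fit$shape, scale = fit$scale)
}

#' Method-of-moments Gamma fit
#'
#' `shape = mean^2/var`, `scale = var/mean` from a sample (the permutation
#' statistics of [f24Test()]).
#'
#' @param x positive sample.
#' @return list with `shape` and `scale`.
#' @examples
#' # a sample with mean 2 and variance 2 fits shape 2, scale 1
#' @export
gammaMomentFit <- function(x) {
    m <- mean(x); v <- var(x)
    if (!is.finite(v) || v <= 0 || m <= 0)
        stop("degenerate sample: cannot fit a Gamma distribution")
    list(shape = m^2 / v, scale = v / m)
}

#' One-way ANOVA across time points
#'
#' Classical one-way F test with the distinct times modulo the period as
#' groups: samples from successive periods fold onto the same zeitgeber
#' time and act as replicates. Requires at least one group with two or more
#' members to estimate the within-group variance; with a single replicate
#' everywhere the method is undefined and an error of class
#' `"rhythmscan_anova_undefined"` is thrown (benchmark reports map it to
#' AUROC 0.5 by convention). A series with zero between-group variance
#' (all values equal) is defined to have `F = 0`, `p = 1`.
#'
#' @param x numeric vector (one series) or matrix (series in rows).
#' @param grid a [TimeGrid-class], or a plain numeric vector of group times
#'   (already modulo the period) for designs with fewer than 3 distinct
#'   time points.
#' @return data.frame with one row per series: `F`, `df1`, `df2`, `p`.
#' @examples
#' anovaTest(c(0, 1, 2, 3), c(0, 0, 12, 12))  # F = 8 on (1, 2) df
#' @export
anovaTest <- function(x, grid) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    ft <- if (is(grid, "TimeGrid")) foldedTimes(grid) else as.numeric(grid)
    if (ncol(x) != length(ft)) stop("series length does not match the grid")
    grp <- factor(ft)
    k <- nlevels(grp)
    n <- ncol(x)
    if (k < 2L) stop("need at least 2 time-point groups")
    if (n - k < 1L)
        stop(structure(class = c("rhythmscan_anova_undefined",
                                 "error", "condition"),
                       list(message = paste(
                           "ANOVA undefined: no time point has replicates"),
                           call = sys.call())))
    G <- model.matrix(~ grp - 1)          # n x k indicator
    ng <- colSums(G)
    gsum <- x %*% G
    gmean <- sweep(gsum, 2L, ng, `/`)
    tot <- rowSums(x)
    ssb <- rowSums(sweep(gmean^2, 2L, ng, `*`)) - tot^2 / n
    sst <- rowSums(x^2) - tot^2 / n
    ssw <- pmax(sst - ssb, 0)
    df1 <- k - 1L; df2 <- n - k
    Fstat <- (ssb / df1) / (ssw / df2)
    Fstat[sst == 0] <- 0                   # 0/0: all values equal
    p <- pf(Fstat, df1, df2, lower.tail = FALSE)
    p[sst == 0] <- 1
    data.frame(F = Fstat, df1 = df1, df2 = df2, p = p)
}

#' Interpolated pseudo-replicates
#'
#' Adds one pseudo-replicate per distinct time point: the value at `t_i` is
#' the mean of the replicate-averaged values at the cyclic neighbours
#' `t_{i-1}` and `t_{i+1}` (endpoints wrap modulo the period). This
#' augments the observation count at every time point so that ANOVA can be
#' applied to single-replicate data, but it introduces correlations between
#' data points, so p-values must be recomputed against a Monte-Carlo null
#' ([anovaMCNull()]) rather than taken from the F distribution.
#'
#' @param x numeric vector or matrix (series in rows).
#' @param grid a [TimeGrid-class] with at least 3 distinct time points.
#' @return list with the augmented `values` matrix and `grid`.
#' @export
makePseudoReplicates <- function(x, grid) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    ft <- foldedTimes(grid)
    ut <- sort(unique(ft))
    k <- length(ut)
    grp <- match(ft, ut)
    G <- model.matrix(~ factor(grp, levels = seq_len(k)) - 1)
    means <- sweep(x %*% G, 2L, colSums(G), `/`)   # series x k, time order
    left <- c(k, seq_len(k - 1L)); right <- c(2:k, 1L)
    pseudo <- (means[, left, drop = FALSE] + means[, right, drop = FALSE]) / 2
    list(values = cbind(x, pseudo),
         grid = timeGrid(c(gridTimes(grid), ut), gridPeriod(grid)))
}

#' Monte-Carlo null for pseudo-replicated ANOVA
#'
#' F statistics of i.i.d. Gaussian noise series run through
#' [makePseudoReplicates()] then [anovaTest()] on the given grid. Real
#' series are looked up against this null with the add-one estimator
#' ([anovaEmpiricalP()]); using the nominal F distribution instead would
#' underestimate the p-values because pseudo-replication correlates data
#' points.
#'
#' @param grid the original (un-augmented) [TimeGrid-class].
#' @param nSeries number of noise series (default `1e4`).
#' @param seed integer seed.
#' @return sorted numeric vector of null F statistics.
#' @export
anovaMCNull <- function(grid, nSeries = 1e4, seed) {
    n <- nSamples(grid)
    .withSeed(seed, function() {
        M <- matrix(rnorm(nSeries * n), nSeries, n)
        aug <- makePseudoReplicates(M, grid)
        sort(anovaTest(aug$values, aug$grid)$F)
    })
}

#' Empirical p-value against a Monte-Carlo F null
#'
#' `p = (1 + #{null >= F}) / (N + 1)`.
#'
#' @param F numeric vector of observed F statistics.
#' @param null sorted null statistics from [anovaMCNull()].
#' @return p-values in `(0, 1]`.
#' @export
anovaEmpiricalP <- function(F, null) {
    N <- length(null)
    (1 + N - findInterval(F, null, left.open = TRUE)) / (N + 1)
}
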