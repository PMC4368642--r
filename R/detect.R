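## Orchestration: one call from an expression matrix to a results table, and
## the benchmark harness reproducing the simulation experiments at
## configurable scale.

## Deterministic named sub-seeds derived from one top-level seed, so that the
## null, simulation and imputation streams are independent but reproducible.
.seedStream <- function(seed, what) {
    k <- .stringHash(what)
    as.integer((as.double(seed) * 48271 + k) %% (2^31 - 1))
}

#' Detect rhythmic series in an expression matrix
#'
#' Runs one detection method over every series and returns one row per
#' series with the method's p-value and the across-series
#' Benjamini-Hochberg adjusted value `q`.
#'
#' Methods: `"ejtk"` — best Kendall tau over the reference family with an
#' empirical Monte-Carlo p-value for the selection step; `"jtk-bonferroni"`
#' — the classical procedure (initial normal-approximation p of the best
#' tau, multiplied by the family size); `"jtk-bh"` — minimum
#' Benjamini-Hochberg adjusted per-waveform p within the series; `"f24"` —
#' Fourier projection with Gamma-fit permutation null; `"anova"` — one-way
#' F across time points (set `pseudoReplicates = TRUE` for single-replicate
#' designs, which switches the p-values to a Monte-Carlo null).
#'
#' @param values numeric matrix, series x samples (rownames = ids), or a
#'   [SimulatedDataset-class] (its grid is then used).
#' @param grid a [TimeGrid-class]; ignored when `values` is a
#'   `SimulatedDataset`.
#' @param method detection method, see above.
#' @param family [ReferenceFamily-class] for the JTK variants.
#' @param null optional precomputed [NullDistribution-class] for `"ejtk"`
#'   (signatures must match); sampled on the fly otherwise.
#' @param nNull null size when sampling on the fly.
#' @param seed top-level integer seed; sub-seeds for the null / permutation
#'   streams are derived from it.
#' @param pseudoReplicates augment with interpolated pseudo-replicates
#'   before ANOVA.
#' @param nPerm permutations per series for `"f24"`.
#' @param denseSearch allow a search grid denser than the data.
#' @param cacheDir optional null-cache directory (see [sampleNull()]).
#' @return data.frame with columns `id`, `phase`, `asymmetry`, `tau`,
#'   `p_initial`, `p`, `q`, `method`, `degenerate`; run metadata (method,
#'   family signature, seeds, null size) in the `"metadata"` attribute.
#' @export
detectRhythms <- function(values, grid = NULL,
                          method = c("ejtk", "jtk-bonferroni", "jtk-bh",
                                     "f24", "anova"),
                          family = referenceFamily(),
                          null = NULL, nNull = 2e5, seed = 1L,
                          pseudoReplicates = FALSE, nPerm = 100L,
                          denseSearch = FALSE, cacheDir = NULL) {
    method <- match.arg(method)
    if (is(values, "SimulatedDataset")) {
        grid <- datasetGrid(values)
        values <- datasetValues(values)
    }
    if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
    stopifnot(is(grid, "TimeGrid"))
    ids <- rownames(values) %||% as.character(seq_len(nrow(values)))
    n <- nSamples(grid)
    empty <- nrow(values) == 0L

    if (method %in% c("ejtk", "jtk-bonferroni", "jtk-bh")) {
        m <- familySize(family)
        if (empty) {
            bc <- data.frame(tau = numeric(0), phase = numeric(0),
                             asymmetry = numeric(0), degenerate = logical(0))
            pini <- pmeth <- numeric(0)
        } else if (method == "jtk-bh") {
            bc <- bestCorrelation(values, family, grid,
                                  denseSearch = denseSearch,
                                  returnAll = TRUE)
            pini <- initialPvalue(bc$tau, n)
            pmeth <- .minBHWithin(initialPvalue(attr(bc, "taus"), n))
        } else {
            bc <- bestCorrelation(values, family, grid,
                                  denseSearch = denseSearch)
            pini <- initialPvalue(bc$tau, n)
            pmeth <- if (method == "jtk-bonferroni") bonferroni(pini, m)
                     else NULL
        }
        nullUsed <- NA_integer_
        if (method == "ejtk" && !empty) {
            if (is.null(null))
                null <- sampleNull(grid, family, nNull,
                                   seed = .seedStream(seed, "null"),
                                   cacheDir = cacheDir,
                                   denseSearch = denseSearch)
            if (!identical(null@gridSignature, .gridSignature(grid)) ||
                !identical(null@familySignature, .familySignature(family)))
                stop("supplied null was sampled under a different ",
                     "grid/family")
            pmeth <- empiricalPvalue(bc$tau, null)
            nullUsed <- nullSize(null)
        }
        if (method == "ejtk" && empty) pmeth <- numeric(0)
        out <- data.frame(id = ids, phase = bc$phase,
                          asymmetry = bc$asymmetry, tau = bc$tau,
                          p_initial = pini, p = pmeth,
                          q = bhAdjust(pmeth),
                          method = rep_len(method, length(ids)),
                          degenerate = bc$degenerate,
                          stringsAsFactors = FALSE)
        attr(out, "metadata") <- list(
            method = method, family = .familySignature(family),
            grid = .gridSignature(grid), seed = seed, nNull = nullUsed,
            version = as.character(utils::packageVersion("rhythmscan")))
        return(out)
    }

    if (method == "f24") {
        res <- if (empty) list() else lapply(seq_len(nrow(values)),
            function(i) f24Test(values[i, ], grid,
                                period = gridPeriod(grid), nPerm = nPerm,
                                seed = .seedStream(seed, paste0("f24.", i))))
        p <- vapply(res, `[[`, numeric(1), "p")
        out <- data.frame(id = ids,
                          phase = vapply(res, `[[`, numeric(1), "phase"),
                          asymmetry = rep_len(NA_real_, length(ids)),
                          tau = rep_len(NA_real_, length(ids)),
                          p_initial = p, p = p,
                          q = bhAdjust(p),
                          method = rep_len(method, length(ids)),
                          degenerate = rep_len(FALSE, length(ids)),
                          stringsAsFactors = FALSE)
    } else {                                   # anova
        g2 <- grid; v2 <- values
        if (pseudoReplicates) {
            aug <- makePseudoReplicates(values, grid)
            v2 <- aug$values; g2 <- aug$grid
        }
        av <- anovaTest(v2, g2)
        p <- if (pseudoReplicates) {
            nullF <- anovaMCNull(grid, 1e4,
                                 seed = .seedStream(seed, "anova.null"))
            anovaEmpiricalP(av$F, nullF)
        } else av$p
        if (empty) p <- numeric(0)
        out <- data.frame(id = ids,
                          phase = rep_len(NA_real_, length(ids)),
                          asymmetry = rep_len(NA_real_, length(ids)),
                          tau = rep_len(NA_real_, length(ids)),
                          p_initial = p, p = p,
                          q = bhAdjust(p),
                          method = rep_len(method, length(ids)),
                          degenerate = rep_len(FALSE, length(ids)),
                          stringsAsFactors = FALSE)
    }
    attr(out, "metadata") <- list(
        method = method, grid = .gridSignature(grid), seed = seed,
        pseudoReplicates = pseudoReplicates,
        version = as.character(utils::packageVersion("rhythmscan")))
    out
}

#' Run a simulation benchmark
#'
#' Reproduces the simulated-benchmark layout at configurable scale: for
#' every combination of waveform shape, noise fraction, sampling density
#' and replicate count, generates `nSeries` rhythmic series plus `nSeries`
#' Gaussian-noise negatives, runs each method, and reports the AUROC
#' (p-value orientation: low = rhythmic). Single-replicate ANOVA, for which
#' the method is undefined, is reported as AUROC 0.5 exactly by convention.
#' Identical config and seed give an identical report.
#'
#' @param shapes character vector of waveform shapes.
#' @param noiseFractions numeric vector (e.g. `c(0.25, 0.5)`).
#' @param pointsPerPeriod,replicates integer vectors of design options.
#' @param methods subset of `c("ejtk", "jtk-bonferroni", "jtk-bh", "f24",
#'   "anova")`.
#' @param nSeries series per class per condition.
#' @param seed top-level seed.
#' @param family reference family for the JTK variants.
#' @param nNull null size for `"ejtk"`.
#' @param pseudoReplicates apply pseudo-replication to ANOVA.
#' @param denseSearch allow search grids denser than the data.
#' @return data.frame: one row per condition x method with an `auroc`
#'   column.
#' @export
runBenchmark <- function(shapes = "sine", noiseFractions = 0.5,
                         pointsPerPeriod = 12, replicates = 2,
                         methods = c("ejtk", "f24", "anova"),
                         nSeries = 500, seed = 1L,
                         family = referenceFamily(),
                         nNull = 2e4, pseudoReplicates = FALSE,
                         denseSearch = FALSE) {
    known <- c("ejtk", "jtk-bonferroni", "jtk-bh", "f24", "anova")
    if (!all(methods %in% known))
        stop("unknown method: ", paste(setdiff(methods, known),
                                       collapse = ", "))
    conds <- expand.grid(shape = shapes, noise = noiseFractions,
                         points = pointsPerPeriod, reps = replicates,
                         method = methods, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
    conds$auroc <- NA_real_
    for (i in seq_len(nrow(conds))) {
        cn <- conds[i, ]
        tag <- paste(cn$shape, cn$noise, cn$points, cn$reps, sep = "|")
        pos <- simWaveformData(cn$shape, nSeries, cn$points, cn$reps,
                               cn$noise, seed = .seedStream(seed,
                                   paste0("pos.", tag)))
        neg <- simNoiseData(nSeries, datasetGrid(pos),
                            seed = .seedStream(seed, paste0("neg.", tag)))
        if (cn$method == "anova" && cn$reps == 1L && !pseudoReplicates) {
            conds$auroc[i] <- 0.5       # undefined: reported by convention
            next
        }
        vals <- rbind(datasetValues(pos), datasetValues(neg))
        res <- detectRhythms(vals, datasetGrid(pos), method = cn$method,
                             family = family, nNull = nNull,
                             seed = .seedStream(seed, paste0("det.", tag)),
                             pseudoReplicates = pseudoReplicates,
                             denseSearch = denseSearch)
        conds$auroc[i] <- auroc(res$p[seq_len(nSeries)],
                                res$p[nSeries + seq_len(nSeries)], "low")
    }
    conds
}
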