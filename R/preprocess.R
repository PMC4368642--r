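## Z-score merging of multi-study expression data, probe collapsing, and the
## missing-value policy. Column times are zeitgeber times (ZT) in hours and
## are reduced modulo 24 (ZT24 is equivalent to ZT0); native offsets are
## preserved (a ZT1 column stays at 1 h, no interpolation onto a common
## grid), and same-ZT columns across studies become replicates.

#' Z-score and pool expression studies
#'
#' For each gene in each study, subtracts the mean and divides by the
#' (sample) standard deviation over its finite values, then pools the
#' columns of all studies, keeping native ZT labels. Different affine
#' scales between laboratories cancel, so profiles of the same underlying
#' signal become directly comparable. A gene with fewer than two finite
#' values or zero variance within a study has that gene-study block set to
#' missing, with a warning.
#'
#' @param studies named list of numeric matrices; rownames are gene (or
#'   probe) identifiers, colnames are ZT labels (`"ZT00"`, `"ZT04"`, ... or
#'   plain numbers; repeated labels are replicates). Genes are matched on
#'   the intersection of rownames across studies.
#' @return list with `values` (merged matrix, genes x pooled samples),
#'   `times` (numeric ZT hours per column, modulo 24), `study` (source of
#'   each column), and `scaling` (per-study data.frame of the means/sds
#'   applied).
#' @export
zscoreMerge <- function(studies) {
    if (is.null(names(studies)) || any(!nzchar(names(studies))))
        names(studies) <- paste0("study", seq_along(studies))
    genes <- Reduce(intersect, lapply(studies, rownames))
    if (length(genes) == 0L) stop("no common gene identifiers across studies")
    pieces <- vector("list", length(studies))
    scaling <- vector("list", length(studies))
    for (k in seq_along(studies)) {
        m <- as.matrix(studies[[k]])[genes, , drop = FALSE]
        mu <- apply(m, 1L, function(r) mean(r[is.finite(r)]))
        sdv <- apply(m, 1L, function(r) sd(r[is.finite(r)]))
        bad <- !is.finite(sdv) | sdv == 0
        if (any(bad)) {
            warning(sum(bad), " gene(s) with undefined Z-scores in study '",
                    names(studies)[k], "' set to missing", call. = FALSE)
            m[bad, ] <- NA_real_
            sdv[bad] <- NA_real_
        }
        z <- (m - mu) / sdv
        z[!is.finite(m)] <- NA_real_
        pieces[[k]] <- z
        scaling[[k]] <- data.frame(gene = genes, mean = mu, sd = sdv,
                                   row.names = NULL)
    }
    values <- do.call(cbind, pieces)
    times <- unlist(lapply(studies, function(s)
        parseZTLabels(colnames(s))), use.names = FALSE)
    study <- rep(names(studies), vapply(studies, ncol, integer(1)))
    names(scaling) <- names(studies)
    list(values = values, times = times %% 24, study = study,
         scaling = scaling)
}

#' Parse ZT column labels
#'
#' Accepts `"ZT00"`, `"zt4"`, or plain numeric strings; values are returned
#' in hours (not yet reduced modulo 24).
#'
#' @param labels character vector.
#' @return numeric hours.
#' @export
parseZTLabels <- function(labels) {
    x <- sub("^\\s*[Zz][Tt]\\s*", "", labels)
    x <- sub("\\.[0-9]+$", "", x)        # make.names suffixes on duplicates
    t <- suppressWarnings(as.numeric(x))
    if (anyNA(t))
        stop("unparseable ZT labels: ",
             paste(labels[is.na(t)], collapse = ", "))
    t
}

#' Collapse probes to genes
#'
#' Keeps, for every gene, the probe with the highest mean expression
#' (finite values only); equal means are broken by the lexicographically
#' smaller probe identifier.
#'
#' @param values probe-level matrix with probe rownames.
#' @param map named character vector: `map[probe] = gene`; must cover all
#'   probes.
#' @return gene-level matrix with gene rownames and a `"probe"` attribute
#'   recording the retained probe per gene.
#' @export
collapseProbes <- function(values, map) {
    probes <- rownames(values)
    if (is.null(probes) || anyNA(map[probes]))
        stop("'map' must cover all probe rownames")
    means <- apply(values, 1L, function(r) mean(r[is.finite(r)]))
    ord <- order(map[probes], -means, probes)   # best probe first per gene
    keep <- ord[!duplicated(map[probes][ord])]
    out <- values[keep, , drop = FALSE]
    chosen <- probes[keep]
    rownames(out) <- unname(map[chosen])
    attr(out, "probe") <- stats::setNames(chosen, rownames(out))
    out
}

#' Missing-value policy: drop heavily missing series, impute the rest
#'
#' Series with strictly more than half their points missing are discarded
#' (exactly half is retained). Remaining missing entries are replaced by
#' seeded Gaussian draws whose mean and standard deviation match the finite
#' values of the retained matrix as a whole — this keeps a single
#' permutation null valid for every series instead of one per
#' missing-data pattern. Discarding precedes the computation of the
#' imputation moments.
#'
#' @param values numeric matrix (typically Z-scored), NAs mark missing.
#' @param seed integer seed for the imputation draws.
#' @return list with `values` (filtered, imputed), `dropped` (rownames or
#'   indices of discarded series), and `imputed` (count of filled cells).
#' @export
applyNAPolicy <- function(values, seed) {
    frac <- rowMeans(!is.finite(values))
    drop <- frac > 0.5
    kept <- values[!drop, , drop = FALSE]
    ids <- if (!is.null(rownames(values))) rownames(values)
           else seq_len(nrow(values))
    fin <- kept[is.finite(kept)]
    na <- !is.finite(kept)
    if (any(na)) {
        kept[na] <- .withSeed(seed, function()
            rnorm(sum(na), mean = mean(fin), sd = sd(fin)))
    }
    list(values = kept, dropped = ids[drop], imputed = sum(na))
}
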