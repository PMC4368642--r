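## Detector scoring: AUROC (rank / Mann-Whitney form), Matthews correlation
## coefficient, cumulative discovery curves.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' outranks a random negative, with ties counted half. Independent of class
#' proportions. `orientation` declares whether small scores indicate
#' rhythmicity (`"low"`, the convention for p-values) or large scores do
#' (`"high"`, for raw test statistics).
#'
#' @param scoresPos scores of the true positives.
#' @param scoresNeg scores of the true negatives.
#' @param orientation `"low"` or `"high"`.
#' @return AUROC in `[0, 1]`; 1 is perfect, 0.5 is random.
#' @examples
#' auroc(c(.001, .01), c(.5, .9), "low")   # 1
#' @export
auroc <- function(scoresPos, scoresNeg, orientation = c("low", "high")) {
    orientation <- match.arg(orientation)
    nP <- length(scoresPos); nN <- length(scoresNeg)
    if (nP == 0L || nN == 0L) stop("both classes must be non-empty")
    s <- c(scoresPos, scoresNeg)
    if (orientation == "low") s <- -s
    r <- rank(s)                       # midranks: ties get half credit
    (sum(r[seq_len(nP)]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Matthews correlation coefficient
#'
#' Balanced summary of the 2x2 confusion matrix in `[-1, 1]`: 1 when calls
#' match truth exactly, -1 when they are exactly inverted, 0 when any
#' denominator factor vanishes.
#'
#' @param calls logical vector of positive calls.
#' @param truth logical vector of true labels, same length.
#' @return MCC.
#' @export
mcc <- function(calls, truth) {
    if (length(calls) != length(truth)) stop("length mismatch")
    calls <- as.logical(calls); truth <- as.logical(truth)
    tp <- as.numeric(sum(calls & truth)); tn <- as.numeric(sum(!calls & !truth))
    fp <- as.numeric(sum(calls & !truth)); fn <- as.numeric(sum(!calls & truth))
    den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den2 == 0) return(0)
    (tp * tn - fp * fn) / sqrt(den2)
}

#' Cumulative discovery counts
#'
#' Number of series with p-value (or FDR-adjusted value) at or below each
#' threshold — the cumulative-histogram view of a detector's output.
#'
#' @param p numeric vector of p/q-values in `(0, 1]`.
#' @param thresholds significance thresholds (default a grid up to 0.2).
#' @return named integer vector of counts, non-decreasing in the threshold.
#' @export
cumulativeDiscoveries <- function(p, thresholds = seq(0.01, 0.2, by = 0.01)) {
    out <- vapply(thresholds, function(th) sum(p <= th), integer(1))
    names(out) <- format(thresholds)
    out
}
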