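# Independent oracles kept deliberately naive: these re-derive expected
# values by enumeration or textbook formulas, never by calling the code they
# check.

# O(n^2) brute-force Kendall tau (tau-a): explicit double loop over pairs.
bruteTau <- function(x, y) {
  n <- length(x)
  num <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- num + sign(x[j] - x[i]) * sign(y[j] - y[i])
    }
  }
  num / (n * (n - 1) / 2)
}

# All permutations of 1:n (recursive, fine for n <= 7).
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Exact one-sided upper-tail p of Kendall's S against the identity ranking,
# over all n! rank orders: p(s) = #{S' >= s} / n!.
exactKendallSTailFun <- function(n) {
  P <- allPerms(n)
  ref <- seq_len(n)
  S <- apply(P, 1, function(pm) {
    num <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num <- num + sign(pm[j] - pm[i])
      }
    }
    num
  })
  function(s) mean(S >= s)
}

# Trapezoidal AUROC from an explicit threshold sweep over the empirical ROC
# curve (scores oriented so larger = more positive).
trapezoidAuroc <- function(scoresPos, scoresNeg) {
  th <- sort(unique(c(scoresPos, scoresNeg, Inf, -Inf)), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(scoresPos >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(scoresNeg >= t), numeric(1))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}
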