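mkStudy <- function(values, times) {
  colnames(values) <- sprintf("ZT%02d", times)
  values
}

test_that("Z-scoring centres and scales each gene within each study", {
  s <- mkStudy(matrix(c(1, 2, 3), 1, dimnames = list("g1", NULL)),
               c(0, 4, 8))
  m <- zscoreMerge(list(a = s))
  expect_equal(unname(m$values[1, ]), c(-1, 0, 1))
  # post-merge property: every finite gene-study block has mean 0, sd 1
  set.seed(15)
  s1 <- mkStudy(matrix(rnorm(40, 5, 3), 4,
                       dimnames = list(paste0("g", 1:4), NULL)),
                rep(seq(0, 20, 4), length.out = 10))
  s2 <- mkStudy(matrix(rnorm(24, -2, 0.1), 4,
                       dimnames = list(paste0("g", 1:4), NULL)),
                seq(1, 21, 4))
  s1[2, 3] <- NA
  m <- zscoreMerge(list(x = s1, y = s2))
  for (st in unique(m$study)) {
    blk <- m$values[, m$study == st, drop = FALSE]
    for (i in seq_len(nrow(blk))) {
      v <- blk[i, is.finite(blk[i, ])]
      expect_lt(abs(mean(v)), 1e-12)
      expect_lt(abs(sd(v) - 1), 1e-12)
    }
  }
})

test_that("Z-scores are invariant to affine rescaling between laboratories", {
  set.seed(16)
  base <- matrix(rnorm(30), 3, dimnames = list(paste0("g", 1:3), NULL))
  s1 <- mkStudy(base, rep(seq(0, 16, 4), 2))
  s2 <- mkStudy(7 * base + 100, rep(seq(0, 16, 4), 2))
  m <- zscoreMerge(list(a = s1, b = s2))
  expect_equal(m$values[, m$study == "a"], m$values[, m$study == "b"],
               ignore_attr = TRUE)
})

test_that("ZT labels parse and fold: ZT24 is ZT0", {
  expect_equal(parseZTLabels(c("ZT00", "zt4", "8", "ZT24")), c(0, 4, 8, 24))
  s <- mkStudy(matrix(rnorm(8), 2, dimnames = list(c("g1", "g2"), NULL)),
               c(0, 8, 16, 24))
  m <- zscoreMerge(list(a = s))
  expect_equal(m$times, c(0, 8, 16, 0))
  expect_error(parseZTLabels("ZTx"), "unparseable")
})

test_that("genes with undefined Z-scores are blanked with a warning", {
  s <- mkStudy(rbind(g1 = c(1, 1, 1, 1), g2 = c(1, 2, 3, 4)),
               c(0, 6, 12, 18))
  expect_warning(m <- zscoreMerge(list(a = s)), "undefined Z-scores")
  expect_true(all(is.na(m$values["g1", ])))
  expect_false(anyNA(m$values["g2", ]))
})

test_that("probe collapsing keeps the highest-mean probe with a lexicographic tie-break", {
  v <- rbind(p1 = c(5, 5, 5), p2 = c(3, 3, 3), p3 = c(1, 2, 3))
  map <- c(p1 = "gA", p2 = "gA", p3 = "gB")
  out <- collapseProbes(v, map)
  expect_equal(rownames(out), c("gA", "gB"))
  expect_equal(attr(out, "probe")[["gA"]], "p1")
  expect_equal(unname(out["gA", ]), c(5, 5, 5))
  # single probe: identity
  one <- collapseProbes(v["p3", , drop = FALSE], map)
  expect_equal(unname(one[1, ]), c(1, 2, 3))
  # equal means: lexicographically smaller probe id retained
  v2 <- rbind(pB = c(2, 2), pA = c(1, 3))
  out2 <- collapseProbes(v2, c(pA = "g", pB = "g"))
  expect_equal(unname(attr(out2, "probe")), "pA")
  expect_error(collapseProbes(v, map[1:2]), "cover")
})

test_that("NA policy drops strictly-more-than-half-missing series and imputes the rest", {
  m <- matrix(rnorm(32), 4, 8,
              dimnames = list(paste0("g", 1:4), NULL))
  m[1, 1:5] <- NA       # 5 of 8 missing: dropped
  m[2, 1:4] <- NA       # exactly half: retained
  out <- applyNAPolicy(m, seed = 2)
  expect_equal(out$dropped, "g1")
  expect_equal(rownames(out$values), c("g2", "g3", "g4"))
  expect_false(anyNA(out$values))
  expect_equal(out$imputed, 4)
  # identical seeds give identical imputations
  expect_identical(out$values, applyNAPolicy(m, seed = 2)$values)
  expect_false(identical(out$values, applyNAPolicy(m, seed = 3)$values))
  # no missing values: identity
  clean <- matrix(rnorm(12), 2)
  expect_equal(applyNAPolicy(clean, seed = 1)$values, clean)
})

test_that("moderate masking plus imputation preserves most detections", {
  # metadataset-like fixture: long pooled series (12 time points x 4
  # replicates, as when several studies are merged), clearly rhythmic
  # signals. Masking a quarter of the points removes ~44% of the rank
  # pairs, so the check needs series long enough that detections have
  # margin over the max-tau null; the surviving headroom is what
  # imputation must not destroy
  grid <- regularGrid(12, 4)
  fam <- referenceFamily()
  set.seed(31)
  combos <- familyGrid(fam)
  pick <- sample(nrow(combos), 100, replace = TRUE)
  pos <- t(sapply(pick, function(k)
    evaluateWaveform(grid, combos$phase[k], combos$asymmetry[k]) +
      rnorm(nSamples(grid), sd = 0.2)))
  neg <- matrix(rnorm(900 * nSamples(grid)), 900)
  v <- rbind(pos, neg)
  rownames(v) <- paste0("s", seq_len(nrow(v)))
  null <- suppressWarnings(sampleNull(grid, fam, 2e4, seed = 55))
  callsAt <- function(values) {
    res <- detectRhythms(values, grid, "ejtk", null = null, seed = 1)
    res$id[res$q <= 0.05]
  }
  full <- callsAt(v)
  # mask 25% of the points of every rhythmic series, then impute
  masked <- v
  set.seed(77)
  for (i in seq_len(100))
    masked[i, sample(ncol(v), ncol(v) / 4)] <- NA
  imp <- applyNAPolicy(masked, seed = 9)
  expect_length(imp$dropped, 0)
  kept <- callsAt(imp$values)
  expect_gte(length(intersect(kept, full)) / length(full), 0.9)
})
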