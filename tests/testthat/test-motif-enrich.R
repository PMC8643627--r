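test_that("identical foreground and background enrich nothing", {
  set.seed(20)
  seqs <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""),
    character(1))
  panel <- defaultMotifPanel(n = 3, nDrivers = 1, seed = 21)
  rec <- enrichTwoSets(seqs, seqs, panel, seed = 1)
  expect_true(all(rec$p >= 0.5))
  expect_false(any(rec$enriched))
})

test_that("Fisher p equals the exhaustive hypergeometric tail", {
  ## one-sided P(fg hits >= a) for fixed margins, enumerated from
  ## binomial coefficients (independent of stats::fisher.test)
  hyperTail <- function(a, nf, b, nb) {
    K <- a + b; N <- nf + nb
    amax <- min(K, nf)
    pr <- vapply(0:amax, function(x)
      exp(lchoose(nf, x) + lchoose(nb, K - x) - lchoose(N, K)), 1)
    sum(pr[(a:amax) + 1L])
  }
  cases <- rbind(c(18, 20, 5, 20), c(3, 10, 7, 10), c(0, 5, 5, 5),
                 c(12, 15, 2, 30))
  for (i in seq_len(nrow(cases))) {
    a <- cases[i, 1]; nf <- cases[i, 2]; b <- cases[i, 3]; nb <- cases[i, 4]
    got <- fisher.test(matrix(c(a, nf - a, b, nb - b), 2),
                       alternative = "greater")$p.value
    expect_equal(got, hyperTail(a, nf, b, nb), tolerance = 1e-12)
  }
})

test_that("planted motifs are flagged enriched against background", {
  panel <- defaultMotifPanel(n = 5, nDrivers = 2, seed = 22)
  lab <- simulateLabeledSequences(nPerClass = 200, panel = panel,
                                  pActive = 0.6, pInactive = 0.1,
                                  seed = 23)
  fg <- lab$sequences[lab$labels == "active"]
  bg <- lab$sequences[lab$labels == "inactive"]
  rec <- enrichTwoSets(fg, bg, panel, seed = 24)
  drv <- rec[startsWith(rec$motif, "driver"), ]
  expect_true(all(drv$enriched))
  expect_true(all(drv$E <= 1e-3))
  expect_true(all(drv$log_ratio > 0))
})

test_that("background subsampling is stable across seeds", {
  panel <- defaultMotifPanel(n = 2, nDrivers = 1, seed = 25)
  lab <- simulateLabeledSequences(nPerClass = 100, panel = panel,
                                  seed = 26)
  fg <- lab$sequences[lab$labels == "active"][1:40]
  bg <- lab$sequences[lab$labels == "inactive"]  # larger: subsampling on
  e1 <- enrichTwoSets(fg, bg, panel, seed = 1)$E[1]
  e2 <- enrichTwoSets(fg, bg, panel, seed = 2)$E[1]
  expect_lt(abs(log10(e1) - log10(e2)), 1)  # mean-of-10 E-values agree
  expect_error(enrichTwoSets(bg, fg, panel), "smaller than")
  expect_error(enrichTwoSets(fg[0], bg, panel), "empty foreground")
})

test_that("a composite planted in one class shows its max Z there", {
  hs <- rarHalfSite()
  dr5 <- buildComposite(hs, "DR", 5)
  set.seed(27)
  mkSeqs <- function(n, plant) {
    vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
      if (plant && runif(1) < 0.7)
        substr(s, 50, 49 + motifWidth(dr5)) <-
          starrkit:::sampleMotifInstance(dr5)
      s
    }, character(1))
  }
  sets <- list(induced = mkSeqs(60, TRUE), repressed = mkSeqs(60, FALSE),
               non_responding = mkSeqs(60, FALSE))
  res <- spacingEnrichment(sets, buildAllComposites(hs), seed = 28)
  expect_true("DR5" %in% rownames(res$Z))
  expect_equal(names(which.max(res$Z["DR5", ])), "induced")
  ## Z-scored rows have mean 0 and unit variance
  expect_true(all(abs(rowMeans(res$Z)) < 1e-9))
  expect_true(all(abs(apply(res$Z, 1, sd) - 1) < 1e-9))
})

test_that("no composite passes on random sequence", {
  hs <- rarHalfSite()
  comps <- buildAllComposites(hs)
  for (seed in 31:33) {
    set.seed(seed)
    sets <- lapply(c(a = 1, b = 2, c = 3), function(i)
      vapply(1:40, function(j)
        paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = ""),
        character(1)))
    res <- spacingEnrichment(sets, comps, seed = seed)
    expect_equal(nrow(res$E), 0L)
  }
})

test_that("enrichment-matrix clustering recovers planted row groups", {
  set.seed(34)
  mu <- rbind(c(8, 0, 0), c(0, 8, 0), c(0, 0, 8))
  mat <- mu[rep(1:3, each = 6), ] + matrix(rnorm(54, sd = 0.3), 18)
  rownames(mat) <- sprintf("m%02d", 1:18)
  res <- clusterEnrichmentMatrix(mat, k = 3)
  expect_equal(mclust::adjustedRandIndex(res$groups, rep(1:3, each = 6)), 1)
  ## identical rows merge first
  m2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(9, 9))
  tree <- clusterEnrichmentMatrix(m2)$tree
  expect_equal(tree$height[1], 0)
  ## partition invariant under row permutation
  perm <- sample(nrow(mat))
  res2 <- clusterEnrichmentMatrix(mat[perm, ], k = 3)
  expect_equal(mclust::adjustedRandIndex(res$groups,
                                         res2$groups[rownames(mat)]), 1)
})
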