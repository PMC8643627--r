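test_that("k-means recovers planted clusters and orders labels by activity", {
  cfg <- synthConfig(seed = 50L, nHmClusters = 2L, hmNoiseSd = 0.2)
  hm <- simulateHmMatrix(cfg, 80L)
  km <- kmeansHm(hm$matrix, k = 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(hm$labels, km$labels), 1)
  ## zero-noise: exact recovery
  cfg0 <- synthConfig(seed = 51L, nHmClusters = 3L, hmNoiseSd = 0)
  hm0 <- simulateHmMatrix(cfg0, 60L)
  km0 <- kmeansHm(hm0$matrix, k = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(hm0$labels, km0$labels), 1)
  ## labels ordered by the activity column: cluster 1 has the highest mean
  act <- tapply(hm0$matrix[, "H3K27ac"], km0$labels, mean)
  expect_equal(order(-act), seq_along(act))
  expect_error(kmeansHm(hm0$matrix, k = 100), "exceeds")
})

test_that("k-means partition is invariant to row order", {
  cfg <- synthConfig(seed = 52L, nHmClusters = 3L, hmNoiseSd = 0.5)
  hm <- simulateHmMatrix(cfg, 90L)
  km <- kmeansHm(hm$matrix, k = 3, seed = 7)
  set.seed(1)
  perm <- sample(nrow(hm$matrix))
  km2 <- kmeansHm(hm$matrix[perm, ], k = 3, seed = 7)
  expect_equal(mclust::adjustedRandIndex(km$labels[perm], km2$labels), 1)
})

test_that("column standardization absorbs per-mark affine rescaling", {
  cfg <- synthConfig(seed = 53L, nHmClusters = 3L, hmNoiseSd = 0.5)
  hm <- simulateHmMatrix(cfg, 90L)
  km <- kmeansHm(hm$matrix, k = 3, seed = 7)
  scaled <- sweep(sweep(hm$matrix, 2, c(2, 5, 1, 3, 7, 2, 4, 9), "*"),
                  2, seq_len(8), "+")
  km2 <- kmeansHm(scaled, k = 3, seed = 7)
  expect_equal(mclust::adjustedRandIndex(km$labels, km2$labels), 1)
})

test_that("expression by group conserves genes and detects monotone signal", {
  set.seed(54)
  n <- 1000
  groups <- rep(1:5, each = n / 5)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(n) * 2000L, width = 200L))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(n) * 2000L + 500L, width = 1L))
  genes$gene_id <- sprintf("g%04d", seq_len(n))
  tpm <- setNames(rgamma(n, shape = 2, rate = 1) * 2^groups,
                  genes$gene_id)
  res <- expressionByGroup(groups, regions, genes, tpm)
  expect_equal(sum(lengths(res$expression)), n)  # every gene in one group
  expect_true(all(diff(res$summary$mean) > 0))
  expect_true(all(res$tests$p <= 0.05))

  ## identical TPMs everywhere: no signal
  flat <- suppressWarnings(expressionByGroup(groups, regions, genes,
                            setNames(rep(1, n), genes$gene_id)))
  expect_true(all(flat$tests$p > 0.99))
})

test_that("Mann-Whitney on a 4-vs-4 toy equals exhaustive enumeration", {
  a <- c(1.2, 3.4, 2.2, 5.0)
  b <- c(0.8, 4.1, 6.3, 7.2)
  got <- wilcox.test(a, b)$p.value
  ## enumerate all choose(8,4) group assignments of the pooled values
  pool <- c(a, b)
  U <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- U(a, b)
  combos <- utils::combn(8, 4)
  stats <- apply(combos, 2, function(idx) U(pool[idx], pool[-idx]))
  mu <- length(a) * length(b) / 2
  pexact <- mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
  expect_equal(got, pexact, tolerance = 1e-12)
})

test_that("overlap accounting matches a brute-force pair scan", {
  set.seed(55)
  mk <- function(n) GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(5000, n), width = sample(50:150, n, TRUE)))
  sets <- list(starr = mk(30), crup = mk(40))
  res <- overlapAccounting(sets)
  brute <- sum(vapply(seq_along(sets$starr), function(i)
    any(GenomicRanges::start(sets$starr)[i] <=
          GenomicRanges::end(sets$crup) &
        GenomicRanges::end(sets$starr)[i] >=
          GenomicRanges::start(sets$crup)), logical(1)))
  got <- res$pairwise$overlap[res$pairwise$set_a == "starr"]
  expect_equal(got, brute)

  ## disjoint and identical sets
  far <- GenomicRanges::shift(sets$starr, 1e6)
  expect_equal(overlapAccounting(list(a = sets$starr,
    b = far))$pairwise$overlap, c(0L, 0L))
  expect_equal(overlapAccounting(list(a = sets$starr,
    b = sets$starr))$pairwise$overlap, c(30L, 30L))

  ## composition splits the labeled set by overlap status
  labs <- rep(c("A", "B", "C"), each = 10)
  comp <- overlapAccounting(sets, labels = labs)$composition$crup
  expect_equal(sum(comp), 30)
})
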