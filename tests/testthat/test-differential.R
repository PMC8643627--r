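mkSe <- function(umiLif, umiRa, input = rep(50L, nrow(umiLif))) {
  n <- nrow(umiLif)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq_len(n) * 1000L, width = 300L))
  names(regions) <- sprintf("region_%04d", seq_len(n))
  umi <- cbind(umiLif, umiRa)
  colnames(umi) <- c(paste0("LIF_", seq_len(ncol(umiLif))),
                     paste0("RA_", seq_len(ncol(umiRa))))
  rownames(umi) <- names(regions)
  cd <- S4Vectors::DataFrame(
    condition = rep(c("LIF", "RA"), c(ncol(umiLif), ncol(umiRa))),
    replicate = c(seq_len(ncol(umiLif)), seq_len(ncol(umiRa))),
    row.names = colnames(umi))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(umi = umi), rowRanges = regions, colData = cd)
  SummarizedExperiment::rowData(se)$input_count <- input
  SummarizedExperiment::rowData(se)$distinct_fragments <- rep(5L, n)
  new("StarrExperiment", se)
}

test_that("identical counts in both conditions are stable with zero lfc", {
  u <- matrix(50L, 20, 2)
  se <- mkSe(u, u)
  d <- differentialEnhancers(se)
  expect_true(all(d$class == "stable"))
  expect_true(all(abs(d$log2fc) < 1e-12))
})

test_that("condition swap exactly exchanges the differential classes", {
  fx <- differentialFixture()
  d <- fx$diff
  swapped <- differentialEnhancers(fx$se, conditions = c("RA", "LIF"))
  expect_equal(d$log2fc, -swapped$log2fc)
  expect_equal(d$region[d$class == "RA-inducible"],
               swapped$region[swapped$class == "LIF-dependent"])
  expect_equal(d$region[d$class == "LIF-dependent"],
               swapped$region[swapped$class == "RA-inducible"])
})

test_that("planted condition-specific enhancers are classified correctly", {
  fx <- differentialFixture()
  tab <- table(fx$diff$class, fx$sim$truth$class)
  expect_equal(unname(tab["RA-inducible", "RA-inducible"]),
               sum(fx$sim$truth$class == "RA-inducible"))
  expect_equal(unname(tab["LIF-dependent", "LIF-dependent"]),
               sum(fx$sim$truth$class == "LIF-dependent"))
  ## stable and inactive regions stay out of the differential classes
  expect_equal(sum(fx$diff$class != "stable"),
               sum(fx$sim$truth$class %in% c("RA-inducible",
                                             "LIF-dependent")))
})

test_that("a missing condition is refused before testing", {
  u <- matrix(50L, 5, 2)
  se <- mkSe(u, u)
  expect_error(differentialEnhancers(se, conditions = c("LIF", "EtOH")),
               "absent")
})

test_that("null libraries stay within the false-discovery budget", {
  fracs <- vapply(c(401L, 402L, 403L), function(seed) {
    cfg <- synthConfig(seed = seed, nInputRegions = 150L, depth = 100,
                       inputDepth = 150, fracActive = 0,
                       fracRaInducible = 0, fracLifDependent = 0)
    sim <- simulateGenome(cfg)
    lib <- simulateReporterLibrary(cfg, sim)
    mol <- dedupUmi(lib$fragments)
    se <- quantifyRegions(sim$regions, mol, lib$input)
    d <- differentialEnhancers(se)
    mean(d$class != "stable")
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("response-class sets are equal-sized, disjoint and floored", {
  fx <- differentialFixture()
  truth <- fx$sim$truth
  peaks <- fx$sim$regions[truth$class != "inactive"]
  ## floor disabled: at desk scale the library-composition normalization
  ## shifts absolute scores; the floor itself is tested separately
  rar <- classifyResponseSites(fx$diff, fx$sim$regions, peaks,
                               fraction = 0.10, floor = -Inf)
  expect_equal(length(rar$induced), rar$size)
  expect_equal(length(rar$repressed), rar$size)
  expect_equal(length(rar$non_responding), rar$size)
  expect_length(intersect(rar$induced, rar$repressed), 0)
  expect_length(intersect(rar$induced, rar$non_responding), 0)
  expect_length(intersect(rar$repressed, rar$non_responding), 0)

  ## planted induced/repressed sites are recovered
  expect_gte(jaccard(rar$induced,
                     truth$region[truth$class == "RA-inducible"]), 0.8)
  expect_gte(jaccard(rar$repressed,
                     truth$region[truth$class == "LIF-dependent"]), 0.8)
})

test_that("neighbor-gene pairing counts follow the DE table", {
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1000, 5000, 9000), width = 200))
  diff <- data.frame(region = c("e1", "e2", "e3"),
                     score_lif = 1, score_ra = 1,
                     log2fc = c(2, -2, 2), p = 0, p_adj = 0,
                     class = c("RA-inducible", "LIF-dependent",
                               "RA-inducible"))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1200, 5200, 9200), width = 1))
  genes$gene_id <- c("gUp", "gDown", "gMissing")
  de <- data.frame(gene_id = c("gUp", "gDown"),
                   log2fc = c(3, -3), p_adj = c(0.001, 0.001))
  expect_warning(
    counts <- pairDiffGenes(diff, regions, genes, de),
    "missing")
  ra <- counts[counts$class == "RA-inducible", ]
  expect_equal(ra$up, 1L)
  expect_equal(ra$unchanged, 1L)  # missing gene counted as unchanged
  lif <- counts[counts$class == "LIF-dependent", ]
  expect_equal(lif$down, 1L)
  ## genes beyond the pairing distance contribute nothing
  far <- pairDiffGenes(diff, regions, genes, de, maxDistance = 10)
  expect_true(all(far$up == 0 & far$down == 0 & far$unchanged == 0))
})
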