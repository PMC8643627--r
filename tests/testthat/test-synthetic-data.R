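test_that("config invariants are enforced", {
  expect_error(synthConfig(fracActive = 0.02, fracRaInducible = 0.02,
                           fracLifDependent = 0.02), "exceed")
  expect_error(synthConfig(pcrDuplicationRate = 0.5), "pcrDuplicationRate")
  expect_error(synthConfig(nHmClusters = 1L), "2 planted")
})

test_that("simulated regions are non-overlapping, sized and deterministic", {
  cfg <- synthConfig(seed = 11L, nInputRegions = 100L)
  sim <- simulateGenome(cfg)
  expect_length(sim$regions, 100L)
  hits <- GenomicRanges::findOverlaps(sim$regions, drop.self = TRUE)
  expect_length(hits, 0L)

  sim2 <- simulateGenome(cfg)
  expect_identical(as.character(sim$genome), as.character(sim2$genome))
  expect_identical(sim$truth, sim2$truth)

  expect_error(
    simulateGenome(synthConfig(seed = 1, nInputRegions = 500L,
                               nChrom = 1L, chromLength = 100000L)),
    "increase chromLength")
})

test_that("region widths follow the configured log-normal law", {
  cfg <- synthConfig(seed = 12L, nInputRegions = 2000L, nChrom = 4L,
                     chromLength = 1000000L)
  sim <- simulateGenome(cfg)
  med <- median(GenomicRanges::width(sim$regions))
  expect_lt(abs(med - 350) / 350, 0.10)
})

test_that("motif insertion frequencies match configured probabilities", {
  panel <- defaultMotifPanel(n = 2, nDrivers = 1, seed = 5)
  lab <- simulateLabeledSequences(nPerClass = 500L, panel = panel,
                                  pActive = 0.6, pInactive = 0.1,
                                  seed = 13L)
  act <- which(lab$labels == "active")
  ins <- lab$insertions
  fA <- mean(act %in% ins$seq[ins$motif == "driver_1"])
  fI <- mean(setdiff(seq_len(1000), act) %in%
             ins$seq[ins$motif == "driver_1"])
  ## binomial 3-sigma bands at n = 500
  expect_lt(abs(fA - 0.6), 3 * sqrt(0.6 * 0.4 / 500))
  expect_lt(abs(fI - 0.1), 3 * sqrt(0.1 * 0.9 / 500))
})

test_that("reporter library conserves molecules and duplicate counts", {
  cfg <- synthConfig(seed = 14L, nInputRegions = 40L, depth = 50,
                     inputDepth = 50, conditions = "LIF",
                     fracRaInducible = 0, fracLifDependent = 0)
  sim <- simulateGenome(cfg)
  lib <- simulateReporterLibrary(cfg, sim)
  ## every fragment maps to exactly one molecule; per-molecule row counts
  ## equal the recorded multiplicities
  expect_true(all(lib$fragments$molecule_id %in% lib$molecules$molecule_id))
  tab <- table(lib$fragments$molecule_id)
  expect_equal(as.integer(tab[as.character(lib$molecules$molecule_id)]),
               lib$molecules$reads)
  expect_equal(sum(lib$molecules$reads), nrow(lib$fragments))
})

test_that("duplication rate 1 emits every molecule exactly once", {
  cfg <- synthConfig(seed = 15L, nInputRegions = 30L, depth = 30,
                     inputDepth = 30, pcrDuplicationRate = 1,
                     conditions = "LIF",
                     fracRaInducible = 0, fracLifDependent = 0)
  sim <- simulateGenome(cfg)
  lib <- simulateReporterLibrary(cfg, sim)
  expect_equal(nrow(lib$fragments), nrow(lib$molecules))
  expect_true(all(lib$molecules$reads == 1L))
})

test_that("planted fold ratios are recovered at the molecule level", {
  cfg <- synthConfig(seed = 16L, nInputRegions = 60L, depth = 500,
                     conditions = "LIF", activityGrid = 8,
                     fracActive = 0.2, fracRaInducible = 0,
                     fracLifDependent = 0, pcrDuplicationRate = 1)
  sim <- simulateGenome(cfg)
  lib <- simulateReporterLibrary(cfg, sim)
  mol <- dedupUmi(lib$fragments)
  counts <- table(factor(mol$region, levels = sim$truth$region))
  act <- sim$truth$is_active
  ratio <- mean(counts[act]) / mean(counts[!act])
  expect_lt(abs(ratio - 8) / 8, 0.1)
})

test_that("HM matrix has planted structure and is deterministic", {
  cfg <- synthConfig(seed = 17L, nHmClusters = 3L, hmNoiseSd = 0)
  hm <- simulateHmMatrix(cfg, 60L)
  ## zero noise: rows within a cluster identical
  for (k in 1:3) {
    rows <- hm$matrix[hm$labels == k, , drop = FALSE]
    expect_true(all(apply(rows, 2, function(x) diff(range(x)) == 0)))
  }
  hm2 <- simulateHmMatrix(cfg, 60L)
  expect_identical(hm$matrix, hm2$matrix)
})
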