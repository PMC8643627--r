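## Shared fixtures. Simulations are cached per configuration so several
## test files can reuse the same (expensive) standard fixture.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache)) {
    assign(key, force(expr), envir = .fixtureCache)
  }
  get(key, envir = .fixtureCache)
}

## The standard single-condition calling fixture: study defaults (depth
## 500, folds 2-32x, 3 replicates), no condition-specific enhancers.
standardCallingConfig <- function(seed) {
  synthConfig(seed = seed, conditions = "LIF",
              fracRaInducible = 0, fracLifDependent = 0)
}

standardCallingFixture <- function(seed = 101L) {
  cached(paste0("call_", seed), {
    cfg <- standardCallingConfig(seed)
    sim <- simulateGenome(cfg)
    lib <- simulateReporterLibrary(cfg, sim)
    mol <- dedupUmi(lib$fragments)
    se <- callEnhancers(quantifyRegions(sim$regions, mol, lib$input))
    list(cfg = cfg, sim = sim, lib = lib, mol = mol, se = se,
         activity = activityTable(se))
  })
}

## Two-condition fixture with planted RA-inducible / LIF-dependent
## enhancers sized so that the 10% response-class selection matches the
## planted class sizes (9 induced + 9 repressed of 90 occupied sites).
differentialFixture <- function(seed = 201L) {
  cached(paste0("diff_", seed), {
    cfg <- synthConfig(seed = seed, nInputRegions = 300L, depth = 150,
                       inputDepth = 300, fracActive = 0.3,
                       fracRaInducible = 0.03, fracLifDependent = 0.03,
                       activityGrid = c(8, 16, 32), inductionFold = 4)
    sim <- simulateGenome(cfg)
    lib <- simulateReporterLibrary(cfg, sim)
    mol <- dedupUmi(lib$fragments)
    se <- callEnhancers(quantifyRegions(sim$regions, mol, lib$input))
    list(cfg = cfg, sim = sim, se = se,
         diff = differentialEnhancers(se))
  })
}

## Jackpot fixture: shallow library of weak (2x) enhancers plus one
## 100x-amplified molecule in the first inactive region.
jackpotFixture <- function(seed = 301L) {
  cached(paste0("jack_", seed), {
    cfg <- synthConfig(seed = seed, conditions = "LIF",
                       nInputRegions = 200L, depth = 20, inputDepth = 200,
                       activityGrid = 2, fracActive = 0.1,
                       fracRaInducible = 0, fracLifDependent = 0,
                       pcrDuplicationRate = 1.5, jackpot = TRUE)
    sim <- simulateGenome(cfg)
    lib <- simulateReporterLibrary(cfg, sim)
    mol <- dedupUmi(lib$fragments)
    se <- callEnhancers(quantifyRegions(sim$regions, mol, lib$input))
    list(cfg = cfg, sim = sim, lib = lib, se = se)
  })
}

## Classifier recovery fixture: 5 driver motifs planted 60%/10%.
classifierFixture <- function(seed = 7L) {
  cached(paste0("clf_", seed), {
    panel <- defaultMotifPanel(n = 10L, nDrivers = 5L, seed = 3L)
    lab <- simulateLabeledSequences(nPerClass = 300L, panel = panel,
                                    seed = seed)
    features <- buildFeatureTable(lab$sequences, panel)
    list(panel = panel, lab = lab, features = features)
  })
}

## A deterministic single-consensus motif (probability-1 columns).
exactMotif <- function(consensus, name = consensus) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  prof <- matrix(0, 4, length(bases),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  prof[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- 1
  MotifMatrix(name, prof)
}

## Random fragment tables for the dedup oracle.
randomFragments <- function(n, seed, umis = 8L, coords = 5L) {
  set.seed(seed)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = sample(seq_len(coords) * 100L, n, replace = TRUE),
    end = 0L, strand = sample(c("+", "-"), n, replace = TRUE),
    umi = paste0("ACGT", sample(c("AAAA", "AAAT", "AATT", "ATTT", "TTTT",
                                  "CCCC", "GGGG", "CGCG")[seq_len(umis)],
                                n, replace = TRUE)),
    replicate = sample(1:2, n, replace = TRUE),
    condition = "LIF", stringsAsFactors = FALSE) |>
    transform(end = start + 150L)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
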