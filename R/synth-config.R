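#' Configure the synthetic reporter-assay study
#'
#' Builds a validated [SynthConfig-class] describing every input the
#' simulated study generates: a toy genome with non-overlapping accessible
#' regions, an input fragment library, UMI-tagged reporter molecules with
#' PCR-duplicate structure, planted active/differential enhancers, motif
#' insertions, and a histone-modification matrix with planted cluster
#' structure.
#'
#' Defaults describe the standard study conditions: three biological
#' replicates, 500 unique reporter molecules per region per replicate,
#' planted fold-activations spanning 2-32x, 10-bp random UMIs, a mean PCR
#' duplication of 4 reads per molecule and region widths log-normal around
#' a 350 bp median (active enhancers in reporter screens of this kind
#' average roughly 340-390 bp). A 5% active fraction keeps "active regions
#' are a minority" while leaving enough planted enhancers at desk scale to
#' estimate recovery rates.
#'
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @param nChrom,chromLength genome size.
#' @param nInputRegions number of non-overlapping accessible regions.
#' @param fracActive fraction of regions planted as active enhancers.
#' @param activityGrid multiset of fold-activations assigned (recycled) to
#'   active regions.
#' @param nReplicates biological replicates per condition.
#' @param conditions subset of `c("LIF", "RA")`.
#' @param fracRaInducible,fracLifDependent fractions of regions (out of all
#'   regions) planted as condition-specific; their sum must not exceed
#'   `fracActive`.
#' @param inductionFold fold-change between conditions for differential
#'   regions.
#' @param umiLength UMI length in bp (random-mer; collisions possible).
#' @param pcrDuplicationRate mean reads per unique molecule (geometric
#'   multiplicity; 1 = no duplication).
#' @param depth expected unique molecules per region per replicate at fold 1.
#' @param inputDepth expected input-library fragments per region.
#' @param gc genome GC content.
#' @param fragVariants mean number of distinct fragment coordinate variants
#'   per region (fragments jitter within the region, so the
#'   "captured by >= 3 different fragments" filter is meaningful).
#' @param jackpot if TRUE a single molecule in the first inactive region is
#'   amplified `jackpotReads` times, emulating a PCR jackpot artefact.
#' @param jackpotReads reads for the jackpot molecule.
#' @param motifPanel list of [MotifMatrix-class] planted into regions; NULL
#'   uses [defaultMotifPanel()].
#' @param pActive,pInactive per-motif insertion probability for driver
#'   motifs in active vs inactive regions (non-driver panel members are
#'   planted at `pInactive` everywhere).
#' @param nHmClusters,hmNoiseSd planted histone-modification cluster count
#'   and Gaussian noise level.
#' @return a [SynthConfig-class] object.
#' @examples
#' synthConfig(seed = 1, nInputRegions = 50L)
#' @export
synthConfig <- function(seed = 1L, nChrom = 2L, chromLength = 400000L,
                        nInputRegions = 200L, fracActive = 0.05,
                        activityGrid = c(2, 4, 8, 16, 32),
                        nReplicates = 3L, conditions = c("LIF", "RA"),
                        fracRaInducible = 0.0125, fracLifDependent = 0.0125,
                        inductionFold = 4, umiLength = 10L,
                        pcrDuplicationRate = 4, depth = 500,
                        inputDepth = 500, gc = 0.45, fragVariants = 8,
                        jackpot = FALSE, jackpotReads = 100L,
                        motifPanel = NULL, pActive = 0.6, pInactive = 0.1,
                        nHmClusters = 3L, hmNoiseSd = 0.5) {
  new("SynthConfig", seed = as.integer(seed), nChrom = as.integer(nChrom),
      chromLength = as.integer(chromLength),
      nInputRegions = as.integer(nInputRegions), fracActive = fracActive,
      activityGrid = as.numeric(activityGrid),
      nReplicates = as.integer(nReplicates), conditions = conditions,
      fracRaInducible = fracRaInducible, fracLifDependent = fracLifDependent,
      inductionFold = inductionFold, umiLength = as.integer(umiLength),
      pcrDuplicationRate = pcrDuplicationRate, depth = depth,
      inputDepth = inputDepth, gc = gc, fragVariants = fragVariants,
      jackpot = jackpot, jackpotReads = as.integer(jackpotReads),
      motifPanel = if (is.null(motifPanel)) list() else motifPanel,
      pActive = pActive, pInactive = pInactive,
      nHmClusters = as.integer(nHmClusters), hmNoiseSd = hmNoiseSd)
}

#' Generate a panel of synthetic motifs
#'
#' Produces information-rich position probability matrices (one dominant
#' base per column) with distinct random consensi; the first `nDrivers`
#' are flagged as drivers, i.e. candidates for preferential insertion into
#' active regions.
#'
#' @param n panel size.
#' @param width motif width in bp.
#' @param nDrivers number of leading motifs marked as drivers.
#' @param dominance probability of the dominant base per column.
#' @param seed integer seed.
#' @return list of [MotifMatrix-class]; driver motifs are named
#'   `driver_1..k`, the rest `neutral_*`.
#' @export
defaultMotifPanel <- function(n = 10L, width = 10L, nDrivers = 5L,
                              dominance = 0.88, seed = 1L) {
  stopifnot(nDrivers <= n)
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      cons <- sample(4L, width, replace = TRUE)
      prof <- matrix((1 - dominance) / 3, 4L, width,
                     dimnames = list(DNA_BASES4, NULL))
      prof[cbind(cons, seq_len(width))] <- dominance
      nm <- if (i <= nDrivers) sprintf("driver_%d", i)
            else sprintf("neutral_%d", i - nDrivers)
      MotifMatrix(nm, prof)
    })
  })
}
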