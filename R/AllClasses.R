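#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData rowRanges
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

## ---------------------------------------------------------------------------
## MotifMatrix
## ---------------------------------------------------------------------------

#' Position probability matrix for a transcription-factor binding motif
#'
#' A `MotifMatrix` holds per-position base probabilities over \{A,C,G,T\}
#' together with the background base composition used for log-odds scoring.
#' Matrices read from JASPAR PFM files carry their cluster label in
#' `clusterId` (clustered motif sets group similar TF matrices into
#' non-redundant clusters which are then used as enrichment and model
#' features).
#'
#' @slot name motif identifier.
#' @slot clusterId clustered-motif group label (defaults to `name`).
#' @slot profile 4 x width numeric matrix, rows A, C, G, T; every column
#'   sums to 1.
#' @slot background length-4 base frequencies summing to 1.
#' @exportClass MotifMatrix
setClass("MotifMatrix",
  representation(name = "character", clusterId = "character",
                 profile = "matrix", background = "numeric"))

setValidity("MotifMatrix", function(object) {
  p <- object@profile
  if (!is.numeric(p) || nrow(p) != 4L)
    return("profile must be a numeric matrix with 4 rows (A,C,G,T)")
  if (!identical(rownames(p), DNA_BASES4))
    return("profile rows must be named A, C, G, T")
  if (any(p < 0)) return("profile entries must be >= 0")
  if (ncol(p) < 1L) return("profile must have at least one column")
  if (any(abs(colSums(p) - 1) > 1e-9))
    return("every profile column must sum to 1 (tolerance 1e-9)")
  b <- object@background
  if (length(b) != 4L || any(b < 0) || abs(sum(b) - 1) > 1e-9)
    return("background must be 4 non-negative frequencies summing to 1")
  if (!nzchar(object@name)) return("name must be non-empty")
  TRUE
})

#' Construct a MotifMatrix
#'
#' @param name motif identifier.
#' @param profile 4 x width matrix of per-position base probabilities
#'   (rows in A, C, G, T order; row names are set if missing).
#' @param clusterId clustered-motif group label; defaults to `name`.
#' @param background base frequencies, default uniform.
#' @return a [MotifMatrix-class] object.
#' @examples
#' m <- MotifMatrix("toy", matrix(c(1, 0, 0, 0), 4, 3,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' motifWidth(m)
#' @export
MotifMatrix <- function(name, profile, clusterId = name,
                        background = rep(0.25, 4)) {
  if (is.null(rownames(profile))) rownames(profile) <- DNA_BASES4
  new("MotifMatrix", name = as.character(name),
      clusterId = as.character(clusterId),
      profile = profile, background = as.numeric(background))
}

## ---------------------------------------------------------------------------
## CompositeMotif
## ---------------------------------------------------------------------------

#' Nuclear-receptor repeat motif assembled from a half-site
#'
#' Direct (DR), inverted (IR) and everted (ER) repeats of a hexameric
#' half-site separated by a background-uniform spacer of 0-8 bp; the motif
#' architectures recognized by RAR/RXR-type nuclear-receptor dimers.
#'
#' @slot orientation one of "DR", "IR", "ER".
#' @slot spacing spacer width in bp (0-8).
#' @slot halfSite the 4 x w half-site probability matrix the repeat was
#'   assembled from.
#' @exportClass CompositeMotif
setClass("CompositeMotif", contains = "MotifMatrix",
  representation(orientation = "character", spacing = "integer",
                 halfSite = "matrix"))

setValidity("CompositeMotif", function(object) {
  if (!object@orientation %in% c("DR", "IR", "ER"))
    return("orientation must be one of DR, IR, ER")
  if (object@spacing < 0L || object@spacing > 8L)
    return("spacing must be in 0..8")
  if (ncol(object@profile) != 2L * ncol(object@halfSite) + object@spacing)
    return("composite width must equal 2*half-site width + spacing")
  TRUE
})

## ---------------------------------------------------------------------------
## StarrExperiment
## ---------------------------------------------------------------------------

#' Container for quantified reporter activity over candidate regions
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment]. Rows are
#' candidate regions (the merged accessible input-library regions), columns
#' are reporter samples (replicate x condition), and the `"umi"` assay holds
#' UMI-deduplicated unique-molecule counts. `rowData` carries the
#' input-library fragment count and the number of distinct fragment
#' coordinates supporting each region; enhancer calling
#' ([callEnhancers()]) appends activity scores and the active flag.
#'
#' @exportClass StarrExperiment
setClass("StarrExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("StarrExperiment", function(object) {
  if (!"umi" %in% SummarizedExperiment::assayNames(object))
    return("assay 'umi' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("replicate", "condition") %in% colnames(cd)))
    return("colData must have 'replicate' and 'condition'")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("input_count", "distinct_fragments") %in% colnames(rd)))
    return("rowData must have 'input_count' and 'distinct_fragments'")
  if (any(SummarizedExperiment::assay(object, "umi") < 0))
    return("umi counts must be non-negative")
  TRUE
})

## ---------------------------------------------------------------------------
## ClassifierReport
## ---------------------------------------------------------------------------

#' Result of a nested cross-validated elastic-net activity classifier
#'
#' @slot foldAUC per-outer-fold AUC on the held-out portion.
#' @slot coefficients data.frame with columns `feature` and `coefficient`
#'   from the final refit (original feature scale), covering every feature.
#' @slot alpha,lambda selected elastic-net mixing and penalty parameters.
#' @slot nObs number of training observations.
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(foldAUC = "numeric", coefficients = "data.frame",
                 alpha = "numeric", lambda = "numeric", nObs = "integer"))

setValidity("ClassifierReport", function(object) {
  if (any(object@foldAUC < 0 | object@foldAUC > 1))
    return("AUC values must lie in [0, 1]")
  if (!all(c("feature", "coefficient") %in% colnames(object@coefficients)))
    return("coefficients needs 'feature' and 'coefficient' columns")
  TRUE
})

## ---------------------------------------------------------------------------
## SynthConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic reporter-assay generator
#'
#' All tunables of the simulated study in one validated object; see
#' [synthConfig()] for the defaults and their meaning.
#'
#' @exportClass SynthConfig
setClass("SynthConfig",
  representation(seed = "integer", nChrom = "integer", chromLength = "integer",
    nInputRegions = "integer", fracActive = "numeric", activityGrid = "numeric",
    nReplicates = "integer", conditions = "character",
    fracRaInducible = "numeric", fracLifDependent = "numeric",
    inductionFold = "numeric", umiLength = "integer",
    pcrDuplicationRate = "numeric", depth = "numeric", inputDepth = "numeric",
    gc = "numeric", fragVariants = "numeric", jackpot = "logical",
    jackpotReads = "integer", motifPanel = "list", pActive = "numeric",
    pInactive = "numeric", nHmClusters = "integer", hmNoiseSd = "numeric"))

setValidity("SynthConfig", function(object) {
  fr <- c(object@fracActive, object@fracRaInducible, object@fracLifDependent)
  if (any(fr < 0 | fr > 1)) return("fractions must lie in [0, 1]")
  if (object@fracRaInducible + object@fracLifDependent > object@fracActive)
    return("fracRaInducible + fracLifDependent must not exceed fracActive")
  if (object@pcrDuplicationRate < 1)
    return("pcrDuplicationRate must be >= 1 (mean reads per molecule)")
  if (any(object@activityGrid < 1)) return("activityGrid folds must be >= 1")
  if (object@umiLength < 1L) return("umiLength must be positive")
  if (object@nHmClusters < 2L) return("need at least 2 planted HM clusters")
  if (!all(object@conditions %in% c("LIF", "RA")))
    return("conditions must be a subset of {LIF, RA}")
  TRUE
})
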