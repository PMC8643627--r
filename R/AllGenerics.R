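#' @include AllClasses.R
NULL

#' Motif accessors
#'
#' @param x a [MotifMatrix-class].
#' @return `motifName()` and `motifCluster()` return character scalars,
#'   `motifWidth()` an integer, `motifProfile()` the 4 x width probability
#'   matrix and `motifBackground()` the background frequencies.
#' @aliases motifName motifCluster motifWidth motifProfile motifBackground
#' @name motif-accessors
#' @export
setGeneric("motifName", function(x) standardGeneric("motifName"))
#' @rdname motif-accessors
#' @export
setGeneric("motifCluster", function(x) standardGeneric("motifCluster"))
#' @rdname motif-accessors
#' @export
setGeneric("motifWidth", function(x) standardGeneric("motifWidth"))
#' @rdname motif-accessors
#' @export
setGeneric("motifProfile", function(x) standardGeneric("motifProfile"))
#' @rdname motif-accessors
#' @export
setGeneric("motifBackground", function(x) standardGeneric("motifBackground"))

#' @rdname motif-accessors
setMethod("motifName", "MotifMatrix", function(x) x@name)
#' @rdname motif-accessors
setMethod("motifCluster", "MotifMatrix", function(x) x@clusterId)
#' @rdname motif-accessors
setMethod("motifWidth", "MotifMatrix", function(x) ncol(x@profile))
#' @rdname motif-accessors
setMethod("motifProfile", "MotifMatrix", function(x) x@profile)
#' @rdname motif-accessors
setMethod("motifBackground", "MotifMatrix", function(x) x@background)

setMethod("show", "MotifMatrix", function(object) {
  cat("MotifMatrix", object@name,
      sprintf("(cluster %s), width %d\n", object@clusterId,
              ncol(object@profile)))
  cat("consensus:", motifConsensus(object), "\n")
})

setMethod("show", "CompositeMotif", function(object) {
  cat(sprintf("CompositeMotif %s%d (%s, spacer %d bp), width %d\n",
              object@orientation, object@spacing, object@name,
              object@spacing, ncol(object@profile)))
})

#' StarrExperiment accessors
#'
#' @param x a [StarrExperiment-class].
#' @return `umiCounts()` the regions x samples unique-molecule count matrix;
#'   `inputCounts()` and `distinctFragments()` per-region integers;
#'   `activityTable()` a data.frame view of the per-region quantification
#'   (one row per candidate region).
#' @aliases umiCounts inputCounts distinctFragments activityTable
#' @name starr-accessors
#' @export
setGeneric("umiCounts", function(x) standardGeneric("umiCounts"))
#' @rdname starr-accessors
#' @export
setGeneric("inputCounts", function(x) standardGeneric("inputCounts"))
#' @rdname starr-accessors
#' @export
setGeneric("distinctFragments", function(x) standardGeneric("distinctFragments"))
#' @rdname starr-accessors
#' @export
setGeneric("activityTable", function(x) standardGeneric("activityTable"))

#' @rdname starr-accessors
setMethod("umiCounts", "StarrExperiment",
          function(x) SummarizedExperiment::assay(x, "umi"))
#' @rdname starr-accessors
setMethod("inputCounts", "StarrExperiment",
          function(x) SummarizedExperiment::rowData(x)$input_count)
#' @rdname starr-accessors
setMethod("distinctFragments", "StarrExperiment",
          function(x) SummarizedExperiment::rowData(x)$distinct_fragments)

#' @rdname starr-accessors
setMethod("activityTable", "StarrExperiment", function(x) {
  gr <- SummarizedExperiment::rowRanges(x)
  rd <- SummarizedExperiment::rowData(x)
  out <- data.frame(
    region = names(x) %||% as.character(seq_len(nrow(x))),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # BED-style in the table view
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rd))
})

setMethod("show", "StarrExperiment", function(object) {
  cat("StarrExperiment:", nrow(object), "regions x", ncol(object),
      "samples\n")
  cat("conditions:",
      paste(unique(SummarizedExperiment::colData(object)$condition),
            collapse = ", "), "\n")
  rd <- SummarizedExperiment::rowData(object)
  if ("is_active" %in% colnames(rd))
    cat("active regions:", sum(rd$is_active), "/", nrow(object), "\n")
})

#' ClassifierReport accessors
#'
#' @param x a [ClassifierReport-class].
#' @return `foldAUC()` the per-outer-fold held-out AUCs, `meanAUC()` their
#'   mean, `classifierCoefficients()` the full coefficient table.
#' @aliases foldAUC meanAUC classifierCoefficients
#' @name classifier-accessors
#' @export
setGeneric("foldAUC", function(x) standardGeneric("foldAUC"))
#' @rdname classifier-accessors
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))
#' @rdname classifier-accessors
#' @export
setGeneric("classifierCoefficients",
           function(x) standardGeneric("classifierCoefficients"))

#' @rdname classifier-accessors
setMethod("foldAUC", "ClassifierReport", function(x) x@foldAUC)
#' @rdname classifier-accessors
setMethod("meanAUC", "ClassifierReport", function(x) mean(x@foldAUC))
#' @rdname classifier-accessors
setMethod("classifierCoefficients", "ClassifierReport",
          function(x) x@coefficients)

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf(
    "ClassifierReport: %d outer folds, mean AUC %.3f (sd %.3f)\n",
    length(object@foldAUC), mean(object@foldAUC), sd(object@foldAUC)))
  cat(sprintf("selected alpha %.2f, lambda %.4g; %d features\n",
              object@alpha, object@lambda, nrow(object@coefficients)))
})

setMethod("show", "SynthConfig", function(object) {
  cat("SynthConfig: seed", object@seed, "-", object@nInputRegions,
      "regions on", object@nChrom, "chromosome(s) of",
      object@chromLength, "bp\n")
  cat(sprintf(
    "  active %.1f%% (folds %s), RA-inducible %.1f%%, LIF-dependent %.1f%%\n",
    100 * object@fracActive, paste(object@activityGrid, collapse = "/"),
    100 * object@fracRaInducible, 100 * object@fracLifDependent))
  cat(sprintf("  %d replicate(s) x {%s}, depth %g molecules/region, PCR rate %g\n",
              object@nReplicates, paste(object@conditions, collapse = ","),
              object@depth, object@pcrDuplicationRate))
})
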