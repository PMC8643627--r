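#' Differential enhancer activity between two conditions
#'
#' Identifies regions that gain (RA-inducible) or lose (LIF-dependent)
#' reporter activity upon differentiation. The effect size is the
#' difference of merged log2 STARR scores (`RA - LIF`); significance comes
#' from a two-sided Fisher exact test on pooled unique-molecule counts
#' (region vs rest of library, by condition), BH-adjusted across regions.
#' A region is classed `RA-inducible` when `log2fc >= lfcThreshold` and
#' `p_adj <= fdr`, `LIF-dependent` when `log2fc <= -lfcThreshold` and
#' `p_adj <= fdr`, otherwise `stable` - the same effect-size and
#' significance thresholds used for differential gene expression
#' (|log2FC| >= 1, adjusted p <= 0.05).
#'
#' @param se a [StarrExperiment-class] quantified in both conditions.
#' @param conditions length-2 character, reference condition first
#'   (default `c("LIF", "RA")`; log2fc is second minus first).
#' @param lfcThreshold minimum |log2 fold change| (default 1).
#' @param fdr BH-adjusted p threshold (default 0.05).
#' @param pseudocount for score computation.
#' @return data.frame with one row per region: `region`, `score_lif`,
#'   `score_ra` (merged log scores per condition), `log2fc`, `p`, `p_adj`,
#'   `class`.
#' @export
differentialEnhancers <- function(se, conditions = c("LIF", "RA"),
                                  lfcThreshold = 1, fdr = 0.05,
                                  pseudocount = 1) {
  stopifnot(length(conditions) == 2L)
  cd <- SummarizedExperiment::colData(se)
  for (cond in conditions)
    if (!cond %in% cd$condition)
      stop("condition ", cond, " absent from the experiment; ",
           "quantification must precede differential testing")
  u1 <- rowSums(umiCounts(se)[, cd$condition == conditions[1L], drop = FALSE])
  u2 <- rowSums(umiCounts(se)[, cd$condition == conditions[2L], drop = FALSE])
  U1 <- sum(u1); U2 <- sum(u2)
  s1 <- mergedLogScores(se, conditions[1L], pseudocount)
  s2 <- mergedLogScores(se, conditions[2L], pseudocount)
  log2fc <- s2 - s1
  p <- vapply(seq_along(u1), function(r)
    fisher.test(matrix(c(u2[r], U2 - u2[r], u1[r], U1 - u1[r]), 2L))$p.value,
    numeric(1))
  p_adj <- p.adjust(p, "BH")
  class <- rep("stable", length(u1))
  class[log2fc >= lfcThreshold & p_adj <= fdr] <- "RA-inducible"
  class[log2fc <= -lfcThreshold & p_adj <= fdr] <- "LIF-dependent"
  data.frame(region = rownames(se) %||% as.character(seq_along(u1)),
             score_lif = s1, score_ra = s2, log2fc = log2fc,
             p = p, p_adj = p_adj, class = class,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify receptor-occupied sites by their response to ligand
#'
#' Restricted to quantified regions that overlap a ChIP peak (>= 1 bp) and
#' clear a minimum mean activity floor (mean of the two conditions' merged
#' log scores), the most induced `fraction` of eligible regions (by
#' log2fc), the equally many most repressed, and the same number of
#' remaining eligible regions with log2fc closest to zero form the
#' `induced`, `repressed` and `non_responding` sets. The three sets are
#' disjoint and of equal cardinality.
#'
#' @param diff differential table from [differentialEnhancers()].
#' @param regions `GRanges` parallel to `diff` (the quantified candidate
#'   regions).
#' @param peaks `GRanges` of receptor ChIP peaks.
#' @param fraction fraction of eligible regions per extreme (default 0.10).
#' @param floor minimum mean log STARR score (default 2.5).
#' @return list with character vectors `induced`, `repressed`,
#'   `non_responding` (region ids), the `eligible` ids, and `size`.
#' @export
classifyResponseSites <- function(diff, regions, peaks, fraction = 0.10,
                                  floor = 2.5) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("fraction must lie strictly between 0 and 0.5")
  stopifnot(length(regions) == nrow(diff))
  occupied <- GenomicRanges::countOverlaps(regions, peaks, minoverlap = 1L,
                                           ignore.strand = TRUE) > 0
  meanScore <- (diff$score_lif + diff$score_ra) / 2
  eligible <- which(occupied & meanScore >= floor)
  k <- roundHalfUp(fraction * length(eligible))
  if (k < 1 || 3L * k > length(eligible))
    stop("only ", length(eligible), " eligible regions; cannot form three ",
         "disjoint sets of ", max(k, 1L))
  lfc <- diff$log2fc[eligible]
  desc <- order(-lfc, eligible)
  asc <- order(lfc, eligible)
  induced <- eligible[desc[seq_len(k)]]
  repressed <- eligible[asc[seq_len(k)]]
  rest <- setdiff(eligible, c(induced, repressed))
  nz <- order(abs(diff$log2fc[rest]), rest)
  non_responding <- rest[nz[seq_len(k)]]
  ids <- diff$region
  list(induced = ids[sort(induced)], repressed = ids[sort(repressed)],
       non_responding = ids[sort(non_responding)],
       eligible = ids[sort(eligible)], size = as.integer(k))
}

#' Count differentially expressed genes near differential enhancers
#'
#' Pairs each non-stable enhancer with its nearest TSS and tallies, per
#' enhancer class, how many paired genes are up- or down-regulated
#' according to a precomputed differential-expression table (genes missing
#' from the table count as unchanged, with a warning).
#'
#' @param diff table from [differentialEnhancers()].
#' @param regions `GRanges` parallel to `diff`.
#' @param genes `GRanges` of width-1 TSSs with `gene_id`.
#' @param deTable data.frame with columns `gene_id`, `log2fc`, `p_adj`.
#' @param lfcThreshold,fdr thresholds defining up/down genes (defaults 1
#'   and 0.05).
#' @param maxDistance maximum pairing distance in bp.
#' @return data.frame with one row per enhancer class and columns `up`,
#'   `down`, `unchanged`, `unpaired`.
#' @export
pairDiffGenes <- function(diff, regions, genes, deTable, lfcThreshold = 1,
                          fdr = 0.05, maxDistance = 1e6) {
  stopifnot(length(regions) == nrow(diff))
  keep <- diff$class != "stable"
  classes <- c("RA-inducible", "LIF-dependent")
  out <- data.frame(class = classes, up = 0L, down = 0L, unchanged = 0L,
                    unpaired = 0L, stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  paired <- nearestTss(regions[keep], genes, maxDistance)
  status <- rep("unpaired", nrow(paired))
  hasGene <- !is.na(paired$gene_id)
  m <- match(paired$gene_id[hasGene], deTable$gene_id)
  if (anyNA(m))
    warning(sum(is.na(m)), " paired gene(s) missing from the expression ",
            "table; counted as unchanged")
  st <- rep("unchanged", sum(hasGene))
  ok <- !is.na(m)
  lfc <- deTable$log2fc[m[ok]]
  padj <- deTable$p_adj[m[ok]]
  st[ok][lfc >= lfcThreshold & padj <= fdr] <- "up"
  st[ok][lfc <= -lfcThreshold & padj <= fdr] <- "down"
  status[hasGene] <- st
  cls <- diff$class[keep]
  for (i in seq_along(classes)) {
    sel <- cls == classes[i]
    out$up[i] <- sum(status[sel] == "up")
    out$down[i] <- sum(status[sel] == "down")
    out$unchanged[i] <- sum(status[sel] == "unchanged")
    out$unpaired[i] <- sum(status[sel] == "unpaired")
  }
  out
}
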