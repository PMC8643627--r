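#' Pairs of overlapping intervals between two region sets
#'
#' Reports every pair (i, j) with at least 1 bp of overlap, once per pair,
#' ignoring strand. Thin wrapper over [GenomicRanges::findOverlaps()] kept
#' as the single overlap entry point so half-open BED semantics (adjacent
#' intervals do not overlap) hold everywhere.
#'
#' @param a,b `GRanges`.
#' @return data.frame with columns `a` and `b`, the indices of overlapping
#'   pairs.
#' @export
overlapPairs <- function(a, b) {
  hits <- GenomicRanges::findOverlaps(a, b, minoverlap = 1L,
                                      ignore.strand = TRUE)
  data.frame(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

#' Nearest transcription start site for each region
#'
#' Pairs each region with the gene whose TSS is closest to the region
#' midpoint, the explicit stand-in for distance-based enhancer-gene
#' assignment. Genes farther than `maxDistance` from the midpoint are not
#' paired; distance ties are broken by lexicographic gene id.
#'
#' @param regions a `GRanges` of regions.
#' @param genes a `GRanges` of width-1 TSS positions with a `gene_id`
#'   metadata column.
#' @param maxDistance maximum midpoint-to-TSS distance in bp (default 1e6).
#' @return data.frame with one row per region: `gene_id` (NA when no gene
#'   is within range) and `distance`.
#' @export
nearestTss <- function(regions, genes, maxDistance = 1e6) {
  stopifnot(maxDistance > 0)
  if (length(genes) > 0 && any(GenomicRanges::width(genes) != 1L))
    stop("gene TSS ranges must have width exactly 1")
  gene_id <- if (length(genes)) as.character(genes$gene_id) else character()
  out <- data.frame(gene_id = rep(NA_character_, length(regions)),
                    distance = rep(NA_real_, length(regions)))
  if (length(genes) == 0L || length(regions) == 0L) return(out)
  mid <- floor((GenomicRanges::start(regions) +
                GenomicRanges::end(regions)) / 2)
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gpos <- GenomicRanges::start(genes)
  for (ch in unique(rchrom)) {
    gi <- which(gchrom == ch)
    if (length(gi) == 0L) next
    ri <- which(rchrom == ch)
    for (i in ri) {
      d <- abs(gpos[gi] - mid[i])
      dmin <- min(d)
      if (dmin > maxDistance) next
      cand <- gi[d == dmin]
      pick <- cand[order(gene_id[cand])][1L]
      out$gene_id[i] <- gene_id[pick]
      out$distance[i] <- dmin
    }
  }
  out
}

#' Strand-aware promoter windows around TSSs
#'
#' For a plus-strand TSS at 0-based position t the window is
#' `[t - upstream, t + downstream)`; minus-strand genes extend upstream
#' toward larger coordinates, `[t - downstream, t + upstream)`. Windows are
#' truncated at the chromosome origin.
#'
#' @param genes a `GRanges` of width-1 TSS positions (strand used; `*` is
#'   treated as `+`).
#' @param upstream,downstream window extents in bp; both >= 0 and not both
#'   zero.
#' @return a `GRanges` of promoter windows, parallel to `genes`.
#' @export
promoterWindows <- function(genes, upstream = 1000, downstream = 0) {
  stopifnot(upstream >= 0, downstream >= 0, upstream + downstream > 0)
  if (length(genes) > 0 && any(GenomicRanges::width(genes) != 1L))
    stop("gene TSS ranges must have width exactly 1")
  t0 <- GenomicRanges::start(genes) - 1L  # 0-based TSS position
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  bed_start <- ifelse(minus, t0 - downstream, t0 - upstream)
  bed_end <- ifelse(minus, t0 + upstream, t0 + downstream)
  bed_start <- pmax(bed_start, 0)
  GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                         IRanges::IRanges(bed_start + 1, bed_end),
                         strand = GenomicRanges::strand(genes))
}
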