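#' Normalized STARR activity score
#'
#' The activity of a region is the depth-normalized ratio of its
#' unique-molecule reporter abundance to its input-library abundance,
#' `((u + c)/(U + c)) / ((i + c)/(I + c))`, with pseudocount `c`
#' guaranteeing a finite, strictly positive score; the log STARR score is
#' its log2. Replicate scores are averaged on the log scale for merged
#' scores.
#'
#' @param u region unique-molecule (UMI) count; vectorized.
#' @param U library total unique molecules.
#' @param i region input-library fragment count; vectorized.
#' @param I input library total.
#' @param pseudocount positive pseudocount, default 1.
#' @return numeric vector of linear STARR scores (use `log2()` for log
#'   scores).
#' @examples
#' starrScore(9, 100, 1, 100)          # 5
#' log2(starrScore(9, 100, 1, 100))    # ~2.32
#' @export
starrScore <- function(u, U, i, I, pseudocount = 1) {
  stopifnot(pseudocount > 0, U > 0, I > 0)
  ((u + pseudocount) / (U + pseudocount)) /
    ((i + pseudocount) / (I + pseudocount))
}

#' Quantify reporter molecules over candidate regions
#'
#' Builds a [StarrExperiment-class] from deduplicated reporter molecules
#' and the input library: one row per candidate region, one column per
#' replicate x condition sample, `"umi"` assay of unique-molecule counts,
#' with per-region input counts and the number of distinct fragment
#' coordinates in `rowData`. Molecules are assigned to regions by >= 1 bp
#' overlap (first overlapping region for the rare straddling fragment).
#'
#' @param regions `GRanges` of candidate regions (the merged input-library
#'   regions).
#' @param molecules deduplicated molecules from [dedupUmi()] (or any
#'   data.frame with chrom, start, end, replicate, condition).
#' @param input input-library fragment data.frame (chrom, start, end).
#' @return a [StarrExperiment-class].
#' @export
quantifyRegions <- function(regions, molecules, input) {
  if (is.null(names(regions)))
    names(regions) <- sprintf("region_%04d", seq_along(regions))
  mgr <- GenomicRanges::GRanges(molecules$chrom,
    IRanges::IRanges(molecules$start, molecules$end))
  hit <- GenomicRanges::findOverlaps(mgr, regions, minoverlap = 1L,
                                     ignore.strand = TRUE, select = "first")
  sample_id <- paste(molecules$condition, molecules$replicate, sep = "_")
  samples <- sort(unique(sample_id))
  keep <- !is.na(hit)
  umi <- matrix(0L, length(regions), length(samples),
                dimnames = list(names(regions), samples))
  tab <- table(factor(names(regions)[hit[keep]], levels = names(regions)),
               factor(sample_id[keep], levels = samples))
  umi[] <- as.integer(tab)

  igr <- GenomicRanges::GRanges(input$chrom,
    IRanges::IRanges(input$start, input$end))
  ihit <- GenomicRanges::findOverlaps(igr, regions, minoverlap = 1L,
                                      ignore.strand = TRUE, select = "first")
  input_count <- as.integer(table(factor(names(regions)[ihit[!is.na(ihit)]],
                                         levels = names(regions))))

  dfrag <- data.table::as.data.table(
    data.frame(region = names(regions)[hit[keep]],
               start = molecules$start[keep], end = molecules$end[keep]))
  dd <- dfrag[, list(nfrag = data.table::uniqueN(paste(start, end))),
              by = "region"]
  distinct_fragments <- integer(length(regions))
  names(distinct_fragments) <- names(regions)
  distinct_fragments[dd$region] <- dd$nfrag

  cd <- S4Vectors::DataFrame(
    condition = sub("_[0-9]+$", "", samples),
    replicate = as.integer(sub("^.*_", "", samples)),
    row.names = samples)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(umi = umi), rowRanges = regions, colData = cd)
  SummarizedExperiment::rowData(se)$input_count <- input_count
  SummarizedExperiment::rowData(se)$distinct_fragments <- distinct_fragments
  new("StarrExperiment", se)
}

#' Per-sample and merged log STARR scores
#'
#' @param se a [StarrExperiment-class].
#' @param condition restrict to samples of one condition (default: all).
#' @param pseudocount passed to [starrScore()].
#' @return `sampleLogScores()` a regions x samples matrix of log2 scores;
#'   `mergedLogScores()` their per-region mean across the selected samples.
#' @export
sampleLogScores <- function(se, condition = NULL, pseudocount = 1) {
  cols <- selectSamples(se, condition)
  u <- umiCounts(se)[, cols, drop = FALSE]
  U <- colSums(u)
  i <- inputCounts(se)
  I <- sum(i)
  out <- sapply(seq_along(cols), function(j)
    log2(starrScore(u[, j], U[j], i, I, pseudocount)))
  dimnames(out) <- list(rownames(u), cols)
  out
}

#' @rdname sampleLogScores
#' @export
mergedLogScores <- function(se, condition = NULL, pseudocount = 1) {
  rowMeans(sampleLogScores(se, condition, pseudocount))
}

selectSamples <- function(se, condition = NULL) {
  cd <- SummarizedExperiment::colData(se)
  cols <- colnames(se)
  if (!is.null(condition)) {
    cols <- cols[cd$condition %in% condition]
    if (length(cols) == 0L) stop("no samples for condition ", condition)
  }
  cols
}

#' Call active enhancers against the input-library background
#'
#' Per replicate, a region is "called" when a one-sided binomial test of
#' its unique-molecule count against the input-library background is
#' significant after Benjamini-Hochberg adjustment at `fdr`, and the
#' region must also pass the same test in the merged (pooled) sample. The
#' test conditions on the region's combined reporter + input count
#' (`n = u + i`, expected reporter share `U/(U + I)`), the exact test for
#' a ratio of two counting processes, so noise in the input coverage of a
#' region cannot masquerade as reporter enrichment. A
#' region is flagged active when it is called in at least `minReplicates`
#' replicates, passes in the merged pool, and is supported by at least
#' `minFragments` distinct fragment coordinates. The output partitions the
#' candidates: every region is either active or inactive.
#'
#' @param se a [StarrExperiment-class].
#' @param condition restrict calling to samples of one condition.
#' @param fdr BH-adjusted significance threshold (default 0.05).
#' @param minReplicates minimum replicates a region must be called in
#'   (default 2).
#' @param minFragments minimum distinct fragment coordinates (default 3).
#' @param pseudocount for zero-input expectations and scores.
#' @return the input object with rowData columns `called_in`,
#'   `called_merged`, `log_score`, `starr_score` and `is_active` filled in.
#' @export
callEnhancers <- function(se, condition = NULL, fdr = 0.05,
                          minReplicates = 2L, minFragments = 3L,
                          pseudocount = 1) {
  cols <- selectSamples(se, condition)
  if (minReplicates > length(cols))
    stop("minReplicates exceeds the number of samples selected")
  u <- umiCounts(se)[, cols, drop = FALSE]
  i <- inputCounts(se)
  I <- sum(i)
  callOne <- function(uvec) {
    U <- sum(uvec)
    p0 <- U / (U + I)
    p <- pbinom(uvec - 1L, uvec + i, p0, lower.tail = FALSE)
    padj <- p.adjust(p, "BH")
    if (fdr <= 0) rep(FALSE, length(uvec)) else padj <= fdr
  }
  called <- vapply(seq_along(cols), function(j) callOne(u[, j]),
                   logical(nrow(u)))
  called_in <- rowSums(called)
  called_merged <- callOne(rowSums(u))
  log_score <- mergedLogScores(se, condition, pseudocount)
  rd <- SummarizedExperiment::rowData(se)
  rd$called_in <- as.integer(called_in)
  rd$called_merged <- called_merged
  rd$log_score <- log_score
  rd$starr_score <- 2^log_score
  rd$is_active <- called_in >= minReplicates & called_merged &
    distinctFragments(se) >= minFragments
  SummarizedExperiment::rowData(se) <- rd
  se
}

#' Group regions into quantiles of ascending activity
#'
#' Splits regions into `k` equal-size rank groups of ascending log STARR
#' score (any remainder goes to the lowest groups); group `k` holds the
#' most active regions. Ties are broken by input order, so the grouping is
#' deterministic. The 10th and 90th percentile score cuts are returned
#' alongside.
#'
#' @param logScore numeric log STARR scores.
#' @param k number of groups (default 5).
#' @return list with `group` (integer 1..k per region), `p10` and `p90`
#'   (percentile score cuts).
#' @export
activityQuantiles <- function(logScore, k = 5L) {
  n <- length(logScore)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of regions (", n, ")")
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  ord <- order(logScore, seq_len(n))
  group <- integer(n)
  group[ord] <- rep(seq_len(k), times = sizes)
  list(group = group,
       p10 = unname(quantile(logScore, 0.10)),
       p90 = unname(quantile(logScore, 0.90)))
}

#' Select the score extremes of a region set
#'
#' Returns the indices of the `fraction` highest- and lowest-scoring
#' regions. The set size is `fraction * n` rounded half up (so 1% of
#' 170190 regions gives 1702 and 10% of 16769 gives 1677); ties are broken
#' by input order.
#'
#' @param logScore numeric scores.
#' @param fraction fraction per extreme, in (0, 0.5).
#' @return list with integer index vectors `top` and `bottom` and the
#'   common `size`.
#' @export
selectExtremes <- function(logScore, fraction) {
  if (!(fraction > 0 && fraction < 0.5))
    stop("fraction must lie strictly between 0 and 0.5")
  n <- length(logScore)
  k <- roundHalfUp(n * fraction)
  if (k < 1) stop("fraction ", fraction, " of ", n, " regions selects 0")
  desc <- order(-logScore, seq_len(n))
  asc <- order(logScore, seq_len(n))
  list(top = sort(desc[seq_len(k)]), bottom = sort(asc[seq_len(k)]),
       size = as.integer(k))
}
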