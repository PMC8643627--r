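#' k-means clustering of histone-modification profiles
#'
#' Column-standardizes the region x mark enrichment matrix, runs k-means
#' with multiple restarts (best by total within-cluster sum of squares),
#' and relabels clusters in descending order of the mean of a designated
#' activity mark so labels are stable across runs (raw k-means labels are
#' arbitrary).
#'
#' @param mat numeric regions x marks matrix.
#' @param k number of clusters (default 8, the usual number of
#'   chromatin-state groups distinguished at enhancers).
#' @param restarts random restarts (default 10).
#' @param seed integer seed.
#' @param activityColumn column (name or index) whose descending cluster
#'   mean defines label order; defaults to `"H3K27ac"` when present, else
#'   column 1.
#' @return list with `labels` (integer per region, 1 = most active
#'   cluster), `centroids` (k x marks, on the standardized scale) and
#'   `withinss`.
#' @export
kmeansHm <- function(mat, k = 8L, restarts = 10L, seed = 1L,
                     activityColumn = NULL) {
  if (k > nrow(mat)) stop("k exceeds the number of rows (", nrow(mat), ")")
  if (is.null(activityColumn))
    activityColumn <- if ("H3K27ac" %in% colnames(mat)) "H3K27ac" else 1L
  z <- scale(mat)
  z[, attr(z, "scaled:scale") == 0] <- 0
  fit <- withSeed(seed, kmeans(z, centers = k, nstart = restarts,
                               iter.max = 50L))
  act <- fit$centers[, activityColumn]
  relabel <- order(-act, seq_len(k))
  newLabel <- integer(k)
  newLabel[relabel] <- seq_len(k)
  list(labels = newLabel[fit$cluster],
       centroids = fit$centers[relabel, , drop = FALSE],
       withinss = fit$tot.withinss)
}

#' Expression of genes paired with grouped regions
#'
#' Pairs each region with its nearest TSS, splits the paired genes by the
#' region's group label (activity quantile or chromatin cluster), and
#' compares neighboring groups with two-sided Mann-Whitney tests (exact
#' for small samples, via [stats::wilcox.test()]'s default switching),
#' BH-adjusted across the neighboring comparisons. Every paired gene
#' contributes to exactly one group.
#'
#' @param groups integer/factor group label per region (assumed ordered,
#'   e.g. ascending activity).
#' @param regions `GRanges` parallel to `groups`.
#' @param genes `GRanges` of width-1 TSSs with `gene_id`.
#' @param tpm named numeric vector of gene expression (TPM).
#' @param maxDistance maximum pairing distance.
#' @return list with `expression` (per-group list of TPM vectors),
#'   `summary` (group, n, mean, median) and `tests` (neighboring-group
#'   Mann-Whitney p-values with BH adjustment; tests against empty groups
#'   are skipped with a warning).
#' @export
expressionByGroup <- function(groups, regions, genes, tpm,
                              maxDistance = 1e6) {
  stopifnot(length(groups) == length(regions))
  paired <- nearestTss(regions, genes, maxDistance)
  lv <- sort(unique(groups))
  expr <- lapply(lv, function(g) {
    ids <- paired$gene_id[groups == g & !is.na(paired$gene_id)]
    unname(tpm[ids[ids %in% names(tpm)]])
  })
  names(expr) <- as.character(lv)
  summ <- data.frame(group = lv, n = lengths(expr),
                     mean = vapply(expr, function(x)
                       if (length(x)) mean(x) else NA_real_, 1),
                     median = vapply(expr, function(x)
                       if (length(x)) median(x) else NA_real_, 1))
  tests <- data.frame(group_a = head(lv, -1), group_b = lv[-1],
                      p = NA_real_)
  for (i in seq_len(nrow(tests))) {
    a <- expr[[i]]; b <- expr[[i + 1L]]
    if (length(a) == 0L || length(b) == 0L) {
      warning("group with zero paired genes; comparison ", lv[i], " vs ",
              lv[i + 1L], " skipped")
      next
    }
    p <- suppressWarnings(wilcox.test(a, b)$p.value)
    tests$p[i] <- if (is.na(p)) 1 else p  # degenerate all-tie comparison
  }
  tests$p_adj <- p.adjust(tests$p, "BH")
  list(expression = expr, summary = summ, tests = tests)
}

#' Overlap accounting between named region sets
#'
#' Pairwise >= 1 bp overlap counts between named interval sets (e.g.
#' reporter-called enhancers vs chromatin-predicted enhancers), plus, when
#' per-region labels are supplied for one set, the label composition of
#' its members that do or do not overlap another set.
#'
#' @param sets named list of `GRanges` (>= 2 sets).
#' @param labels optional integer/character labels parallel to
#'   `sets[[labelSet]]`.
#' @param labelSet name of the labeled set (default first).
#' @return list with `pairwise` (data.frame set_a, set_b, overlap counts:
#'   members of set_a overlapping set_b) and, when labels are given,
#'   `composition` (label x overlapping/non-overlapping counts against
#'   every other set).
#' @export
overlapAccounting <- function(sets, labels = NULL,
                              labelSet = names(sets)[1L]) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  nm <- names(sets)
  pw <- expand.grid(set_a = nm, set_b = nm, stringsAsFactors = FALSE)
  pw <- pw[pw$set_a != pw$set_b, ]
  pw$overlap <- mapply(function(a, b)
    sum(GenomicRanges::countOverlaps(sets[[a]], sets[[b]],
        minoverlap = 1L, ignore.strand = TRUE) > 0),
    pw$set_a, pw$set_b)
  rownames(pw) <- NULL
  out <- list(pairwise = pw)
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(sets[[labelSet]]))
    comp <- list()
    for (other in setdiff(nm, labelSet)) {
      ov <- GenomicRanges::countOverlaps(sets[[labelSet]], sets[[other]],
        minoverlap = 1L, ignore.strand = TRUE) > 0
      comp[[other]] <- table(label = labels, overlapping = ov)
    }
    out$composition <- comp
  }
  out
}
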