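#' Two-set motif enrichment with background subsampling
#'
#' AME-style enrichment: for each motif, the number of foreground vs
#' background regions containing at least one significant hit is compared
#' with a one-sided Fisher exact test, and the p-value is scaled
#' Bonferroni-style by the number of motifs tested into an E-value. When
#' the background is larger than the foreground, `nSubsamples` equal-size
#' background subsamples are drawn (seeded) and the mean E-value over
#' subsamples is reported, which stabilizes the comparison against
#' background composition. The `log_ratio` column contrasts the two sets:
#' `-log10(E_fg_vs_bg) + log10(E_bg_vs_fg)`, large positive values meaning
#' the motif discriminates the foreground.
#'
#' @param fgSeqs,bgSeqs `DNAStringSet` (or character) region sequences;
#'   `length(bgSeqs) >= length(fgSeqs)` is required when subsampling
#'   applies.
#' @param motifs list of [MotifMatrix-class].
#' @param thresholdP per-position hit tail probability (default 1e-4).
#' @param nSubsamples background subsamples (default 10).
#' @param eThreshold E-value at or below which a motif is flagged enriched
#'   (default 1e-3).
#' @param seed seed for the background subsampling.
#' @return data.frame with one row per motif: `motif`, `cluster`,
#'   `fg_hits`, `fg_n`, `bg_hits` (mean over subsamples), `bg_n`, `p`, `E`
#'   (means over subsamples), `log_ratio`, `enriched`.
#' @export
enrichTwoSets <- function(fgSeqs, bgSeqs, motifs, thresholdP = 1e-4,
                          nSubsamples = 10L, eThreshold = 1e-3,
                          seed = 1L) {
  nf <- length(fgSeqs); nb <- length(bgSeqs)
  if (nf == 0L) stop("empty foreground set")
  if (nb < nf)
    stop("background smaller than foreground; subsampling requires ",
         "length(bgSeqs) >= length(fgSeqs)")
  nm <- length(motifs)
  fgHit <- countHitsPerRegion(fgSeqs, motifs, thresholdP, perMotif = TRUE) > 0
  bgHit <- countHitsPerRegion(bgSeqs, motifs, thresholdP, perMotif = TRUE) > 0
  draws <- if (nb > nf) {
    withSeed(seed, lapply(seq_len(nSubsamples), function(s)
      sample.int(nb, nf)))
  } else list(seq_len(nb))
  oneSided <- function(a, na, b, nbn)  # P(fg hits >= observed)
    fisher.test(matrix(c(a, na - a, b, nbn - b), 2L),
                alternative = "greater")$p.value
  res <- lapply(seq_len(nm), function(j) {
    fh <- sum(fgHit[, j])
    per <- vapply(draws, function(idx) {
      bh <- sum(bgHit[idx, j])
      pf <- oneSided(fh, nf, bh, nf)
      pr <- oneSided(bh, nf, fh, nf)
      c(bh, pf, pr)
    }, numeric(3))
    bh <- mean(per[1L, ])
    p <- mean(per[2L, ])
    E <- mean(pmin(per[2L, ] * nm, nm))
    Erev <- mean(pmin(per[3L, ] * nm, nm))
    data.frame(motif = motifName(motifs[[j]]),
               cluster = motifCluster(motifs[[j]]),
               fg_hits = fh, fg_n = nf, bg_hits = bh, bg_n = nf,
               p = p, E = E, log_ratio = -log10(E) + log10(Erev),
               enriched = E <= eThreshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Spacing/orientation enrichment across response classes
#'
#' Enriches each response class (e.g. induced / repressed / non-responding
#' receptor-occupied regions) against the pooled other classes for every
#' repeat variant, keeps variants reaching `eThreshold` in at least one
#' class, and Z-scores `-log10(E)` within each variant row so the class
#' with the strongest relative enrichment stands out.
#'
#' @param setSeqs named list of `DNAStringSet`s, one per class (>= 2
#'   non-empty classes).
#' @param composites list of [CompositeMotif-class] (or any motifs).
#' @param thresholdP hit tail probability.
#' @param eThreshold row-retention E-value cutoff (default 1e-3).
#' @param nSubsamples,seed background subsampling controls (see
#'   [enrichTwoSets()]).
#' @return list with matrices `E` (variants x classes, retained rows only)
#'   and `Z` (row-wise Z-scores of `-log10 E`); both empty (0 rows) when
#'   no variant passes.
#' @export
spacingEnrichment <- function(setSeqs, composites, thresholdP = 1e-4,
                              eThreshold = 1e-3, nSubsamples = 10L,
                              seed = 1L) {
  stopifnot(length(setSeqs) >= 2L, all(lengths(setSeqs) > 0L))
  classes <- names(setSeqs) %||% paste0("set", seq_along(setSeqs))
  E <- matrix(NA_real_, length(composites), length(setSeqs),
              dimnames = list(vapply(composites, motifName, ""), classes))
  for (ci in seq_along(setSeqs)) {
    fg <- setSeqs[[ci]]
    bg <- do.call(c, lapply(setSeqs[-ci], as.character))
    rec <- enrichTwoSets(fg, bg, composites, thresholdP,
                         nSubsamples, eThreshold, seed = seed + ci)
    E[, ci] <- rec$E
  }
  keep <- apply(E, 1, min) <= eThreshold
  E <- E[keep, , drop = FALSE]
  if (nrow(E) == 0L) return(list(E = E, Z = E))
  nl <- -log10(E)
  Z <- t(apply(nl, 1, function(r) {
    s <- sd(r)
    if (s == 0) rep(0, length(r)) else (r - mean(r)) / s
  }))
  dimnames(Z) <- dimnames(E)
  list(E = E, Z = Z)
}

#' Hierarchical clustering of a motif-enrichment matrix
#'
#' Agglomerative clustering with Ward linkage on Manhattan (L1) distances,
#' the combination used to order motif-by-class enrichment heatmaps.
#'
#' @param mat numeric matrix (e.g. motifs x classes of `-log10 E`).
#' @param k optional number of groups to cut the dendrogram into.
#' @return list with the `hclust` object (`tree`), the leaf `order`
#'   (labels), and `groups` (named cluster labels, when `k` given).
#' @export
clusterEnrichmentMatrix <- function(mat, k = NULL) {
  stopifnot(all(is.finite(mat)))
  d <- dist(mat, method = "manhattan")
  tree <- hclust(d, method = "ward.D")
  out <- list(tree = tree, order = rownames(mat)[tree$order])
  if (!is.null(k)) out$groups <- cutree(tree, k = k)
  out
}
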