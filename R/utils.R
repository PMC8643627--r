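#' @importFrom methods new validObject is setValidity show
#' @importFrom stats kmeans hclust dist fisher.test p.adjust pbinom phyper
#'   wilcox.test quantile rnorm runif rpois rgeom rbinom sd median cutree
#' @importFrom utils head read.table write.table
#' @importFrom mclust adjustedRandIndex
#' @importFrom data.table := .N .SD
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Round half away from zero (commercial rounding), used wherever a
## fraction of a set size is turned into a count.
roundHalfUp <- function(x) floor(x + 0.5)

## Hamming distance between two equal-length UMI strings; 'N' matches
## nothing, including another 'N'.
umiHamming <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("UMIs differ in length")
  sum(av != bv | av == "N" | bv == "N")
}

## Area under the ROC curve via the rank (Mann-Whitney) identity.
aucFromScores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1L | labels == TRUE
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Deterministic ordering: descending by score, ties by original index.
orderByScoreDesc <- function(score) order(-score, seq_along(score))

`%||%` <- function(a, b) if (is.null(a)) b else a
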