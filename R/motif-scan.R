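## PWM scanning with an exact background score distribution.
##
## Scores are log2 odds (motif probability over background). The hit
## threshold for a tail probability p is computed from the exact
## distribution of the window score under the background model by dynamic
## programming (per-column convolution) on scores discretized to
## SCAN_GRANULARITY bits, so thresholds are reproducible and independent
## of the scanned sequence.

SCAN_GRANULARITY <- 0.01
LOG_ODDS_EPS <- 1e-4  # floor for motif probabilities in log-odds scores

logOddsMatrix <- function(motif) {
  log2(pmax(motifProfile(motif), LOG_ODDS_EPS) / motifBackground(motif))
}

## Exact tail threshold: the smallest achievable score s such that
## P(window score >= s) <= p under the background model. Returns +Inf when
## even the maximal score is too likely (short/weak motifs).
scoreThreshold <- function(motif, p, granularity = SCAN_GRANULARITY) {
  stopifnot(p > 0, p < 1)
  S <- round(logOddsMatrix(motif) / granularity)  # integer scores, 4 x w
  bg <- motifBackground(motif)
  probs <- 1
  lo <- 0L
  for (j in seq_len(ncol(S))) {
    col <- S[, j]
    new_lo <- lo + min(col)
    new_hi <- lo + length(probs) - 1L + max(col)
    acc <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      sh <- (lo + col[b]) - new_lo
      idx <- seq_along(probs) + sh
      acc[idx] <- acc[idx] + probs * bg[b]
    }
    probs <- acc
    lo <- new_lo
  }
  tail <- rev(cumsum(rev(probs)))
  k <- which(tail <= p)
  if (length(k) == 0L) return(Inf)
  (k[1L] - 1L + lo) * granularity
}

## Window scores of one motif along one sequence (integer-coded),
## NA where the window contains a non-ACGT base.
windowScores <- function(codes, lodds) {
  w <- ncol(lodds)
  L <- length(codes)
  if (L < w) return(numeric(0))
  n <- L - w + 1L
  sc <- numeric(n)
  for (j in seq_len(w)) sc <- sc + lodds[j * 4L - 4L + codes[j:(j + n - 1L)]]
  sc
}

encodeSeq <- function(seq) {
  v <- match(strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]],
             DNA_BASES4)
  v[is.na(v)] <- NA_integer_
  v
}

#' Scan a sequence for motif hits
#'
#' Scores every offset on both strands with the motif's log2-odds matrix
#' and reports positions whose score reaches the exact-background-tail
#' threshold for `thresholdP` (see Details). Windows containing a non-ACGT
#' base are skipped. When `greedy = TRUE` overlapping hits are resolved
#' greedily by descending score (ties by offset, forward strand first), the
#' mode used for per-region hit counting.
#'
#' @details The threshold is the smallest score whose tail probability
#' under the background base distribution is at most `thresholdP`,
#' computed exactly by dynamic programming over the discretized score
#' distribution. Very short motifs may have no achievable score that rare
#' (e.g. any 4-mer has background probability ~0.4%); such scans return no
#' hits - use a larger `thresholdP` for short matrices.
#'
#' @param seq a `DNAString`, `DNAStringSet` element or character sequence.
#' @param motif a [MotifMatrix-class].
#' @param thresholdP tail probability defining a hit (default 1e-4).
#' @param greedy resolve overlapping hits greedily by descending score.
#' @return data.frame with columns `offset` (0-based from sequence start),
#'   `strand`, `score` (bits).
#' @examples
#' m <- MotifMatrix("octamer", matrix(rep(c(.91, .03, .03, .03), 8), 4,
#'   dimnames = list(c("A", "C", "G", "T"), NULL)))
#' scanMotif(paste(rep("AAAAAAAA", 3), collapse = "CGTGCGTG"), m)
#' @export
scanMotif <- function(seq, motif, thresholdP = 1e-4, greedy = FALSE) {
  stopifnot(thresholdP > 0, thresholdP < 1)
  thr <- scoreThreshold(motif, thresholdP)
  scanMotifAt(seq, motif, thr, greedy)
}

## Internal scan with a precomputed threshold (lets callers amortize the
## DP across many sequences).
scanMotifAt <- function(seq, motif, thr, greedy = FALSE) {
  codes <- if (is.integer(seq)) seq else encodeSeq(seq)
  lodds <- logOddsMatrix(motif)
  w <- ncol(lodds)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric())
  if (length(codes) < w || !is.finite(thr)) return(empty)
  fw <- windowScores(codes, lodds)
  rc <- lodds[4:1, w:1, drop = FALSE]  # reverse-complement scoring matrix
  rv <- windowScores(codes, rc)
  eps <- SCAN_GRANULARITY / 2
  fi <- which(!is.na(fw) & fw >= thr - eps)
  ri <- which(!is.na(rv) & rv >= thr - eps)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fw[fi]),
    data.frame(offset = ri - 1L, strand = rep("-", length(ri)),
               score = rv[ri]))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(-hits$score, hits$offset, hits$strand), , drop = FALSE]
  if (greedy && nrow(hits) > 1L) {
    kept <- logical(nrow(hits))
    occ_s <- integer(0); occ_e <- integer(0)
    for (i in seq_len(nrow(hits))) {
      s <- hits$offset[i]; e <- s + w - 1L
      if (!any(s <= occ_e & e >= occ_s)) {
        kept[i] <- TRUE
        occ_s <- c(occ_s, s); occ_e <- c(occ_e, e)
      }
    }
    hits <- hits[kept, , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Count significant motif hits per region
#'
#' Counts non-overlapping significant hits (greedy by descending score)
#' per motif and sums them over the supplied motif set, one total per
#' region - the per-region "number of significant motifs" used to compare
#' activity groups.
#'
#' @param sequences a `DNAStringSet` (or character vector) of region
#'   sequences.
#' @param motifs list of [MotifMatrix-class].
#' @param thresholdP hit tail probability (default 1e-4).
#' @param perMotif if TRUE return the regions x motifs count matrix
#'   instead of row totals.
#' @return integer vector of per-region totals, or a count matrix when
#'   `perMotif = TRUE`.
#' @export
countHitsPerRegion <- function(sequences, motifs, thresholdP = 1e-4,
                               perMotif = FALSE) {
  codes <- lapply(as.character(sequences), encodeSeq)
  counts <- vapply(motifs, function(m) {
    thr <- scoreThreshold(m, thresholdP)
    vapply(codes, function(cs) nrow(scanMotifAt(cs, m, thr, greedy = TRUE)),
           integer(1))
  }, integer(length(codes)))
  counts <- matrix(counts, nrow = length(codes),
                   dimnames = list(names(sequences),
                                   vapply(motifs, motifName, "")))
  if (perMotif) counts else as.integer(rowSums(counts))
}

## Consensus string of a motif (most probable base per column).
motifConsensus <- function(motif) {
  paste(DNA_BASES4[apply(motifProfile(motif), 2, which.max)], collapse = "")
}
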