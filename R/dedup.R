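#' UMI-aware deduplication of reporter fragments
#'
#' Collapses PCR duplicates of reporter fragments into unique molecules.
#' Deduplication is performed independently within every replicate x
#' condition partition (it never crosses replicates).
#'
#' In `"exact"` mode one molecule is kept per distinct
#' (chrom, start, end, strand, umi) tuple. In `"directional"` mode, UMIs
#' observed at identical coordinates are additionally merged into a
#' UMI within `maxHamming` substitutions that is at least twice as
#' abundant, greedily by descending abundance (ties broken
#' lexicographically) - the directional network rule used to absorb UMIs
#' created by sequencing errors. `N` in a UMI matches nothing (every
#' comparison involving `N`, including `N` vs `N`, counts as a mismatch).
#'
#' @param fragments data.frame with columns chrom, start, end, strand, umi,
#'   replicate, condition (extra columns are carried through from the
#'   representative read).
#' @param mode `"exact"` (default) or `"directional"`.
#' @param maxHamming maximum Hamming distance for directional merging.
#' @return data.frame of unique molecules with a `reads` column giving the
#'   duplicate multiplicity of each molecule.
#' @examples
#' f <- data.frame(chrom = "chr1", start = 1, end = 50, strand = "+",
#'                 umi = c("AAAA", "AAAA", "AAAT"), replicate = 1,
#'                 condition = "LIF")
#' dedupUmi(f)                         # 2 molecules
#' dedupUmi(f, "directional", 1)       # AAAT absorbed into AAAA
#' @export
dedupUmi <- function(fragments, mode = c("exact", "directional"),
                     maxHamming = 1L) {
  mode <- match.arg(mode)
  if (maxHamming < 0) stop("maxHamming must be >= 0")
  need <- c("chrom", "start", "end", "strand", "umi", "replicate",
            "condition")
  if (!all(need %in% colnames(fragments)))
    stop("fragments must have columns: ", paste(need, collapse = ", "))
  if (any(nchar(fragments$umi) == 0L)) stop("empty UMI encountered")
  dt <- data.table::as.data.table(fragments)
  keycols <- c("replicate", "condition", "chrom", "start", "end", "strand",
               "umi")
  extras <- setdiff(names(dt), keycols)
  if (length(extras)) {
    mol <- dt[, c(lapply(.SD, `[`, 1L), list(reads = .N)),
              by = keycols, .SDcols = extras]
  } else {
    mol <- dt[, list(reads = .N), by = keycols]
  }
  if (mode == "directional") {
    grpcols <- setdiff(keycols, "umi")
    merged <- mol[, {
      if (.N == 1L) .SD
      else {
        o <- order(-reads, umi)
        sd <- .SD[o]
        keep <- rep(TRUE, .N)
        reads2 <- sd$reads
        for (i in seq_len(.N)[-1L]) {
          for (j in seq_len(i - 1L)) {
            if (!keep[j]) next
            if (umiHamming(sd$umi[i], sd$umi[j]) <= maxHamming &&
                sd$reads[j] >= 2L * sd$reads[i]) {
              reads2[j] <- reads2[j] + reads2[i]
              keep[i] <- FALSE
              break
            }
          }
        }
        sd2 <- sd[keep]
        sd2$reads <- reads2[keep]
        sd2
      }
    }, by = grpcols]
    mol <- merged
  }
  data.table::setorderv(mol, c("replicate", "condition", "chrom", "start",
                               "end", "umi"))
  as.data.frame(mol)
}
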