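#' Read a BED3/BED6 file into a GRanges
#'
#' BED semantics (0-based half-open intervals) are converted to the 1-based
#' closed convention of [GenomicRanges::GRanges] at this boundary; strand is
#' taken from column 6 when present, otherwise unstranded. Lines starting
#' with `track`, `browser` or `#` are skipped.
#'
#' @param path path to a tab-separated BED file.
#' @return a `GRanges`; the BED name column (4), when present, becomes
#'   `names()`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200\tx\t0\t-", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | !nzchar(chrom))
  if (length(bad))
    stop("malformed BED line ", lineno[bad[1L]], ": non-numeric coordinates")
  bad <- which(end <= start | start < 0)
  if (length(bad))
    stop("invalid interval at BED line ", lineno[bad[1L]],
         ": need 0 <= start < end")
  strand <- rep(".", length(lines))
  has6 <- nf >= 6L
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid strand at BED line ",
         lineno[which(!strand %in% c("+", "-", "."))[1L]])
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end),
                               strand = strand)
  has4 <- nf >= 4L
  if (any(has4)) {
    nm <- rep(NA_character_, length(lines))
    nm[has4] <- vapply(fields[has4], `[[`, "", 4L)
    if (!anyNA(nm)) names(gr) <- nm
  }
  gr
}

#' Write a GRanges as BED6
#'
#' The exact inverse of [readBed()]: coordinates are converted back to
#' 0-based half-open, `names()` populate column 4 (or `.`), and `*` strand
#' is written as `.`, so a write/read round trip reproduces coordinates and
#' strand exactly.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  nm <- names(gr) %||% rep(".", length(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm, score = 0L, strand = strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read motifs from a JASPAR PFM text file
#'
#' Parses JASPAR-format position frequency matrices (a `>name` header
#' followed by four base rows of counts, with or without the
#' `A [ ... ]` bracket decoration) and converts counts to per-column
#' probabilities with a pseudocount of 0.5 per cell, which keeps log-odds
#' scores finite for matrices containing zero counts.
#'
#' The second whitespace-separated token of the header, when present, is
#' used as the cluster label, so clustered motif collections can carry
#' their cluster ids through enrichment and classification.
#'
#' @param path path to a JASPAR PFM file.
#' @param pseudocount added to every cell before normalization (default 0.5).
#' @param background background base frequencies for the resulting motifs.
#' @return a list of [MotifMatrix-class] objects (empty list for an empty
#'   file).
#' @export
readJasparPfm <- function(path, pseudocount = 0.5,
                          background = rep(0.25, 4)) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' motif headers found in ", path)
  ends <- c(heads[-1L] - 1L, length(lines))
  motifs <- vector("list", length(heads))
  for (i in seq_along(heads)) {
    header <- sub("^>\\s*", "", lines[heads[i]])
    toks <- strsplit(header, "\\s+")[[1]]
    name <- toks[1L]
    cluster <- if (length(toks) >= 2L) toks[2L] else name
    body <- lines[seq(heads[i] + 1L, ends[i])]
    if (length(body) != 4L)
      stop("motif ", name, ": expected 4 base rows, got ", length(body))
    rows <- lapply(body, function(l) {
      nums <- regmatches(l, gregexpr("-?[0-9.]+", l))[[1]]
      as.numeric(nums)
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("motif ", name, ": base rows have unequal lengths")
    counts <- do.call(rbind, rows)
    lead <- toupper(substr(body, 1L, 1L))
    rownames(counts) <- if (all(lead %in% DNA_BASES4)) lead else DNA_BASES4
    counts <- counts[DNA_BASES4, , drop = FALSE]
    prob <- sweep(counts + pseudocount, 2,
                  colSums(counts) + 4 * pseudocount, "/")
    motifs[[i]] <- MotifMatrix(name, prob, clusterId = cluster,
                               background = background)
  }
  motifs
}

#' Write motifs in JASPAR PFM format
#'
#' Probabilities are scaled to integer counts (x1000) so the files can be
#' re-read by [readJasparPfm()] (up to the pseudocount renormalization).
#'
#' @param motifs a list of [MotifMatrix-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeJasparPfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(sprintf(">%s %s", motifName(m), motifCluster(m)), con)
    counts <- round(motifProfile(m) * 1000)
    for (b in DNA_BASES4)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(counts[b, ], collapse = " ")), con)
  }
  invisible(path)
}

#' Fetch region sequences from a genome
#'
#' Extracts the (uppercased) sequence of each region from an in-memory
#' genome; minus-strand regions are not reverse-complemented (reporter
#' fragments are scanned on both strands downstream).
#'
#' @param genome a named [Biostrings::DNAStringSet], one entry per
#'   chromosome.
#' @param regions a `GRanges` within the genome bounds.
#' @return a `DNAStringSet` with one entry per region, named after
#'   `names(regions)` when present.
#' @export
fetchSequences <- function(genome, regions) {
  chrom <- as.character(GenomicRanges::seqnames(regions))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) not in genome: ", paste(missing, collapse = ", "))
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(regions), function(i) {
    toupper(as.character(Biostrings::subseq(
      genome[[chrom[i]]],
      GenomicRanges::start(regions)[i],
      GenomicRanges::end(regions)[i])))
  }, character(1)))
  names(seqs) <- names(regions)
  seqs
}
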