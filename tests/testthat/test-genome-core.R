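test_that("BED reading preserves half-open semantics, strand and errors", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200",
               "chr1\t100\t200\tx\t0\t-"), f)
  gr <- readBed(f)
  expect_equal(GenomicRanges::start(gr), c(101L, 101L))  # 1-based internal
  expect_equal(GenomicRanges::end(gr), c(200L, 200L))
  expect_equal(as.character(GenomicRanges::strand(gr)), c("*", "-"))

  writeLines("chr1\t200\t100", f)
  expect_error(readBed(f), "line 1")
  writeLines(c("chr1\t10\t20", "chr1\t5"), f)
  expect_error(readBed(f), "line 2")
})

test_that("BED write/read round trip reproduces coordinates exactly", {
  set.seed(1)
  start <- sample.int(1e5, 40)
  gr <- GenomicRanges::GRanges("chr3",
    IRanges::IRanges(start, width = sample(50:500, 40, TRUE)),
    strand = sample(c("+", "-", "*"), 40, TRUE))
  names(gr) <- sprintf("r%02d", seq_along(gr))
  f <- withr::local_tempfile(fileext = ".bed")
  writeBed(gr, f)
  back <- readBed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(as.character(GenomicRanges::strand(back)),
               as.character(GenomicRanges::strand(gr)))
  expect_equal(names(back), names(gr))
})

test_that("JASPAR PFM parsing applies the 0.5 pseudocount per cell", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">toy cluster9",
               "A [ 4 0 ]", "C [ 0 4 ]", "G [ 0 0 ]", "T [ 0 0 ]"), f)
  m <- readJasparPfm(f)
  expect_length(m, 1)
  expect_equal(motifCluster(m[[1]]), "cluster9")
  ## (4 + 0.5) / (4 + 4 * 0.5) = 0.75
  expect_equal(unname(motifProfile(m[[1]])["A", 1]), 0.75)
  expect_equal(unname(motifProfile(m[[1]])["C", 2]), 0.75)
  expect_equal(unname(colSums(motifProfile(m[[1]]))), c(1, 1))

  writeLines(character(), f)
  expect_equal(readJasparPfm(f), list())

  writeLines(c(">bad", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), f)
  expect_error(readJasparPfm(f), "4 base rows")

  writeLines(c(">bad", "A [ 1 2 ]", "C [ 1 ]", "G [ 1 2 ]", "T [ 1 2 ]"), f)
  expect_error(readJasparPfm(f), "unequal")
})

test_that("motif write/read survives a round trip up to renormalization", {
  panel <- defaultMotifPanel(n = 3, nDrivers = 1, seed = 4)
  f <- withr::local_tempfile(fileext = ".pfm")
  writeJasparPfm(panel, f)
  back <- readJasparPfm(f)
  expect_equal(vapply(back, motifName, ""), vapply(panel, motifName, ""))
  expect_equal(motifProfile(back[[1]]), motifProfile(panel[[1]]),
               tolerance = 0.01)
})

test_that("overlapPairs matches a quadratic scan and is symmetric", {
  set.seed(42)
  mk <- function(n) GenomicRanges::GRanges(
    sample(c("chrA", "chrB"), n, TRUE),
    IRanges::IRanges(sample.int(2000, n), width = sample(20:200, n, TRUE)))
  a <- mk(50); b <- mk(50)
  got <- overlapPairs(a, b)
  brute <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    same <- as.character(GenomicRanges::seqnames(a))[i] ==
            as.character(GenomicRanges::seqnames(b))[j]
    ov <- min(GenomicRanges::end(a)[i], GenomicRanges::end(b)[j]) -
          max(GenomicRanges::start(a)[i], GenomicRanges::start(b)[j]) + 1
    if (same && ov >= 1) brute[[length(brute) + 1]] <- c(i, j)
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(got), nrow(brute))
  expect_setequal(paste(got$a, got$b), paste(brute[, 1], brute[, 2]))
  swapped <- overlapPairs(b, a)
  expect_setequal(paste(got$a, got$b), paste(swapped$b, swapped$a))
})

test_that("adjacent half-open intervals do not overlap", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10", "chr1\t10\t20", "chr1\t9\t20"), f)
  gr <- readBed(f)
  expect_equal(nrow(overlapPairs(gr[1], gr[2])), 0)
  expect_equal(nrow(overlapPairs(gr[1], gr[3])), 1)
})

test_that("nearestTss picks the closest gene with deterministic ties", {
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1500, 5000), width = 1))
  genes$gene_id <- c("g_near", "g_far")
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(900, 1100))
  expect_equal(nearestTss(region, genes)$gene_id, "g_near")
  expect_true(is.na(nearestTss(region, genes, maxDistance = 100)$gene_id))
  expect_true(is.na(nearestTss(region,
    GenomicRanges::GRanges())$gene_id))

  ## tie at equal distance resolved lexicographically
  tie <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(900, 1100), width = 1))
  tie$gene_id <- c("zzz", "aaa")
  expect_equal(nearestTss(region, tie)$gene_id, "aaa")
})

test_that("nearestTss agrees with an exhaustive scan on random inputs", {
  set.seed(7)
  regions <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(1e6, 100), width = 300))
  genes <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(sample.int(1e6, 20), width = 1))
  genes$gene_id <- sprintf("g%02d", 1:20)
  got <- nearestTss(regions, genes, maxDistance = 1e6)
  mid <- floor((GenomicRanges::start(regions) +
                GenomicRanges::end(regions)) / 2)
  for (i in seq_along(regions)) {
    d <- abs(GenomicRanges::start(genes) - mid[i])
    best <- sort(genes$gene_id[d == min(d)])[1]
    expect_equal(got$gene_id[i], best)
    expect_equal(got$distance[i], min(d))
  }
})

test_that("promoter windows are strand-aware and clamp at the origin", {
  tss <- function(pos, strand) {
    g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos + 1, width = 1),
                                strand = strand)
    g$gene_id <- "g"
    g
  }
  ## plus strand, 1 kb upstream: BED [9000, 10000)
  w <- promoterWindows(tss(10000, "+"), upstream = 1000, downstream = 0)
  expect_equal(GenomicRanges::start(w), 9001L)
  expect_equal(GenomicRanges::end(w), 10000L)
  ## minus strand mirrors upstream toward larger coordinates
  w <- promoterWindows(tss(10000, "-"), upstream = 500, downstream = 0)
  expect_equal(GenomicRanges::start(w), 10001L)
  expect_equal(GenomicRanges::end(w), 10500L)
  ## clamped at the chromosome origin
  w <- promoterWindows(tss(300, "+"), upstream = 1000, downstream = 0)
  expect_equal(GenomicRanges::start(w), 1L)
  expect_equal(GenomicRanges::width(w), 300L)
  ## width property on plus strand: min(u + d, tss + d)
  for (pos in c(100, 5000)) for (d in c(0, 200)) {
    w <- promoterWindows(tss(pos, "+"), upstream = 1000, downstream = d)
    expect_equal(GenomicRanges::width(w), min(1000 + d, pos + d))
  }
})

test_that("sequence fetch returns uppercased region sequence", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "aacgtACGTTTTT"))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 9))
  names(gr) <- "r1"
  expect_equal(as.character(fetchSequences(genome, gr)), c(r1 = "CGTACGT"))
  expect_error(fetchSequences(genome,
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 5))), "chrX")
})
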