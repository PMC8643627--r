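## Synthetic-data generators. Everything is deterministic given the config
## seed; the genome, the reporter library and the HM matrix draw from
## separate derived seeds so regenerating one component does not shift the
## random stream of another.

sampleBases <- function(n, gc) {
  sample(DNA_BASES4, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

sampleMotifInstance <- function(motif) {
  prof <- motifProfile(motif)
  paste(vapply(seq_len(ncol(prof)), function(j)
    sample(DNA_BASES4, 1L, prob = prof[, j]), character(1)), collapse = "")
}

## Place m non-overlapping widths uniformly on [1, len] by distributing the
## free space as random gaps (deterministic given the RNG state).
placeNonOverlapping <- function(widths, len) {
  m <- length(widths)
  free <- len - sum(widths) - m  # keep >= 1 bp between regions
  if (free < 0)
    stop("regions cannot be placed without overlap; ",
         "increase chromLength or reduce nInputRegions")
  cuts <- sort(c(0, runif(m, 0, free)))
  gaps <- diff(cuts)
  starts <- cumsum(c(1, head(widths, -1) + 1)) + floor(cumsum(gaps))
  starts
}

#' Simulate a toy genome with accessible candidate regions
#'
#' Generates i.i.d. background sequence at the configured GC content,
#' places non-overlapping candidate regions with log-normal widths
#' (median 350 bp), assigns ground-truth activity classes and
#' fold-activations, and plants motif instances from the configured panel
#' (driver motifs preferentially into active regions).
#'
#' @param config a [SynthConfig-class].
#' @return a list with elements `genome` (named `DNAStringSet`), `regions`
#'   (named `GRanges`), `truth` (per-region data.frame: `region`,
#'   `is_active`, `class`, `fold_lif`, `fold_ra`, `width`) and
#'   `motifTruth` (planted insertions: `region`, `motif`, `offset`), plus
#'   `panel`, the motif list used.
#' @examples
#' sim <- simulateGenome(synthConfig(seed = 7, nInputRegions = 20L))
#' sum(sim$truth$is_active)
#' @export
simulateGenome <- function(config) {
  validObject(config)
  panel <- if (length(config@motifPanel)) config@motifPanel
           else defaultMotifPanel(seed = config@seed)
  withSeed(config@seed, {
    n <- config@nInputRegions
    chroms <- sprintf("chr%d", seq_len(config@nChrom))
    seqs <- lapply(chroms, function(ch)
      paste(sampleBases(config@chromLength, config@gc), collapse = ""))
    names(seqs) <- chroms

    widths <- pmax(60L, as.integer(round(exp(rnorm(n, log(350), 0.3)))))
    chrom_of <- rep(chroms, length.out = n)
    start <- integer(n)
    for (ch in chroms) {
      idx <- which(chrom_of == ch)
      if (length(idx))
        start[idx] <- placeNonOverlapping(widths[idx], config@chromLength)
    }
    regions <- GenomicRanges::GRanges(chrom_of,
      IRanges::IRanges(start, width = widths))
    names(regions) <- sprintf("region_%04d", seq_len(n))

    ## ground-truth activity classes
    nActive <- roundHalfUp(config@fracActive * n)
    nRa <- roundHalfUp(config@fracRaInducible * n)
    nLif <- roundHalfUp(config@fracLifDependent * n)
    active_idx <- sort(sample.int(n, nActive))
    cls <- rep("inactive", n)
    cls[active_idx] <- "stable"
    if (nRa > 0) cls[active_idx[seq_len(nRa)]] <- "RA-inducible"
    if (nLif > 0)
      cls[active_idx[nActive - seq_len(nLif) + 1L]] <- "LIF-dependent"
    fold <- rep(1, n)
    fold[active_idx] <- rep_len(config@activityGrid, nActive)[
      sample.int(nActive)]
    fold_lif <- ifelse(cls == "RA-inducible",
                       pmax(1, fold / config@inductionFold), fold)
    fold_ra <- ifelse(cls == "LIF-dependent",
                      pmax(1, fold / config@inductionFold), fold)
    fold_lif[cls == "inactive"] <- 1
    fold_ra[cls == "inactive"] <- 1
    truth <- data.frame(region = names(regions), is_active = cls != "inactive",
                        class = cls, fold = fold, fold_lif = fold_lif,
                        fold_ra = fold_ra, width = widths,
                        stringsAsFactors = FALSE)

    ## plant motif instances (drivers enriched in active regions)
    ins <- list()
    for (m in panel) {
      driver <- startsWith(motifName(m), "driver")
      p <- ifelse(truth$is_active & driver, config@pActive, config@pInactive)
      hit <- runif(n) < p
      for (i in which(hit)) {
        w <- motifWidth(m)
        if (widths[i] <= w) next
        off <- sample.int(widths[i] - w, 1L)  # 1-based offset in region
        inst <- sampleMotifInstance(m)
        pos <- start[i] + off - 1L
        substr(seqs[[chrom_of[i]]], pos, pos + w - 1L) <- inst
        ins[[length(ins) + 1L]] <- data.frame(
          region = names(regions)[i], motif = motifName(m),
          offset = off - 1L, stringsAsFactors = FALSE)
      }
    }
    motifTruth <- if (length(ins)) do.call(rbind, ins)
      else data.frame(region = character(), motif = character(),
                      offset = integer())
    list(genome = Biostrings::DNAStringSet(unlist(seqs)),
         regions = regions, truth = truth, motifTruth = motifTruth,
         panel = panel)
  })
}

#' Simulate an input library and UMI-tagged reporter fragments
#'
#' Unique reporter molecules are drawn per region, replicate and condition
#' with expectation `depth * fold(condition)`; each molecule receives a
#' random UMI (collisions possible, as with real random-mers) and one of a
#' small set of fragment coordinate variants (start jitter within the
#' region), and is emitted as `1 + Geometric` duplicate reads so the mean
#' read multiplicity equals `pcrDuplicationRate`. With `jackpot = TRUE` a
#' single molecule of the first inactive region is amplified
#' `jackpotReads`-fold, emulating the PCR jackpot artefacts that UMI
#' filtering is designed to remove.
#'
#' @param config a [SynthConfig-class].
#' @param sim output of [simulateGenome()] for the same config.
#' @return list with `fragments` (read-level data.frame: chrom, start, end,
#'   strand, umi, replicate, condition, molecule_id), `molecules`
#'   (pre-PCR ground truth, one row per unique molecule incl. `reads`),
#'   `input` (input-library fragment rows), and `jackpotRegion` /
#'   `jackpotReplicate` (NA unless a jackpot was planted).
#' @export
simulateReporterLibrary <- function(config, sim) {
  validObject(config)
  regions <- sim$regions
  truth <- sim$truth
  withSeed(config@seed + 1L, {
    n <- length(regions)
    chrom <- as.character(GenomicRanges::seqnames(regions))
    rstart <- GenomicRanges::start(regions)
    rwidth <- GenomicRanges::width(regions)

    ## fragment coordinate variants per region
    nVar <- 1L + rpois(n, max(0, config@fragVariants - 1))
    vl <- lapply(seq_len(n), function(i) {
      vw <- pmax(50L, pmin(rwidth[i],
        as.integer(round(rwidth[i] * runif(nVar[i], 0.7, 1)))))
      vs <- rstart[i] + vapply(rwidth[i] - vw, function(s)
        if (s > 0) sample.int(s, 1L) else 0L, integer(1))
      data.table::data.table(region = i, vstart = vs, vend = vs + vw - 1L)
    })
    variants <- data.table::rbindlist(vl)
    variants[, variant := seq_len(.N)]

    ## input library rows
    icount <- rpois(n, config@inputDepth)
    pick <- unlist(lapply(seq_len(n), function(i) {
      vi <- variants[variants$region == i, ]$variant
      if (icount[i] == 0L) integer()
      else vi[sample.int(length(vi), icount[i], replace = TRUE)]
    }))
    input <- variants[match(pick, variants$variant), ]
    input_df <- data.frame(chrom = chrom[input$region],
                           start = input$vstart, end = input$vend,
                           strand = "+", region = names(regions)[input$region],
                           stringsAsFactors = FALSE)

    ## reporter molecules
    fold <- cbind(LIF = truth$fold_lif, RA = truth$fold_ra)
    grids <- expand.grid(region = seq_len(n),
                         replicate = seq_len(config@nReplicates),
                         condition = config@conditions,
                         stringsAsFactors = FALSE)
    mcount <- rpois(nrow(grids),
                    config@depth * fold[cbind(grids$region,
                                              match(grids$condition,
                                                    colnames(fold)))])
    mol <- data.table::data.table(
      region = rep(grids$region, mcount),
      replicate = rep(grids$replicate, mcount),
      condition = rep(grids$condition, mcount))
    nm <- nrow(mol)
    mol[, molecule_id := seq_len(nm)]
    pickv <- unlist(lapply(seq_len(nrow(grids)), function(g) {
      i <- grids$region[g]
      vi <- variants[variants$region == i, ]$variant
      if (mcount[g] == 0L) integer()
      else vi[sample.int(length(vi), mcount[g], replace = TRUE)]
    }))
    mol[, variant := pickv]
    mol[, umi := do.call(paste0, lapply(seq_len(config@umiLength),
      function(i) sample(DNA_BASES4, nm, replace = TRUE)))]
    if (config@pcrDuplicationRate > 1) {
      mol[, reads := 1L + rgeom(nm, 1 / config@pcrDuplicationRate)]
    } else mol[, reads := 1L]

    jackpotRegion <- NA_character_
    jackpotReplicate <- NA_integer_
    if (config@jackpot) {
      inactive <- which(!truth$is_active)
      if (length(inactive) == 0L) stop("jackpot needs an inactive region")
      jr <- inactive[1L]
      jackpotRegion <- names(regions)[jr]
      jm <- which(mol$region == jr)[1L]
      if (!is.na(jm)) {
        mol[jm, reads := config@jackpotReads]
        jackpotReplicate <- mol$replicate[jm]
      }
    }

    frag_idx <- rep(seq_len(nm), mol$reads)
    fr <- mol[frag_idx, ]
    vmap <- variants[match(fr$variant, variants$variant), ]
    fragments <- data.frame(chrom = chrom[fr$region],
                            start = vmap$vstart, end = vmap$vend,
                            strand = "+", umi = fr$umi,
                            replicate = fr$replicate,
                            condition = fr$condition,
                            molecule_id = fr$molecule_id,
                            region = names(regions)[fr$region],
                            stringsAsFactors = FALSE)
    molecules <- data.frame(chrom = chrom[mol$region],
                            start = variants$vstart[match(mol$variant,
                                                          variants$variant)],
                            end = variants$vend[match(mol$variant,
                                                      variants$variant)],
                            strand = "+", umi = mol$umi,
                            replicate = mol$replicate,
                            condition = mol$condition,
                            molecule_id = mol$molecule_id,
                            region = names(regions)[mol$region],
                            reads = mol$reads, stringsAsFactors = FALSE)
    list(fragments = fragments, molecules = molecules, input = input_df,
         jackpotRegion = jackpotRegion, jackpotReplicate = jackpotReplicate)
  })
}

HM_MARKS <- c("H3K4me1", "H3K4me3", "H3K27ac", "H3K122ac",
              "H3K36me3", "H3K79me2", "H3K27me3", "H3K9me3")

#' Simulate a histone-modification enrichment matrix with planted clusters
#'
#' Each planted cluster has a distinct mean vector over the eight marks
#' (signature marks at enrichment 3, others at 0) plus Gaussian noise, so
#' cluster recovery can be scored against the returned labels.
#'
#' @param config a [SynthConfig-class] (uses `nHmClusters`, `hmNoiseSd`,
#'   `seed`).
#' @param regions a `GRanges` (rows of the matrix) or an integer count.
#' @return list with `matrix` (regions x 8 marks) and `labels` (planted
#'   cluster of each row).
#' @export
simulateHmMatrix <- function(config, regions) {
  validObject(config)
  n <- if (is.numeric(regions)) as.integer(regions) else length(regions)
  rn <- if (is.numeric(regions)) sprintf("region_%04d", seq_len(n))
        else names(regions)
  k <- config@nHmClusters
  withSeed(config@seed + 2L, {
    mu <- matrix(0, k, length(HM_MARKS))
    for (c in seq_len(k))
      mu[c, ((seq_along(HM_MARKS) - c) %% k) == 0] <- 3
    labels <- sample.int(k, n, replace = TRUE)
    mat <- mu[labels, , drop = FALSE] +
      matrix(rnorm(n * length(HM_MARKS), sd = config@hmNoiseSd), n)
    dimnames(mat) <- list(rn, HM_MARKS)
    list(matrix = mat, labels = labels)
  })
}

#' Simulate labeled sequences with planted motifs
#'
#' A stand-alone fixture generator for motif-enrichment and classifier
#' recovery experiments: equal numbers of "active" and "inactive"
#' sequences, with driver motifs inserted at probability `pActive` into
#' active and `pInactive` into inactive sequences (neutral panel members at
#' `pInactive` everywhere), and active sequences drawn slightly wider, as
#' observed for high-activity enhancers (385 vs 338 bp medians).
#'
#' @param nPerClass sequences per class.
#' @param panel list of [MotifMatrix-class]; driver motifs are those whose
#'   name starts with `"driver"`.
#' @param pActive,pInactive insertion probabilities.
#' @param widthActive,widthInactive median widths (log-normal, sdlog 0.25).
#' @param gc background GC content.
#' @param seed integer seed.
#' @return list with `sequences` (`DNAStringSet`), `labels` (factor
#'   active/inactive), `widths`, and `insertions` (data.frame seq, motif).
#' @export
simulateLabeledSequences <- function(nPerClass = 300L,
                                     panel = defaultMotifPanel(),
                                     pActive = 0.6, pInactive = 0.1,
                                     widthActive = 385, widthInactive = 338,
                                     gc = 0.45, seed = 1L) {
  withSeed(seed, {
    n <- 2L * nPerClass
    labels <- factor(rep(c("active", "inactive"), each = nPerClass),
                     levels = c("active", "inactive"))
    widths <- as.integer(round(exp(rnorm(n,
      log(ifelse(labels == "active", widthActive, widthInactive)), 0.25))))
    widths <- pmax(widths, 60L)
    seqs <- vapply(widths, function(w)
      paste(sampleBases(w, gc), collapse = ""), character(1))
    ins <- list()
    for (m in panel) {
      driver <- startsWith(motifName(m), "driver")
      p <- ifelse(labels == "active" & driver, pActive, pInactive)
      hit <- which(runif(n) < p)
      for (i in hit) {
        w <- motifWidth(m)
        if (widths[i] <= w) next
        off <- sample.int(widths[i] - w, 1L)
        substr(seqs[i], off, off + w - 1L) <- sampleMotifInstance(m)
        ins[[length(ins) + 1L]] <- data.frame(seq = i,
          motif = motifName(m), stringsAsFactors = FALSE)
      }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- sprintf("seq_%04d", seq_len(n))
    list(sequences = out, labels = labels, widths = widths,
         insertions = if (length(ins)) do.call(rbind, ins)
           else data.frame(seq = integer(), motif = character()))
  })
}
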